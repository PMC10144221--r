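# Flow-cytometry live/dead viability: event loading, debris and
# agglomerate exclusion by a rectangular scatter gate, live/dead
# classification by green (calcein) / red (PI) thresholds, and the
# viability ratio live / (live + dead).

#' Construct a flow-cytometry event table
#'
#' @param events A data frame (or list) with numeric columns `fsc`
#'   (forward scatter), `ssc` (side scatter), `green` (calcein-AM
#'   channel) and `red` (PI channel), arbitrary linear units.
#' @param channel_map Optional named character vector mapping the
#'   required names to column names present in `events`, e.g.
#'   `c(green = "FL1-A", red = "FL3-A")`.
#' @return An object of class `event_table` (a data frame).
#' @export
event_table <- function(events, channel_map = NULL) {
  events <- as.data.frame(events)
  need <- c("fsc", "ssc", "green", "red")
  if (!is.null(channel_map))
    for (nm in names(channel_map)) {
      if (!channel_map[[nm]] %in% names(events))
        stop("channel not found: ", channel_map[[nm]])
      names(events)[names(events) == channel_map[[nm]]] <- nm
    }
  missing <- setdiff(need, names(events))
  if (length(missing))
    stop("channel not found: ", paste(missing, collapse = ", "))
  events <- events[need]
  if (!nrow(events)) stop("invalid events: no rows")
  if (!all(vapply(events, is.numeric, logical(1))))
    stop("invalid events: channels must be numeric")
  class(events) <- c("event_table", "data.frame")
  events
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Event table: %d events, channels %s\n", nrow(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Read flow-cytometry events from FCS or CSV
#'
#' FCS 3.0/3.1 list-mode files with linear float or integer data are
#' supported, as is a CSV fallback with columns `fsc,ssc,green,red`
#' (or any names remapped through `channel_map`).
#'
#' @param path Path to a `.fcs` or `.csv` file.
#' @param channel_map Optional channel-name mapping, see
#'   [event_table()].
#' @return An `event_table`.
#' @export
read_events <- function(path, channel_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "fcs") return(read_fcs(path, channel_map))
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop("parse error: ", conditionMessage(e)))
  event_table(d, channel_map)
}

#' Rectangular gating configuration
#'
#' @param fsc_bounds,ssc_bounds Length-2 lower/upper scatter-gate
#'   bounds; events outside either interval are excluded as debris or
#'   agglomerates.
#' @param red_threshold Red (PI) intensity above which an event is
#'   dead.
#' @param green_threshold Green (calcein) intensity above which an
#'   event is live (when not red).
#' @param double_positive How to classify events above both thresholds:
#'   `"dead"` (default; PI entry indicates a compromised membrane) or
#'   `"live"`.
#' @return An object of class `gating_config`.
#' @export
gating_config <- function(fsc_bounds, ssc_bounds, red_threshold,
                          green_threshold,
                          double_positive = c("dead", "live")) {
  double_positive <- match.arg(double_positive)
  for (b in list(fsc_bounds, ssc_bounds))
    if (length(b) != 2 || !b[1] < b[2])
      stop("invalid gate: bounds must be increasing length-2")
  if (red_threshold <= 0 || green_threshold <= 0)
    stop("invalid gate: thresholds must be > 0")
  structure(list(fsc_bounds = fsc_bounds, ssc_bounds = ssc_bounds,
                 red_threshold = red_threshold,
                 green_threshold = green_threshold,
                 double_positive = double_positive),
            class = "gating_config")
}

#' Percentile-based default scatter gate
#'
#' Without instrument calibration, scatter bounds default to pooled
#' scatter percentiles; tighten them to the visible cell cluster to
#' exclude debris and agglomerates.
#'
#' @param events An `event_table`.
#' @param probs Lower/upper percentile, default `c(0.01, 0.99)`.
#' @return A list with `fsc_bounds` and `ssc_bounds`.
#' @export
default_scatter_gate <- function(events, probs = c(0.01, 0.99)) {
  stopifnot(inherits(events, "event_table"))
  list(fsc_bounds = unname(stats::quantile(events$fsc, probs)),
       ssc_bounds = unname(stats::quantile(events$ssc, probs)))
}

#' Derive the dead-cell red threshold from a killed control
#'
#' The control sample contains fixated and permeabilized (all-dead)
#' cells stained with PI; the returned threshold is the `quantile`
#' lower quantile of its red-channel distribution after scatter
#' gating, so at least `1 - quantile` of known-dead events classify as
#' dead.
#'
#' @param control An `event_table` of the all-dead control (>= 100
#'   events).
#' @param quantile Lower quantile, default 0.01.
#' @param fsc_bounds,ssc_bounds Optional scatter gate applied first.
#' @return The red threshold (intensity units).
#' @export
derive_dead_threshold <- function(control, quantile = 0.01,
                                  fsc_bounds = NULL, ssc_bounds = NULL) {
  stopifnot(inherits(control, "event_table"))
  keep <- rep(TRUE, nrow(control))
  if (!is.null(fsc_bounds))
    keep <- keep & control$fsc >= fsc_bounds[1] & control$fsc <= fsc_bounds[2]
  if (!is.null(ssc_bounds))
    keep <- keep & control$ssc >= ssc_bounds[1] & control$ssc <= ssc_bounds[2]
  red <- control$red[keep]
  if (length(red) < 100) stop("insufficient control")
  unname(stats::quantile(red, quantile, type = 7))
}

#' Gate events and classify live/dead
#'
#' Events outside the rectangular scatter gate are excluded (debris and
#' agglomerates).  Remaining events are classified dead if red exceeds
#' the red threshold (including double positives when
#' `double_positive = "dead"`), live if green exceeds the green
#' threshold and red does not, and unclassified (double negative)
#' otherwise.
#'
#' @param events An `event_table`.
#' @param config A `gating_config`.
#' @return An object of class `gated_events`: `events` (the in-gate
#'   table with a `class` column), counts `n_live`, `n_dead`,
#'   `n_unclassified`, `n_excluded`, `fraction_excluded`, and the
#'   `config`.
#' @export
gate <- function(events, config) {
  stopifnot(inherits(events, "event_table"),
            inherits(config, "gating_config"))
  inside <- events$fsc >= config$fsc_bounds[1] &
            events$fsc <= config$fsc_bounds[2] &
            events$ssc >= config$ssc_bounds[1] &
            events$ssc <= config$ssc_bounds[2]
  if (!any(inside)) stop("all events excluded")
  g <- events[inside, , drop = FALSE]
  red_hi <- g$red > config$red_threshold
  green_hi <- g$green > config$green_threshold
  cls <- rep("unclassified", nrow(g))
  if (config$double_positive == "dead") {
    cls[red_hi] <- "dead"
    cls[green_hi & !red_hi] <- "live"
  } else {
    cls[green_hi] <- "live"
    cls[red_hi & !green_hi] <- "dead"
  }
  g$class <- cls
  structure(list(events = g,
                 n_live = sum(cls == "live"),
                 n_dead = sum(cls == "dead"),
                 n_unclassified = sum(cls == "unclassified"),
                 n_excluded = sum(!inside),
                 fraction_excluded = mean(!inside),
                 config = config),
            class = "gated_events")
}

#' @export
print.gated_events <- function(x, ...) {
  cat(sprintf(paste0("Gated events: %d live, %d dead, %d unclassified; ",
                     "%.1f%% excluded by scatter gate\n"),
              x$n_live, x$n_dead, x$n_unclassified,
              100 * x$fraction_excluded))
  invisible(x)
}

#' Cell viability from gated events
#'
#' Viability is the number of live cells divided by the total number of
#' cells (live + dead); unclassified double-negative events are not
#' cells and are excluded from the denominator.
#'
#' @param gated A `gated_events`.
#' @param conf_level Confidence level of the binomial interval.
#' @return An object of class `viability_result`: `n_live`, `n_dead`,
#'   `viability`, `fraction_excluded`, and the exact binomial `ci`.
#' @export
viability <- function(gated, conf_level = 0.95) {
  stopifnot(inherits(gated, "gated_events"))
  n <- gated$n_live + gated$n_dead
  if (n == 0) stop("no cells after gating")
  ci <- stats::binom.test(gated$n_live, n,
                          conf.level = conf_level)$conf.int
  structure(list(n_live = gated$n_live, n_dead = gated$n_dead,
                 viability = gated$n_live / n,
                 fraction_excluded = gated$fraction_excluded,
                 ci = as.numeric(ci), conf_level = conf_level),
            class = "viability_result")
}

#' @export
print.viability_result <- function(x, ...) {
  cat(sprintf("Viability: %.1f%% (%d live / %d cells; %g%% CI %.1f-%.1f%%)\n",
              100 * x$viability, x$n_live, x$n_live + x$n_dead,
              100 * x$conf_level, 100 * x$ci[1], 100 * x$ci[2]))
  invisible(x)
}
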