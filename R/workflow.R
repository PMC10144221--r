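# Batch orchestration, replicate aggregation, first-order uncertainty
# propagation and the statistics used on printing-accuracy data sets:
# Jarque-Bera normality checks and one-way ANOVA across formulations.

#' First-order (Taylor) uncertainty propagation
#'
#' For a quantity f(x_1, ..., x_k) with independent input standard
#' deviations sigma_i and sensitivity coefficients c_i = df/dx_i, the
#' propagated standard deviation is sqrt(sum((c_i sigma_i)^2)).  The
#' normalized metrics are linear in their measured inputs, so the
#' first-order result is exact for them:
#' r_n uses c = 1/(2 r_model) for both radii, a_n uses
#' c = 1/(2 a_model) for both angles, and w_n uses c = 1/d_nozzle.
#'
#' @param coefficients Sensitivity coefficients c_i (partial
#'   derivatives), length >= 1.
#' @param sds Input standard deviations sigma_i >= 0, same length.
#' @return The propagated standard deviation.
#' @export
#' @examples
#' propagate_uncertainty(c(1, 1) / 30, c(0.03, 0.03))  # r_n, r_model 15
propagate_uncertainty <- function(coefficients, sds) {
  if (length(coefficients) != length(sds) || !length(sds))
    stop("invalid input: coefficient/sd length mismatch")
  if (any(sds < 0)) stop("invalid input: negative sd")
  sqrt(sum((coefficients * sds)^2))
}

#' Jarque-Bera test of normality
#'
#' JB = n/6 (S^2 + (K - 3)^2 / 4) with sample skewness S and kurtosis
#' K; under normality JB is asymptotically chi-squared with 2 degrees
#' of freedom.
#'
#' @param x Numeric vector, length >= 4, non-degenerate.
#' @return An object of class `htest` with `statistic` and `p.value`.
#' @export
jarque_bera <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("invalid input: need >= 4 observations")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) stop("invalid input: constant sample")
  S <- mean((x - m)^3) / s2^1.5
  K <- mean((x - m)^4) / s2^2
  jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
  structure(list(statistic = c(JB = jb), parameter = c(df = 2),
                 p.value = stats::pchisq(jb, 2, lower.tail = FALSE),
                 method = "Jarque-Bera normality test",
                 data.name = deparse(substitute(x))),
            class = "htest")
}

#' Aggregate replicate metrics and compare formulations
#'
#' Per formulation and metric: mean, standard deviation, n and a
#' Jarque-Bera normality p-value (alpha 0.05).  Across formulations:
#' one-way ANOVA per metric with a significance flag at p < 0.05, plus
#' unadjusted pairwise t comparisons (each comparison is tested at its
#' own alpha; no multiple-testing correction is applied, which is
#' noted in pipeline reports).
#'
#' @param data Data frame with a `formulation` column and numeric
#'   metric columns (e.g. the output of [metrics_row()] rows bound
#'   together, or a pipeline `metrics.csv`).
#' @param metrics Metric column names; defaults to every numeric
#'   column except `replicate`.
#' @return An object of class `aggregate_result`: `groups` (per
#'   formulation x metric summary), `anova` (per metric), `pairwise`
#'   (per metric pair comparisons).
#' @export
aggregate_metrics <- function(data, metrics = NULL) {
  data <- as.data.frame(data)
  if (!"formulation" %in% names(data))
    stop("invalid input: 'formulation' column required")
  if (is.null(metrics))
    metrics <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                       c("replicate"))
  if (!length(metrics)) stop("no data for group")
  data$formulation <- factor(data$formulation)
  groups <- list(); anv <- list(); pw <- list()
  for (mcol in metrics) {
    for (g in levels(data$formulation)) {
      v <- data[[mcol]][data$formulation == g]
      v <- v[is.finite(v)]
      if (!length(v)) next
      jb_p <- if (length(v) >= 4 && stats::sd(v) > 0)
        jarque_bera(v)$p.value else NA_real_
      groups[[length(groups) + 1]] <- data.frame(
        formulation = g, metric = mcol, mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        n = length(v), jb_p = jb_p,
        normal = if (is.na(jb_p)) NA else jb_p >= 0.05)
    }
    sub <- data[is.finite(data[[mcol]]), c("formulation", mcol)]
    sub$formulation <- droplevels(sub$formulation)
    applicable <- nlevels(sub$formulation) >= 2 &&
      all(tapply(sub[[mcol]], sub$formulation, length) >= 2) &&
      stats::sd(sub[[mcol]]) > 0
    if (applicable) {
      fit <- stats::lm(sub[[mcol]] ~ sub$formulation)
      p <- stats::anova(fit)[["Pr(>F)"]][1]
      anv[[length(anv) + 1]] <- data.frame(
        metric = mcol, p = p, significant = p < 0.05, applicable = TRUE)
      pt <- stats::pairwise.t.test(sub[[mcol]], sub$formulation,
                                   p.adjust.method = "none",
                                   pool.sd = FALSE)
      pv <- as.data.frame(as.table(pt$p.value))
      pv <- pv[!is.na(pv$Freq), ]
      if (nrow(pv))
        pw[[length(pw) + 1]] <- data.frame(
          metric = mcol, group1 = as.character(pv$Var1),
          group2 = as.character(pv$Var2), p = pv$Freq,
          significant = pv$Freq < 0.05)
    } else {
      anv[[length(anv) + 1]] <- data.frame(
        metric = mcol, p = NA_real_, significant = NA, applicable = FALSE)
    }
  }
  structure(list(groups = do.call(rbind, groups),
                 anova = do.call(rbind, anv),
                 pairwise = if (length(pw)) do.call(rbind, pw) else NULL),
            class = "aggregate_result")
}

#' @export
print.aggregate_result <- function(x, ...) {
  cat("Per-group summaries:\n")
  print(x$groups, row.names = FALSE, digits = 4)
  cat("\nOne-way ANOVA across formulations:\n")
  print(x$anova, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Batch configuration for the analysis pipeline
#'
#' @param formulations Unique formulation labels.
#' @param cad Named list of [cad_target()]s by structure kind.
#' @param binarize_params List of [binarize()] parameters.  The default
#'   threshold offset of 10 intensity units suits dark-background
#'   photographs with a foreground/background contrast of about 180;
#'   set 0 for noise-free masks.
#' @param min_area_mm2 Debris filter, mm^2.
#' @param seed Integer seed recorded with the run.
#' @param out_dir Output directory for reports.
#' @return An object of class `batch_config`.
#' @export
batch_config <- function(formulations,
                         cad = list(line = cad_target("line"),
                                    circle = cad_target("circle"),
                                    angle = cad_target("angle")),
                         binarize_params = list(median_window = 3,
                                                threshold_window = 101,
                                                threshold_offset = 10),
                         min_area_mm2 = 0.2, seed = 1,
                         out_dir = tempfile("printability_run_")) {
  if (anyDuplicated(formulations)) stop("invalid config: duplicate labels")
  structure(list(formulations = formulations, cad = cad,
                 binarize_params = binarize_params,
                 min_area_mm2 = min_area_mm2, seed = seed,
                 out_dir = out_dir),
            class = "batch_config")
}

#' Run the full analysis pipeline over a batch of inputs
#'
#' Images are binarized, segmented and analyzed according to their
#' structure kind; viscosity CSVs are fitted; event files are gated
#' and reduced to viability.  Failures are isolated per item: a
#' corrupt input is flagged in the report and the remaining items are
#' processed.  Reports (`metrics.csv`, `aggregate.csv`,
#' `viability.csv`, `report.json`, `run.log`) are written to
#' `config$out_dir`; identical inputs and configuration produce
#' byte-identical CSVs.
#'
#' @param config A [batch_config()].
#' @param images Data frame with columns `path`, `kind`,
#'   `formulation`, `replicate` (optional).
#' @param curves Data frame with columns `path`, `formulation`
#'   (optional), for rheometer CSVs.
#' @param events Data frame with columns `path`, `formulation`,
#'   plus gating columns `fsc_lo`, `fsc_hi`, `ssc_lo`, `ssc_hi`,
#'   `red_threshold`, `green_threshold` (optional).
#' @return An object of class `pipeline_result`: `metrics`,
#'   `aggregate`, `viability`, `fits`, `failures`, `ok` (TRUE when no
#'   item failed) and the output directory.
#' @export
run_pipeline <- function(config, images = NULL, curves = NULL,
                         events = NULL) {
  stopifnot(inherits(config, "batch_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = logf, append = TRUE)
  cat("", file = logf)
  failures <- list(); metric_rows <- list()
  if (!is.null(images)) for (i in seq_len(nrow(images))) {
    it <- images[i, , drop = FALSE]
    res <- tryCatch({
      img <- read_gray_image(it$path)
      bin <- do.call(binarize, c(list(img), config$binarize_params))
      seg <- segment_components(crop_roi(bin, it$kind,
                                         min_area_mm2 = config$min_area_mm2),
                                config$min_area_mm2)
      m <- analyze_structure(seg, config$cad[[it$kind]])
      row <- metrics_row(m)
      row$formulation <- it$formulation
      row$replicate <- if ("replicate" %in% names(it)) it$replicate else i
      row$path <- it$path
      row
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log_line("FAIL image %s: %s", it$path, conditionMessage(res))
      failures[[length(failures) + 1]] <-
        data.frame(stage = "image", path = it$path,
                   error = conditionMessage(res))
    } else {
      log_line("ok image %s (%s)", it$path, it$kind)
      metric_rows[[length(metric_rows) + 1]] <- res
    }
  }
  metrics_df <- if (length(metric_rows)) {
    cols <- unique(unlist(lapply(metric_rows, names)))
    do.call(rbind, lapply(metric_rows, function(r) {
      r[setdiff(cols, names(r))] <- NA
      r[cols]
    }))
  } else NULL
  fits <- list()
  if (!is.null(curves)) for (i in seq_len(nrow(curves))) {
    it <- curves[i, , drop = FALSE]
    res <- tryCatch(fit_power_law(read_viscosity_csv(it$path)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      log_line("FAIL curve %s: %s", it$path, conditionMessage(res))
      failures[[length(failures) + 1]] <-
        data.frame(stage = "curve", path = it$path,
                   error = conditionMessage(res))
    } else {
      log_line("ok curve %s: n=%.4g K=%.5g", it$path, res$n, res$K)
      fits[[length(fits) + 1]] <-
        list(path = it$path,
             formulation = if ("formulation" %in% names(it))
               it$formulation else NA,
             model = res)
    }
  }
  viab_rows <- list()
  if (!is.null(events)) for (i in seq_len(nrow(events))) {
    it <- events[i, , drop = FALSE]
    res <- tryCatch({
      ev <- read_events(it$path)
      cfg <- gating_config(c(it$fsc_lo, it$fsc_hi),
                           c(it$ssc_lo, it$ssc_hi),
                           it$red_threshold, it$green_threshold)
      v <- viability(gate(ev, cfg))
      data.frame(path = it$path, formulation = it$formulation,
                 n_live = v$n_live, n_dead = v$n_dead,
                 viability = v$viability,
                 fraction_excluded = v$fraction_excluded)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log_line("FAIL events %s: %s", it$path, conditionMessage(res))
      failures[[length(failures) + 1]] <-
        data.frame(stage = "events", path = it$path,
                   error = conditionMessage(res))
    } else {
      log_line("ok events %s: viability %.3f", it$path, res$viability)
      viab_rows[[length(viab_rows) + 1]] <- res
    }
  }
  viab_df <- if (length(viab_rows)) do.call(rbind, viab_rows) else NULL
  agg <- NULL
  if (!is.null(metrics_df) &&
      length(unique(metrics_df$formulation)) >= 1) {
    num <- setdiff(names(metrics_df)[vapply(metrics_df, is.numeric,
                                            logical(1))], "replicate")
    agg <- tryCatch(aggregate_metrics(metrics_df, num),
                    error = function(e) NULL)
  }
  if (!is.null(metrics_df))
    utils::write.csv(metrics_df,
                     file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE)
  if (!is.null(agg)) {
    utils::write.csv(cbind(agg$groups,
                           note = "p-values unadjusted (per-comparison alpha 0.05)"),
                     file.path(config$out_dir, "aggregate.csv"),
                     row.names = FALSE)
  }
  if (!is.null(viab_df))
    utils::write.csv(viab_df, file.path(config$out_dir, "viability.csv"),
                     row.names = FALSE)
  report <- list(
    seed = config$seed,
    n_images = if (is.null(images)) 0 else nrow(images),
    n_curves = if (is.null(curves)) 0 else nrow(curves),
    n_events = if (is.null(events)) 0 else nrow(events),
    n_failures = length(failures),
    fits = lapply(fits, function(f)
      list(path = f$path, n = f$model$n, K = f$model$K,
           r_squared = f$model$r_squared)),
    anova = if (!is.null(agg)) agg$anova else NULL,
    note = "pairwise p-values are unadjusted; alpha 0.05 per comparison")
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 8, force = TRUE)
  structure(list(metrics = metrics_df, aggregate = agg,
                 viability = viab_df, fits = fits,
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 ok = length(failures) == 0,
                 out_dir = config$out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run: %d metric rows, %d viability rows, %d failures\n",
              if (is.null(x$metrics)) 0 else nrow(x$metrics),
              if (is.null(x$viability)) 0 else nrow(x$viability),
              if (is.null(x$failures)) 0 else nrow(x$failures)))
  cat("Reports in ", x$out_dir, "\n")
  invisible(x)
}
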