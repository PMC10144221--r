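# Rheology: Ostwald-de Waele fitting and power-law Hagen-Poiseuille
# pressure/flow planning for a cylindrical nozzle.
#
# Unit policy: every public interface uses mm, s, kPa and Pa.s^n.  The
# R^(n+1) term of the pressure formula makes the computation extremely
# unit-sensitive, so all physics is evaluated in SI (m, Pa, s) inside a
# single conversion layer and converted back at the boundary.

#' Construct a viscosity curve
#'
#' A viscosity curve holds apparent viscosity eta (Pa.s) measured as a
#' function of shear rate gamma-dot (1/s), as exported by a rotational
#' rheometer.
#'
#' @param shear_rates Numeric vector of shear rates, 1/s. Strictly
#'   positive and strictly increasing, length >= 3.
#' @param viscosities Numeric vector of apparent viscosities, Pa.s,
#'   strictly positive, same length as `shear_rates`.
#' @param replicate Optional free-text replicate label.
#' @return An object of class `viscosity_curve`.
#' @export
#' @examples
#' g <- 10^seq(-1, 3, length.out = 20)
#' viscosity_curve(g, 146.39 * g^(0.35 - 1))
viscosity_curve <- function(shear_rates, viscosities, replicate = NA_character_) {
  shear_rates <- as.numeric(shear_rates)
  viscosities <- as.numeric(viscosities)
  if (length(shear_rates) != length(viscosities) || length(shear_rates) < 3)
    stop("invalid curve: need >= 3 matching shear-rate/viscosity pairs")
  if (anyNA(shear_rates) || anyNA(viscosities) ||
      any(shear_rates <= 0) || any(viscosities <= 0))
    stop("invalid curve: shear rates and viscosities must be positive")
  if (any(diff(shear_rates) <= 0))
    stop("invalid curve: shear rates must be strictly increasing")
  structure(list(shear_rates = shear_rates, viscosities = viscosities,
                 replicate = as.character(replicate)),
            class = "viscosity_curve")
}

#' @export
print.viscosity_curve <- function(x, ...) {
  cat(sprintf("Viscosity curve (%d points, %.3g-%.3g 1/s)",
              length(x$shear_rates), min(x$shear_rates), max(x$shear_rates)))
  if (!is.na(x$replicate)) cat(", replicate", x$replicate)
  cat("\n")
  invisible(x)
}

#' Read rheometer viscosity curves from CSV
#'
#' Expects columns `shear_rate_1_per_s` and `viscosity_Pa_s`, plus an
#' optional `replicate` column; one curve is returned per replicate
#' level (a single `viscosity_curve` when there is only one).
#'
#' @param path Path to a CSV file with a header row, decimal point.
#' @return A `viscosity_curve`, or a list of them for multi-replicate files.
#' @export
read_viscosity_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("shear_rate_1_per_s", "viscosity_Pa_s")
  if (!all(need %in% names(d)))
    stop("invalid curve: columns ", paste(need, collapse = ", "), " required")
  if (!"replicate" %in% names(d)) d$replicate <- "1"
  curves <- lapply(split(d, d$replicate), function(g) {
    g <- g[order(g$shear_rate_1_per_s), ]
    viscosity_curve(g$shear_rate_1_per_s, g$viscosity_Pa_s, g$replicate[1])
  })
  if (length(curves) == 1) curves[[1]] else unname(curves)
}

#' Construct a power-law (Ostwald-de Waele) model directly
#'
#' eta = K * gamma-dot^(n-1), with flow-behavior exponent `n`
#' (dimensionless) and consistency index `K` (Pa.s^n).
#'
#' @param n Flow-behavior exponent, > 0 (n < 1: shear thinning).
#' @param K Consistency index, Pa.s^n, > 0.
#' @param fit_range Shear-rate interval the model refers to, 1/s.
#' @param r_squared Coefficient of determination of the log-log fit.
#' @return An object of class `power_law`.
#' @export
power_law <- function(n, K, fit_range = c(NA_real_, NA_real_),
                      r_squared = NA_real_) {
  if (!is.finite(n) || n <= 0) stop("invalid model: n must be > 0")
  if (!is.finite(K) || K <= 0) stop("invalid model: K must be > 0")
  structure(list(n = n, K = K, fit_range = as.numeric(fit_range),
                 r_squared = as.numeric(r_squared)),
            class = "power_law")
}

#' Fit the Ostwald-de Waele model to viscosity curves
#'
#' Ordinary least squares on log(eta) versus log(gamma-dot): the model
#' eta = K * gamma-dot^(n-1) is linear in log-log space with slope n - 1
#' and intercept log K.  Points outside `fit_range` are ignored, which
#' is how the low-shear viscosity plateau is excluded from the
#' shear-thinning fit; the default range starts at 1 1/s.
#'
#' @param curve A `viscosity_curve` or a list of them (replicates are
#'   pooled into one regression).
#' @param fit_range Length-2 shear-rate interval (1/s) delimiting the
#'   shear-thinning regime to fit.
#' @return A `power_law` model with `n`, `K`, the realized `fit_range`
#'   and the log-log `r_squared`.
#' @seealso [required_pressure()], [flow_rate()], [viscosity_at()]
#' @export
#' @examples
#' g <- 10^seq(0, 3, length.out = 25)
#' fit <- fit_power_law(viscosity_curve(g, 284.09 * g^(0.32 - 1)))
#' coef(fit)
fit_power_law <- function(curve, fit_range = c(1, Inf)) {
  curves <- if (inherits(curve, "viscosity_curve")) list(curve) else curve
  if (!length(curves) || !all(vapply(curves, inherits, TRUE, "viscosity_curve")))
    stop("invalid curve: expected viscosity_curve or list of them")
  if (length(fit_range) != 2 || !fit_range[1] < fit_range[2])
    stop("invalid fit range")
  g <- unlist(lapply(curves, `[[`, "shear_rates"))
  e <- unlist(lapply(curves, `[[`, "viscosities"))
  keep <- g >= fit_range[1] & g <= fit_range[2]
  if (sum(keep) < 3) stop("insufficient data: fewer than 3 points in fit range")
  lg <- log(g[keep]); le <- log(e[keep])
  fit <- stats::lm(le ~ lg)
  b <- unname(stats::coef(fit))
  ss_tot <- sum((le - mean(le))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  r2 <- min(1, max(0, r2))
  power_law(n = b[2] + 1, K = exp(b[1]),
            fit_range = range(g[keep]), r_squared = r2)
}

#' @export
coef.power_law <- function(object, ...) c(n = object$n, K = object$K)

#' @export
print.power_law <- function(x, ...) {
  cat(sprintf("Ostwald-de Waele model: n = %.4g, K = %.6g Pa.s^n\n", x$n, x$K))
  if (!anyNA(x$fit_range))
    cat(sprintf("  fitted over %.3g-%.3g 1/s (R^2 = %.4f)\n",
                x$fit_range[1], x$fit_range[2], x$r_squared))
  invisible(x)
}

#' @export
summary.power_law <- function(object, ...) {
  print(object)
  if (object$n < 1) cat("  shear thinning (n < 1)\n")
  else if (object$n > 1) cat("  shear thickening (n > 1)\n")
  else cat("  Newtonian (n = 1)\n")
  invisible(object)
}

#' Predicted apparent viscosity at given shear rates
#'
#' @param object A `power_law` model.
#' @param shear_rate Shear rate(s), 1/s, > 0.
#' @param ... Unused.
#' @return Apparent viscosity, Pa.s.
#' @export
predict.power_law <- function(object, shear_rate, ...)
  viscosity_at(object, shear_rate)

#' @rdname predict.power_law
#' @param model A `power_law` model.
#' @export
viscosity_at <- function(model, shear_rate) {
  stopifnot(inherits(model, "power_law"))
  if (any(!is.finite(shear_rate)) || any(shear_rate <= 0))
    stop("invalid shear rate")
  model$K * shear_rate^(model$n - 1)
}

#' @export
plot.power_law <- function(x, curve = NULL, ...) {
  rng <- if (!anyNA(x$fit_range)) x$fit_range else c(0.1, 1000)
  g <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = 200)
  graphics::plot(g, viscosity_at(x, g), type = "l", log = "xy",
                 xlab = "shear rate (1/s)", ylab = "viscosity (Pa.s)", ...)
  if (inherits(curve, "viscosity_curve"))
    graphics::points(curve$shear_rates, curve$viscosities, pch = 1)
  invisible(x)
}

#' Cylindrical nozzle geometry
#'
#' @param radius Inner capillary radius R, mm. Default 0.305 mm
#'   (0.61 mm inner-diameter dispensing nozzle).
#' @param length Capillary length l, mm. Default 12.7 mm.
#' @return An object of class `nozzle_geometry`.
#' @export
nozzle_geometry <- function(radius = 0.305, length = 12.7) {
  if (!is.finite(radius) || radius <= 0) stop("invalid nozzle: radius must be > 0")
  if (!is.finite(length) || length <= 0) stop("invalid nozzle: length must be > 0")
  structure(list(radius = radius, length = length), class = "nozzle_geometry")
}

#' @export
print.nozzle_geometry <- function(x, ...) {
  cat(sprintf("Nozzle: R = %.3g mm, l = %.3g mm\n", x$radius, x$length))
  invisible(x)
}

# SI evaluation of Q = (n pi / (3n+1)) R^3 (R p / (2 K l))^(1/n), m^3/s
.flow_rate_si <- function(n, K, R, l, p)
  (n * pi / (3 * n + 1)) * R^3 * (R * p / (2 * K * l))^(1 / n)

#' Volumetric flow rate of a power-law fluid through the nozzle
#'
#' Power-law Hagen-Poiseuille relation for laminar flow of an
#' Ostwald-de Waele fluid through a cylindrical capillary:
#' Q = n pi / (3n + 1) * R^3 * (R p / (2 K l))^(1/n).
#' At n = 1 (K = mu) this reduces to the classical Q = pi R^4 p / (8 mu l).
#'
#' @param model A `power_law` model.
#' @param nozzle A `nozzle_geometry`.
#' @param pressure Pneumatic pressure drop p over the capillary, kPa, > 0.
#' @return Volumetric flow rate Q, mm^3/s.
#' @export
flow_rate <- function(model, nozzle, pressure) {
  stopifnot(inherits(model, "power_law"), inherits(nozzle, "nozzle_geometry"))
  if (any(!is.finite(pressure)) || any(pressure <= 0)) stop("invalid pressure")
  q_si <- .flow_rate_si(model$n, model$K, nozzle$radius * 1e-3,
                        nozzle$length * 1e-3, pressure * 1e3)
  q_si * 1e9                                  # m^3/s -> mm^3/s
}

#' Pneumatic pressure required for a target extrusion velocity
#'
#' Closed-form inversion of the power-law Hagen-Poiseuille relation at
#' Q = v.bar pi R^2: p = 2 K l / R * (v.bar (3n + 1) / (n R))^n.
#' The mean extrusion velocity v.bar is the nozzle-exit speed matched to
#' the print-head travel speed, so material deposition keeps pace with
#' the path.
#'
#' @param model A `power_law` model.
#' @param nozzle A `nozzle_geometry`.
#' @param mean_velocity Mean extrusion velocity v.bar, mm/s, > 0.
#' @return Required pressure, kPa.
#' @export
#' @examples
#' required_pressure(power_law(0.32, 284.09), nozzle_geometry(), 10)
required_pressure <- function(model, nozzle, mean_velocity) {
  stopifnot(inherits(model, "power_law"), inherits(nozzle, "nozzle_geometry"))
  if (any(!is.finite(mean_velocity)) || any(mean_velocity <= 0))
    stop("invalid velocity")
  R <- nozzle$radius * 1e-3; l <- nozzle$length * 1e-3
  v <- mean_velocity * 1e-3; n <- model$n
  p_si <- 2 * model$K * l / R * (v * (3 * n + 1) / (n * R))^n
  p_si * 1e-3                                 # Pa -> kPa
}

#' Extrusion plan: consistent pressure / velocity / flow-rate triple
#'
#' Given either the target mean velocity or the pneumatic pressure, the
#' remaining quantities are completed through the power-law
#' Hagen-Poiseuille relation and Q = v.bar pi R^2.
#'
#' @param model A `power_law` model.
#' @param nozzle A `nozzle_geometry`.
#' @param mean_velocity Mean extrusion velocity, mm/s (give this or
#'   `pressure`).
#' @param pressure Pneumatic pressure, kPa.
#' @return An object of class `extrusion_plan` with fields
#'   `mean_velocity` (mm/s), `pressure` (kPa), `flow_rate` (mm^3/s),
#'   `model` and `nozzle`.
#' @export
extrusion_plan <- function(model, nozzle = nozzle_geometry(),
                           mean_velocity = NULL, pressure = NULL) {
  stopifnot(inherits(model, "power_law"), inherits(nozzle, "nozzle_geometry"))
  if (is.null(mean_velocity) == is.null(pressure))
    stop("give exactly one of mean_velocity or pressure")
  if (is.null(pressure)) {
    pressure <- required_pressure(model, nozzle, mean_velocity)
  } else {
    if (!is.finite(pressure) || pressure <= 0) stop("invalid pressure")
    mean_velocity <- flow_rate(model, nozzle, pressure) / (pi * nozzle$radius^2)
  }
  structure(list(mean_velocity = mean_velocity, pressure = pressure,
                 flow_rate = mean_velocity * pi * nozzle$radius^2,
                 model = model, nozzle = nozzle),
            class = "extrusion_plan")
}

#' @export
print.extrusion_plan <- function(x, ...) {
  cat(sprintf(paste0("Extrusion plan: p = %.4g kPa, v = %.4g mm/s, ",
                     "Q = %.4g mm^3/s\n"),
              x$pressure, x$mean_velocity, x$flow_rate))
  print(x$model); print(x$nozzle)
  invisible(x)
}
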