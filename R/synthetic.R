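# Synthetic ground-truthed inputs for every analysis stage: rendered
# structure photographs, noisy viscosity curves, and cytometry event
# mixtures.  Every generated artifact carries a machine-readable ground
# truth so recovery tests never compare against hard-coded numbers.

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Rendering specification for a synthetic structure photograph
#'
#' Emulates the acquisition setup of single-layer structure
#' photography: printed material as a bright constant-width stroke
#' (round caps and joins) on a dark background, imaged by a monochrome
#' camera at a known pixel pitch, with optical blur, sensor noise and
#' an uneven-illumination ramp.
#'
#' @param cad A [cad_target()] describing the printed path.
#' @param stroke_width Deposited filament width, mm.
#' @param px_per_mm Pixel pitch, default 52.
#' @param fg,bg Foreground / background intensity, 8-bit levels
#'   (`fg > bg`).
#' @param blur_sigma Gaussian optical blur, mm.
#' @param noise_sigma Additive Gaussian sensor noise, intensity units.
#' @param illumination_gradient Linear intensity ramp across the frame
#'   width, intensity units.
#' @param gaps List of `c(position_mm, length_mm)` material gaps,
#'   positions measured along the path.
#' @param bulges List of `c(position_mm, extra_width_mm)` local bulges.
#' @param rotation Pose rotation, degrees.
#' @param translation Pose translation `c(dx, dy)`, mm.
#' @param actual_length Realized line length, mm (defaults to the CAD
#'   length; lets a "too short" print be rendered with known truth).
#' @param actual_radius Realized circle centerline radius, mm.
#' @param angle_offsets Per-vertex deviations added to the designed
#'   angles, degrees.
#' @param marker_angle Angular position of the circle start marker,
#'   degrees (before pose rotation).
#' @param margin_mm Background margin around the structure, mm.
#' @param seed Integer seed; renders are deterministic per seed.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(cad, stroke_width = 0.61, px_per_mm = 52,
                        fg = 200, bg = 20, blur_sigma = 0.02,
                        noise_sigma = 3, illumination_gradient = 10,
                        gaps = NULL, bulges = NULL,
                        rotation = 0, translation = c(0, 0),
                        actual_length = cad$line_length,
                        actual_radius = cad$circle_radius,
                        angle_offsets = 0,
                        marker_angle = 0, margin_mm = 3, seed = 1) {
  stopifnot(inherits(cad, "cad_target"))
  if (stroke_width <= 0) stop("invalid spec: stroke_width must be > 0")
  if (fg <= bg || fg > 255 || bg < 0)
    stop("invalid spec: need 0 <= bg < fg <= 255")
  structure(list(cad = cad, stroke_width = stroke_width,
                 px_per_mm = px_per_mm, fg = fg, bg = bg,
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 illumination_gradient = illumination_gradient,
                 gaps = gaps, bulges = bulges, rotation = rotation,
                 translation = translation,
                 actual_length = actual_length,
                 actual_radius = actual_radius,
                 angle_offsets = rep_len(angle_offsets,
                                         length(cad$designed_angles)),
                 marker_angle = marker_angle,
                 margin_mm = margin_mm, seed = seed),
            class = "render_spec")
}

# Zigzag centerline of the angle composite: consecutive segments of
# `seg_len` turning alternately so that vertex j has interior angle
# angles[j] (degrees).
.angle_path <- function(angles, seg_len = 10) {
  pos <- c(0, 0); heading <- 0
  pts <- matrix(pos, 1)
  sgn <- 1
  for (a in angles) {
    pos <- pos + seg_len * c(cos(heading), sin(heading))
    pts <- rbind(pts, pos)
    heading <- heading + sgn * (pi - a * pi / 180)
    sgn <- -sgn
  }
  pos <- pos + seg_len * c(cos(heading), sin(heading))
  rbind(pts, pos)
}

# Split an open polyline into sub-polylines with arc-length intervals
# [pos, pos + len] removed.
.split_path <- function(pts, gaps) {
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                          pts[-nrow(pts), , drop = FALSE])^2))
  cs <- c(0, cumsum(seglen))
  total <- cs[length(cs)]
  point_at <- function(t) {
    t <- min(max(t, 0), total)
    i <- max(which(cs <= t + 1e-12)); i <- min(i, length(seglen))
    f <- if (seglen[i] > 0) (t - cs[i]) / seglen[i] else 0
    pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
  }
  cuts <- if (is.null(gaps)) matrix(numeric(0), 0, 2) else
    do.call(rbind, lapply(gaps, function(g) c(g[1], g[1] + g[2])))
  keep <- list(); t0 <- 0
  if (nrow(cuts)) cuts <- cuts[order(cuts[, 1]), , drop = FALSE]
  for (i in seq_len(nrow(cuts))) {
    if (cuts[i, 1] > t0) keep[[length(keep) + 1]] <- c(t0, cuts[i, 1])
    t0 <- max(t0, cuts[i, 2])
  }
  if (t0 < total) keep[[length(keep) + 1]] <- c(t0, total)
  lapply(keep, function(iv) {
    inner <- which(cs > iv[1] & cs < iv[2])
    do.call(rbind, c(list(point_at(iv[1])),
                     lapply(inner, function(i) pts[i, ]),
                     list(point_at(iv[2]))))
  })
}

# Separable Gaussian blur (edge-replicated borders), sigma in px.
.gauss_blur <- function(m, sigma) {
  h <- max(1, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  pass <- function(m) {                      # along rows
    nr <- nrow(m)
    idx <- function(d) pmin(pmax(seq_len(nr) + d, 1), nr)
    out <- m * k[h + 1]
    for (d in seq_len(h))
      out <- out + k[h + 1 + d] * m[idx(d), , drop = FALSE] +
                   k[h + 1 - d] * m[idx(-d), , drop = FALSE]
    out
  }
  t(pass(t(pass(m))))
}

# Minimum distance from grid pixels to a segment set; X, Y in mm.
.dist_to_segments <- function(X, Y, segs) {
  d <- rep(Inf, length(X))
  for (sg in segs) {
    for (i in seq_len(nrow(sg) - 1)) {
      a <- sg[i, ]; b <- sg[i + 1, ]
      ab <- b - a; len2 <- sum(ab^2)
      if (len2 == 0) {
        di <- sqrt((X - a[1])^2 + (Y - a[2])^2)
      } else {
        t <- pmin(1, pmax(0, ((X - a[1]) * ab[1] + (Y - a[2]) * ab[2]) / len2))
        di <- sqrt((X - a[1] - t * ab[1])^2 + (Y - a[2] - t * ab[2])^2)
      }
      d <- pmin(d, di)
    }
  }
  d
}

# Distance to a set of circular arcs (cx, cy, r, a0, a1 in degrees,
# counterclockwise from a0 to a1).
.dist_to_arcs <- function(X, Y, arcs) {
  d <- rep(Inf, length(X))
  for (a in arcs) {
    dx <- X - a$c[1]; dy <- Y - a$c[2]
    dc <- sqrt(dx^2 + dy^2)
    ang <- (atan2(dy, dx) * 180 / pi - a$a0) %% 360
    span <- (a$a1 - a$a0) %% 360
    if (span == 0) span <- 360
    inside <- ang <= span
    di <- abs(dc - a$r)
    if (any(!inside)) {
      p0 <- a$c + a$r * c(cos(a$a0 * pi / 180), sin(a$a0 * pi / 180))
      p1 <- a$c + a$r * c(cos((a$a0 + span) * pi / 180),
                          sin((a$a0 + span) * pi / 180))
      de <- pmin(sqrt((X - p0[1])^2 + (Y - p0[2])^2),
                 sqrt((X - p1[1])^2 + (Y - p1[2])^2))
      di[!inside] <- de[!inside]
    }
    d <- pmin(d, di)
  }
  d
}

#' Render a synthetic structure photograph with ground truth
#'
#' The CAD path is rasterized as a constant-width stroke with round
#' caps and joins, using area-coverage anti-aliasing (edge pixels take
#' intermediate intensities, as in real photographs), then Gaussian
#' blur, a linear illumination gradient and additive Gaussian noise are
#' applied.  Deterministic for a fixed seed.
#'
#' @param spec A [render_spec()].
#' @return A list with `image` (a [gray_image()]) and `truth`, the
#'   ground-truth sidecar: stroke width, material path length, realized
#'   radius / vertex angles, gap count, marker angle and the normalized
#'   metrics an ideal analyzer should recover.
#' @export
render_structure <- function(spec) {
  stopifnot(inherits(spec, "render_spec"))
  ppm <- spec$px_per_mm; w <- spec$stroke_width
  if (w * ppm < 2) stop("resolution too low: stroke under 2 px")
  cad <- spec$cad
  rot <- spec$rotation * pi / 180
  Rm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  xform <- function(p) sweep(p %*% t(Rm), 2, -spec$translation)
  segs <- list(); arcs <- list(); discs <- list()
  truth <- list(kind = cad$kind, stroke_width = w, px_per_mm = ppm,
                gap_count = length(spec$gaps),
                w_n = w / cad$nozzle_diameter, seed = spec$seed)
  if (cad$kind == "line") {
    L <- spec$actual_length
    pts <- cbind(c(-L / 2, L / 2), c(0, 0))
    segs <- lapply(.split_path(pts, spec$gaps), xform)
    truth$path_length <- sum(vapply(segs, function(s)
      sum(sqrt(rowSums((s[-1, , drop = FALSE] -
                        s[-nrow(s), , drop = FALSE])^2))), numeric(1)))
    truth$l_n <- truth$path_length / cad$line_length
  } else if (cad$kind == "circle") {
    r <- spec$actual_radius
    if (length(spec$gaps)) {
      # gaps as angular intervals from arc-length positions
      circum <- 2 * pi * r
      kept <- list(); t0 <- 0
      cuts <- do.call(rbind, lapply(spec$gaps, function(g)
        c(g[1], g[1] + g[2])))
      cuts <- cuts[order(cuts[, 1]), , drop = FALSE]
      for (i in seq_len(nrow(cuts))) {
        if (cuts[i, 1] > t0) kept[[length(kept) + 1]] <- c(t0, cuts[i, 1])
        t0 <- max(t0, cuts[i, 2])
      }
      if (t0 < circum) kept[[length(kept) + 1]] <- c(t0, circum)
      arcs <- lapply(kept, function(iv)
        list(c = spec$translation * 0, r = r,
             a0 = iv[1] / circum * 360, a1 = iv[2] / circum * 360))
      truth$path_length <- sum(vapply(kept, diff, numeric(1)))
    } else {
      arcs <- list(list(c = c(0, 0), r = r, a0 = 0, a1 = 360))
      truth$path_length <- 2 * pi * r
    }
    # pose: rotate arc start angles, then translate centers
    arcs <- lapply(arcs, function(a) {
      a$a0 <- a$a0 + spec$rotation; a$a1 <- a$a1 + spec$rotation
      a$c <- as.numeric(xform(matrix(a$c, 1))); a
    })
    truth$centerline_radius <- r
    truth$r_n <- r / cad$circle_radius
    mang <- (spec$marker_angle + spec$rotation) %% 360
    mc <- xform(matrix((spec$actual_radius - cad$marker_diameter) *
                         c(cos(spec$marker_angle * pi / 180),
                           sin(spec$marker_angle * pi / 180)), 1))
    discs <- list(list(c = as.numeric(mc), r = cad$marker_diameter / 2))
    truth$marker_angle <- mang
  } else {
    actual <- cad$designed_angles + spec$angle_offsets
    pts <- .angle_path(actual)
    pts <- sweep(pts, 2, colMeans(pts))       # center the path
    segs <- lapply(.split_path(pts, spec$gaps), xform)
    truth$vertex_angles <- actual
    truth$a_n <- actual / cad$designed_angles
    truth$path_length <- sum(vapply(segs, function(s)
      sum(sqrt(rowSums((s[-1, , drop = FALSE] -
                        s[-nrow(s), , drop = FALSE])^2))), numeric(1)))
  }
  for (b in spec$bulges) {
    # a bulge is a local over-deposition: a wider disc on the path
    p <- if (cad$kind == "circle") {
      a <- b[1] / (2 * pi * spec$actual_radius) * 360 + spec$rotation
      arcs[[1]]$c + spec$actual_radius * c(cos(a * pi / 180),
                                           sin(a * pi / 180))
    } else {
      s1 <- segs[[1]]
      as.numeric(s1[1, ] + (s1[nrow(s1), ] - s1[1, ]) *
                   min(1, b[1] / max(truth$path_length, 1e-9)))
    }
    discs[[length(discs) + 1]] <- list(c = as.numeric(p),
                                       r = (w + b[2]) / 2)
  }
  # raster extent
  all_pts <- rbind(do.call(rbind, segs),
                   do.call(rbind, lapply(arcs, function(a)
                     rbind(a$c + a$r + w, a$c - a$r - w))),
                   do.call(rbind, lapply(discs, function(d)
                     rbind(d$c + d$r, d$c - d$r))))
  xr <- range(all_pts[, 1]) + c(-1, 1) * spec$margin_mm
  yr <- range(all_pts[, 2]) + c(-1, 1) * spec$margin_mm
  cols <- seq(ceiling(xr[1] * ppm), floor(xr[2] * ppm))
  rows <- seq(ceiling(yr[1] * ppm), floor(yr[2] * ppm))
  X <- rep(cols / ppm, each = length(rows))
  Y <- rep(rows / ppm, times = length(cols))
  d <- rep(Inf, length(X))
  if (length(segs)) d <- pmin(d, .dist_to_segments(X, Y, segs))
  if (length(arcs)) d <- pmin(d, .dist_to_arcs(X, Y, arcs))
  cover <- pmin(1, pmax(0, 0.5 + (w / 2 - d) * ppm))
  for (dc in discs) {
    dd <- sqrt((X - dc$c[1])^2 + (Y - dc$c[2])^2)
    cover <- pmax(cover, pmin(1, pmax(0, 0.5 + (dc$r - dd) * ppm)))
  }
  img <- matrix(spec$bg + (spec$fg - spec$bg) * cover,
                nrow = length(rows), ncol = length(cols))
  truth$foreground_area_mm2 <- sum(cover) / ppm^2
  if (spec$blur_sigma > 0)
    img <- .gauss_blur(img, spec$blur_sigma * ppm)
  if (spec$illumination_gradient != 0) {
    ramp <- (seq_along(cols) - 1) / max(1, length(cols) - 1) - 0.5
    img <- img + matrix(spec$illumination_gradient * ramp,
                        nrow = length(rows), ncol = length(cols),
                        byrow = TRUE)
  }
  if (spec$noise_sigma > 0)
    img <- img + .with_seed(spec$seed,
                            matrix(stats::rnorm(length(img), 0,
                                                spec$noise_sigma),
                                   nrow(img)))
  img <- round(pmin(pmax(img, 0), 255))
  list(image = gray_image(img, ppm), truth = truth)
}

#' Write / read a ground-truth sidecar
#'
#' @param truth Ground-truth list from a generator.
#' @param path JSON path.
#' @return `path` invisibly; `read_ground_truth` returns the list.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Simulate rheometer viscosity curves from a power-law model
#'
#' Log-spaced shear rates; viscosities follow
#' eta = K gamma-dot^(n-1) times multiplicative lognormal noise with
#' coefficient of variation `noise_cv`.  Deterministic per seed.
#'
#' @param model A [power_law()] ground-truth model.
#' @param range Shear-rate interval, 1/s.
#' @param points Points per curve (>= 3).
#' @param noise_cv Coefficient of variation of the lognormal noise.
#' @param replicates Number of replicate curves.
#' @param seed Integer seed.
#' @return A list with `curves` (list of [viscosity_curve()]) and
#'   `truth` (the generating `n`, `K`, `noise_cv`).
#' @export
simulate_viscosity <- function(model, range = c(0.1, 1000), points = 30,
                               noise_cv = 0.05, replicates = 1, seed = 1) {
  stopifnot(inherits(model, "power_law"))
  if (points < 3) stop("invalid points: need >= 3")
  if (noise_cv < 0) stop("invalid noise")
  g <- 10^seq(log10(range[1]), log10(range[2]), length.out = points)
  eta0 <- model$K * g^(model$n - 1)
  sdlog <- sqrt(log(1 + noise_cv^2))
  curves <- .with_seed(seed, lapply(seq_len(replicates), function(i) {
    eta <- eta0 * stats::rlnorm(points, -sdlog^2 / 2, sdlog)
    viscosity_curve(g, eta, sprintf("sim%02d", i))
  }))
  list(curves = curves,
       truth = list(n = model$n, K = model$K, noise_cv = noise_cv,
                    replicates = replicates, seed = seed))
}

#' Default cluster parameters for the cytometry simulator
#'
#' Lognormal cluster locations (meanlog on natural log scale) and
#' spreads per channel for the four event populations: live cells
#' (high green calcein, low red), dead cells (high red PI, low green),
#' debris (low scatter) and agglomerates (very high scatter).  These
#' are documented defaults, not instrument calibrations; override any
#' entry to emulate a different cytometer setup.
#'
#' @return Nested list `params[[population]][[channel]] = c(meanlog, sdlog)`.
#' @export
cytometry_sim_params <- function() {
  list(
    live = list(fsc = c(log(5e4), 0.35), ssc = c(log(3e4), 0.35),
                green = c(log(1e4), 0.40), red = c(log(1e2), 0.50)),
    dead = list(fsc = c(log(4e4), 0.35), ssc = c(log(3.5e4), 0.35),
                green = c(log(1e2), 0.50), red = c(log(5e3), 0.50)),
    debris = list(fsc = c(log(2e3), 0.50), ssc = c(log(1.5e3), 0.50),
                  green = c(log(5e1), 0.60), red = c(log(5e1), 0.60)),
    agglomerate = list(fsc = c(log(4e5), 0.30), ssc = c(log(3e5), 0.30),
                       green = c(log(2e4), 0.60), red = c(log(2e3), 0.80)))
}

#' Simulate a flow-cytometry event mixture with known viability
#'
#' Events are drawn from four lognormal clusters in (forward scatter,
#' side scatter, green, red): live, dead, debris and agglomerates.
#' Among cell events (neither debris nor agglomerate), a fraction
#' `viability` is live.  True labels are returned in the ground truth.
#' Deterministic per seed.
#'
#' @param n_events Total number of events, > 0.
#' @param viability True live fraction among cells, in `[0, 1]`.
#' @param debris_fraction,agglomerate_fraction Fractions of all events
#'   that are debris / agglomerates; their sum must be < 1.
#' @param seed Integer seed.
#' @param params Cluster parameters, see [cytometry_sim_params()].
#' @return A list with `events` (an [event_table()]) and `truth`
#'   (`labels`, realized `viability` among generated cells, and the
#'   generating fractions).
#' @export
simulate_cytometry <- function(n_events, viability, debris_fraction = 0,
                               agglomerate_fraction = 0, seed = 1,
                               params = cytometry_sim_params()) {
  if (!is.finite(n_events) || n_events <= 0) stop("invalid count")
  fr <- c(debris_fraction, agglomerate_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) >= 1 ||
      viability < 0 || viability > 1)
    stop("invalid fractions")
  .with_seed(seed, {
    lab <- sample(c("debris", "agglomerate", "cell"), n_events,
                  replace = TRUE,
                  prob = c(fr, 1 - sum(fr)))
    cell <- lab == "cell"
    lab[cell] <- ifelse(stats::runif(sum(cell)) < viability,
                        "live", "dead")
    draw <- function(pop, ch) {
      p <- params[[pop]][[ch]]
      stats::rlnorm(sum(lab == pop), p[1], p[2])
    }
    d <- data.frame(fsc = numeric(n_events), ssc = numeric(n_events),
                    green = numeric(n_events), red = numeric(n_events))
    for (pop in names(params))
      for (ch in names(d))
        d[[ch]][lab == pop] <- draw(pop, ch)
    n_live <- sum(lab == "live"); n_dead <- sum(lab == "dead")
    list(events = event_table(d),
         truth = list(labels = lab,
                      viability = n_live / max(1, n_live + n_dead),
                      target_viability = viability,
                      debris_fraction = debris_fraction,
                      agglomerate_fraction = agglomerate_fraction,
                      seed = seed))
  })
}
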