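# Printing-accuracy metrics for single-layer line, circle and angle
# structures.  All quantities are normalized against the CAD target:
#   w_n = w / d_nozzle          (normalized filament width)
#   l_n = l / l_model           (normalized line length)
#   r_n = (r_i + r_o) / (2 r_model)   (normalized radii to midline)
#   a_n = (a_i + a_o) / (2 a_model)   (normalized angle to midline)
# The midline is the nozzle-center trajectory, so combining the inner
# and outer boundary into one parameter cancels the stroke width: a
# perfectly placed structure scores exactly 1 whatever its width.

#' CAD target description for a printed structure
#'
#' @param kind Structure kind: `"line"`, `"circle"` or `"angle"`.
#' @param line_length Designed line length l_model, mm.
#' @param circle_radius Designed circle radius r_model, mm.
#' @param marker_diameter Diameter of the print-start marker circle, mm.
#' @param designed_angles Designed vertex angles of the angle composite,
#'   degrees, in path order.
#' @param nozzle_diameter Nozzle inner diameter d_nozzle, mm.
#' @return An object of class `cad_target`.
#' @export
cad_target <- function(kind = c("line", "circle", "angle"),
                       line_length = 30, circle_radius = 15,
                       marker_diameter = 3,
                       designed_angles = c(30, 45, 60),
                       nozzle_diameter = 0.61) {
  kind <- match.arg(kind)
  dims <- c(line_length, circle_radius, marker_diameter, nozzle_diameter)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("invalid CAD target: dimensions must be > 0")
  if (any(designed_angles <= 0) || any(designed_angles >= 180))
    stop("invalid CAD target: angles must be in (0, 180) degrees")
  structure(list(kind = kind, line_length = line_length,
                 circle_radius = circle_radius,
                 marker_diameter = marker_diameter,
                 designed_angles = designed_angles,
                 nozzle_diameter = nozzle_diameter),
            class = "cad_target")
}

#' @export
print.cad_target <- function(x, ...) {
  cat(sprintf("CAD target: %s (nozzle %.3g mm)\n", x$kind, x$nozzle_diameter))
  invisible(x)
}

# ---- internal geometry helpers --------------------------------------

# Principal direction of a 2-column point matrix; unit vector.
.pca_direction <- function(xy) {
  xy <- sweep(xy, 2, colMeans(xy))
  v <- eigen(crossprod(xy) / nrow(xy), symmetric = TRUE)$vectors[, 1]
  v / sqrt(sum(v^2))
}

# Geometric (orthogonal-distance) circle fit: Kasa algebraic solution
# refined by Gauss-Newton on (cx, cy, r).
.fit_circle <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  A <- cbind(x, y, 1)
  sol <- stats::lm.fit(A, x^2 + y^2)$coefficients
  cx <- sol[1] / 2; cy <- sol[2] / 2
  r <- sqrt(sol[3] + cx^2 + cy^2)
  for (i in 1:25) {
    dx <- x - cx; dy <- y - cy
    d <- sqrt(dx^2 + dy^2)
    resid <- d - r
    J <- cbind(-dx / d, -dy / d, -1)
    step <- tryCatch(stats::lm.fit(J, -resid)$coefficients,
                     error = function(e) c(0, 0, 0))
    if (anyNA(step)) break
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
    if (max(abs(step)) < 1e-12 * r) break
  }
  list(center = c(x = unname(cx), y = unname(cy)), radius = unname(r),
       rms = sqrt(mean((sqrt((x - cx)^2 + (y - cy)^2) - r)^2)))
}

# Douglas-Peucker simplification of a closed polyline (matrix, first
# point != last).  Returns indices of retained vertices.
.dp_simplify <- function(poly, tol) {
  n <- nrow(poly)
  d0 <- (poly[, 1] - poly[1, 1])^2 + (poly[, 2] - poly[1, 2])^2
  anchor2 <- which.max(d0)
  keep <- rep(FALSE, n); keep[c(1, anchor2)] <- TRUE
  recurse <- function(i, j) {          # open sub-polyline poly[i..j]
    if (j - i < 2) return()
    seg <- poly[j, ] - poly[i, ]
    len2 <- sum(seg^2)
    idx <- (i + 1):(j - 1)
    if (len2 == 0) {
      d <- sqrt((poly[idx, 1] - poly[i, 1])^2 +
                (poly[idx, 2] - poly[i, 2])^2)
    } else {
      t <- ((poly[idx, 1] - poly[i, 1]) * seg[1] +
            (poly[idx, 2] - poly[i, 2]) * seg[2]) / len2
      t <- pmin(1, pmax(0, t))
      d <- sqrt((poly[idx, 1] - poly[i, 1] - t * seg[1])^2 +
                (poly[idx, 2] - poly[i, 2] - t * seg[2])^2)
    }
    k <- which.max(d)
    if (d[k] > tol) {
      keep[idx[k]] <<- TRUE
      recurse(i, idx[k]); recurse(idx[k], j)
    }
  }
  recurse(1, anchor2)
  # second half, wrapped: treat as open polyline anchor2..n..1
  wrapped <- rbind(poly[anchor2:n, , drop = FALSE], poly[1, , drop = FALSE])
  keep2 <- rep(FALSE, nrow(wrapped)); keep2[c(1, nrow(wrapped))] <- TRUE
  poly_save <- poly; keep_save <- keep
  poly <- wrapped; keep <- keep2
  recurse(1, nrow(wrapped))
  keep2 <- keep
  poly <- poly_save
  keep <- keep_save
  idx2 <- which(keep2); idx2 <- idx2[idx2 < nrow(wrapped)]
  sort(unique(c(which(keep), anchor2 - 1 + idx2)))
}

# Circular arc-length parameterization of a closed polyline.
.arc_pos <- function(poly) {
  seglen <- sqrt(rowSums((poly - poly[c(2:nrow(poly), 1), ])^2))
  cumsum(c(0, seglen[-length(seglen)]))
}

# Points of a closed polyline within arc distance [a0, a1] of vertex k,
# on the backward (-1) or forward (+1) side.
.arm_points <- function(poly, s, total, k, a0, a1, side) {
  ds <- (s - s[k]) * side
  ds <- ds %% total
  poly[ds >= a0 & ds <= a1, , drop = FALSE]
}

# Measure the corner at boundary index k: angle between straight-line
# fits to the two boundary arms at arc distance [a0, a1] from the apex,
# the turn orientation (convex/reflex), and the apex refined to the
# intersection of the two arm lines.
.corner_measure <- function(poly, s, total, k, a0, a1) {
  apex <- poly[k, ]
  arms <- lapply(c(-1, 1), function(side) {
    pts <- .arm_points(poly, s, total, k, a0, a1, side)
    if (nrow(pts) < 4) return(NULL)
    dir <- .pca_direction(pts)
    if (sum((colMeans(pts) - apex) * dir) < 0) dir <- -dir
    list(dir = dir, center = colMeans(pts))
  })
  if (is.null(arms[[1]]) || is.null(arms[[2]])) return(NULL)
  u <- arms[[1]]$dir; v <- arms[[2]]$dir
  ang <- acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
  cross <- -u[1] * v[2] + u[2] * v[1]     # turn sign: in = -u, out = v
  # refined apex: intersection of the two arm lines; skip near-parallel
  # arms and reject far-away intersections (shallow angles shoot off)
  refined <- apex
  det <- u[1] * (-v[2]) - (-v[1]) * u[2]
  if (abs(det) > 0.05) {
    rhs <- arms[[2]]$center - arms[[1]]$center
    t1 <- (rhs[1] * (-v[2]) - (-v[1]) * rhs[2]) / det
    cand <- arms[[1]]$center + t1 * u
    if (sum((cand - apex)^2) < 2.5^2) refined <- cand
  }
  list(angle = ang, convex = cross > 0, apex = refined, raw_apex = apex)
}

# Foreground width along the perpendicular cross-section at a point:
# length of the contiguous foreground run containing the centerline
# (so a probe near a sharp vertex never counts the neighboring arm),
# by sub-pixel sampling of the label image.
.probe_width <- function(label_image, ppm, point, direction, half_mm = 2.5,
                         step_px = 0.2) {
  e <- c(-direction[2], direction[1])
  t <- seq(-half_mm, half_mm, by = step_px / ppm)
  px <- round(t * e[1] * ppm + point[1] * ppm)
  py <- round(t * e[2] * ppm + point[2] * ppm)
  ok <- px >= 1 & px <= ncol(label_image) & py >= 1 & py <= nrow(label_image)
  hit <- logical(length(t))
  hit[ok] <- label_image[cbind(py[ok], px[ok])] > 0
  if (!any(hit)) return(0)
  r <- rle(hit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  center <- (length(t) + 1) / 2
  cand <- which(r$values)
  d <- pmax(starts[cand] - center, center - ends[cand], 0)
  r$lengths[cand[which.min(d)]] * step_px / ppm
}

# ---- line ------------------------------------------------------------

#' Analyze a printed line structure
#'
#' The principal axis of the largest component defines the line
#' direction.  The filament width is the mean foreground pixel count
#' per one-pixel cross-section perpendicular to that axis, averaged
#' over the middle `middle_fraction` of the designed length; the line
#' length is the material-covered extent along the axis summed over all
#' components in the line corridor, with the measured width subtracted
#' from each segment's extent to compensate the rounded end caps (so a
#' continuous ideal print scores l_n = 1 and interrupted prints score
#' below 1 by exactly the missing material).
#'
#' @param components A `labeled_components` from [segment_components()].
#' @param cad A `cad_target` with `kind = "line"`.
#' @param middle_fraction Fraction of the designed length, centered,
#'   over which the width is averaged (default 1/3).
#' @param corridor_mm Half-width of the corridor around the axis within
#'   which components count as line segments.
#' @return An object of class `line_metrics`: `width`, `width_sd`,
#'   `normalized_width`, `length`, `normalized_length`,
#'   `segment_count`, `interrupted`.
#' @export
analyze_line <- function(components, cad, middle_fraction = 1 / 3,
                         corridor_mm = 2) {
  stopifnot(inherits(components, "labeled_components"),
            inherits(cad, "cad_target"))
  if (cad$kind != "line") stop("structure/CAD mismatch: expected kind 'line'")
  comps <- components$components
  if (!length(comps)) stop("no object detected")
  ppm <- components$px_per_mm
  main <- comps[[1]]
  pts_mm <- function(cc) cbind(cc$pixels[, 2], cc$pixels[, 1]) / ppm
  mu <- main$centroid
  u <- .pca_direction(pts_mm(main))
  v <- c(-u[2], u[1])
  in_corridor <- vapply(comps, function(cc)
    abs(sum((cc$centroid - mu) * v)) <= corridor_mm, logical(1))
  segs <- comps[in_corridor]
  all_pts <- do.call(rbind, lapply(segs, pts_mm))
  t_all <- (all_pts[, 1] - mu[1]) * u[1] + (all_pts[, 2] - mu[2]) * u[2]
  # width over the middle fraction of the designed length
  t_mid <- (max(t_all) + min(t_all)) / 2
  half <- cad$line_length * middle_fraction / 2
  sel <- t_all >= t_mid - half & t_all <= t_mid + half
  bins <- floor((t_all[sel] - (t_mid - half)) * ppm + 1e-6)
  counts <- tabulate(bins + 1)
  counts <- counts[counts > 0]               # skip gap bins
  if (!length(counts)) stop("no object detected")
  width <- mean(counts) / ppm
  width_sd <- if (length(counts) > 1) stats::sd(counts) / ppm else 0
  # material-covered length (cap-compensated extent per segment)
  extents <- vapply(segs, function(cc) {
    p <- pts_mm(cc)
    t <- (p[, 1] - mu[1]) * u[1] + (p[, 2] - mu[2]) * u[2]
    diff(range(t)) + 1 / ppm                 # pixel extent
  }, numeric(1))
  len <- sum(pmax(extents - width, 0))
  structure(list(width = width, width_sd = width_sd,
                 normalized_width = width / cad$nozzle_diameter,
                 length = len,
                 normalized_length = len / cad$line_length,
                 segment_count = length(segs),
                 interrupted = length(segs) > 1,
                 axis = list(center = mu, direction = u)),
            class = c("line_metrics", "structure_metrics"))
}

# ---- circle ----------------------------------------------------------

#' Analyze a printed circle structure
#'
#' The largest component is the printed annulus; geometric
#' (orthogonal-distance) least-squares circles are fitted to its
#' interior-hole boundary (inner radius r_i) and outer boundary
#' (outer radius r_o).  The small start-marker component is located by
#' its size, and the filament width is measured as the radial extent
#' between outer and inner boundary over an arc of `arc_fraction` of
#' the circumference centered diametrically opposite the marker.
#'
#' @param components A `labeled_components`.
#' @param cad A `cad_target` with `kind = "circle"`.
#' @param arc_fraction Fraction of the circumference over which the
#'   width is averaged (default 0.02, i.e. 7.2 degrees).
#' @return An object of class `circle_metrics`: `inner_radius`,
#'   `outer_radius`, `normalized_radii`, `width_at_180`,
#'   `normalized_width`, `center`, `start_marker_angle` (degrees from
#'   the +x axis, image coordinates), `marker_found`.
#' @export
analyze_circle <- function(components, cad, arc_fraction = 0.02) {
  stopifnot(inherits(components, "labeled_components"),
            inherits(cad, "cad_target"))
  if (cad$kind != "circle")
    stop("structure/CAD mismatch: expected kind 'circle'")
  comps <- components$components
  if (!length(comps)) stop("no object detected")
  ring <- comps[[1]]
  if (!length(ring$holes)) stop("no ring detected")
  hole_areas <- vapply(ring$holes, function(h)
    abs(.polygon_area(h[, 1], h[, 2])), numeric(1))
  inner_b <- ring$holes[[which.max(hole_areas)]]
  fit_i <- .fit_circle(inner_b)
  fit_o <- .fit_circle(ring$outer)
  center <- (fit_i$center + fit_o$center) / 2
  # start marker: remaining component closest in size to the marker
  marker_found <- FALSE; marker_angle <- 0
  others <- comps[-1]
  if (length(others)) {
    dia <- vapply(others, function(cc)
      mean(c(cc$bbox_mm["xmax"] - cc$bbox_mm["xmin"],
             cc$bbox_mm["ymax"] - cc$bbox_mm["ymin"])) +
        1 / components$px_per_mm, numeric(1))
    m <- others[[which.min(abs(dia - cad$marker_diameter))]]
    marker_found <- TRUE
    marker_angle <- atan2(m$centroid[2] - center[2],
                          m$centroid[1] - center[1]) * 180 / pi
  } else {
    warning("no start marker detected; using angular position 0")
  }
  # width opposite the marker, over arc_fraction of the circumference
  target <- (marker_angle + 180) %% 360
  halfwin <- arc_fraction * 360 / 2
  radial <- function(b) {
    ang <- (atan2(b[, 2] - center[2], b[, 1] - center[1]) * 180 / pi) %% 360
    d <- pmin(abs(ang - target), 360 - abs(ang - target))
    r <- sqrt((b[, 1] - center[1])^2 + (b[, 2] - center[2])^2)
    mean(r[d <= halfwin])
  }
  width <- radial(ring$outer) - radial(inner_b)
  structure(list(inner_radius = fit_i$radius, outer_radius = fit_o$radius,
                 normalized_radii =
                   (fit_i$radius + fit_o$radius) / (2 * cad$circle_radius),
                 width_at_180 = width,
                 normalized_width = width / cad$nozzle_diameter,
                 center = center,
                 start_marker_angle = marker_angle,
                 marker_found = marker_found),
            class = c("circle_metrics", "structure_metrics"))
}

# ---- angle -----------------------------------------------------------

#' Analyze a printed angle composite structure
#'
#' The outer boundary of the (single) stroked-path component is traced
#' and simplified; corner candidates are measured by fitting straight
#' lines to the two boundary arms in an arc-length window
#' `arm_window * d_nozzle` away from the apex (excluding the rounded
#' apex itself), and refined to the arm-line intersection.  Rounded end
#' caps (near-zero corner angle) mark the path endpoints; the remaining
#' corners are paired across the stroke into path vertices, ordered
#' along the path, and matched to the designed angles (both path
#' directions are tried).  The member of each pair at a reflex boundary
#' turn is the inner angle a_i, the convex one the outer angle a_o;
#' a_n = (a_i + a_o) / (2 a_model).  The filament width is probed
#' perpendicular to the centerline at `n_width_probes` points on the
#' straight segments.
#'
#' @param components A `labeled_components`.
#' @param cad A `cad_target` with `kind = "angle"`.
#' @param arm_window Arm-fit window in multiples of the nozzle
#'   diameter, `c(from, to)` from the apex.
#' @param dp_tol_mm Douglas-Peucker tolerance for corner candidates, mm.
#' @param cluster_mm Radius within which corner candidates merge, mm.
#' @param cap_angle_deg Corners below this angle are end caps.
#' @param max_corner_deg Corners above this angle are not corners.
#' @param pair_max_mm Maximum apex separation of an inner/outer pair
#'   (the separation grows as stroke width / sin(angle/2), so sharp
#'   wide corners need room).
#' @param n_width_probes Number of width probes along the path.
#' @return An object of class `angle_metrics`: data frame `vertices`
#'   (columns `designed`, `inner`, `outer`, `normalized`, `x`, `y`),
#'   `widths`, `normalized_width`.
#' @export
analyze_angle <- function(components, cad, arm_window = c(1, 5),
                          dp_tol_mm = 0.08, cluster_mm = 0.7,
                          cap_angle_deg = 20, max_corner_deg = 160,
                          pair_max_mm = 6.5, n_width_probes = 5) {
  stopifnot(inherits(components, "labeled_components"),
            inherits(cad, "cad_target"))
  if (cad$kind != "angle")
    stop("structure/CAD mismatch: expected kind 'angle'")
  comps <- components$components
  if (!length(comps)) stop("no object detected")
  ppm <- components$px_per_mm
  main <- comps[[1]]
  poly <- main$outer[-nrow(main$outer), , drop = FALSE]   # open the loop
  if (.polygon_area(poly[, 1], poly[, 2]) < 0)
    poly <- poly[nrow(poly):1, , drop = FALSE]            # orient CCW
  s <- .arc_pos(poly)
  total <- s[length(s)] +
    sqrt(sum((poly[nrow(poly), ] - poly[1, ])^2))
  # stroke-width estimate from the distance transform (sets the cap
  # exclusion scale so the cap arc never contaminates the arm fits)
  sub <- matrix(0, diff(range(main$pixels[, 1])) + 3,
                diff(range(main$pixels[, 2])) + 3)
  sub[cbind(main$pixels[, 1] - min(main$pixels[, 1]) + 2,
            main$pixels[, 2] - min(main$pixels[, 2]) + 2)] <- 1
  dm <- EBImage::distmap(sub)
  w_est <- 2 * stats::quantile(dm[dm > 0], 0.95) / ppm
  a0 <- max(arm_window[1] * cad$nozzle_diameter, 0.95 * pi * w_est / 2)
  a1 <- max(arm_window[2] * cad$nozzle_diameter, a0 + 1.5)
  cand <- .dp_simplify(poly, dp_tol_mm)
  corners <- list()
  for (k in cand) {
    cm <- .corner_measure(poly, s, total, k, a0, a1)
    if (!is.null(cm) && cm$angle <= max_corner_deg) {
      cm$s <- s[k]; cm$k <- k
      corners[[length(corners) + 1]] <- cm
    }
  }
  if (!length(corners)) stop("structure/CAD mismatch: no corners found")
  ang <- vapply(corners, `[[`, numeric(1), "angle")
  apex <- do.call(rbind, lapply(corners, `[[`, "apex"))
  svals <- vapply(corners, `[[`, numeric(1), "s")
  conv <- vapply(corners, `[[`, logical(1), "convex")
  # caps (stroke ends) turn through +180 so they are convex; a sharp
  # inner corner can measure far below cap_angle before refinement but
  # is reflex, so the reflex sign vetoes the cap label.  Only below
  # ~2 deg (true caps measure < 1 deg; contaminated corners do not get
  # that low) is the turn sign numerical noise and the angle alone
  # decides.
  is_cap <- ang < cap_angle_deg & (ang < 2 | conv)
  # merge cap candidates into distinct endpoints
  caps <- apex[is_cap, , drop = FALSE]
  caps_s <- svals[is_cap]
  cap_pts <- list(); cap_s <- numeric(0)
  if (nrow(caps)) {
    used <- rep(FALSE, nrow(caps))
    for (i in seq_len(nrow(caps))) {
      if (used[i]) next
      near <- which(!used & sqrt((caps[, 1] - caps[i, 1])^2 +
                                 (caps[, 2] - caps[i, 2])^2) < 2)
      used[near] <- TRUE
      cap_pts[[length(cap_pts) + 1]] <- colMeans(caps[near, , drop = FALSE])
      cap_s <- c(cap_s, caps_s[near[1]])
    }
  }
  # true corners: outside cap zones, then clustered by refined apex
  keep <- !is_cap
  if (length(cap_pts)) {
    for (cp in cap_pts)
      keep <- keep & sqrt((apex[, 1] - cp[1])^2 +
                          (apex[, 2] - cp[2])^2) > 2.2 * w_est
  }
  corners <- corners[keep]; ang <- ang[keep]
  apex <- apex[keep, , drop = FALSE]
  if (!length(corners)) stop("structure/CAD mismatch: no corners found")
  used <- rep(FALSE, length(corners))
  merged <- list()
  for (i in order(abs(180 - ang), decreasing = TRUE)) {
    if (used[i]) next
    near <- which(!used & sqrt((apex[, 1] - apex[i, 1])^2 +
                               (apex[, 2] - apex[i, 2])^2) < cluster_mm)
    used[near] <- TRUE
    merged[[length(merged) + 1]] <- corners[[i]]
  }
  # refine each corner: a candidate sitting a little way down one arm
  # has its far window straddling the true apex, which mixes the arms
  # and biases the angle low; re-measuring at the boundary point
  # nearest the arm-line intersection converges onto the apex
  thr_win_mm <- 101 / ppm
  if (!is.null(components$provenance$threshold_window))
    thr_win_mm <- components$provenance$threshold_window / ppm
  merged <- Filter(Negate(is.null), lapply(merged, function(cm) {
    reflex <- !cm$convex           # the cluster turn sign is reliable;
    best <- cm; k <- cm$k          # intermediate fits may flip it
    for (iter in 1:3) {
      k2 <- which.min((poly[, 1] - best$apex[1])^2 +
                      (poly[, 2] - best$apex[2])^2)
      if (k2 == k) break
      cm2 <- .corner_measure(poly, s, total, k2, a0, a1)
      if (is.null(cm2) || cm2$angle > max_corner_deg) break
      cm2$s <- s[k2]; cm2$k <- k2
      best <- cm2; k <- k2
    }
    # reflex (inner) corners sit in a concave notch; where the notch is
    # narrower than the threshold window the traced boundary bends, so
    # push the arm window out past that zone before the final fit.
    # Iterate: the first angle estimate is biased low, which would
    # overshoot the window; the cap at 3.8 mm keeps the fit on this
    # vertex's own arms.
    if (reflex && best$angle > 1) {
      for (pass in 1:2) {
        a0r <- min(0.75 * thr_win_mm /
                     (2 * sin(min(best$angle, 175) * pi / 360)), 3.8)
        if (a0r <= a0) break
        cm3 <- .corner_measure(poly, s, total, best$k, a0r,
                               a0r + max(a1 - a0, 1.4))
        if (is.null(cm3) || cm3$angle > max_corner_deg) break
        cm3$s <- best$s; cm3$k <- best$k
        best <- cm3
      }
      best$convex <- FALSE
    }
    if (best$angle <= max_corner_deg) best else NULL
  }))
  if (!length(merged)) stop("structure/CAD mismatch: no corners found")
  # pair corners across the stroke into path vertices
  m <- length(merged)
  mapex <- do.call(rbind, lapply(merged, `[[`, "apex"))
  mang <- vapply(merged, `[[`, numeric(1), "angle")
  mconv <- vapply(merged, `[[`, logical(1), "convex")
  ms <- vapply(merged, `[[`, numeric(1), "s")
  dmat <- as.matrix(stats::dist(mapex))
  diag(dmat) <- Inf
  # an inner/outer pair has opposite boundary-turn signs; never pair
  # two corners of the same convexity (e.g. the inner apexes of two
  # adjacent sharp vertices, which can approach each other)
  dmat[outer(mconv, mconv, `==`)] <- Inf
  pairs <- list(); taken <- rep(FALSE, m)
  repeat {
    if (all(taken) || min(dmat[!taken, !taken]) > pair_max_mm) break
    idx <- which(dmat == min(dmat[!taken, !taken]) &
                 outer(!taken, !taken, `&`), arr.ind = TRUE)[1, ]
    taken[idx] <- TRUE
    dmat[idx, ] <- Inf; dmat[, idx] <- Inf
    pairs[[length(pairs) + 1]] <- sort(idx)
  }
  # drop flat-end signatures: two ~90 deg corners one stroke width apart
  if (length(pairs)) {
    flat <- vapply(pairs, function(p) {
      sep <- sqrt(sum((mapex[p[1], ] - mapex[p[2], ])^2))
      all(mang[p] > 70 & mang[p] < 110) && sep < 1.5 * w_est
    }, logical(1))
    if (any(flat) &&
        length(pairs) - sum(flat) == length(cad$designed_angles)) {
      for (p in pairs[flat]) {
        cap_pts[[length(cap_pts) + 1]] <- colMeans(mapex[p, , drop = FALSE])
        cap_s <- c(cap_s, ms[p[1]])
      }
      pairs <- pairs[!flat]
    }
  }
  if (length(pairs) != length(cad$designed_angles))
    stop(sprintf("structure/CAD mismatch: %d vertices found, %d designed",
                 length(pairs), length(cad$designed_angles)))
  vert <- do.call(rbind, lapply(pairs, function(p)
    colMeans(mapex[p, , drop = FALSE])))
  k <- nrow(vert)
  ends <- if (length(cap_pts) >= 2) do.call(rbind, cap_pts[1:2]) else NULL
  # order vertices along the path.  Walking the outer boundary from an
  # end cap meets the path vertices in path order (one stroke side is
  # traversed forward), so order by first boundary encounter after the
  # cap; without caps fall back to a shortest-Hamiltonian-path heuristic.
  if (length(cap_s)) {
    first_s <- vapply(pairs, function(p)
      min((ms[p] - cap_s[1]) %% total), numeric(1))
    ord <- order(first_s)
  } else {
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    }
    best <- NULL; best_len <- Inf
    for (p in perms(seq_len(k))) {
      path <- vert[p, , drop = FALSE]
      len <- sum(sqrt(rowSums((path[-1, , drop = FALSE] -
                               path[-nrow(path), , drop = FALSE])^2)))
      if (len < best_len) { best_len <- len; best <- p }
    }
    ord <- best
  }
  # match designed angles: try both path directions
  meas_mean <- vapply(pairs, function(p) mean(mang[p]), numeric(1))[ord]
  fwd <- sum(abs(meas_mean - cad$designed_angles))
  rev_ <- sum(abs(rev(meas_mean) - cad$designed_angles))
  if (rev_ < fwd) ord <- rev(ord)
  vertices <- do.call(rbind, lapply(seq_len(k), function(j) {
    p <- pairs[[ord[j]]]
    inner <- if (!mconv[p[1]]) p[1] else p[2]
    outer_ <- if (!mconv[p[1]]) p[2] else p[1]
    data.frame(designed = cad$designed_angles[j],
               inner = mang[inner], outer = mang[outer_],
               normalized = (mang[inner] + mang[outer_]) /
                 (2 * cad$designed_angles[j]),
               x = mean(mapex[p, 1]), y = mean(mapex[p, 2]))
  }))
  # width probes at the straight-segment midpoints
  path <- vert[ord, , drop = FALSE]
  if (!is.null(ends)) {
    # attach each endpoint to its nearer terminal vertex
    d1 <- sqrt(sum((ends[1, ] - path[1, ])^2)) +
          sqrt(sum((ends[2, ] - path[k, ])^2))
    d2 <- sqrt(sum((ends[2, ] - path[1, ])^2)) +
          sqrt(sum((ends[1, ] - path[k, ])^2))
    if (d2 < d1) ends <- ends[2:1, , drop = FALSE]
    path <- rbind(ends[1, ], path, ends[2, ])
  }
  probes <- list()
  nseg <- nrow(path) - 1
  fracs <- c(0.5, 0.35, 0.65)
  for (f in fracs) {
    for (i in seq_len(nseg)) {
      if (length(probes) >= n_width_probes) break
      a <- path[i, ]; b <- path[i + 1, ]
      probes[[length(probes) + 1]] <-
        list(point = a + f * (b - a), dir = (b - a) / sqrt(sum((b - a)^2)))
    }
    if (length(probes) >= n_width_probes) break
  }
  widths <- vapply(probes, function(pr)
    .probe_width(components$label_image, ppm, pr$point, pr$dir,
                 half_mm = max(1.2, 1.5 * w_est)), numeric(1))
  widths <- widths[widths > 0]
  structure(list(vertices = vertices,
                 widths = widths,
                 normalized_width = mean(widths) / cad$nozzle_diameter,
                 endpoints = ends,
                 stroke_width_estimate = w_est),
            class = c("angle_metrics", "structure_metrics"))
}

# ---- dispatch + printing --------------------------------------------

#' Analyze a structure according to its CAD target kind
#'
#' @param components A `labeled_components`.
#' @param cad A `cad_target`.
#' @param ... Passed to the kind-specific analyzer.
#' @return A `line_metrics`, `circle_metrics` or `angle_metrics`.
#' @export
analyze_structure <- function(components, cad, ...) {
  switch(cad$kind,
         line = analyze_line(components, cad, ...),
         circle = analyze_circle(components, cad, ...),
         angle = analyze_angle(components, cad, ...))
}

#' @export
print.line_metrics <- function(x, ...) {
  cat(sprintf("Line: w = %.3f mm (w_n = %.3f), l = %.2f mm (l_n = %.3f)\n",
              x$width, x$normalized_width, x$length, x$normalized_length))
  cat(sprintf("  %d segment(s)%s\n", x$segment_count,
              if (x$interrupted) ", interrupted" else ""))
  invisible(x)
}

#' @export
print.circle_metrics <- function(x, ...) {
  cat(sprintf("Circle: r_i = %.3f, r_o = %.3f mm (r_n = %.4f), w_n = %.3f\n",
              x$inner_radius, x$outer_radius, x$normalized_radii,
              x$normalized_width))
  cat(sprintf("  marker at %.1f deg%s\n", x$start_marker_angle,
              if (!x$marker_found) " (not found, fallback)" else ""))
  invisible(x)
}

#' @export
print.angle_metrics <- function(x, ...) {
  cat(sprintf("Angle composite: w_n = %.3f\n", x$normalized_width))
  print(x$vertices[, c("designed", "inner", "outer", "normalized")],
        row.names = FALSE)
  invisible(x)
}

#' One-row data frame summary of structure metrics
#'
#' @param metrics A `structure_metrics` object.
#' @return A one-row data frame with the normalized metric columns
#'   (`w_n`, `l_n`, `r_n`, `a_n_<angle>`, `interrupted`) applicable to
#'   the structure kind, `NA` elsewhere.
#' @export
metrics_row <- function(metrics) {
  row <- data.frame(kind = NA_character_, w_n = NA_real_, l_n = NA_real_,
                    r_n = NA_real_, interrupted = NA)
  if (inherits(metrics, "line_metrics")) {
    row$kind <- "line"
    row$w_n <- metrics$normalized_width
    row$l_n <- metrics$normalized_length
    row$interrupted <- metrics$interrupted
  } else if (inherits(metrics, "circle_metrics")) {
    row$kind <- "circle"
    row$w_n <- metrics$normalized_width
    row$r_n <- metrics$normalized_radii
  } else if (inherits(metrics, "angle_metrics")) {
    row$kind <- "angle"
    row$w_n <- metrics$normalized_width
    for (j in seq_len(nrow(metrics$vertices)))
      row[[sprintf("a_n_%g", metrics$vertices$designed[j])]] <-
        metrics$vertices$normalized[j]
  }
  row
}
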