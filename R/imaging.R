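# Imaging: calibrated grayscale photographs -> binary masks -> labeled
# components with sub-pixel boundary polylines.
#
# Coordinate convention: pixel centers sit at integer (row, col) indices
# starting at 1; x = col (rightward), y = row (downward); physical
# coordinates in mm are index / px_per_mm.  All metric outputs are mm.

#' Construct a calibrated grayscale image
#'
#' @param pixels Numeric matrix of intensities (8- or 16-bit scale).
#' @param px_per_mm Pixel pitch, pixels per mm. Default 52 (monochrome
#'   camera used for single-layer structure photographs).
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, px_per_mm = 52) {
  if (!is.matrix(pixels) || !length(pixels)) stop("invalid image")
  if (!is.finite(px_per_mm) || px_per_mm <= 0) stop("invalid pixel pitch")
  structure(list(pixels = pixels, px_per_mm = px_per_mm),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("Grayscale image %d x %d px (%.3g x %.3g mm at %g px/mm)\n",
              nrow(x$pixels), ncol(x$pixels),
              ncol(x$pixels) / x$px_per_mm, nrow(x$pixels) / x$px_per_mm,
              x$px_per_mm))
  invisible(x)
}

#' @export
plot.gray_image <- function(x, ...) {
  graphics::image(t(x$pixels)[, nrow(x$pixels):1, drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  axes = FALSE, ...)
  invisible(x)
}

#' Read a grayscale PNG or TIFF photograph
#'
#' The pixel pitch is taken from `px_per_mm` if given, otherwise from a
#' JSON sidecar `<image>.json` containing `{"px_per_mm": ...}`, else the
#' default 52 px/mm is assumed.  Multi-channel images are averaged to
#' one channel.  Intensities are returned on the 8-bit (0-255) scale.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param px_per_mm Optional pixel pitch override, pixels/mm.
#' @return A `gray_image`.
#' @export
read_gray_image <- function(path, px_per_mm = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)
  if (is.null(px_per_mm)) {
    sidecar <- paste0(path, ".json")
    px_per_mm <- if (file.exists(sidecar))
      jsonlite::read_json(sidecar)$px_per_mm else 52
  }
  gray_image(a * 255, px_per_mm)
}

#' Write a binary mask as PNG
#'
#' @param bin A `binary_structure`.
#' @param path Output path (`.png`); a JSON sidecar with the pixel pitch
#'   and preprocessing provenance is written next to it.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(bin, path) {
  stopifnot(inherits(bin, "binary_structure"))
  png::writePNG(bin$mask * 1, path)
  jsonlite::write_json(c(list(px_per_mm = bin$px_per_mm), bin$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

# Shift a matrix by (dr, dc) with edge replication.
.shift_rep <- function(m, dr, dc) {
  m[pmin(pmax(seq_len(nrow(m)) + dr, 1), nrow(m)),
    pmin(pmax(seq_len(ncol(m)) + dc, 1), ncol(m)), drop = FALSE]
}

# Vectorized 3x3 median via the 19-exchange median-of-9 sorting network
# (Paeth), on edge-replicated shifts.
.median3 <- function(m) {
  p <- list()
  for (dr in -1:1) for (dc in -1:1)
    p[[length(p) + 1]] <- .shift_rep(m, dr, dc)
  xch <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  net <- list(c(2, 3), c(5, 6), c(8, 9), c(1, 2), c(4, 5), c(7, 8),
              c(2, 3), c(5, 6), c(8, 9), c(1, 4), c(6, 9), c(5, 8),
              c(4, 7), c(2, 5), c(3, 6), c(5, 8), c(5, 3), c(7, 5),
              c(5, 3))
  for (e in net) xch(e[1], e[2])
  p[[5]]
}

# Separable box mean with edge-replicated borders (running sums).
.box_mean <- function(m, w) {
  h <- (w - 1) %/% 2; wk <- 2 * h + 1
  pass <- function(m) {                      # smooth along rows
    nr <- nrow(m)
    padded <- m[c(rep(1, h), seq_len(nr), rep(nr, h)), , drop = FALSE]
    cs <- apply(padded, 2, cumsum)
    (rbind(cs[seq(wk, nrow(cs)), , drop = FALSE]) -
       rbind(0, cs[seq_len(nrow(cs) - wk), , drop = FALSE])) / wk
  }
  t(pass(t(pass(m))))
}

#' Binarize a structure photograph by local-mean thresholding
#'
#' Each pixel is first replaced by the median of its
#' `median_window` x `median_window` neighborhood to suppress shot
#' noise, then compared against the local mean over a
#' `threshold_window` x `threshold_window` box (edge-replicated
#' borders): a pixel is foreground iff its filtered intensity exceeds
#' local mean + `threshold_offset`.  Local thresholding makes the
#' result invariant to global intensity shifts and robust to the uneven
#' illumination of ring-light photographs; the window should be about
#' four times the expected filament width in pixels (default 101 px at
#' 52 px/mm for a 0.61 mm nozzle).  `threshold_offset` rejects
#' background noise; raise it to a few noise standard deviations for
#' noisy acquisitions.
#'
#' @param image A `gray_image`.
#' @param median_window Odd median-filter window edge, px (default 3;
#'   1 disables the filter).
#' @param threshold_window Local-mean window edge, px, >= 3.
#' @param threshold_offset Intensity offset added to the local mean.
#' @return An object of class `binary_structure`: logical `mask`
#'   (TRUE = printed material), `px_per_mm`, and the preprocessing
#'   `provenance`.
#' @export
binarize <- function(image, median_window = 3, threshold_window = 101,
                     threshold_offset = 0) {
  stopifnot(inherits(image, "gray_image"))
  if (!length(image$pixels)) stop("invalid image")
  if (median_window < 1 || median_window %% 2 != 1)
    stop("median_window must be odd and >= 1")
  if (threshold_window < 3) stop("threshold_window must be >= 3")
  px <- image$pixels
  scale <- max(px, 255)                       # EBImage filters want [0,1]
  f <- px / scale
  if (median_window == 3) f <- .median3(f)
  else if (median_window > 1)
    f <- EBImage::medianFilter(f, (median_window - 1) / 2)
  local_mean <- .box_mean(f, threshold_window)
  # the 1e-9 guard absorbs running-sum rounding in the box mean so a
  # uniform region can never self-threshold
  mask <- f > local_mean + threshold_offset / scale + 1e-9
  structure(list(mask = matrix(as.logical(mask), nrow(px), ncol(px)),
                 px_per_mm = image$px_per_mm,
                 provenance = list(median_window = median_window,
                                   threshold_window = threshold_window,
                                   threshold_offset = threshold_offset)),
            class = "binary_structure")
}

#' @export
print.binary_structure <- function(x, ...) {
  cat(sprintf("Binary structure %d x %d px, %.3g%% foreground (%g px/mm)\n",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask), x$px_per_mm))
  invisible(x)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards with a union-find pass.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]),  as.vector(lab[-1, -nc])))  # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      while (parent[a] != a) a <- parent[a]
      while (parent[b] != b) b <- parent[b]
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nlab), function(i) {
    while (parent[i] != i) i <- parent[i]; i
  }, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

# Shoelace signed area of a closed polyline (x, y in mm).
.polygon_area <- function(x, y) {
  n <- length(x)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

# Trace sub-pixel boundaries of a single-component submask at the
# half-pixel contour level (marching squares via contourLines).  Returns
# closed polylines as two-column (x, y) mm matrices in global
# coordinates; the largest |area| polyline is the outer boundary.
.trace_boundaries <- function(submask, row0, col0, px_per_mm) {
  padded <- matrix(0, nrow(submask) + 2, ncol(submask) + 2)
  padded[2:(nrow(submask) + 1), 2:(ncol(submask) + 1)] <- submask
  cl <- grDevices::contourLines(x = seq_len(nrow(padded)),
                                y = seq_len(ncol(padded)),
                                z = padded, levels = 0.5)
  polys <- lapply(cl, function(p) {
    # p$x are row indices in the padded frame, p$y column indices
    row_g <- p$x - 1 + row0; col_g <- p$y - 1 + col0
    m <- cbind(x = col_g / px_per_mm, y = row_g / px_per_mm)
    if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])  # close
    m
  })
  areas <- vapply(polys, function(m) abs(.polygon_area(m[, 1], m[, 2])),
                  numeric(1))
  list(outer = polys[[which.max(areas)]],
       holes = polys[order(areas, decreasing = TRUE)][-1])
}

#' Segment a binary mask into labeled components
#'
#' 8-connected component labeling; components smaller than
#' `min_area_mm2` are discarded as debris.  Each retained component
#' carries its area, centroid and bounding box in mm, its pixel
#' coordinates, and closed outer / interior-hole boundary polylines
#' traced at the half-pixel contour level (sub-pixel, marching-squares
#' style), so radii and angles are not quantized to whole pixels.
#'
#' @param bin A `binary_structure`.
#' @param min_area_mm2 Minimum component area, mm^2 (default 0.2:
#'   suppresses specks without deleting thin filaments).
#' @return An object of class `labeled_components`: list `components`
#'   (sorted by area, descending), `px_per_mm`, `label_image`.
#'   Each component has `area_mm2`, `centroid` (x, y mm), `bbox_mm`
#'   (xmin, xmax, ymin, ymax), `n_pixels`, `pixels` (row/col matrix),
#'   `outer` boundary polyline and `holes` polyline list (mm).
#' @export
segment_components <- function(bin, min_area_mm2 = 0.2) {
  stopifnot(inherits(bin, "binary_structure"))
  if (!length(bin$mask)) stop("invalid image")
  ppm <- bin$px_per_mm
  lab <- .label8(bin$mask)
  nlab <- max(lab)
  if (nlab == 0) stop("no object detected")
  counts <- tabulate(lab[lab > 0], nlab)
  keep <- which(counts / ppm^2 >= min_area_mm2)
  if (!length(keep)) stop("no object detected")
  keep <- keep[order(counts[keep], decreasing = TRUE)]
  comps <- lapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    rows <- range(idx[, 1]); cols <- range(idx[, 2])
    sub <- matrix(0, diff(rows) + 1, diff(cols) + 1)
    sub[cbind(idx[, 1] - rows[1] + 1, idx[, 2] - cols[1] + 1)] <- 1
    b <- .trace_boundaries(sub, rows[1], cols[1], ppm)
    list(label = k,
         n_pixels = nrow(idx),
         area_mm2 = nrow(idx) / ppm^2,
         centroid = c(x = mean(idx[, 2]) / ppm, y = mean(idx[, 1]) / ppm),
         bbox_mm = c(xmin = cols[1] / ppm, xmax = cols[2] / ppm,
                     ymin = rows[1] / ppm, ymax = rows[2] / ppm),
         pixels = idx,
         outer = b$outer,
         holes = b$holes)
  })
  structure(list(components = comps, px_per_mm = ppm, label_image = lab,
                 provenance = bin$provenance),
            class = "labeled_components")
}

#' @export
print.labeled_components <- function(x, ...) {
  cat(sprintf("%d component(s):\n", length(x$components)))
  for (cc in x$components)
    cat(sprintf("  area %.3g mm^2, centroid (%.2f, %.2f) mm, %d hole(s)\n",
                cc$area_mm2, cc$centroid[1], cc$centroid[2], length(cc$holes)))
  invisible(x)
}

#' Write labeled components to JSON
#'
#' @param components A `labeled_components`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_components_json <- function(components, path) {
  stopifnot(inherits(components, "labeled_components"))
  out <- lapply(components$components, function(cc)
    list(area_mm2 = cc$area_mm2, centroid_mm = as.list(cc$centroid),
         bbox_mm = as.list(cc$bbox_mm),
         outer_boundary = apply(cc$outer, 1, as.list),
         holes = lapply(cc$holes, function(h) apply(h, 1, as.list))))
  jsonlite::write_json(list(px_per_mm = components$px_per_mm,
                            components = out),
                       path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}

#' Crop a binary mask to the region of interest
#'
#' The mask is cropped to the union bounding box of the components that
#' survive the debris filter, expanded by `margin_mm` on each side.
#'
#' @param bin A `binary_structure`.
#' @param structure_kind Structure kind the ROI is for (`"line"`,
#'   `"circle"` or `"angle"`); recorded in the provenance.
#' @param margin_mm Margin around the union bounding box, mm.
#' @param min_area_mm2 Debris filter forwarded to [segment_components()].
#' @return A cropped `binary_structure`; the provenance records the
#'   pixel offset (`roi_row0`, `roi_col0`) of the crop.
#' @export
crop_roi <- function(bin, structure_kind = c("line", "circle", "angle"),
                     margin_mm = 2, min_area_mm2 = 0.2) {
  structure_kind <- match.arg(structure_kind)
  stopifnot(inherits(bin, "binary_structure"))
  if (!any(bin$mask)) stop("no object detected")
  seg <- segment_components(bin, min_area_mm2)
  ppm <- bin$px_per_mm
  rows <- range(unlist(lapply(seg$components, function(cc) cc$pixels[, 1])))
  cols <- range(unlist(lapply(seg$components, function(cc) cc$pixels[, 2])))
  m <- round(margin_mm * ppm)
  r0 <- max(1, rows[1] - m); r1 <- min(nrow(bin$mask), rows[2] + m)
  c0 <- max(1, cols[1] - m); c1 <- min(ncol(bin$mask), cols[2] + m)
  structure(list(mask = bin$mask[r0:r1, c0:c1, drop = FALSE],
                 px_per_mm = ppm,
                 provenance = c(bin$provenance,
                                list(roi_kind = structure_kind,
                                     roi_row0 = r0, roi_col0 = c0,
                                     roi_margin_mm = margin_mm))),
            class = "binary_structure")
}
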