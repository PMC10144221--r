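# Shared fixtures: small rendered structures are cached per session so
# several tests can reuse one render, and a minimal even-odd polygon
# rasterizer supports constructed-geometry oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached_render <- function(key, spec) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, render_structure(spec), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Standard analysis chain used throughout the tests: the threshold
# offset of 20 intensity units sits a few noise standard deviations
# above the local mean for the renderer's 180-unit contrast.
analyze_render <- function(render, kind, offset = 20, ...) {
  seg <- segment_components(binarize(render$image,
                                     threshold_offset = offset))
  analyze_structure(seg, cad_target(kind), ...)
}

# Even-odd rule point-in-polygon (vectorized over points).
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    if (any(cross)) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
      inside[cross] <- xor(inside[cross], px[cross] < xint[cross])
    }
    j <- i
  }
  inside
}

# Rasterize a polygon (mm coordinates) into a binary_structure.
polygon_mask <- function(vx, vy, px_per_mm = 52, pad_mm = 2) {
  cols <- seq(floor((min(vx) - pad_mm) * px_per_mm),
              ceiling((max(vx) + pad_mm) * px_per_mm))
  rows <- seq(floor((min(vy) - pad_mm) * px_per_mm),
              ceiling((max(vy) + pad_mm) * px_per_mm))
  px <- rep(cols / px_per_mm, each = length(rows))
  py <- rep(rows / px_per_mm, times = length(cols))
  m <- matrix(points_in_polygon(px, py, vx, vy),
              nrow = length(rows), ncol = length(cols))
  structure(list(mask = m, px_per_mm = px_per_mm,
                 provenance = list(constructed = TRUE)),
            class = "binary_structure")
}
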