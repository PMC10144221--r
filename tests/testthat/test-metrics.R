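# Normalized printing-accuracy metrics for line, circle and angle
# structures, validated against rendered ground truth and constructed
# geometry.

test_that("an ideal line print scores w_n = l_n = 1", {
  r <- cached_render("line61", render_spec(cad_target("line"), seed = 3))
  m <- analyze_render(r, "line")
  expect_equal(m$normalized_width, 1, tolerance = 0.05)
  expect_equal(m$normalized_length, 1, tolerance = 0.01)
  expect_equal(m$segment_count, 1)
  expect_false(m$interrupted)
})

test_that("over-extruded and short lines are quantified", {
  r <- render_structure(render_spec(cad_target("line"),
                                    stroke_width = 0.915,
                                    actual_length = 28.5, seed = 14))
  m <- analyze_render(r, "line")
  expect_equal(m$normalized_width, 1.5, tolerance = 0.05)
  expect_equal(m$normalized_length, 0.95, tolerance = 0.01)
})

test_that("an interrupted line reports its segments", {
  r <- render_structure(render_spec(cad_target("line"),
                                    gaps = list(c(14, 2)), seed = 4))
  m <- analyze_render(r, "line")
  expect_true(m$interrupted)
  expect_equal(m$segment_count, 2)
  expect_equal(m$normalized_length, r$truth$l_n, tolerance = 0.01)
  expect_error(analyze_line(
    segment_components(binarize(r$image, threshold_offset = 20)),
    cad_target("circle")), "structure/CAD mismatch")
})

test_that("cross-section width equals area/length on a rectangle", {
  # isolated rectangle: the two width estimators must agree
  m <- matrix(FALSE, 200, 1700)
  m[90:121, 50:1650] <- TRUE               # 32 px x 1601 px
  bin <- structure(list(mask = m, px_per_mm = 52, provenance = list()),
                   class = "binary_structure")
  seg <- segment_components(bin)
  lm_ <- analyze_line(seg, cad_target("line"))
  area_over_length <- seg$components[[1]]$area_mm2 /
    (1601 / 52)
  expect_equal(lm_$width, area_over_length, tolerance = 0.02)
})

test_that("a perfectly placed circle scores r_n = 1 for any stroke", {
  r <- cached_render("circ61", render_spec(cad_target("circle"), seed = 5))
  m <- analyze_render(r, "circle")
  expect_equal(m$inner_radius, 14.695, tolerance = 0.03)
  expect_equal(m$outer_radius, 15.305, tolerance = 0.03)
  expect_equal(m$normalized_radii, 1, tolerance = 0.002)
  expect_equal(m$normalized_width, 1, tolerance = 0.05)
  expect_true(m$marker_found)
})

test_that("an off-radius circle shifts r_n by the radial offset", {
  r <- render_structure(render_spec(cad_target("circle"),
                                    actual_radius = 15.3, seed = 21))
  m <- analyze_render(r, "circle")
  # (14.995 + 15.605) / 30 for a symmetric 0.61 mm stroke at 15.3 mm
  expect_equal(m$normalized_radii, 1.02, tolerance = 0.002)
})

test_that("a wide circle stroke changes w_n but not r_n", {
  r <- render_structure(render_spec(cad_target("circle"),
                                    stroke_width = 0.915, seed = 22))
  m <- analyze_render(r, "circle")
  expect_equal(m$normalized_width, 1.5, tolerance = 0.05)
  expect_equal(m$normalized_radii, 1, tolerance = 0.002)
})

test_that("a solid component without a hole is not a ring", {
  nr <- 300
  d <- sqrt(outer((1:nr - 150)^2, (1:nr - 150)^2, `+`))
  bin <- structure(list(mask = d < 100, px_per_mm = 52,
                        provenance = list()),
                   class = "binary_structure")
  expect_error(analyze_circle(segment_components(bin),
                              cad_target("circle")), "no ring detected")
})

test_that("an ideal angle composite scores a_n = 1 at every vertex", {
  r <- cached_render("angle6", render_spec(cad_target("angle"), seed = 6))
  m <- analyze_render(r, "angle")
  expect_equal(nrow(m$vertices), 3)
  expect_equal(m$vertices$designed, c(30, 45, 60))
  expect_equal(m$vertices$normalized, c(1, 1, 1), tolerance = 0.03)
  expect_equal(m$normalized_width, r$truth$w_n, tolerance = 0.05)
  expect_true(all(m$vertices$inner > 0 & m$vertices$inner < 180))
  expect_length(m$widths, 5)
})

test_that("widened corners raise a_n by the boundary-angle offset", {
  r <- render_structure(render_spec(cad_target("angle"),
                                    angle_offsets = 3, seed = 23))
  m <- analyze_render(r, "angle")
  # 45 degree vertex printed at 48: (48 + 48) / 90
  expect_equal(m$vertices$normalized[2], 48 / 45, tolerance = 0.03)
  expect_equal(m$vertices$normalized, r$truth$a_n, tolerance = 0.03)
})

test_that("constructed asymmetric corner averages inner and outer angles", {
  # band whose inner boundary arms meet at 40 deg and outer at 50 deg
  # around a designed 45 deg vertex: a_n = (40 + 50) / 90 = 1
  arm <- 12; w <- 0.7
  half_i <- 40 / 2 * pi / 180; half_o <- 50 / 2 * pi / 180
  apex_o <- c(20, 20)
  apex_i <- c(20, 20 + w / sin(half_o))   # inner apex up the bisector
  end_o_l <- apex_o + arm * c(-sin(half_o), cos(half_o))
  end_o_r <- apex_o + arm * c(sin(half_o), cos(half_o))
  end_i_l <- apex_i + (arm - 1) * c(-sin(half_i), cos(half_i))
  end_i_r <- apex_i + (arm - 1) * c(sin(half_i), cos(half_i))
  # round caps joining outer to inner boundary at each band end
  cap_arc <- function(A, B, away) {
    m <- (A + B) / 2
    th <- seq(0, pi, length.out = 24)
    rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                            sin(a) * v[1] + cos(a) * v[2])
    pts <- t(vapply(th, function(a) m + rot(A - m, a), numeric(2)))
    mid <- pts[12, ]
    if (sum((mid - m) * away) < 0)
      pts <- t(vapply(-th, function(a) m + rot(A - m, a), numeric(2)))
    pts
  }
  right <- cap_arc(end_o_r, end_i_r, c(sin(half_o), cos(half_o)))
  left <- cap_arc(end_i_l, end_o_l, c(-sin(half_o), cos(half_o)))
  poly <- rbind(end_o_l, apex_o, end_o_r, right, end_i_r, apex_i,
                end_i_l, left)
  bin <- polygon_mask(poly[, 1], poly[, 2])
  m <- analyze_angle(segment_components(bin),
                     cad_target("angle", designed_angles = 45))
  expect_equal(m$vertices$inner + m$vertices$outer, 90, tolerance = 2)
  expect_equal(m$vertices$normalized, 1, tolerance = 0.022)
})

test_that("vertex count mismatch with the CAD target is an error", {
  r <- cached_render("angle6", render_spec(cad_target("angle"), seed = 6))
  seg <- segment_components(binarize(r$image, threshold_offset = 20))
  expect_error(analyze_angle(seg, cad_target("angle",
                                             designed_angles = c(30, 45))),
               "structure/CAD mismatch")
})

test_that("normalized metrics are pixel-pitch invariant", {
  base <- cad_target("circle")
  m <- lapply(c(52, 104), function(ppm) {
    r <- render_structure(render_spec(base, px_per_mm = ppm, seed = 30))
    seg <- segment_components(binarize(r$image, threshold_offset = 20,
                                       threshold_window = 2 * ppm - 3))
    analyze_circle(seg, base)
  })
  expect_lt(abs(m[[1]]$normalized_radii - m[[2]]$normalized_radii), 0.01)
  expect_lt(abs(m[[1]]$normalized_width - m[[2]]$normalized_width) /
              m[[1]]$normalized_width, 0.01)
})

test_that("normalized metrics are rotation invariant", {
  m <- lapply(c(0, 73), function(rot) {
    r <- render_structure(render_spec(cad_target("angle"), rotation = rot,
                                      seed = 31))
    analyze_render(r, "angle")
  })
  expect_lt(max(abs(m[[1]]$vertices$normalized -
                    m[[2]]$vertices$normalized)), 0.02)
  expect_lt(abs(m[[1]]$normalized_width - m[[2]]$normalized_width) /
              m[[1]]$normalized_width, 0.02)
})

test_that("metrics_row flattens each metric kind", {
  r <- cached_render("line61", render_spec(cad_target("line"), seed = 3))
  row <- metrics_row(analyze_render(r, "line"))
  expect_equal(row$kind, "line")
  expect_false(is.na(row$w_n))
  expect_true(is.na(row$r_n))
  ra <- cached_render("angle6", render_spec(cad_target("angle"), seed = 6))
  rowa <- metrics_row(analyze_render(ra, "angle"))
  expect_true(all(c("a_n_30", "a_n_45", "a_n_60") %in% names(rowa)))
})
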