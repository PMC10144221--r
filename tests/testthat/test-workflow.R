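# Uncertainty propagation, normality/ANOVA aggregation and pipeline
# orchestration.

test_that("Taylor propagation matches the closed linear form", {
  expect_equal(propagate_uncertainty(c(1, 1) / 30, c(0.03, 0.03)),
               sqrt(2) * 0.03 / 30)
  expect_equal(propagate_uncertainty(1, 0.2), 0.2)
  expect_error(propagate_uncertainty(c(1, 2), 0.1), "invalid input")
  expect_error(propagate_uncertainty(1, -0.1), "invalid input")
})

test_that("Taylor propagation agrees with a Monte-Carlo oracle", {
  set.seed(31)
  # normalized angle: a_n = (a_i + a_o) / (2 * 45), sd 1.2 deg each
  draws <- (rnorm(1e5, 44, 1.2) + rnorm(1e5, 47, 1.2)) / 90
  mc <- sd(draws)
  taylor <- propagate_uncertainty(c(1, 1) / 90, c(1.2, 1.2))
  expect_lt(abs(taylor - mc) / mc, 0.02)
  # normalized radii: r_n = (r_i + r_o) / (2 * 15)
  draws_r <- (rnorm(1e5, 14.7, 0.03) + rnorm(1e5, 15.3, 0.03)) / 30
  expect_lt(abs(propagate_uncertainty(c(1, 1) / 30, c(0.03, 0.03)) -
                sd(draws_r)) / sd(draws_r), 0.02)
})

test_that("Jarque-Bera statistic matches an external oracle value", {
  # frozen vector (set.seed(42); rnorm(30)) with statistic and p-value
  # computed independently in statsmodels
  x <- c(1.370958, -0.564698, 0.363128, 0.632863, 0.404268, -0.106125,
         1.511522, -0.094659, 2.018424, -0.062714, 1.30487, 2.286645,
         -1.388861, -0.278789, -0.133321, 0.63595, -0.284253, -2.656455,
         -2.440467, 1.320113, -0.306639, -1.781308, -0.171917, 1.214675,
         1.895193, -0.430469, -0.257269, -1.763163, 0.460097, -0.639995)
  jb <- jarque_bera(x)
  expect_equal(unname(jb$statistic), 0.5846612159, tolerance = 1e-8)
  expect_equal(jb$p.value, 0.7465216891, tolerance = 1e-8)
  expect_error(jarque_bera(rep(1, 10)), "constant")
  # heavy-tailed data is rejected
  set.seed(8)
  expect_lt(jarque_bera(rt(500, df = 2))$p.value, 0.01)
})

test_that("aggregation summarizes groups and flags degenerate ANOVA", {
  d <- data.frame(formulation = rep(c("A3G3", "A4G3"), each = 24),
                  w_n = rep(1.5, 48))
  agg <- aggregate_metrics(d, "w_n")
  expect_equal(agg$groups$sd, c(0, 0))
  expect_equal(agg$groups$n, c(24, 24))
  expect_false(agg$anova$applicable)
  expect_error(aggregate_metrics(data.frame(x = 1)), "formulation")
})

test_that("ANOVA flags a real effect at the study's sample size", {
  set.seed(9)
  d <- data.frame(formulation = rep(c("a", "b"), each = 24),
                  w_n = c(rnorm(24, 1.00, 0.05), rnorm(24, 1.10, 0.05)))
  agg <- aggregate_metrics(d, "w_n")
  expect_true(agg$anova$significant)
  expect_true(all(agg$groups$normal))
  expect_equal(nrow(agg$pairwise), 1)
})

test_that("type-I error of the group comparison is near nominal", {
  set.seed(10)
  hits <- vapply(1:400, function(i) {
    d <- data.frame(formulation = rep(c("a", "b"), each = 24),
                    w_n = rnorm(48, 1.5, 0.1))
    aggregate_metrics(d, "w_n")$anova$significant
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.025)
})

test_that("the pipeline processes a mixed batch end to end", {
  dir <- tempfile("batch_")
  dir.create(dir)
  imgs <- list()
  for (i in 1:2) {
    r <- render_structure(render_spec(cad_target("line"),
                                      stroke_width = 0.61 + 0.05 * i,
                                      seed = 50 + i))
    p <- file.path(dir, sprintf("line_%d.png", i))
    png::writePNG(r$image$pixels / 255, p)
    jsonlite::write_json(list(px_per_mm = 52), paste0(p, ".json"),
                         auto_unbox = TRUE)
    imgs[[i]] <- data.frame(path = p, kind = "line",
                            formulation = c("A3G3", "A4G3")[i],
                            replicate = 1)
  }
  curve_csv <- file.path(dir, "curve.csv")
  sim <- simulate_viscosity(power_law(0.32, 284.09), replicates = 2,
                            seed = 60)
  write.csv(do.call(rbind, lapply(sim$curves, function(cu)
    data.frame(shear_rate_1_per_s = cu$shear_rates,
               viscosity_Pa_s = cu$viscosities,
               replicate = cu$replicate))), curve_csv, row.names = FALSE)
  ev_csv <- file.path(dir, "events.csv")
  csim <- simulate_cytometry(3000, 0.9, seed = 61)
  write.csv(as.data.frame(csim$events), ev_csv, row.names = FALSE)
  cfg <- batch_config(c("A3G3", "A4G3"),
                      binarize_params = list(threshold_offset = 20),
                      out_dir = file.path(dir, "out"))
  res <- run_pipeline(cfg,
                      images = do.call(rbind, imgs),
                      curves = data.frame(path = curve_csv),
                      events = data.frame(path = ev_csv,
                                          formulation = "A3G3",
                                          fsc_lo = 1.3e4, fsc_hi = 2.5e5,
                                          ssc_lo = 8e3, ssc_hi = 1.8e5,
                                          red_threshold = 800,
                                          green_threshold = 1000))
  expect_true(res$ok)
  expect_equal(nrow(res$metrics), 2)
  expect_equal(res$fits[[1]]$model$n, 0.32, tolerance = 0.02)
  expect_equal(res$viability$viability, csim$truth$viability,
               tolerance = 0.02)
  expect_true(file.exists(file.path(cfg$out_dir, "metrics.csv")))
  expect_true(file.exists(file.path(cfg$out_dir, "report.json")))
  # error isolation: a corrupt image is flagged, the rest survive
  bad <- file.path(dir, "broken.png")
  writeLines("not a png", bad)
  res2 <- run_pipeline(cfg,
                       images = rbind(do.call(rbind, imgs),
                                      data.frame(path = bad, kind = "line",
                                                 formulation = "A3G3",
                                                 replicate = 2)))
  expect_false(res2$ok)
  expect_equal(nrow(res2$metrics), 2)
  expect_equal(nrow(res2$failures), 1)
})

test_that("pipeline reports are byte-identical across reruns", {
  dir <- tempfile("det_")
  dir.create(dir)
  r <- render_structure(render_spec(cad_target("line"), seed = 70))
  p <- file.path(dir, "line.png")
  png::writePNG(r$image$pixels / 255, p)
  jsonlite::write_json(list(px_per_mm = 52), paste0(p, ".json"),
                       auto_unbox = TRUE)
  imgs <- data.frame(path = p, kind = "line", formulation = "A3G3",
                     replicate = 1)
  run_once <- function(out) {
    cfg <- batch_config("A3G3",
                        binarize_params = list(threshold_offset = 20),
                        out_dir = out)
    run_pipeline(cfg, images = imgs)
    readBin(file.path(out, "metrics.csv"), "raw",
            file.size(file.path(out, "metrics.csv")))
  }
  expect_identical(run_once(file.path(dir, "o1")),
                   run_once(file.path(dir, "o2")))
})
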