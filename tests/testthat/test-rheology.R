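# Ostwald-de Waele fitting and power-law Hagen-Poiseuille planning.

test_that("fit recovers exact power-law parameters from noiseless curves", {
  # Newtonian limit: constant viscosity
  g <- 10^seq(-1, 3, length.out = 20)
  fit <- fit_power_law(viscosity_curve(g, rep(2, 20)), c(0.1, Inf))
  expect_equal(fit$n, 1, tolerance = 1e-9)
  expect_equal(fit$K, 2, tolerance = 1e-9)
  # shear-thinning parameter sets used for the two alginate/GelMA inks
  for (par in list(c(0.35, 146.39), c(0.32, 284.09))) {
    g <- 10^seq(0, 3, length.out = 20)
    fit <- fit_power_law(viscosity_curve(g, par[2] * g^(par[1] - 1)))
    expect_equal(unname(coef(fit)), par, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("fit range excludes the low-shear plateau and rejects sparse data", {
  g <- 10^seq(-1, 3, length.out = 40)
  eta <- 146.39 * g^(0.35 - 1)
  eta[g < 1] <- 150                      # viscosity plateau at low shear
  fit <- fit_power_law(viscosity_curve(g, eta), c(1, 1000))
  expect_equal(fit$n, 0.35, tolerance = 1e-6)
  expect_error(fit_power_law(viscosity_curve(g, eta), c(900, 1000)),
               "insufficient data")
  expect_error(viscosity_curve(c(1, 2), c(1, 2)), "invalid curve")
  expect_error(viscosity_curve(c(1, 2, 2), c(1, 2, 3)), "invalid curve")
  expect_error(viscosity_curve(c(1, 2, 3), c(1, -2, 3)), "invalid curve")
})

test_that("fit recovers parameters from noisy pooled replicates", {
  for (par in list(c(0.35, 146.39), c(0.32, 284.09))) {
    truth <- power_law(par[1], par[2])
    sim <- simulate_viscosity(truth, c(0.1, 1000), points = 30,
                              noise_cv = 0.05, replicates = 9, seed = 101)
    fit <- fit_power_law(sim$curves, c(0.1, Inf))
    expect_lt(abs(fit$n - par[1]), 0.02)
    expect_lt(abs(fit$K - par[2]) / par[2], 0.05)
  }
})

test_that("viscosity prediction follows eta = K shear^(n-1)", {
  expect_equal(viscosity_at(power_law(1, 2), 17), 2)
  expect_equal(viscosity_at(power_law(0.32, 284.09), 1), 284.09)
  # the stiffer ink stays more viscous at process shear rates
  ratio <- viscosity_at(power_law(0.32, 284.09), 1000) /
    viscosity_at(power_law(0.35, 146.39), 1000)
  expect_equal(ratio, 1.58, tolerance = 0.01)
  expect_error(viscosity_at(power_law(1, 1), -1), "invalid shear rate")
  # shear thinning: strictly decreasing viscosity for n < 1
  g <- 10^seq(-1, 3, length.out = 50)
  expect_true(all(diff(viscosity_at(power_law(0.4, 100), g)) < 0))
})

test_that("pressure planning reproduces the printed operating point", {
  nz <- nozzle_geometry()                # 0.61 mm ID, 12.7 mm length
  p <- required_pressure(power_law(0.32, 284.09), nz, 10)
  expect_equal(p, 129.1, tolerance = 5e-4)
  expect_equal(flow_rate(power_law(0.32, 284.09), nz, p),
               10 * pi * 0.305^2, tolerance = 1e-9)
  plan <- extrusion_plan(power_law(0.32, 284.09), nz, mean_velocity = 10)
  expect_equal(plan$flow_rate, plan$mean_velocity * pi * nz$radius^2)
  expect_error(required_pressure(power_law(1, 1), nz, 0), "invalid velocity")
  expect_error(flow_rate(power_law(1, 1), nz, -5), "invalid pressure")
})

test_that("Newtonian limit matches the classical Hagen-Poiseuille formulas", {
  set.seed(1)
  for (i in 1:100) {
    mu <- runif(1, 0.1, 100)
    R <- runif(1, 0.05, 1) * 1e-3; l <- runif(1, 2, 40) * 1e-3
    p <- runif(1, 1, 500) * 1e3
    q_classic <- pi * R^4 * p / (8 * mu * l) * 1e9
    q <- flow_rate(power_law(1, mu),
                   nozzle_geometry(R * 1e3, l * 1e3), p * 1e-3)
    expect_equal(q, q_classic, tolerance = 1e-12)
    v <- runif(1, 0.5, 30)               # mm/s
    p_classic <- 8 * mu * (l) * (v * 1e-3) / R^2 * 1e-3
    expect_equal(required_pressure(power_law(1, mu),
                                   nozzle_geometry(R * 1e3, l * 1e3), v),
                 p_classic, tolerance = 1e-12)
  }
})

test_that("pressure/flow inversion roundtrips for random fluids", {
  set.seed(2)
  for (i in 1:200) {
    m <- power_law(runif(1, 0.1, 1), runif(1, 1, 1000))
    nz <- nozzle_geometry(runif(1, 0.05, 1), runif(1, 2, 40))
    v <- runif(1, 0.1, 50)
    p <- required_pressure(m, nz, v)
    expect_equal(flow_rate(m, nz, p), v * pi * nz$radius^2,
                 tolerance = 1e-9)
  }
})

test_that("required pressure is monotone in velocity, K, l and radius", {
  base <- list(n = 0.4, K = 200, R = 0.305, l = 12.7, v = 10)
  p0 <- required_pressure(power_law(base$n, base$K),
                          nozzle_geometry(base$R, base$l), base$v)
  expect_gt(required_pressure(power_law(base$n, base$K),
                              nozzle_geometry(base$R, base$l), 2 * base$v), p0)
  expect_gt(required_pressure(power_law(base$n, 2 * base$K),
                              nozzle_geometry(base$R, base$l), base$v), p0)
  expect_gt(required_pressure(power_law(base$n, base$K),
                              nozzle_geometry(base$R, 2 * base$l), base$v), p0)
  expect_lt(required_pressure(power_law(base$n, base$K),
                              nozzle_geometry(2 * base$R, base$l), base$v), p0)
})

test_that("viscosity CSV roundtrips through the reader", {
  g <- 10^seq(0, 2, length.out = 10)
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(shear_rate_1_per_s = rep(g, 2),
                       viscosity_Pa_s = rep(100 * g^-0.6, 2),
                       replicate = rep(c("a", "b"), each = 10)),
            f, row.names = FALSE)
  curves <- read_viscosity_csv(f)
  expect_length(curves, 2)
  expect_equal(curves[[1]]$viscosities, 100 * g^-0.6)
  expect_error(read_viscosity_csv(tempfile()), "file not found")
})
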