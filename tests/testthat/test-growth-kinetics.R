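test_that("log2 regression recovers exact and degenerate rates", {
  e <- estimate_growth_rate(doubling_series())
  expect_equal(e$rate, 1, tolerance = 1e-14)
  expect_equal(e$r_squared, 1, tolerance = 1e-14)
  expect_equal(e$n_points, 4L)

  flat <- fluorescence_series("c", 10, 1, 0:2, c(500, 500, 500))
  ef <- estimate_growth_rate(flat)
  expect_identical(ef$rate, 0)
  expect_gte(ef$r_squared, 0)
  expect_lte(ef$r_squared, 1)
})

test_that("estimate matches the closed-form OLS oracle on noisy data", {
  # series with true rate 0.8 and multiplicative lognormal noise
  tt <- 0:5
  f0 <- with_seed(71, 3000 * 2^(0.8 * tt) * exp(rnorm(6, 0, 0.05)))
  e <- estimate_growth_rate(fluorescence_series("x", 15, 1, tt, f0))
  # independent hand evaluation of the OLS slope on the same log2 values
  y <- log2(f0)
  slope <- sum((tt - mean(tt)) * (y - mean(y))) / sum((tt - mean(tt))^2)
  expect_equal(e$rate, slope, tolerance = 1e-12)
  expect_equal(e$rate, 0.8, tolerance = 0.1)
})

test_that("rate is invariant to f0 scaling and time shifts, exact on noise-free data", {
  for (i in 1:20) {
    r <- with_seed(100 + i, runif(1, -0.5, 2))
    tt <- 0:5
    f0 <- 1500 * 2^(r * tt)
    base <- estimate_growth_rate(fluorescence_series("p", 10, 1, tt, f0),
                                 window = range(tt))
    expect_equal(base$rate, r, tolerance = 1e-10)
    scaled <- estimate_growth_rate(
      fluorescence_series("p", 10, 1, tt, f0 * 37.5), window = range(tt))
    expect_equal(scaled$rate, base$rate, tolerance = 1e-10)
    shifted <- estimate_growth_rate(
      fluorescence_series("p", 10, 1, tt + 11, f0), window = range(tt) + 11)
    expect_equal(shifted$rate, base$rate, tolerance = 1e-10)
  }
})

test_that("window selection restricts the regression and auto mode maximizes r2", {
  # exponential for 5 days then a plateau: the default window must ignore day 6+
  tt <- 0:8
  f0 <- c(100 * 2^(0:5), rep(3200, 3))
  e <- estimate_growth_rate(fluorescence_series("w", 20, 1, tt, f0))
  expect_equal(e$rate, 1, tolerance = 1e-10)
  expect_equal(e$n_points, 6L)
  # auto picks a clean contiguous run covering the exponential phase
  ea <- estimate_growth_rate(fluorescence_series("w", 20, 1, tt, f0),
                             window = "auto")
  expect_gte(ea$r_squared, 0.999)
  expect_gte(ea$n_points, 4L)
})

test_that("nonpositive f0 and short windows raise named errors", {
  s <- fluorescence_series("bad", 5, 2, 0:3, c(100, 0, 400, 800))
  expect_error(estimate_growth_rate(s), "day 1")
  expect_error(estimate_growth_rate(s), "bad")
  expect_warning(e <- estimate_growth_rate(s, drop_nonpositive = TRUE),
                 "dropping")
  expect_equal(e$n_points, 3L)
  expect_error(estimate_growth_rate(doubling_series(), window = c(10, 12)),
               "fewer than 2")
  expect_error(fluorescence_series("x", 1, 1, c(0, 0, 1), c(1, 2, 3)),
               "strictly increasing")
  expect_error(fluorescence_series("x", 1, 1, 1, 5), "at least 2")
})

test_that("replicate averaging uses the sample-sd standard error", {
  s <- average_replicates(list(list(rate = 1), list(rate = 1),
                               list(rate = 1), list(rate = 1)))
  expect_equal(s$mean_rate, 1)
  expect_identical(s$se_rate, 0)

  s2 <- average_replicates(lapply(c(0.9, 1.0, 1.1, 1.0),
                                  function(r) list(rate = r)))
  expect_equal(s2$mean_rate, 1)
  expect_equal(s2$se_rate, sqrt(0.02 / 3) / 2, tolerance = 1e-12)
  expect_equal(s2$n_replicates, 4L)

  expect_error(average_replicates(list()), "empty")
  mixed <- list(list(rate = 1, strain_id = "a", temperature = 5),
                list(rate = 2, strain_id = "b", temperature = 5))
  expect_error(average_replicates(mixed), "mix strains")
})

test_that("viability fractions and verdicts follow the counts", {
  dead <- viability_fraction(data.frame(viable = c(0, 0, 0), total = 400))
  expect_equal(dead$mean_fraction, 0)
  expect_identical(dead$verdict, "no viable cells")

  v <- viability_fraction(data.frame(viable = c(20, 40, 60), total = 400))
  expect_equal(v$fractions, c(0.05, 0.10, 0.15))
  expect_equal(v$mean_fraction, 0.10)
  expect_identical(v$verdict, "viable cells detected")

  all_alive <- viability_fraction(data.frame(viable = 400, total = 400))
  expect_equal(all_alive$mean_fraction, 1)
  expect_error(viability_fraction(data.frame(viable = 0, total = 0)), "> 0")
  expect_error(viability_fraction(data.frame(viable = 5, total = 4)),
               "viable <= total")
})

test_that("F0 CSV round trip reproduces the rate table", {
  sim <- simulate_panel(panel_spec(n_strains = 3, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(sim$f0, path, row.names = FALSE)
  series <- read_f0_csv(path)
  expect_length(series, 3 * 7 * 4)
  tab <- growth_rate_table(series)
  expect_identical(names(tab), c("strain_id", "temperature_c", "mean_rate",
                                 "se_rate", "n_replicates"))
  expect_equal(nrow(tab), 21)
  expect_true(all(tab$n_replicates == 4))
  expect_equal(tab, growth_rate_table(sim$f0))
  expect_error(read_f0_csv({
    p <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), p, row.names = FALSE); p
  }), "missing column")
})
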