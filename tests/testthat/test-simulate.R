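test_that("Yule trees are binary, unit-depth, and bit-reproducible", {
  tr <- simulate_tree(24, seed = 3)
  expect_equal(ape::Ntip(tr), 24)
  expect_equal(tr$Nnode, 23)
  expect_true(all(tr$edge.length > 0))
  d <- ape::node.depth.edgelength(tr)[1:24]
  expect_equal(unname(d), rep(1, 24), tolerance = 1e-12)
  expect_identical(ape::write.tree(tr), ape::write.tree(simulate_tree(24, seed = 3)))
  expect_error(simulate_tree(1), "at least 2")
})

test_that("trait simulation honors its covariance and degenerate cases", {
  tr <- simulate_tree(16, seed = 8)
  expect_identical(simulate_trait(tr, 0, 4.5, 1, seed = 1),
                   stats::setNames(rep(4.5, 16), tr$tip.label))
  expect_identical(simulate_trait(tr, 1, 0, 0.5, seed = 9),
                   simulate_trait(tr, 1, 0, 0.5, seed = 9))
  expect_error(simulate_trait(nonclock_tree(), 1, 0, 1), "ultrametric")
  expect_error(simulate_trait(tr, 1, 0, 1.5), "lambda")

  # Monte-Carlo sample covariance vs sigma2 * C(lambda), elementwise
  sigma2 <- 2; lambda <- 0.6
  C <- ape::vcv(tr)
  V <- sigma2 * (lambda * C + (1 - lambda) * diag(diag(C)))
  draws <- with_seed(10, vapply(1:2000, function(i)
    simulate_trait(tr, sigma2, 0, lambda), numeric(16)))
  S <- stats::cov(t(draws))
  expect_lt(max(abs(S - V)), 0.1 * max(V))
  # diagonal within 10% elementwise (off-diagonals checked on the max above)
  expect_true(all(abs(diag(S) - diag(V)) <= 0.1 * diag(V)))
})

test_that("the strain panel implements its stated couplings", {
  spec <- panel_spec(n_strains = 12, seed = 21)
  panel <- generate_strain_panel(spec)
  p <- panel$params
  expect_equal(nrow(p), 12)
  expect_true(all(p$t_opt >= 9 & p$t_opt <= 27))
  expect_true(all(p$t_max > p$t_opt))
  expect_true(all(p$beta > 0))
  # hotter is better: exactly affine in t_opt with the stated slope, so two
  # strains 10 degC apart in optimum differ by 0.5 divisions/day
  expect_equal(diff(p$mu_max), 0.05 * diff(p$t_opt), tolerance = 1e-12)
  # the 80% width attains its target by construction
  for (i in c(1, 5, 12)) {
    pr <- performance_range(as.list(p[i, c("mu_max", "t_opt", "t_max", "beta")]))
    expect_equal(pr$width, p$width_target[i], tolerance = 1e-6)
    expect_equal(p$width_target[i], 3 + 0.26 * p$t_opt[i], tolerance = 1e-12)
  }
  # metadata invariant: yearly mean is the mean of the four seasons
  ss <- panel$strains
  expect_equal(ss$sst_mean,
               rowMeans(ss[c("sst_winter", "sst_spring", "sst_summer",
                             "sst_autumn")]),
               tolerance = 1e-12)
  expect_true(all(ss$sst_sd >= 0))
})

test_that("noise-free fits round-trip the generated curves", {
  spec <- panel_spec(n_strains = 6, noise_sigma = 0, seed = 22)
  sim <- simulate_panel(spec)
  tab <- growth_rate_table(sim$f0)
  for (sid in sim$params$strain_id[c(1, 4, 6)]) {
    f <- fit_thermal_curve(tab[tab$strain_id == sid, ])
    truth <- sim$params[sim$params$strain_id == sid, ]
    expect_equal(f$mu_max, truth$mu_max, tolerance = 1e-3)
    expect_equal(f$t_opt, truth$t_opt, tolerance = 1e-2)
    expect_equal(f$t_max, truth$t_max, tolerance = 1e-2)
    expect_equal(f$beta, truth$beta, tolerance = 1e-2)
  }
})

test_that("growth simulation is exact without noise and flat above t_max", {
  spec <- panel_spec(n_strains = 2, noise_sigma = 0, seed = 23)
  p <- c(tpc_ref(), list(strain_id = "ref"))
  series <- simulate_growth_experiment(p, spec, seed = 24)
  expect_length(series, 7 * 4)
  for (s in series) {
    mu <- blanchard_growth(s$temperature, tpc_ref())
    e <- estimate_growth_rate(s)
    expect_equal(e$rate, mu, tolerance = 1e-10)
  }
  hot <- Filter(function(s) s$temperature > tpc_ref()$t_max, series)
  expect_gt(length(hot), 0)
  for (s in hot) expect_equal(diff(range(s$f0)), 0)

  # with noise, the mean recovered rate stays near the true curve
  spec2 <- panel_spec(n_strains = 2, noise_sigma = 0.05, seed = 25)
  rates <- with_seed(26, replicate(50, {
    s <- simulate_growth_experiment(p, spec2)[[17]]  # 20 degC, replicate 1
    estimate_growth_rate(s)$rate
  }))
  expect_equal(mean(rates), tpc_ref()$mu_max,
               tolerance = 3 * stats::sd(rates) / sqrt(50))
  expect_error(simulate_growth_experiment(
    p, panel_spec(n_strains = 2, noise_sigma = -1)), "noise_sigma")
})

test_that("written panels are complete and reproducible", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  spec <- panel_spec(n_strains = 4, seed = 27)
  write_panel(simulate_panel(spec), dir1)
  write_panel(simulate_panel(spec), dir2)
  files <- c("f0.csv", "tree.nwk", "strains.csv", "params.csv", "truth.json")
  for (f in files) {
    expect_true(file.exists(file.path(dir1, f)))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  truth <- jsonlite::read_json(file.path(dir1, "truth.json"))
  expect_equal(truth$hotter_slope, 0.05)
  expect_equal(truth$width_slope, 0.26)
  expect_equal(truth$trait_lambda, 0.94)
})
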