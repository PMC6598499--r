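test_that("phylogenetic covariance equals hand-computed shared depths", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_vcv(tr)
  expect_equal(unname(C[c("A", "B", "C"), c("A", "B", "C")]),
               rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))
  expect_true(isSymmetric(C))

  two <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(phylo_vcv(two)), diag(2))

  expect_warning(phylo_vcv(nonclock_tree()), "not ultrametric")
})

test_that("rate smoothing fixes clocklike trees and always equalizes depths", {
  tr <- simulate_tree(8, seed = 2)
  clock <- tr
  clock$edge.length <- tr$edge.length * 0.7
  u <- ultrametricize_pl(clock, 0.1)
  d <- ape::node.depth.edgelength(u)[1:8]
  expect_lt(diff(range(d)) / max(d), 1e-6)
  rates <- attr(u, "rates")
  expect_lt(diff(range(rates)), 1e-4)
  expect_equal(mean(rates), 0.7, tolerance = 1e-3)

  # distorted branch lengths: depths still exactly equal, topology untouched
  warp <- tr
  warp$edge.length <- with_seed(9, tr$edge.length * exp(rnorm(nrow(tr$edge), 0, 0.5)))
  uw <- ultrametricize_pl(warp, 0.1)
  dw <- ape::node.depth.edgelength(uw)[1:8]
  expect_lt(diff(range(dw)) / max(dw), 1e-6)
  expect_true(ape::all.equal.phylo(tr, uw, use.edge.length = FALSE))

  unrooted <- ape::unroot(nonclock_tree())
  expect_error(ultrametricize_pl(unrooted), "rooted")
})

test_that("the smoothing solution matches a brute-force grid optimum", {
  tre <- nonclock_tree()
  u <- ultrametricize_pl(tre, 0.1)
  # iterative grid refinement over the free inner-node age and the 4 rates;
  # node numbering: tips 1-3, root 4, inner node 5
  objective <- function(h, r) pl_objective(tre, c(0, 0, 0, 1, h), r, 0.1)
  lo <- c(0.02, rep(0.005, 4)); hi <- c(0.98, rep(2, 4))
  best <- list(val = -Inf)
  for (pass in 1:4) {
    axes <- mapply(function(l, h) seq(l, h, length.out = 9), lo, hi,
                   SIMPLIFY = FALSE)
    gr <- as.matrix(expand.grid(axes))
    vals <- apply(gr, 1, function(p) objective(p[1], p[2:5]))
    k <- which.max(vals)
    best <- list(par = gr[k, ], val = vals[k])
    step <- (hi - lo) / 8
    lo <- pmax(best$par - step, c(1e-3, rep(1e-4, 4)))
    hi <- best$par + step
  }
  expect_gte(attr(u, "objective"), best$val - 1e-3)
  expect_equal(attr(u, "objective"), best$val, tolerance = 1e-3)
})

test_that("lambda likelihood behaves at its endpoints and rejects degenerate traits", {
  tr <- simulate_tree(32, seed = 13)
  y <- simulate_trait(tr, 1, 0, 0.7, seed = 14)
  fit <- fit_pagels_lambda(tr, y)
  C <- ape::vcv(tr)
  ll_at <- function(lam) {
    V <- C * lam; diag(V) <- diag(C)
    n <- length(y)
    L <- chol(V)
    zy <- backsolve(L, y[rownames(C)], transpose = TRUE)
    z1 <- backsolve(L, rep(1, n), transpose = TRUE)
    a <- sum(z1 * zy) / sum(z1^2)
    s2 <- sum((zy - a * z1)^2) / n
    -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(L))) + n)
  }
  expect_gte(fit$log_likelihood, ll_at(0) - 1e-8)
  expect_gte(fit$log_likelihood, ll_at(1) - 1e-8)
  expect_equal(fit$log_likelihood_0, ll_at(0), tolerance = 1e-8)
  expect_gte(fit$lambda, 0)
  expect_lte(fit$lambda, 1)
  expect_gt(fit$p_value, 0)
  expect_lte(fit$p_value, 1)

  const <- stats::setNames(rep(3, ape::Ntip(tr)), tr$tip.label)
  expect_error(fit_pagels_lambda(tr, const), "constant")
  expect_error(fit_pagels_lambda(tr, y[-1]), "missing for tip")
})

test_that("Blomberg's K matches a component-wise hand assembly on 3 tips", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  y <- c(A = 1.2, B = 0.8, C = 3.1)
  k <- blombergs_k(tr, y)
  # independent assembly from explicit 3x3 matrices
  C <- rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2))
  Ci <- solve(C)
  yv <- y[c("A", "B", "C")]
  a <- sum(Ci %*% yv) / sum(Ci)
  mse0 <- sum((yv - a)^2) / 2
  mse <- drop(t(yv - a) %*% Ci %*% (yv - a)) / 2
  expected <- (sum(diag(C)) - 3 / sum(Ci)) / 2
  expect_equal(k$K, (mse0 / mse) / expected, tolerance = 1e-12)
})

test_that("K is invariant to affine trait transforms", {
  tr <- simulate_tree(24, seed = 31)
  y <- simulate_trait(tr, 2, 5, 1, seed = 32)
  k0 <- blombergs_k(tr, y)$K
  expect_equal(blombergs_k(tr, 3.2 * y + 11)$K, k0, tolerance = 1e-10)
})

test_that("the K permutation test is seeded, bounded, and loses signal on shuffles", {
  tr <- simulate_tree(48, seed = 41)
  y <- simulate_trait(tr, 1, 0, 1, seed = 42)
  p1 <- k_permutation_test(tr, y, n_perm = 199, seed = 7)
  p2 <- k_permutation_test(tr, y, n_perm = 199, seed = 7)
  expect_identical(p1$p_value, p2$p_value)
  expect_gte(p1$p_value, 1 / 200)
  expect_error(k_permutation_test(tr, y, n_perm = 50), "at least 99")

  # shuffling the trait across tips destroys the Brownian signal
  ks <- with_seed(43, replicate(30, blombergs_k(
    tr, stats::setNames(sample(y), names(y)))$K))
  expect_lt(mean(ks), blombergs_k(tr, y)$K)
})
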