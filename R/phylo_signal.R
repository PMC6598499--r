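#' Penalized-likelihood objective for rate smoothing
#'
#' The criterion maximized by [ultrametricize_pl()]: a Poisson branch-length
#' log-likelihood, sum over edges of `b*log(r*t) - r*t` (with `b` the input
#' edge length in expected substitutions, `r` the edge rate, `t` the edge
#' duration implied by the node ages), minus `smoothing` times a roughness
#' penalty: squared rate differences between every ancestor-descendant edge
#' pair, plus the sample variance of the rates of the edges emanating from
#' the root. Exposed so that independent optimizers (e.g. brute-force grid
#' searches in tests) can score candidate solutions.
#'
#' @param tree a rooted `phylo` tree carrying the observed branch lengths.
#' @param ages numeric vector of node ages indexed by ape node number
#'   (length `Ntip + Nnode`); tips must be 0 and every parent strictly older
#'   than its children.
#' @param rates positive numeric vector of per-edge rates, in `tree$edge`
#'   order.
#' @param smoothing nonnegative penalty weight.
#' @return The objective value (to be maximized).
#' @export
pl_objective <- function(tree, ages, rates, smoothing) {
  b <- tree$edge.length
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  tt <- ages[parent] - ages[child]
  if (any(tt <= 0)) return(-Inf)
  mu <- rates * tt
  ll <- sum(b * log(mu) - mu)
  root <- ape::Ntip(tree) + 1L
  # ancestor edge index for each edge (NA for edges hanging off the root)
  pe <- match(parent, child)
  inner <- which(!is.na(pe))
  rough <- sum((rates[pe[inner]] - rates[inner])^2)
  root_rates <- rates[parent == root]
  if (length(root_rates) > 1L) rough <- rough + stats::var(root_rates)
  ll - smoothing * rough
}

#' Ultrametricize a tree by penalized-likelihood rate smoothing
#'
#' Converts a phylogram (branch lengths in expected substitutions per site)
#' into a relative time tree by jointly estimating node ages and per-edge
#' substitution rates, maximizing [pl_objective()]. The root age is fixed at
#' 1 and tips at 0, so every root-to-tip path in the output equals 1 exactly;
#' the topology is untouched. Ages are parameterized as logistic fractions
#' of the parent age and rates as log-rates, making the search unconstrained
#' (BFGS with numerical gradients).
#'
#' @param tree rooted `phylo` with nonnegative branch lengths. Polytomies
#'   are resolved arbitrarily into zero-length branches with a warning;
#'   zero-length edges are floored at a small epsilon so the Poisson
#'   likelihood stays finite.
#' @param smoothing penalty weight (the study default is 0.1).
#' @param max_iter BFGS iteration cap.
#' @return An ultrametric `phylo` of depth 1 with attributes `rates`
#'   (per-edge), `objective` (value of [pl_objective()] at the solution) and
#'   `smoothing`.
#' @export
ultrametricize_pl <- function(tree, smoothing = 0.1, max_iter = 500) {
  if (!inherits(tree, "phylo")) stopf("tree must be a phylo object")
  if (!ape::is.rooted(tree)) stopf("ultrametricization requires a rooted tree")
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stopf("branch lengths must be nonnegative")
  if (!ape::is.binary(tree)) {
    warnf("resolving polytomies arbitrarily into zero-length branches")
    tree <- ape::multi2di(tree)
  }
  b <- tree$edge.length
  eps <- 1e-8 * max(mean(b), .Machine$double.eps)
  if (any(b <= 0)) {
    warnf("flooring %d zero-length edge(s) at %.3g", sum(b <= 0), eps)
    b[b <= 0] <- eps
    tree$edge.length <- b
  }

  n <- ape::Ntip(tree)
  root <- n + 1L
  nnode <- tree$Nnode
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  nE <- nrow(tree$edge)

  # internal nodes (excluding root) in preorder so parents resolve first
  pre_edges <- reorder(tree, "cladewise")$edge
  ord_nodes <- pre_edges[pre_edges[, 2] > n, 2]  # preorder, excludes root
  parent_of <- integer(n + nnode)
  parent_of[child] <- parent

  ages_from_u <- function(u) {
    ages <- numeric(n + nnode)
    ages[root] <- 1
    frac <- stats::plogis(u)
    for (i in seq_along(ord_nodes)) {
      nd <- ord_nodes[i]
      ages[nd] <- ages[parent_of[nd]] * frac[i]
    }
    ages
  }

  # clock-like initial ages from node heights above the deepest descendant tip
  depth <- ape::node.depth.edgelength(tree)
  maxd <- max(depth[seq_len(n)])
  ages0 <- pmax(1 - depth / maxd, 1e-4)
  ages0[seq_len(n)] <- 0
  ages0[root] <- 1
  u0 <- numeric(length(ord_nodes))
  for (i in seq_along(ord_nodes)) {
    nd <- ord_nodes[i]
    fr <- min(max(ages0[nd] / ages0[parent_of[nd]], 0.05), 0.95)
    ages0[nd] <- ages0[parent_of[nd]] * fr
    u0[i] <- stats::qlogis(fr)
  }
  t0 <- ages0[parent] - ages0[child]
  r0 <- sum(b) / sum(t0)
  v0 <- rep(log(r0), nE)

  nu <- length(ord_nodes)
  negobj <- function(par) {
    ages <- ages_from_u(par[seq_len(nu)])
    rates <- exp(par[nu + seq_len(nE)])
    val <- pl_objective(tree, ages, rates, smoothing)
    if (!is.finite(val)) return(1e10)
    -val
  }
  fit <- stats::optim(c(u0, v0), negobj, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  # a second pass helps when BFGS stops early on rough numerical gradients
  fit <- stats::optim(fit$par, negobj, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))

  ages <- ages_from_u(fit$par[seq_len(nu)])
  rates <- exp(fit$par[nu + seq_len(nE)])
  out <- tree
  out$edge.length <- ages[parent] - ages[child]
  attr(out, "rates") <- rates
  attr(out, "objective") <- -fit$value
  attr(out, "smoothing") <- smoothing
  out
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Entry (i, j) is the shared path length from the root down to the most
#' recent common ancestor of tips i and j; the diagonal holds the root-to-tip
#' depths. On an ultrametric tree this is the covariance (up to sigma^2) of a
#' Brownian trait at the tips.
#'
#' @param tree a `phylo` tree; a warning is issued if it is not ultrametric
#'   (the diagonal then varies).
#' @return symmetric matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("tree must be a phylo object")
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    warnf("tree is not ultrametric; proceeding, but the diagonal of the covariance will vary")
  ape::vcv(tree)
}

# Pagel lambda transform: scale off-diagonal shared paths, keep tip depths
.lambda_cov <- function(C, lambda) {
  V <- C * lambda
  diag(V) <- diag(C)
  V
}

# profile log-likelihood of a trait under N(a*1, s2*V) with a, s2 profiled out
.mvn_profile_ll <- function(V, y) {
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(list(ll = -Inf))
  n <- length(y)
  z_y <- backsolve(L, y, transpose = TRUE)
  z_1 <- backsolve(L, rep(1, n), transpose = TRUE)
  a <- sum(z_1 * z_y) / sum(z_1^2)
  r <- z_y - a * z_1
  s2 <- sum(r^2) / n
  if (s2 <= 0) return(list(ll = -Inf, root = a, sigma2 = s2))
  logdet <- 2 * sum(log(diag(L)))
  list(ll = -0.5 * (n * log(2 * pi * s2) + logdet + n), root = a, sigma2 = s2)
}

.match_trait <- function(tree, trait) {
  if (is.null(names(trait))) stopf("trait vector must be named by tip label")
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss))
    stopf("trait missing for tip(s): %s", paste(miss, collapse = ", "))
  y <- as.numeric(trait[tree$tip.label])
  if (any(!is.finite(y))) stopf("trait values must be finite")
  y
}

#' Maximum-likelihood Pagel's lambda for a continuous trait
#'
#' Profiles the multivariate-normal likelihood of the tip trait over the
#' lambda-transformed Brownian covariance (off-diagonals scaled by lambda,
#' diagonal kept), with the root state and rate sigma^2 solved analytically
#' at each lambda. The search covers lambda in `[0, 1]` by a 50-point grid
#' followed by local refinement. The p-value is a likelihood-ratio test of
#' the fitted lambda against lambda = 0 referred to a plain chi-squared with
#' 1 df, the convention of the common comparative-methods tools; because
#' lambda = 0 sits on the boundary this reference is conservative (markedly
#' so on Yule-shaped trees, where the null LR is far lighter-tailed than
#' chi-squared(1)). `boundary_correction = TRUE` switches to the 50:50
#' chi-squared(0)/chi-squared(1) boundary mixture, which is less
#' conservative but still not exact here.
#'
#' @param tree ultrametric `phylo`.
#' @param trait named numeric vector (one value per tip).
#' @param boundary_correction use the boundary mixture reference for the LR
#'   test instead of plain chi-squared(1) (default `FALSE`).
#' @return list with `lambda`, `sigma2`, `root_state`, `log_likelihood`,
#'   `log_likelihood_0`, `p_value`, `method`.
#' @export
fit_pagels_lambda <- function(tree, trait, boundary_correction = FALSE) {
  y <- .match_trait(tree, trait)
  if (stats::sd(y) == 0) stopf("trait is constant: lambda is undefined")
  C <- suppressWarnings(phylo_vcv(tree))
  llfun <- function(lam) .mvn_profile_ll(.lambda_cov(C, lam), y)$ll
  grid <- seq(0, 1, length.out = 50)
  lls <- vapply(grid, llfun, numeric(1))
  k <- which.max(lls)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(llfun, c(lo, hi), maximum = TRUE, tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective), cbind(grid, lls))
  best <- cand[which.max(cand[, 2]), ]
  lambda <- unname(best[1])
  fit <- .mvn_profile_ll(.lambda_cov(C, lambda), y)
  ll0 <- llfun(0)
  lr <- max(0, 2 * (fit$ll - ll0))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  if (boundary_correction) p <- if (lr == 0) 1 else 0.5 * p
  list(lambda = lambda, sigma2 = fit$sigma2, root_state = fit$root,
       log_likelihood = fit$ll, log_likelihood_0 = ll0,
       p_value = min(p, 1), method = "Pagel's lambda (ML, profile likelihood)")
}

# K statistic given precomputed pieces; y may be an n x m matrix of trait
# columns, in which case a vector of K values is returned.
.k_stat <- function(Cinv, w, expected, y) {
  y <- as.matrix(y)
  n <- nrow(y)
  a <- drop(crossprod(w, y))
  d <- sweep(y, 2, a)
  mse0 <- colSums(d^2) / (n - 1)
  mse <- colSums(d * (Cinv %*% d)) / (n - 1)
  (mse0 / mse) / expected
}

.k_setup <- function(C) {
  Cinv <- chol2inv(chol(C))
  sumC <- sum(Cinv)
  n <- nrow(C)
  list(Cinv = Cinv, w = rowSums(Cinv) / sumC,
       expected = (sum(diag(C)) - n / sumC) / (n - 1))
}

#' Blomberg's K for a continuous trait
#'
#' K compares the observed ratio of the tip-level mean squared deviation
#' from the phylogenetically corrected mean (MSE0) to the
#' covariance-whitened mean square (MSE), against the ratio expected under
#' Brownian motion, `(tr(C) - N / sum(C^-1)) / (N - 1)`. K near 1 indicates
#' Brownian-like signal, K near 0 phylogenetic independence.
#'
#' @inheritParams fit_pagels_lambda
#' @return list with `K` and the intermediate `mse0`, `mse`,
#'   `expected_ratio`.
#' @export
blombergs_k <- function(tree, trait) {
  y <- .match_trait(tree, trait)
  if (stats::sd(y) == 0) stopf("trait is constant: K is undefined")
  C <- suppressWarnings(phylo_vcv(tree))
  st <- .k_setup(C)
  n <- length(y)
  a <- sum(st$w * y)
  mse0 <- sum((y - a)^2) / (n - 1)
  mse <- drop(crossprod(y - a, st$Cinv %*% (y - a))) / (n - 1)
  list(K = (mse0 / mse) / st$expected, mse0 = mse0, mse = mse,
       expected_ratio = st$expected)
}

#' Permutation test for Blomberg's K
#'
#' Permutes the trait values across the tips and recomputes K; the p-value
#' uses the add-one correction `p = (1 + #(K_perm >= K_obs)) / (n_perm + 1)`,
#' so it is bounded below by `1/(n_perm + 1)` and deterministic for a given
#' seed.
#'
#' @inheritParams fit_pagels_lambda
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed or `NULL`.
#' @return list with `K`, `p_value`, `n_perm`.
#' @export
k_permutation_test <- function(tree, trait, n_perm = 999, seed = NULL) {
  if (!is_num1(n_perm) || n_perm < 99) stopf("n_perm must be at least 99")
  n_perm <- as.integer(n_perm)
  y <- .match_trait(tree, trait)
  if (stats::sd(y) == 0) stopf("trait is constant: K is undefined")
  C <- suppressWarnings(phylo_vcv(tree))
  st <- .k_setup(C)
  k_obs <- .k_stat(st$Cinv, st$w, st$expected, y)
  k_perm <- with_seed(seed, {
    Y <- replicate(n_perm, sample(y))
    .k_stat(st$Cinv, st$w, st$expected, Y)
  })
  p <- (1 + sum(k_perm >= k_obs)) / (n_perm + 1)
  list(K = unname(k_obs), p_value = p, n_perm = n_perm)
}
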