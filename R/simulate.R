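#' Simulate a Yule tree rescaled to unit depth
#'
#' Pure-birth (Yule) tree conditioned on the number of tips, rescaled so
#' every root-to-tip path equals 1. Tip labels are `s01, s02, ...`.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed or `NULL` (use the current RNG stream).
#' @return ultrametric `phylo` of depth 1.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (!is_num1(n_tips) || n_tips < 2) stopf("n_tips must be at least 2")
  n_tips <- as.integer(n_tips)
  with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
    tr$tip.label <- sprintf("s%02d", seq_len(n_tips))
    tr
  })
}

#' Simulate a lambda-structured continuous trait on a tree
#'
#' One multivariate-normal draw with mean `root_state` and covariance
#' `sigma2 * C(lambda)`, where C is the Brownian covariance of the tree and
#' the lambda transform scales its off-diagonal entries. `lambda = 1` is
#' pure Brownian motion; `lambda = 0` gives independent tips.
#'
#' @param tree ultrametric `phylo`.
#' @param sigma2 Brownian rate (>= 0; 0 returns `root_state` at every tip).
#' @param root_state trait value at the root.
#' @param lambda phylogenetic signal in `[0, 1]`.
#' @param seed integer seed or `NULL`.
#' @return named numeric vector of tip trait values.
#' @export
simulate_trait <- function(tree, sigma2 = 1, root_state = 0, lambda = 1,
                           seed = NULL) {
  if (!inherits(tree, "phylo")) stopf("tree must be a phylo object")
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    stopf("simulate_trait requires an ultrametric tree")
  if (!is_num1(sigma2) || sigma2 < 0) stopf("sigma2 must be >= 0")
  if (!is_num1(lambda) || lambda < 0 || lambda > 1)
    stopf("lambda must lie in [0, 1]")
  n <- ape::Ntip(tree)
  if (sigma2 == 0)
    return(stats::setNames(rep(root_state, n), tree$tip.label))
  C <- .lambda_cov(ape::vcv(tree), lambda)
  U <- chol(sigma2 * C)
  with_seed(seed, {
    y <- root_state + drop(crossprod(U, stats::rnorm(n)))
    stats::setNames(y, tree$tip.label)
  })
}

#' Specification of a synthetic strain panel
#'
#' Collects every knob of the synthetic-data generator, with defaults that
#' emulate the reference experiment: 24 strains assayed at
#' {0.5, 5, 10, 15, 20, 25, 33} degC in 4 replicates; thermal optima with
#' strong phylogenetic signal (lambda 0.94) spread over 9-27 degC; a
#' "hotter is better" coupling of 0.05 divisions/day per degC of optimum; an
#' 80%-performance-range width growing by 0.26 degC per degC of optimum;
#' multiplicative lognormal measurement noise on F0; and a site SST that
#' recovers the 0.6 degC-of-optimum-per-degC-of-SST regression.
#'
#' @param n_strains number of strains.
#' @param temperatures assay temperatures (degC).
#' @param n_replicates replicates per temperature.
#' @param trait_lambda Pagel's lambda of the simulated optimum.
#' @param topt_range range (degC) the optima are rescaled into.
#' @param hotter_slope divisions/day of mu_max per degC of optimum.
#' @param mu_base mu_max at a hypothetical 0 degC optimum (divisions/day).
#' @param width_slope degC of 80%-range width per degC of optimum.
#' @param width_base width at a hypothetical 0 degC optimum (degC).
#' @param tmax_offset fixed t_max - t_opt gap (degC); beta is then solved so
#'   the curve attains the target width.
#' @param noise_sigma lognormal sigma of the multiplicative F0 noise.
#' @param sst_slope degC of optimum per degC of yearly SST (the generative
#'   regression slope).
#' @param sst_intercept optimum (degC) at SST = 0.
#' @param sst_noise_sd SD of the site-level scatter around the SST relation.
#' @param f0_init initial fluorescence, proportional to the ~3000 cells/ml
#'   inoculum.
#' @param days measurement days of the growth assay.
#' @param seed integer seed or `NULL`.
#' @return a `panel_spec` list.
#' @export
panel_spec <- function(n_strains = 24,
                       temperatures = c(0.5, 5, 10, 15, 20, 25, 33),
                       n_replicates = 4, trait_lambda = 0.94,
                       topt_range = c(9, 27), hotter_slope = 0.05,
                       mu_base = 0.2, width_slope = 0.26, width_base = 3,
                       tmax_offset = 10, noise_sigma = 0.05,
                       sst_slope = 0.6, sst_intercept = 8.8,
                       sst_noise_sd = 3.8, f0_init = 3000, days = 0:5,
                       seed = NULL) {
  if (!is_num1(n_strains) || n_strains < 2) stopf("n_strains must be >= 2")
  if (!is_num1(n_replicates) || n_replicates < 1)
    stopf("n_replicates must be >= 1")
  if (length(topt_range) != 2L || topt_range[1] >= topt_range[2])
    stopf("topt_range must be c(low, high) with low < high")
  if (!is_num1(noise_sigma) || noise_sigma < 0)
    stopf("noise_sigma must be >= 0")
  if (!is_num1(trait_lambda) || trait_lambda < 0 || trait_lambda > 1)
    stopf("trait_lambda must lie in [0, 1]")
  structure(as.list(environment()), class = "panel_spec")
}

# solve beta by bisection so the fraction-level performance range has the
# requested width, given fixed t_opt and t_max (width is decreasing in beta)
.solve_beta_for_width <- function(mu_max, t_opt, t_max, target_width,
                                  fraction = 0.8) {
  wfun <- function(lb) {
    performance_range(list(mu_max = mu_max, t_opt = t_opt, t_max = t_max,
                           beta = exp(lb)), fraction)$width - target_width
  }
  lo <- -7; hi <- 5
  if (wfun(lo) < 0)
    stopf("target width %.2f infeasible even at beta = exp(%g); increase tmax_offset",
          target_width, lo)
  if (wfun(hi) > 0)
    stopf("target width %.2f infeasible at beta = exp(%g)", target_width, hi)
  exp(stats::uniroot(wfun, c(lo, hi), tol = 1e-10)$root)
}

# core generator; assumes the caller controls the RNG stream
.generate_core <- function(spec) {
  n <- spec$n_strains
  tree <- simulate_tree(n)
  z <- simulate_trait(tree, sigma2 = 1, root_state = 0,
                      lambda = spec$trait_lambda)
  lohi <- spec$topt_range
  zr <- range(z)
  t_opt <- if (diff(zr) > 0)
    lohi[1] + (z - zr[1]) / diff(zr) * diff(lohi)
  else stats::setNames(rep(mean(lohi), n), names(z))
  mu_max <- spec$mu_base + spec$hotter_slope * t_opt
  width_target <- spec$width_base + spec$width_slope * t_opt
  t_max <- t_opt + spec$tmax_offset
  beta <- vapply(seq_len(n), function(i)
    .solve_beta_for_width(mu_max[i], t_opt[i], t_max[i], width_target[i]),
    numeric(1))
  params <- data.frame(strain_id = tree$tip.label, mu_max = unname(mu_max),
                       t_opt = unname(t_opt), t_max = unname(t_max),
                       beta = beta, width_target = unname(width_target),
                       stringsAsFactors = FALSE)

  sst_signal <- (t_opt - spec$sst_intercept) / spec$sst_slope
  sst <- sst_signal + stats::rnorm(n, 0, spec$sst_noise_sd)
  # the OLS slope of t_opt on the noisy SST is attenuated relative to
  # sst_slope; record the implied value so recovery tests have a truth
  vs <- stats::var(sst_signal)
  sst_slope_implied <- spec$sst_slope * vs / (vs + spec$sst_noise_sd^2)

  lat <- pmax(-78, pmin(78, 66 - 2.4 * sst + stats::rnorm(n, 0, 4)))
  lon <- stats::runif(n, -180, 180)
  zone <- cut(sst, c(-Inf, 5, 18, 24, Inf),
              labels = c("cold", "temperate", "subtropical", "tropical"))
  amp <- 1 + 5 * abs(lat) / 90
  seasons <- t(vapply(seq_len(n), function(i)
    sst[i] + amp[i] * c(-1, -1/3, 1, 1/3), numeric(4)))
  colnames(seasons) <- c("sst_winter", "sst_spring", "sst_summer", "sst_autumn")
  strains <- data.frame(strain_id = tree$tip.label, lat_dd = lat, lon_dd = lon,
                        climate_zone = as.character(zone), seasons,
                        sst_mean = rowMeans(seasons),
                        sst_sd = apply(seasons, 1, stats::sd),
                        stringsAsFactors = FALSE)

  truth <- list(trait_lambda = spec$trait_lambda,
                hotter_slope = spec$hotter_slope, mu_base = spec$mu_base,
                width_slope = spec$width_slope, width_base = spec$width_base,
                sst_slope = spec$sst_slope, sst_intercept = spec$sst_intercept,
                sst_noise_sd = spec$sst_noise_sd,
                sst_slope_implied = sst_slope_implied,
                tmax_offset = spec$tmax_offset, noise_sigma = spec$noise_sigma,
                seed = spec$seed)
  list(spec = spec, tree = tree, params = params, strains = strains,
       truth = truth)
}

#' Generate a synthetic strain panel
#'
#' Simulates a Yule tree, evolves a lambda-structured thermal optimum on it,
#' rescales the optima into `topt_range`, and derives per-strain Blanchard
#' parameters implementing the hotter-is-better and width-optimum couplings
#' of the spec: mu_max is affine in t_opt, t_max sits a fixed offset above
#' t_opt, and beta is solved by bisection so the 80% performance range hits
#' its target width. A noisy yearly SST per strain makes the optimum-SST
#' regression recoverable, and site metadata (coordinates, climate zone,
#' seasonal SSTs) is synthesized for the pipeline's joins.
#'
#' @param spec a [panel_spec()].
#' @return list with `tree`, `params` (strain_id, mu_max, t_opt, t_max,
#'   beta, width_target), `strains` (metadata + synthetic SST), `truth`
#'   (generator parameters, including the attenuation-corrected implied
#'   optimum-on-SST slope), and the `spec`.
#' @export
generate_strain_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "panel_spec"))
  with_seed(spec$seed, .generate_core(spec))
}

#' Simulate the growth experiment for one strain
#'
#' For every temperature x replicate, daily F0 readings over the assay
#' window follow `f0(t) = f0(0) * 2^(mu(T) * t)` times independent
#' multiplicative lognormal noise per observation, with `mu(T)` the
#' Blanchard curve of the strain (zero above t_max gives flat series).
#'
#' @param params one strain's Blanchard parameters (`thermal_curve_params`,
#'   list, or one row of a panel `params` data.frame).
#' @param spec a [panel_spec()] providing temperatures, replicates, days,
#'   `f0_init` and `noise_sigma`.
#' @param seed integer seed or `NULL`.
#' @return list of [fluorescence_series()].
#' @export
simulate_growth_experiment <- function(params, spec = panel_spec(),
                                       seed = NULL) {
  p <- .as_tpc(params)
  sid <- params$strain_id %||% "sim"
  if (spec$noise_sigma < 0) stopf("noise_sigma must be >= 0")
  with_seed(seed, {
    out <- list()
    for (temp in spec$temperatures) {
      mu <- .blanchard(temp, p$mu_max, p$t_opt, p$t_max, p$beta)
      for (rep_i in seq_len(spec$n_replicates)) {
        noise <- if (spec$noise_sigma > 0)
          exp(stats::rnorm(length(spec$days), 0, spec$noise_sigma)) else 1
        f0 <- spec$f0_init * 2^(mu * spec$days) * noise
        out[[length(out) + 1L]] <-
          fluorescence_series(sid, temp, rep_i, spec$days, f0)
      }
    }
    out
  })
}

#' Simulate a full panel experiment
#'
#' [generate_strain_panel()] plus the growth experiment of every strain,
#' all drawn from a single seeded stream so the whole dataset is
#' bit-reproducible.
#'
#' @param spec a [panel_spec()].
#' @return list with the panel fields plus `f0`, a long data.frame in the
#'   [read_f0_csv()] schema.
#' @export
simulate_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "panel_spec"))
  with_seed(spec$seed, {
    panel <- .generate_core(spec)
    rows <- list()
    for (i in seq_len(nrow(panel$params))) {
      series <- simulate_growth_experiment(as.list(panel$params[i, ]), spec)
      for (s in series) {
        rows[[length(rows) + 1L]] <- data.frame(
          strain_id = s$strain_id, temperature_c = s$temperature,
          replicate = s$replicate, time_days = s$times, f0 = s$f0,
          stringsAsFactors = FALSE)
      }
    }
    panel$f0 <- do.call(rbind, rows)
    panel
  })
}

#' Write a simulated panel to disk
#'
#' Emits the pipeline's input files: `f0.csv` (long F0 table), `tree.nwk`
#' (newick), `strains.csv` (metadata + synthetic SST), `params.csv` (true
#' Blanchard parameters) and `truth.json` (generator parameters for
#' recovery tests).
#'
#' @param sim output of [simulate_panel()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(sim$f0, file.path(dir, "f0.csv"), row.names = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(sim$strains, file.path(dir, "strains.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$params, file.path(dir, "params.csv"), row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
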