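#' Summarize seasonal sea-surface temperatures
#'
#' Yearly mean SST as the arithmetic mean of the four seasonal means, and
#' the seasonal variability as their sample standard deviation. Exactly four
#' finite values are required; nothing is imputed.
#'
#' @param seasonal numeric vector of 4 seasonal mean SSTs (degC).
#' @return list with `mean` and `sd` (degC).
#' @export
sst_summary <- function(seasonal) {
  seasonal <- as.numeric(seasonal)
  if (length(seasonal) != 4L || any(!is.finite(seasonal)))
    stopf("sst_summary needs exactly 4 finite seasonal values, got %d",
          length(seasonal))
  list(mean = mean(seasonal), sd = stats::sd(seasonal))
}

#' Pipeline run configuration
#'
#' Bundles input paths and every tunable default of the end-to-end run:
#' regression window (first 5 days), unweighted fit including zero-growth
#' temperatures, performance fraction 0.8, rate-smoothing penalty 0.1, 999
#' permutations.
#'
#' @param f0_csv path to the long F0 table ([read_f0_csv()] schema).
#' @param tree_nwk path to a rooted newick tree whose tips are strain ids.
#' @param strains_csv path to strain metadata (`strain_id`, `lat_dd`,
#'   `lon_dd`, seasonal `sst_*` columns and/or `sst_mean`, `sst_sd`).
#' @param alignment_fasta optional aligned FASTA for the genetic-geographic
#'   Mantel test.
#' @param out_dir output directory.
#' @param window growth-regression window (`c(start, end)` days or
#'   `"auto"`).
#' @param weighted weight the curve fit by 1/se^2.
#' @param include_zero keep zero-growth temperatures in the fit.
#' @param drop_nonpositive drop nonpositive F0 readings with a warning.
#' @param fraction performance fraction for the niche width.
#' @param smoothing penalized-likelihood smoothing weight.
#' @param n_perm permutations for the K and Mantel tests.
#' @param seed integer seed or `NULL`.
#' @return a `run_config` list.
#' @export
run_config <- function(f0_csv, tree_nwk, strains_csv, alignment_fasta = NULL,
                       out_dir = tempfile("thermoniche_run_"),
                       window = c(0, 5), weighted = FALSE,
                       include_zero = TRUE, drop_nonpositive = FALSE,
                       fraction = 0.8, smoothing = 0.1, n_perm = 999,
                       seed = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Field names mirror [run_config()] exactly; unknown fields are an error,
#' unset fields keep their defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stopf("unknown config field(s): %s", paste(extra, collapse = ", "))
  if (!is.null(raw$window) && !identical(raw$window, "auto"))
    raw$window <- as.numeric(raw$window)
  do.call(run_config, raw)
}

.stage <- function(name, log_lines, expr) {
  tryCatch(force(expr), error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full thermal-niche pipeline
#'
#' growth_kinetics -> thermal_response -> phylo_comparative, plus the suite
#' of trait regressions: observed and predicted maximum growth rate against
#' thermal optimum ("hotter is better"), optimum against yearly and seasonal
#' SST, and niche width against optimum, SST seasonality and maximum growth
#' rate. Strains present in one input but absent from another are reported
#' by name before aborting. Writes `rates.csv`, `tpc.csv`, `report.json`
#' and a structured `run.log` into the output directory; two runs with the
#' same config and seed produce byte-identical reports. The regressions are
#' reported without multiplicity correction (flagged in the report).
#'
#' @param config a [run_config()].
#' @return the report, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)  # truncate

  rates <- .stage("growth_kinetics", NULL, {
    series <- read_f0_csv(config$f0_csv)
    growth_rate_table(series, window = config$window,
                      drop_nonpositive = config$drop_nonpositive)
  })
  log_line("stage=growth_kinetics rows=%d strains=%d window=%s",
           nrow(rates), length(unique(rates$strain_id)),
           paste(config$window, collapse = ","))

  tpc <- .stage("thermal_response", NULL, {
    res <- lapply(split(rates, rates$strain_id), function(g) {
      fit <- fit_thermal_curve(g, weighted = config$weighted,
                               include_zero = config$include_zero)
      niche <- performance_range(fit, config$fraction)
      obs_i <- which.max(g$mean_rate)
      data.frame(strain_id = g$strain_id[1],
                 mu_max = fit$mu_max, se_mu_max = fit$se_mu_max,
                 t_opt = fit$t_opt, se_t_opt = fit$se_t_opt,
                 t_max = fit$t_max, se_t_max = fit$se_t_max,
                 beta = fit$beta, se_beta = fit$se_beta,
                 rss = fit$rss, converged = fit$converged,
                 t_low = niche$t_low, t_high = niche$t_high,
                 width = niche$width,
                 mu_obs_max = g$mean_rate[obs_i],
                 t_at_obs_max = g$temperature_c[obs_i],
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, res)
    rownames(df) <- NULL
    df
  })
  log_line("stage=thermal_response strains=%d fraction=%g converged=%d/%d",
           nrow(tpc), config$fraction, sum(tpc$converged), nrow(tpc))

  strains <- .stage("metadata", NULL, {
    df <- utils::read.csv(config$strains_csv, stringsAsFactors = FALSE)
    if (!"strain_id" %in% names(df)) stopf("strains table lacks strain_id")
    season_cols <- intersect(
      c("sst_winter", "sst_spring", "sst_summer", "sst_autumn"), names(df))
    if (length(season_cols) == 4L) {
      ss <- t(apply(df[season_cols], 1, function(v)
        unlist(sst_summary(v), use.names = FALSE)))
      if (!"sst_mean" %in% names(df)) df$sst_mean <- ss[, 1]
      if (!"sst_sd" %in% names(df)) df$sst_sd <- ss[, 2]
    }
    if (!"sst_mean" %in% names(df))
      stopf("strains table needs sst_mean or the four seasonal SST columns")
    df
  })

  .check_join <- function(a, b, what_a, what_b) {
    m1 <- setdiff(a, b); m2 <- setdiff(b, a)
    if (length(m1) || length(m2))
      stopf("strain mismatch between %s and %s: only in %s: {%s}; only in %s: {%s}",
            what_a, what_b, what_a, paste(m1, collapse = ", "),
            what_b, paste(m2, collapse = ", "))
  }
  .stage("join", NULL, .check_join(tpc$strain_id, strains$strain_id,
                                   "growth data", "strain metadata"))
  strains <- strains[match(tpc$strain_id, strains$strain_id), ]

  phylo <- .stage("phylo_comparative", NULL, {
    tree <- ape::read.tree(config$tree_nwk)
    .check_join(tpc$strain_id, tree$tip.label, "growth data", "tree")
    utree <- if (ape::is.ultrametric(tree, tol = 1e-8)) tree
             else ultrametricize_pl(tree, smoothing = config$smoothing)
    topt <- stats::setNames(tpc$t_opt, tpc$strain_id)
    lam <- fit_pagels_lambda(utree, topt)
    kperm <- k_permutation_test(utree, topt, n_perm = config$n_perm,
                                seed = config$seed)
    mantel <- NULL
    if (!is.null(config$alignment_fasta) &&
        all(c("lat_dd", "lon_dd") %in% names(strains))) {
      aln <- ape::read.FASTA(config$alignment_fasta)
      gen <- p_distance_matrix(as.matrix(aln))
      ord <- match(tpc$strain_id, rownames(gen))
      if (any(is.na(ord)))
        stopf("alignment lacks strain(s): %s",
              paste(tpc$strain_id[is.na(ord)], collapse = ", "))
      gen <- gen[ord, ord]
      geo <- geographic_distance_matrix(strains)
      mantel <- mantel_test(gen, geo, n_perm = config$n_perm,
                            seed = config$seed)
    }
    list(lambda = lam$lambda, lambda_sigma2 = lam$sigma2,
         lambda_root = lam$root_state, lambda_logL = lam$log_likelihood,
         lambda_p = lam$p_value, K = kperm$K, K_p = kperm$p_value,
         mantel_r = if (is.null(mantel)) NULL else mantel$r,
         mantel_p = if (is.null(mantel)) NULL else mantel$p_value)
  })
  log_line("stage=phylo_comparative lambda=%.4f K=%.4f n_perm=%d seed=%s",
           phylo$lambda, phylo$K, config$n_perm,
           as.character(config$seed %||% "NULL"))

  reg <- .stage("regressions", NULL, {
    r <- list(
      mu_pred_vs_topt = correlate_and_regress(tpc$t_opt, tpc$mu_max),
      mu_obs_vs_t_at_max = correlate_and_regress(tpc$t_at_obs_max,
                                                 tpc$mu_obs_max),
      topt_vs_sst = correlate_and_regress(strains$sst_mean, tpc$t_opt),
      width_vs_topt = correlate_and_regress(tpc$t_opt, tpc$width),
      width_vs_sst_sd = if (!is.null(strains$sst_sd))
        correlate_and_regress(strains$sst_sd, tpc$width) else NULL,
      width_vs_mu_max = correlate_and_regress(tpc$mu_max, tpc$width))
    for (season in c("sst_winter", "sst_spring", "sst_summer", "sst_autumn"))
      if (season %in% names(strains))
        r[[paste0("topt_vs_", sub("sst_", "", season))]] <-
          correlate_and_regress(strains[[season]], tpc$t_opt)
    r[!vapply(r, is.null, logical(1))]
  })
  log_line("stage=regressions n=%d note=no multiplicity correction",
           length(reg))

  report <- list(
    config = list(window = config$window, weighted = config$weighted,
                  include_zero = config$include_zero,
                  fraction = config$fraction, smoothing = config$smoothing,
                  n_perm = config$n_perm, seed = config$seed),
    n_strains = nrow(tpc),
    phylogenetic_signal = phylo,
    regressions = reg,
    notes = "regressions are reported without multiplicity correction")

  utils::write.csv(rates, file.path(config$out_dir, "rates.csv"),
                   row.names = FALSE)
  utils::write.csv(tpc, file.path(config$out_dir, "tpc.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  report$tpc <- tpc
  report$rates <- rates
  invisible(report)
}
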