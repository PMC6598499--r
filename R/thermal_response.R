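#' Blanchard thermal performance curve
#'
#' Unimodal growth-temperature model
#' \deqn{\mu(T) = \mu_{max} \, x^\beta e^{-\beta (x - 1)}, \qquad
#'       x = \frac{T_{max} - T}{T_{max} - T_{opt}},}
#' which attains its maximum \eqn{\mu_{max}} exactly at \eqn{T = T_{opt}} and
#' falls to zero at \eqn{T = T_{max}}. For \eqn{T > T_{max}} the formula is
#' undefined (negative base); the curve is extended with \eqn{\mu = 0} there,
#' the biological reading of "no growth above the thermal maximum".
#'
#' @param temperature numeric vector of temperatures (degrees C).
#' @param params a `thermal_curve_params` object, or a list / named numeric
#'   vector with entries `mu_max`, `t_opt`, `t_max`, `beta`.
#' @return numeric vector of growth rates (divisions/day).
#' @export
blanchard_growth <- function(temperature, params) {
  p <- .as_tpc(params)
  .blanchard(temperature, p$mu_max, p$t_opt, p$t_max, p$beta)
}

.blanchard <- function(tt, mu_max, t_opt, t_max, beta) {
  x <- (t_max - tt) / (t_max - t_opt)
  out <- numeric(length(tt))
  ok <- tt <= t_max
  out[ok] <- mu_max * x[ok]^beta * exp(-beta * (x[ok] - 1))
  out
}

.as_tpc <- function(params) {
  p <- as.list(params)
  need <- c("mu_max", "t_opt", "t_max", "beta")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stopf("params is missing: %s", paste(miss, collapse = ", "))
  if (!all(vapply(p[need], is_num1, logical(1))))
    stopf("mu_max, t_opt, t_max, beta must each be a single finite number")
  if (p$t_max <= p$t_opt) stopf("t_max (%g) must exceed t_opt (%g)", p$t_max, p$t_opt)
  if (p$mu_max <= 0) stopf("mu_max must be > 0")
  if (p$beta <= 0) stopf("beta must be > 0")
  p
}

#' Fit the Blanchard curve to a growth-temperature profile
#'
#' Nonlinear least squares of replicate-mean growth rates on temperature.
#' The search runs unconstrained in the transformed parameters
#' (log mu_max, t_opt, log(t_max - t_opt), log beta), so t_max > t_opt,
#' mu_max > 0 and beta > 0 hold by construction. A multistart grid
#' (t_opt near the best observed temperature +/- 5 degC, t_max offsets
#' {3, 8, 15} degC, beta in {0.5, 2, 5}) feeds Nelder-Mead, and the best
#' candidate is polished by a Levenberg-Marquardt loop until the relative
#' change in RSS is below 1e-10 (at most 500 iterations in total).
#' Standard errors come from the usual linearization: the Jacobian J of the
#' model in the natural parameters at the optimum gives
#' cov = s^2 (J'WJ)^-1 with s^2 = RSS/(n - 4).
#'
#' @param profile data.frame with columns `temperature_c` (or `temperature`)
#'   and `mean_rate`, optionally `se_rate` and `strain_id`. At least 5
#'   distinct temperatures and one positive rate are required.
#' @param weighted if `TRUE`, weight residuals by 1/se_rate^2 (rows with
#'   `se_rate == 0` get the largest finite weight present).
#' @param include_zero if `FALSE`, temperatures with `mean_rate <= 0` are
#'   excluded from the fit (default keeps them; a zero is information about
#'   the niche edge).
#' @return A `thermal_curve_params` object: `mu_max`, `t_opt`, `t_max`,
#'   `beta`, their standard errors `se_*`, `rss`, `converged`, `n`,
#'   `strain_id`.
#' @export
fit_thermal_curve <- function(profile, weighted = FALSE, include_zero = TRUE) {
  if (!is.data.frame(profile)) profile <- as.data.frame(profile)
  tcol <- if ("temperature_c" %in% names(profile)) "temperature_c" else "temperature"
  if (!tcol %in% names(profile) || !"mean_rate" %in% names(profile))
    stopf("profile needs columns temperature_c (or temperature) and mean_rate")
  tt <- as.numeric(profile[[tcol]])
  y <- as.numeric(profile$mean_rate)
  strain <- if ("strain_id" %in% names(profile)) as.character(profile$strain_id[1]) else NA_character_
  if (!include_zero) {
    keep <- y > 0
    tt <- tt[keep]; y <- y[keep]
  }
  if (length(unique(tt)) < 5L)
    stopf("need at least 5 distinct temperatures for a 4-parameter fit, got %d",
          length(unique(tt)))
  if (!any(y > 0)) stopf("need at least one positive growth rate")
  w <- rep(1, length(y))
  if (weighted) {
    se <- as.numeric(profile$se_rate)
    if (!include_zero) se <- se[profile$mean_rate > 0]
    w <- 1 / se^2
    w[!is.finite(w)] <- max(w[is.finite(w)], 1)
  }

  # theta = (log mu_max, t_opt, log(t_max - t_opt), log beta)
  untrans <- function(th) list(mu_max = exp(th[1]), t_opt = th[2],
                               t_max = th[2] + exp(th[3]), beta = exp(th[4]))
  predfn <- function(th) {
    p <- untrans(th)
    .blanchard(tt, p$mu_max, p$t_opt, p$t_max, p$beta)
  }
  rssfn <- function(th) sum(w * (y - predfn(th))^2)

  t_best <- tt[which.max(y)]
  mu0 <- max(y)
  starts <- expand.grid(topt = t_best + c(-5, 0, 5),
                        dmax = c(3, 8, 15), beta = c(0.5, 2, 5))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    th0 <- c(log(mu0), starts$topt[k], log(starts$dmax[k]), log(starts$beta[k]))
    fit <- tryCatch(
      stats::optim(th0, rssfn, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stopf("thermal-curve optimization failed from every start")
  lm_out <- .lm_polish(best$par, predfn, y, w, max_iter = 500, reltol = 1e-10)
  th <- lm_out$par
  rss <- lm_out$rss
  p <- untrans(th)

  # SEs on the natural scale via a central-difference Jacobian
  natural <- c(p$mu_max, p$t_opt, p$t_max, p$beta)
  fn_nat <- function(q) .blanchard(tt, q[1], q[2], q[3], q[4])
  J <- .num_jacobian(fn_nat, natural)
  n <- length(y)
  dof <- n - 4L
  s2 <- if (dof > 0) rss / dof else NA_real_
  ses <- rep(NA_real_, 4)
  cv <- tryCatch(solve(crossprod(J * sqrt(w))), error = function(e) NULL)
  if (!is.null(cv) && is.finite(s2)) {
    d <- diag(cv) * s2
    ses <- sqrt(pmax(d, 0))
  }

  structure(
    list(mu_max = p$mu_max, t_opt = p$t_opt, t_max = p$t_max, beta = p$beta,
         se_mu_max = ses[1], se_t_opt = ses[2], se_t_max = ses[3],
         se_beta = ses[4], rss = rss,
         converged = isTRUE(lm_out$converged) && best$convergence %in% c(0L, 10L),
         n = n, strain_id = strain),
    class = "thermal_curve_params")
}

#' @export
print.thermal_curve_params <- function(x, ...) {
  cat(sprintf("<thermal_curve_params>%s mu_max=%.3f (SE %.3g)  t_opt=%.2f (SE %.3g)  t_max=%.2f (SE %.3g)  beta=%.3f (SE %.3g)  rss=%.4g%s\n",
              if (is.na(x$strain_id)) "" else paste0(" ", x$strain_id),
              x$mu_max, x$se_mu_max, x$t_opt, x$se_t_opt, x$t_max, x$se_t_max,
              x$beta, x$se_beta, x$rss,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

# Levenberg-Marquardt refinement on the transformed parameters
.lm_polish <- function(th, predfn, y, w, max_iter = 500, reltol = 1e-10) {
  sw <- sqrt(w)
  resid <- function(th) sw * (y - predfn(th))
  e <- resid(th)
  rss <- sum(e^2)
  lambda <- 1e-3
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    J <- .num_jacobian(function(q) sw * predfn(q), th)
    g <- crossprod(J, e)
    H <- crossprod(J)
    step_ok <- FALSE
    for (tries in 1:30) {
      delta <- tryCatch(solve(H + lambda * diag(diag(H) + 1e-12), g),
                        error = function(err) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      th_new <- th + as.numeric(delta)
      e_new <- resid(th_new)
      rss_new <- sum(e_new^2)
      if (is.finite(rss_new) && rss_new <= rss) {
        rel <- (rss - rss_new) / max(rss, .Machine$double.eps)
        th <- th_new; e <- e_new; rss <- rss_new
        lambda <- max(lambda / 10, 1e-12)
        step_ok <- TRUE
        if (rel < reltol) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!step_ok) { converged <- TRUE; break }  # no improving step exists
    if (converged) break
  }
  list(par = th, rss = rss, converged = converged || max_iter == 0)
}

.num_jacobian <- function(fn, x, h = NULL) {
  f0 <- fn(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    hj <- if (is.null(h)) 1e-6 * (abs(x[j]) + 1e-6) else h
    xp <- x; xm <- x
    xp[j] <- x[j] + hj; xm[j] <- x[j] - hj
    J[, j] <- (fn(xp) - fn(xm)) / (2 * hj)
  }
  J
}

#' Thermal performance range of a fitted curve
#'
#' Finds the temperature interval on which the predicted growth rate is at
#' least `fraction` of mu_max (the thermal performance range; the study
#' convention is 80%). The two bounds are the roots of
#' `blanchard_growth(T) = fraction * mu_max` bracketing t_opt, located by
#' bracketed root solving (`uniroot`, tolerance 1e-10 degC). With
#' `fraction = 1` the interval degenerates to the single point t_opt.
#'
#' @param params a `thermal_curve_params` object (or compatible list).
#' @param fraction performance fraction in (0, 1]; default 0.8.
#' @return A `thermal_niche` list: `t_low`, `t_high`, `width`,
#'   `performance_fraction`, `t_opt`.
#' @export
performance_range <- function(params, fraction = 0.8) {
  p <- .as_tpc(params)
  if (!is_num1(fraction) || fraction <= 0 || fraction > 1)
    stopf("fraction must lie in (0, 1], got %g", fraction)
  if (fraction == 1) {
    return(structure(list(t_low = p$t_opt, t_high = p$t_opt, width = 0,
                          performance_fraction = 1, t_opt = p$t_opt),
                     class = "thermal_niche"))
  }
  target <- fraction * p$mu_max
  f <- function(tt) .blanchard(tt, p$mu_max, p$t_opt, p$t_max, p$beta) - target
  hi <- stats::uniroot(f, c(p$t_opt, p$t_max), tol = 1e-10)$root
  lo_br <- p$t_opt - (p$t_max - p$t_opt)
  for (i in 1:200) {
    if (f(lo_br) < 0) break
    lo_br <- p$t_opt - 2 * (p$t_opt - lo_br)
  }
  if (f(lo_br) >= 0)
    stopf("could not bracket the lower performance bound")
  lo <- stats::uniroot(f, c(lo_br, p$t_opt), tol = 1e-10)$root
  structure(list(t_low = lo, t_high = hi, width = hi - lo,
                 performance_fraction = fraction, t_opt = p$t_opt),
            class = "thermal_niche")
}

#' Pearson correlation and simple linear regression
#'
#' Convenience wrapper reporting the Pearson correlation with its two-sided
#' t-test p-value together with the OLS slope, intercept, slope standard
#' error and 95% slope confidence interval of `y ~ x`.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `pearson_r`, `p_value`, `slope`, `intercept`,
#'   `slope_se`, `slope_ci` (length-2), `n`.
#' @export
correlate_and_regress <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (length(x) < 3L) stopf("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("x and y must be finite")
  if (stats::sd(x) == 0) stopf("x is constant: correlation undefined")
  if (stats::sd(y) == 0) stopf("y is constant: correlation undefined")
  ct <- stats::cor.test(x, y)
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an exactly collinear response; that input is legal here
  sm <- suppressWarnings(summary(fit)$coefficients)
  ci <- suppressWarnings(stats::confint(fit, "x", level = 0.95))
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_se = sm["x", "Std. Error"],
       slope_ci = as.numeric(ci), n = length(x))
}
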