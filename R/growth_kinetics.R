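#' Fluorescence time series for one culture
#'
#' Bundles the minimum-fluorescence (F0) measurements of a single replicate
#' culture of one strain at one incubation temperature. F0 from PAM
#' fluorometry is used as a biomass proxy, so the slope of log2(F0) against
#' time estimates the specific growth rate in divisions per day.
#'
#' @param strain_id character label of the strain.
#' @param temperature incubation temperature in degrees C.
#' @param replicate replicate index (positive integer).
#' @param times measurement times in days, strictly increasing, length >= 2.
#' @param f0 F0 fluorescence values (arbitrary units), same length as
#'   `times`, finite and nonnegative.
#' @return An object of class `fluorescence_series`.
#' @export
fluorescence_series <- function(strain_id, temperature, replicate, times, f0) {
  if (length(times) < 2L)
    stopf("a fluorescence series needs at least 2 observations, got %d",
          length(times))
  if (length(f0) != length(times))
    stopf("times (%d) and f0 (%d) lengths differ", length(times), length(f0))
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stopf("times must be finite and strictly increasing")
  if (any(!is.finite(f0)))
    stopf("f0 values must be finite")
  if (any(f0 < 0))
    stopf("f0 values must be nonnegative")
  structure(
    list(strain_id = as.character(strain_id),
         temperature = as.numeric(temperature),
         replicate = as.integer(replicate),
         times = as.numeric(times), f0 = as.numeric(f0)),
    class = "fluorescence_series")
}

#' @export
print.fluorescence_series <- function(x, ...) {
  cat(sprintf("<fluorescence_series> strain %s, %.1f degC, replicate %d, %d points over %.1f d\n",
              x$strain_id, x$temperature, x$replicate, length(x$times),
              diff(range(x$times))))
  invisible(x)
}

#' Estimate a growth rate from a fluorescence series
#'
#' Ordinary least squares of log2(F0) on time (days), restricted to a time
#' window, giving the growth rate in divisions per day. The default window
#' keeps all points in the first five days (the exponential phase of the
#' standard assay). `window = "auto"` instead scans every contiguous run of
#' at least four points and keeps the one maximizing R-squared (ties broken
#' towards more points, then earlier start).
#'
#' @param series a [fluorescence_series()] object.
#' @param window numeric `c(start_day, end_day)` or the string `"auto"`.
#' @param drop_nonpositive if `TRUE`, nonpositive F0 values inside the window
#'   are dropped with a warning instead of raising an error (log2 is
#'   undefined there).
#' @return A `growth_rate_estimate`: list with `rate` (divisions/day),
#'   `r_squared`, `n_points`, `window`, plus the series labels.
#' @export
estimate_growth_rate <- function(series, window = c(0, 5),
                                 drop_nonpositive = FALSE) {
  stopifnot(inherits(series, "fluorescence_series"))
  auto <- identical(window, "auto")
  if (auto) {
    keep <- rep(TRUE, length(series$times))
    win <- range(series$times)
  } else {
    if (!is.numeric(window) || length(window) != 2L || window[1] > window[2])
      stopf("window must be c(start_day, end_day) with start <= end, or \"auto\"")
    keep <- series$times >= window[1] & series$times <= window[2]
    win <- as.numeric(window)
  }
  tt <- series$times[keep]
  ff <- series$f0[keep]
  bad <- which(ff <= 0)
  if (length(bad)) {
    if (!drop_nonpositive)
      stopf("nonpositive f0 (%g) at day %g for strain %s, %.1f degC, replicate %d: log2 undefined",
            ff[bad[1]], tt[bad[1]], series$strain_id, series$temperature,
            series$replicate)
    warnf("dropping %d nonpositive f0 point(s) for strain %s, %.1f degC, replicate %d",
          length(bad), series$strain_id, series$temperature, series$replicate)
    tt <- tt[-bad]; ff <- ff[-bad]
  }
  if (length(tt) < 2L)
    stopf("fewer than 2 usable points in window [%g, %g] (strain %s, %.1f degC)",
          win[1], win[2], series$strain_id, series$temperature)

  if (auto) {
    n <- length(tt)
    if (n < 4L) {
      sel <- seq_len(n)
    } else {
      best <- NULL; best_key <- c(-Inf, -Inf, Inf)
      for (i in seq_len(n - 3L)) for (j in seq(i + 3L, n)) {
        r2 <- .ols_log2(tt[i:j], ff[i:j])$r_squared
        key <- c(r2, j - i + 1L, -i)
        if (key[1] > best_key[1] + 1e-12 ||
            (abs(key[1] - best_key[1]) <= 1e-12 &&
             (key[2] > best_key[2] ||
              (key[2] == best_key[2] && key[3] > best_key[3])))) {
          best <- i:j; best_key <- key
        }
      }
      sel <- best
    }
    tt <- tt[sel]; ff <- ff[sel]
    win <- range(tt)
  }

  fit <- .ols_log2(tt, ff)
  structure(
    list(rate = fit$slope, r_squared = fit$r_squared,
         n_points = length(tt), window = win,
         strain_id = series$strain_id, temperature = series$temperature,
         replicate = series$replicate),
    class = "growth_rate_estimate")
}

# OLS of log2(f) on t; r_squared defined as 1 for an exact fit even when the
# response is constant (zero total sum of squares).
.ols_log2 <- function(tt, ff) {
  y <- log2(ff)
  tb <- mean(tt); yb <- mean(y)
  sxx <- sum((tt - tb)^2)
  slope <- sum((tt - tb) * (y - yb)) / sxx
  res <- y - (yb + slope * (tt - tb))
  tss <- sum((y - yb)^2)
  rss <- sum(res^2)
  r2 <- if (tss <= .Machine$double.eps * max(1, sum(y^2))) 1
        else max(0, min(1, 1 - rss / tss))
  list(slope = slope, r_squared = r2)
}

#' Average replicate growth-rate estimates
#'
#' Arithmetic mean across replicates with a standard error computed from the
#' sample (n-1) standard deviation. A single replicate reports `se_rate = 0`.
#' All estimates must come from the same strain and temperature.
#'
#' @param estimates nonempty list of `growth_rate_estimate` objects (or bare
#'   numeric rates).
#' @return list with `mean_rate`, `se_rate`, `n_replicates`, and the shared
#'   `strain_id` / `temperature` when available.
#' @export
average_replicates <- function(estimates) {
  if (length(estimates) == 0L)
    stopf("cannot average an empty list of growth-rate estimates")
  if (is.numeric(estimates)) estimates <- lapply(estimates, function(r) list(rate = r))
  rates <- vapply(estimates, function(e) e$rate, numeric(1))
  strains <- unique(unlist(lapply(estimates, function(e) e$strain_id)))
  temps <- unique(unlist(lapply(estimates, function(e) e$temperature)))
  if (length(strains) > 1L)
    stopf("estimates mix strains: %s", paste(strains, collapse = ", "))
  if (length(temps) > 1L)
    stopf("estimates mix temperatures: %s", paste(temps, collapse = ", "))
  n <- length(rates)
  se <- if (n > 1L) stats::sd(rates) / sqrt(n) else 0
  list(mean_rate = mean(rates), se_rate = se, n_replicates = n,
       strain_id = if (length(strains)) strains else NA_character_,
       temperature = if (length(temps)) temps else NA_real_)
}

#' Viable-cell fractions from live/dead counts
#'
#' Summarizes SYTOX-type viability counts (cells scored viable out of a
#' total, typically 400 per replicate) into per-replicate fractions, their
#' mean, and an alive/dead verdict: viable cells are "detected" as soon as
#' any replicate has a nonzero fraction.
#'
#' @param counts data.frame with columns `viable` and `total`, or a list of
#'   lists with those fields.
#' @return list with `fractions`, `mean_fraction`, `n_replicates`, `verdict`
#'   (`"viable cells detected"` or `"no viable cells"`).
#' @export
viability_fraction <- function(counts) {
  if (is.data.frame(counts)) {
    viable <- counts$viable; total <- counts$total
  } else {
    viable <- vapply(counts, function(x) x$viable, numeric(1))
    total <- vapply(counts, function(x) x$total, numeric(1))
  }
  if (length(viable) == 0L) stopf("no viability counts supplied")
  if (any(!is.finite(total)) || any(total <= 0))
    stopf("every total count must be > 0")
  if (any(viable < 0 | viable > total))
    stopf("viable counts must satisfy 0 <= viable <= total")
  fr <- viable / total
  list(fractions = fr, mean_fraction = mean(fr), n_replicates = length(fr),
       verdict = if (any(fr > 0)) "viable cells detected" else "no viable cells")
}

#' Read a long-format F0 growth table
#'
#' Expected CSV schema (header mandatory): `strain_id, temperature_c,
#' replicate, time_days, f0`.
#'
#' @param path CSV file path.
#' @return list of [fluorescence_series()] objects, one per
#'   strain x temperature x replicate.
#' @export
read_f0_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain_id", "temperature_c", "replicate", "time_days", "f0")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("F0 table %s is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  f0_series_from_df(df)
}

#' Split a long F0 data.frame into fluorescence series
#'
#' @param df data.frame with the [read_f0_csv()] schema.
#' @return list of [fluorescence_series()] objects.
#' @export
f0_series_from_df <- function(df) {
  key <- interaction(df$strain_id, df$temperature_c, df$replicate, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$time_days), ]
    fluorescence_series(g$strain_id[1], g$temperature_c[1], g$replicate[1],
                        g$time_days, g$f0)
  })
}

#' Per-strain, per-temperature growth-rate summary table
#'
#' Runs [estimate_growth_rate()] on every series and averages replicates,
#' producing the table the thermal-curve fit consumes.
#'
#' @param series list of [fluorescence_series()] (e.g. from [read_f0_csv()])
#'   or a long data.frame with the F0 CSV schema.
#' @param window regression window passed to [estimate_growth_rate()].
#' @param drop_nonpositive passed to [estimate_growth_rate()].
#' @return data.frame with columns `strain_id, temperature_c, mean_rate,
#'   se_rate, n_replicates`.
#' @export
growth_rate_table <- function(series, window = c(0, 5),
                              drop_nonpositive = FALSE) {
  if (is.data.frame(series)) series <- f0_series_from_df(series)
  est <- lapply(series, estimate_growth_rate, window = window,
                drop_nonpositive = drop_nonpositive)
  key <- vapply(est, function(e) paste(e$strain_id, e$temperature, sep = "\r"),
                character(1))
  out <- lapply(split(est, key), average_replicates)
  df <- do.call(rbind, lapply(out, function(s)
    data.frame(strain_id = s$strain_id, temperature_c = s$temperature,
               mean_rate = s$mean_rate, se_rate = s$se_rate,
               n_replicates = s$n_replicates, stringsAsFactors = FALSE)))
  df <- df[order(df$strain_id, df$temperature_c), ]
  rownames(df) <- NULL
  df
}
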