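# Circadian analysis of binned behavior series: variance-normalized
# Lomb-Scargle periodograms with analytic significance thresholds,
# dominant-period extraction, the two-peak piecewise-exponential
# activity model, grooming-shuffling experiments and bootstrap
# correlation tests.

series_values <- function(series) {
  if (inherits(series, "groom_binned")) {
    list(values = series$value,
         t_h = series$bin_start_min / 60,
         bin_minutes = attr(series, "bin_minutes") %||% 30)
  } else if (is.numeric(series)) {
    list(values = series, t_h = NULL, bin_minutes = NULL)
  } else {
    stop("`series` must be a groom_binned object or a numeric vector",
         call. = FALSE)
  }
}

#' Lomb-Scargle periodogram of a binned series
#'
#' Classical normalized periodogram (power normalized by the series
#' variance) on a frequency grid spanning `period_band_h`, oversampled
#' by `oversample` relative to the natural spacing `1/T`. The attribute
#' `N_eff` -- the effective number of independent frequencies,
#' `n * (f_max - f_min) / f_Nyquist` -- feeds the analytic significance
#' thresholds via [threshold_power()]; it matches the Monte-Carlo null
#' quantile of peak power on white noise (see the methods vignette).
#'
#' @param series a `groom_binned` or numeric vector (then `bin_minutes`
#'   must be given).
#' @param period_band_h period range scanned, in hours.
#' @param oversample frequency oversampling factor.
#' @param bin_minutes bin width when `series` is a bare vector.
#' @return object of class `groom_periodogram`: data.frame with
#'   `period_h`, `freq_per_h`, `power`; attributes `N` (grid size),
#'   `N_eff`, `threshold_p05`, `threshold_p01`, `n`.
#' @export
lomb_scargle <- function(series, period_band_h = c(1, 48), oversample = 16,
                         bin_minutes = NULL) {
  s <- series_values(series)
  x <- s$values
  bm <- bin_minutes %||% s$bin_minutes
  if (is.null(bm) && is.null(s$t_h)) {
    stop("`bin_minutes` is required for a bare numeric series", call. = FALSE)
  }
  t <- s$t_h %||% ((seq_along(x) - 1) * bm / 60)
  if (!all(is.finite(x))) stop("series contains non-finite values", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("constant series: spectral power is undefined", call. = FALSE)
  }
  Tspan <- diff(range(t))
  dt <- stats::median(diff(sort(t)))
  f_nyq <- 1 / (2 * dt)
  fmin <- 1 / max(period_band_h)
  fmax <- 1 / min(period_band_h)
  df <- 1 / (oversample * Tspan)
  freqs <- seq(fmin, fmax, by = df)
  xc <- x - mean(x)
  s2 <- stats::var(x)
  power <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    (sum(xc * ct)^2 / sum(ct^2) + sum(xc * st)^2 / sum(st^2)) / (2 * s2)
  }, numeric(1))
  n_eff <- max(1, round(length(x) * (fmax - fmin) / f_nyq))
  structure(
    data.frame(period_h = 1 / freqs, freq_per_h = freqs, power = power),
    N = length(freqs),
    N_eff = n_eff,
    n = length(x),
    threshold_p05 = threshold_power(0.05, n_eff),
    threshold_p01 = threshold_power(0.01, n_eff),
    class = c("groom_periodogram", "data.frame")
  )
}

#' Significance threshold for Lomb-Scargle power
#'
#' Power exceeded with probability `p` by the maximum of `N` independent
#' unit-exponential spectral powers:
#' `-ln(1 - (1 - p)^(1/N))`.
#'
#' @param p p-value in (0, 1).
#' @param N number of independent frequencies.
#' @return threshold power (dimensionless normalized power).
#' @examples
#' threshold_power(0.05, 1)    # -log(0.05) ~ 3.0
#' threshold_power(0.05, 100)  # ~ 7.58
#' @export
threshold_power <- function(p, N) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(N < 1)) stop("`N` must be at least 1", call. = FALSE)
  -log(1 - (1 - p)^(1 / N))
}

#' Dominant period within a band
#'
#' The period of maximal power inside `band_h`, with significance
#' against the periodogram's analytic thresholds. Power ties are
#' resolved toward the lower period.
#'
#' @param pg a `groom_periodogram`.
#' @param band_h period band searched (hours).
#' @return list with `period_h`, `power`, `significant_at` (`"0.01"`,
#'   `"0.05"` or `"none"`).
#' @export
dominant_period <- function(pg, band_h = c(16, 32)) {
  sel <- pg$period_h >= band_h[1] & pg$period_h <= band_h[2]
  if (!any(sel)) stop("no frequencies inside the requested band", call. = FALSE)
  sub <- pg[sel, , drop = FALSE]
  top <- max(sub$power)
  cand <- sub[sub$power == top, , drop = FALSE]
  per <- min(cand$period_h)
  sig <- if (top > attr(pg, "threshold_p01")) "0.01"
         else if (top > attr(pg, "threshold_p05")) "0.05"
         else "none"
  list(period_h = per, power = top, significant_at = sig)
}

# unit-height two-peak profile in [0, 1]: morning peak centered at
# phase 0, evening peak at half the period
unit_two_peak_profile <- function(t_h, period_h = 24, peak_width_h = 3,
                                  rise_rate = 0.6, decay_rate = 0.6) {
  p <- two_peak_model(t_h, c(b_MD = decay_rate, b_MR = rise_rate,
                             b_ER = rise_rate, b_ED = decay_rate,
                             T0 = period_h, T_M = peak_width_h,
                             T_E = peak_width_h, H_M = 1, H_E = 1))
  pmin(1, p)
}

#' Two-peak exponential activity template
#'
#' The package's fixed periodic template for long-timescale activity: a
#' morning and an evening peak, each a plateau of height `H` and width
#' `T` reached by an exponential rise at rate `b_*R` and left by an
#' exponential decay at rate `b_*D`. The morning plateau is centered at
#' circadian phase 0 (lights-on) and the evening plateau at half the
#' period `T0/2`; the two components are summed. All rates are in 1/hour.
#'
#' @param t_h time in hours.
#' @param params named vector with `b_MD`, `b_MR`, `b_ER`, `b_ED`, `T0`,
#'   `T_M`, `T_E`, `H_M`, `H_E`.
#' @return activity value at each time.
#' @export
two_peak_model <- function(t_h, params) {
  p <- as.list(params)
  peak <- function(phi, center, Tw, b_rise, b_decay, H) {
    s <- ((phi - center + p$T0 / 2) %% p$T0) - p$T0 / 2
    ifelse(abs(s) <= Tw / 2, H,
           ifelse(s < 0, H * exp(b_rise * (s + Tw / 2)),
                  H * exp(-b_decay * (s - Tw / 2))))
  }
  phi <- t_h %% p$T0
  peak(phi, 0, p$T_M, p$b_MR, p$b_MD, p$H_M) +
    peak(phi, p$T0 / 2, p$T_E, p$b_ER, p$b_ED, p$H_E)
}

#' Fit the two-peak activity model to a binned series
#'
#' Least-squares fit of [two_peak_model()] by Levenberg-Marquardt.
#' Starting values default to a data-driven heuristic (period from the
#' circadian periodogram peak, heights from the morning/evening maxima)
#' and the fit is deterministic given the start. The reported
#' `fit_error` is the residual sum of squares divided by `n * var(y)`
#' (fraction of variance left unexplained).
#'
#' @param series a `groom_binned` or numeric vector with `bin_minutes`.
#' @param init optional named starting vector (see [two_peak_model()]).
#' @param lower,upper optional box constraints in the same order.
#' @param bin_minutes bin width for a bare vector.
#' @return object of class `groom_peakfit`: list with `params`,
#'   `fit_error`, `fitted`, `converged`, `message`.
#' @export
fit_two_peak_model <- function(series, init = NULL, lower = NULL,
                               upper = NULL, bin_minutes = NULL) {
  s <- series_values(series)
  y <- s$values
  bm <- bin_minutes %||% s$bin_minutes %||% 30
  t_h <- s$t_h %||% ((seq_along(y) - 1) * bm / 60)
  if (diff(range(t_h)) < 40) {
    stop("at least ~2 full circadian periods of data are required",
         call. = FALSE)
  }
  if (is.null(init)) {
    T0 <- tryCatch(
      dominant_period(lomb_scargle(series, bin_minutes = bm),
                      band_h = c(20, 30))$period_h,
      error = function(e) 24
    )
    phase <- t_h %% T0
    near_m <- phase < T0 / 4 | phase > 3 * T0 / 4
    H_M <- max(y[near_m], 0.1 * max(y))
    H_E <- max(y[!near_m], 0.1 * max(y))
    init <- c(b_MD = 0.3, b_MR = 0.3, b_ER = 0.3, b_ED = 0.3, T0 = T0,
              T_M = 3, T_E = 3, H_M = H_M / 2, H_E = H_E / 2)
  }
  pnames <- c("b_MD", "b_MR", "b_ER", "b_ED", "T0", "T_M", "T_E",
              "H_M", "H_E")
  init <- init[pnames]
  lower <- lower %||% c(-2, -2, -2, -2, 18, 0.2, 0.2, 0, 0)
  upper <- upper %||% c(5, 5, 5, 5, 32, 12, 12, Inf, Inf)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ two_peak_model(t_h, c(b_MD = b_MD, b_MR = b_MR, b_ER = b_ER,
                                b_ED = b_ED, T0 = T0, T_M = T_M, T_E = T_E,
                                H_M = H_M, H_E = H_E)),
      start = as.list(init), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 300)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(params = init, fit_error = NA_real_,
                          fitted = NULL, converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "groom_peakfit"))
  }
  params <- stats::coef(fit)[pnames]
  fitted_v <- two_peak_model(t_h, params)
  rss <- sum((y - fitted_v)^2)
  structure(
    list(params = params,
         fit_error = rss / (length(y) * stats::var(y)),
         fitted = fitted_v, converged = TRUE, message = "converged"),
    class = "groom_peakfit"
  )
}

#' Grooming-shuffling experiment
#'
#' Randomly permutes the grooming bins and compensates either locomotion
#' or wakefulness by the conservation rule
#' `modified = original companion + original grooming - randomized
#' grooming`, re-drawing the permutation until every modified bin lies
#' in `[0, 1]`. The non-selected companion series is returned unchanged.
#'
#' @param grooming,locomotion,wake aligned binned series (`groom_binned`
#'   or numeric).
#' @param mode which companion series absorbs the compensation.
#' @param seed RNG seed.
#' @param max_retries permutation retry cap before giving up.
#' @param perm optional explicit permutation (testing hook; e.g. the
#'   identity).
#' @return list with `randomized_grooming`, `locomotion`, `wake`,
#'   `mode`, `n_tries`.
#' @export
shuffle_experiment <- function(grooming, locomotion, wake,
                               mode = c("locomotion", "wake"), seed = NULL,
                               max_retries = 1000, perm = NULL) {
  mode <- match.arg(mode)
  g <- series_values(grooming)$values
  l <- series_values(locomotion)$values
  w <- series_values(wake)$values
  n <- length(g)
  if (length(l) != n || length(w) != n) {
    stop("series are not aligned on the same bins", call. = FALSE)
  }
  companion <- if (mode == "locomotion") l else w
  with_seed(seed, {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      pm <- perm %||% sample.int(n)
      g_rand <- g[pm]
      modified <- companion + g - g_rand
      if (all(modified >= 0 & modified <= 1)) break
      if (!is.null(perm) || tries >= max_retries) {
        stop("no admissible permutation found within the retry cap",
             call. = FALSE)
      }
    }
    list(
      randomized_grooming = g_rand,
      locomotion = if (mode == "locomotion") modified else l,
      wake = if (mode == "wake") modified else w,
      mode = mode, n_tries = tries
    )
  })
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors (n >= 3) with nonzero
#'   variance.
#' @return the correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Bootstrap significance of a Pearson correlation
#'
#' Builds the null distribution by randomly re-pairing `x` with permuted
#' `y` `n_resamples` times and reports the two-tailed empirical p-value
#' `(1 + #{|r_null| >= |r_obs|}) / (n_resamples + 1)` (the +1 continuity
#' correction keeps p strictly positive).
#'
#' @param x,y as in [pearson_r()].
#' @param n_resamples number of random re-pairings.
#' @param seed RNG seed; fixed seed gives an identical p-value.
#' @return object of class `groom_cor`: list with `r`, `p_boot`,
#'   `n_resamples`, `seed`.
#' @export
bootstrap_correlation_p <- function(x, y, n_resamples = 100000, seed = NULL) {
  r_obs <- pearson_r(x, y)
  n <- length(x)
  xs <- (x - mean(x)) / stats::sd(x)
  ys <- (y - mean(y)) / stats::sd(y)
  with_seed(seed, {
    hits <- 0L
    denom <- n - 1
    for (i in seq_len(n_resamples)) {
      r0 <- sum(xs * ys[sample.int(n)]) / denom
      if (abs(r0) >= abs(r_obs)) hits <- hits + 1L
    }
    structure(
      list(r = r_obs, p_boot = (1 + hits) / (n_resamples + 1),
           n_resamples = n_resamples, seed = seed),
      class = "groom_cor"
    )
  })
}
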