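#' Per-temperature linear degradation/production rate
#'
#' Ordinary least squares of concentration on storage time, pooling batches:
#' the citric acid model, whose concentration decreases close to linearly
#' during storage. The slope is returned signed (negative for degradation).
#'
#' @param time storage times, days.
#' @param conc concentrations (any consistent unit; the slope inherits
#'   unit/day).
#' @param temperature storage temperature label, degC.
#' @param by_batch optional batch factor; when supplied, per-batch slopes are
#'   also returned for diagnostics (the headline rate still pools batches).
#' @return `linear_rate_fit`: list with `temperature`, `rate`, `intercept`,
#'   `se`, `n`, and optionally `batch_rates`.
#' @export
linear_rate <- function(time, conc, temperature = NA_real_, by_batch = NULL) {
  ok <- is.finite(time) & is.finite(conc)
  time <- time[ok]; conc <- conc[ok]
  if (length(unique(time)) < 3)
    stop("need >= 3 distinct storage times")
  fit <- stats::lm(conc ~ time)
  sm <- summary(fit)$coefficients
  out <- list(temperature = temperature,
              rate = unname(sm["time", "Estimate"]),
              intercept = unname(sm["(Intercept)", "Estimate"]),
              se = unname(sm["time", "Std. Error"]),
              n = length(time))
  if (!is.null(by_batch)) {
    bb <- by_batch[ok]
    out$batch_rates <- vapply(split(seq_along(time), bb), function(i) {
      if (length(unique(time[i])) < 3) return(NA_real_)
      unname(stats::coef(stats::lm(conc[i] ~ time[i]))[2])
    }, numeric(1))
  }
  class(out) <- "linear_rate_fit"
  out
}

#' @export
print.linear_rate_fit <- function(x, ...) {
  cat(sprintf("<linear_rate_fit @ %s degC: rate %.4g +/- %.3g per day (n=%d)>\n",
              format(x$temperature), x$rate, x$se, x$n))
  invisible(x)
}

#' Arrhenius fit of temperature-dependent rates
#'
#' Regresses the natural log of the absolute rate on reciprocal absolute
#' temperature (K = degC + 273.15); the activation energy is
#' Ea = -slope * R, reported in kJ/mol. The common sign of the rates is
#' carried separately so degradation (negative) rates have a defined
#' logarithm.
#'
#' @param rates list of `linear_rate_fit` objects, or a data.frame with
#'   columns `temperature` and `rate`.
#' @return `arrhenius_fit`: list with `Ea_kJ_mol`, `ln_pre_exponential`,
#'   `slope_K`, `sign`, `points` (data.frame of `inv_T_K`, `ln_abs_rate`),
#'   `Ea_se_kJ_mol`, `r_squared`.
#' @export
arrhenius <- function(rates) {
  if (is.data.frame(rates)) {
    temperature <- rates$temperature; rate <- rates$rate
  } else {
    temperature <- vapply(rates, `[[`, numeric(1), "temperature")
    rate <- vapply(rates, `[[`, numeric(1), "rate")
  }
  if (length(rate) < 3) stop("need rates at >= 3 temperatures")
  if (any(rate == 0)) stop("zero rates have no defined logarithm")
  if (length(unique(sign(rate))) != 1)
    stop("rates must share one sign (all degradation or all production)")
  invT <- 1 / kelvin(temperature)
  lr <- log(abs(rate))
  fit <- stats::lm(lr ~ invT)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  out <- list(
    Ea_kJ_mol = -slope * GAS_CONSTANT / 1000,
    ln_pre_exponential = unname(stats::coef(fit)[1]),
    slope_K = slope,
    sign = sign(rate[1]),
    points = data.frame(temperature = temperature, inv_T_K = invT,
                        ln_abs_rate = lr),
    Ea_se_kJ_mol = unname(sm$coefficients[2, 2]) * GAS_CONSTANT / 1000,
    r_squared = sm$r.squared)
  class(out) <- "arrhenius_fit"
  out
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit: Ea = %.1f +/- %.1f kJ/mol over %d temperatures>\n",
              x$Ea_kJ_mol, x$Ea_se_kJ_mol, nrow(x$points)))
  invisible(x)
}

#' Threshold time of a metabolite at one storage temperature
#'
#' Runs Steel's many-one test with the baseline (time point zero) samples as
#' control and each later collection time point as a treatment group, and
#' returns the first collection time point whose concentration significantly
#' exceeds baseline (`side = "greater"`; use `"less"` for degrading
#' metabolites). The threshold time tau is the mean storage time of the
#' samples at that collection point, with their standard deviation as its
#' dispersion; `defined = FALSE` when no time point reaches significance.
#'
#' @param data data.frame with `timepoint_index`, `storage_time_d` and
#'   `concentration` for one metabolite at one temperature (baseline rows
#'   have `timepoint_index == 0`).
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @param side passed to [steel_test()].
#' @param metabolite,temperature labels carried into the result.
#' @param ... further arguments to [steel_test()].
#' @return `threshold_time`: list with `metabolite`, `temperature`,
#'   `threshold_index`, `tau`, `tau_sd`, `p`, `defined`, `steel` (the full
#'   test table).
#' @export
threshold_time <- function(data, alpha = 0.05, side = "greater",
                           metabolite = NA_character_,
                           temperature = NA_real_, ...) {
  stopifnot(all(c("timepoint_index", "storage_time_d", "concentration")
                %in% names(data)))
  ctrl <- data$concentration[data$timepoint_index == 0]
  if (length(ctrl) == 0) stop("baseline (timepoint 0) group is empty")
  idx <- sort(unique(data$timepoint_index[data$timepoint_index > 0]))
  if (length(idx) == 0) stop("need at least one post-baseline time point")
  trts <- lapply(idx, function(i)
    data$concentration[data$timepoint_index == i])
  names(trts) <- as.character(idx)
  st <- steel_test(ctrl, trts, side = side, ...)
  hit <- which(st$p_adjusted < alpha)
  out <- list(metabolite = metabolite, temperature = temperature,
              threshold_index = NA_integer_, tau = NA_real_,
              tau_sd = NA_real_, p = NA_real_, defined = FALSE, steel = st)
  if (length(hit) > 0) {
    j <- min(hit)
    times <- data$storage_time_d[data$timepoint_index == idx[j]]
    out$threshold_index <- idx[j]
    out$tau <- mean(times)
    out$tau_sd <- stats::sd(times)
    out$p <- st$p_adjusted[j]
    out$defined <- TRUE
  }
  class(out) <- "threshold_time"
  out
}

#' @export
print.threshold_time <- function(x, ...) {
  if (x$defined)
    cat(sprintf("<threshold_time %s @ %s degC: tau = %.2f +/- %.2f d (tp %d, p = %.3f)>\n",
                x$metabolite, format(x$temperature), x$tau, x$tau_sd,
                x$threshold_index, x$p))
  else
    cat(sprintf("<threshold_time %s @ %s degC: not determined>\n",
                x$metabolite, format(x$temperature)))
  invisible(x)
}

#' Exponential decay of threshold time with storage temperature
#'
#' Fits tau = A * exp(k * T) by unweighted nonlinear least squares on the
#' original scale (not log-linear OLS: the two disagree noticeably because
#' original-scale NLS weights the long low-temperature threshold times more
#' heavily). The 95% confidence interval of k comes from the linearized
#' covariance with a t quantile at n - 2 degrees of freedom. If the NLS does
#' not converge, the log-linear estimate is returned flagged as a fallback.
#'
#' @param temperature storage temperatures, degC.
#' @param tau threshold times, days; pairs with non-finite tau (undefined
#'   thresholds) are dropped.
#' @param metabolite label carried into the result.
#' @return `threshold_decay_fit`: list with `A`, `k`, `k_se`, `k_ci`
#'   (95% CI), `sse`, `n`, `fallback`.
#' @export
decay_fit <- function(temperature, tau, metabolite = NA_character_) {
  ok <- is.finite(temperature) & is.finite(tau)
  temperature <- temperature[ok]; tau <- tau[ok]
  n <- length(tau)
  if (n < 3) stop("need >= 3 defined (temperature, tau) pairs")
  if (any(tau <= 0)) stop("threshold times must be positive")
  ll <- stats::lm(log(tau) ~ temperature)
  start <- list(A = exp(unname(stats::coef(ll)[1])),
                k = unname(stats::coef(ll)[2]))
  d <- data.frame(temperature = temperature, tau = tau)
  fit <- tryCatch(
    stats::nls(tau ~ A * exp(k * temperature), data = d, start = start,
               control = stats::nls.control(maxiter = 500, scaleOffset = 1)),
    error = function(e) NULL)
  if (is.null(fit)) {
    sm <- summary(ll)$coefficients
    k <- start$k; se <- sm["temperature", "Std. Error"]
    out <- list(metabolite = metabolite, A = start$A, k = k, k_se = se,
                k_ci = k + c(-1, 1) * stats::qt(0.975, n - 2) * se,
                sse = sum((tau - start$A * exp(k * temperature))^2),
                n = n, fallback = TRUE)
  } else {
    sm <- summary(fit)$coefficients
    k <- unname(sm["k", "Estimate"]); se <- unname(sm["k", "Std. Error"])
    out <- list(metabolite = metabolite,
                A = unname(sm["A", "Estimate"]), k = k, k_se = se,
                k_ci = k + c(-1, 1) * stats::qt(0.975, n - 2) * se,
                sse = sum(stats::resid(fit)^2), n = n, fallback = FALSE)
  }
  class(out) <- "threshold_decay_fit"
  out
}

#' @export
print.threshold_decay_fit <- function(x, ...) {
  cat(sprintf(
    "<threshold_decay_fit %s: tau = %.3g * exp(%.3f T), k 95%% CI [%.3f, %.3f]%s>\n",
    x$metabolite, x$A, x$k, x$k_ci[1], x$k_ci[2],
    if (x$fallback) " (log-linear fallback)" else ""))
  invisible(x)
}
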