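test_that("linear_rate recovers an exact line and rejects tiny designs", {
  t <- c(0, 2, 5, 9, 14)
  fit <- suppressWarnings(linear_rate(t, 10.3 - 0.06 * t, temperature = 4))
  expect_equal(fit$rate, -0.06, tolerance = 1e-12)
  expect_equal(fit$intercept, 10.3, tolerance = 1e-12)
  expect_error(linear_rate(c(1, 1, 2), c(1, 1, 2)), "3 distinct")
})

test_that("duplicating a dataset keeps the slope and shrinks the SE by the exact factor", {
  set.seed(2)
  t <- rep(c(0, 3, 6, 9, 12), each = 2)
  y <- 5 - 0.3 * t + rnorm(10, 0, 0.2)
  f1 <- linear_rate(t, y)
  f2 <- linear_rate(c(t, t), c(y, y))
  expect_equal(f2$rate, f1$rate, tolerance = 1e-12)
  # exact algebra: RSS doubles, df goes n-2 -> 2n-2, Sxx doubles, so
  # se2/se1 = sqrt((n-2)/(2n-2)) -- approaching the 1/sqrt(2) rule of thumb
  n <- length(t)
  expect_equal(f2$se / f1$se, sqrt((n - 2) / (2 * n - 2)), tolerance = 1e-10)
  expect_lt(f2$se, f1$se)
})

test_that("pooled slope is unchanged by a batch-constant offset on a balanced design", {
  t <- rep(c(0, 2, 4, 6, 8), times = 2)
  batch <- rep(c("A", "B"), each = 5)
  set.seed(6)
  y <- 10 - 0.5 * t + rnorm(10, 0, 0.05)
  y2 <- y + ifelse(batch == "A", 0.7, 0)
  f1 <- linear_rate(t, y)
  f2 <- linear_rate(t, y2, by_batch = batch)
  expect_equal(f2$rate, f1$rate, tolerance = 1e-12)
  expect_length(f2$batch_rates, 2)
})

test_that("arrhenius recovers a forward-generated activation energy to 1e-9", {
  Ea <- 100; T <- c(4, 10, 15, 20)
  r <- -arrhenius_rate(T, 0.05, Ea, 4)
  fit <- arrhenius(data.frame(temperature = T, rate = r))
  expect_equal(fit$Ea_kJ_mol, Ea, tolerance = 1e-9)
  expect_equal(fit$sign, -1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("arrhenius degenerate and error paths", {
  T <- c(4, 10, 15, 20)
  eq <- suppressWarnings(arrhenius(data.frame(temperature = T, rate = rep(-0.5, 4))))
  expect_equal(eq$Ea_kJ_mol, 0, tolerance = 1e-12)
  expect_error(arrhenius(data.frame(temperature = T, rate = c(-1, 1, -1, -1))),
               "sign")
  expect_error(arrhenius(data.frame(temperature = T, rate = c(0, -1, -1, -1))),
               "zero")
  expect_error(arrhenius(data.frame(temperature = c(4, 10), rate = c(-1, -2))),
               "3 temperatures")
})

test_that("threshold_time finds the first significant collection point", {
  set.seed(30)
  mk <- function(shift) rnorm(6, 1 + shift, 0.03)
  d <- rbind(
    data.frame(timepoint_index = 0, storage_time_d = 0, concentration = mk(0)),
    data.frame(timepoint_index = 1, storage_time_d = rnorm(6, 2, 0.05),
               concentration = mk(0)),
    data.frame(timepoint_index = 2, storage_time_d = rnorm(6, 5, 0.05),
               concentration = mk(0)),
    data.frame(timepoint_index = 3, storage_time_d = rnorm(6, 9, 0.05),
               concentration = mk(1)))
  tt <- threshold_time(d, alpha = 0.05)
  expect_true(tt$defined)
  expect_equal(tt$threshold_index, 3)
  expect_equal(tt$tau, mean(d$storage_time_d[d$timepoint_index == 3]))
  expect_equal(tt$tau_sd, sd(d$storage_time_d[d$timepoint_index == 3]))
  expect_lt(tt$p, 0.05)

  # degenerate level: everything qualifies at alpha = 1
  t1 <- threshold_time(d, alpha = 1)
  expect_equal(t1$threshold_index, 1)

  # a flat metabolite never crosses
  d0 <- d; d0$concentration <- rep(1, nrow(d0))
  expect_false(threshold_time(d0, alpha = 0.05)$defined)

  expect_error(threshold_time(d[d$timepoint_index > 0, ]), "baseline")
})

test_that("raising all post-baseline concentrations never delays the threshold", {
  set.seed(31)
  d <- do.call(rbind, lapply(0:4, function(i) data.frame(
    timepoint_index = i, storage_time_d = i * 3,
    concentration = rnorm(5, 1 + 0.12 * i, 0.1))))
  tau0 <- threshold_time(d, alpha = 0.05)
  for (delta in c(0.05, 0.2, 0.5)) {
    d2 <- d
    up <- d2$timepoint_index > 0
    d2$concentration[up] <- d2$concentration[up] + delta
    tau1 <- threshold_time(d2, alpha = 0.05)
    if (tau0$defined) {
      expect_true(tau1$defined)
      expect_lte(tau1$threshold_index, tau0$threshold_index)
    }
  }
})

test_that("threshold matches the first scheduled collection at or after the true lag", {
  # lag exactly 12 d at 10 degC; default schedule's first mean day >= 12
  # is the collection at 12.01 d
  cfg <- sim_config(noise_cv = 0.005, baseline_batch_cv = 0,
                    lag_amplitude = 12 * exp(0.254 * 10), lag_decay = -0.254,
                    post_lag_rate = c(ethanol = 5), rate_q10 = 1,
                    seed = 77)
  s <- simulate_concentrations(cfg)
  d <- s[s$metabolite == "ethanol" &
           (s$temperature_C == 10 | s$timepoint_index == 0), ]
  tt <- threshold_time(data.frame(timepoint_index = d$timepoint_index,
                                  storage_time_d = d$storage_time_d,
                                  concentration = d$concentration_M))
  sched <- default_schedule()[["10"]]
  expect_equal(tt$tau, 12.01, tolerance = 0.02)
  expect_equal(sched$mean_day[tt$threshold_index + 1], 12.01)
})

test_that("decay_fit recovers an exact exponential and reports a covering CI", {
  T <- c(4, 10, 15, 20)
  fit <- decay_fit(T, 100 * exp(-0.2 * T))
  expect_equal(fit$A, 100, tolerance = 1e-9)
  expect_equal(fit$k, -0.2, tolerance = 1e-9)
  expect_false(fit$fallback)
  expect_true(fit$k_ci[1] <= fit$k && fit$k <= fit$k_ci[2])
  expect_error(decay_fit(c(4, 10), c(50, 10)), "3 defined")
  expect_error(decay_fit(T, c(-1, 5, 2, 1)), "positive")
  # undefined thresholds are dropped before the count check
  expect_error(decay_fit(c(4, 10, 15, 20), c(NA, NA, 5, 2)), "3 defined")
})

test_that("original-scale NLS differs from log-linear OLS as documented", {
  T <- c(4, 10, 15, 20)
  tau <- c(57, 12.01, 3.82, 1.98)
  fit <- decay_fit(T, tau)
  ll <- unname(coef(lm(log(tau) ~ T))[2])
  expect_lt(fit$k, -0.25)       # original-scale estimate
  expect_gt(ll, -0.22)          # log-linear is visibly flatter
})
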