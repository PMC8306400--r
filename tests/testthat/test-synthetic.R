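test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 123)
  s1 <- simulate_concentrations(cfg)
  s2 <- simulate_concentrations(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_concentrations(sim_config(seed = 124))
  expect_false(identical(s1$concentration_M, s3$concentration_M))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(seed = "a"), "seed")
  expect_error(sim_config(seed = 1.5), "seed")
  expect_error(sim_config(temperatures = c(10, 4, 15, 20)), "increasing")
  expect_error(sim_config(noise_cv = -0.1), "variation")
  expect_error(sim_config(lag_decay = 0.1), "negative")
  expect_error(sim_config(rate_q10 = 0), "rate_q10")
})

test_that("noiseless citric trajectories are exactly linear with the configured rate", {
  cfg <- noiseless_config(seed = 1)
  s <- simulate_concentrations(cfg)
  for (T in cfg$temperatures) {
    d <- s[s$metabolite == "citric" & s$temperature_C == T, ]
    fit <- lm(concentration_M ~ storage_time_d, d)
    expect_lt(max(abs(resid(fit))), 1e-15)
    r_true <- -arrhenius_rate(T, cfg$citric_rate_ref, cfg$citric_Ea,
                              cfg$citric_ref_temp)
    expect_equal(unname(coef(fit)[2]), r_true, tolerance = 1e-10)
  }
})

test_that("worked linear-law example: 0.06 mM/d from 10.3 mM leaves 9.7 mM at 10 d", {
  cfg <- noiseless_config(seed = 1)
  r4 <- arrhenius_rate(4, cfg$citric_rate_ref, cfg$citric_Ea, 4)
  expect_equal((10.3e-3 - r4 * 10) * 1e3, 9.7, tolerance = 1e-9)
})

test_that("lag law matches the closed form and gates the fermentation products", {
  # hand calculator: 157.3 * exp(-0.254 * 10) = 12.4057
  expect_equal(lag_time(10, 157.3, -0.254), 12.40568, tolerance = 1e-5)
  cfg <- noiseless_config(seed = 2)
  s <- simulate_concentrations(cfg)
  L10 <- lag_time(10, cfg$lag_amplitude, cfg$lag_decay)
  d <- s[s$metabolite == "ethanol" & s$temperature_C == 10, ]
  pre <- d$concentration_M[d$storage_time_d < L10]
  expect_true(all(abs(pre - cfg$baseline_means[["ethanol"]]) < 1e-18))
  post <- d[d$storage_time_d >= L10, ]
  expect_true(all(post$concentration_M > cfg$baseline_means[["ethanol"]]))
})

test_that("log lag times are exactly linear in temperature with slope k", {
  cfg <- sim_config(seed = 1)
  L <- lag_time(cfg$temperatures, cfg$lag_amplitude, cfg$lag_decay)
  fit <- lm(log(L) ~ cfg$temperatures)
  expect_equal(unname(coef(fit)[2]), cfg$lag_decay, tolerance = 1e-12)
})

test_that("negative concentrations are truncated at zero with a warning", {
  cfg <- noiseless_config(seed = 3, citric_rate_ref = 5e-3)
  expect_warning(s <- simulate_concentrations(cfg), "truncated")
  expect_true(all(s$concentration_M >= 0))
  late <- s[s$metabolite == "citric" & s$temperature_C == 4 &
              s$storage_time_d > 50, ]
  expect_true(all(late$concentration_M == 0))
})

test_that("butyric acid flag inverts its temperature response", {
  cfg <- noiseless_config(seed = 4, butyric_temp_inverted = TRUE)
  s <- simulate_concentrations(cfg)
  fold <- sapply(c(4, 20), function(T) {
    d <- s[s$metabolite == "butyric" & s$temperature_C == T, ]
    max(d$concentration_M) / min(d$concentration_M)
  })
  expect_gt(fold[1], 10)         # strong increase at 4 degC
  expect_lt(fold[2], 1 + 1e-12)  # flat at 20 degC (lag beyond study end)
})

test_that("simulated spectra obey the forward-model area identity and linearity", {
  kb <- read_knowledge_base()
  smp <- conc_table("a", "acetic", 5e-4)
  sp <- simulate_spectra(smp, kb, noise_sd = 0, ref_conc = 1e-3)[[1]]
  o <- order(sp$ppm)
  # area ratio over tight windows: (c * n_protons) / (ref_conc * 9)
  tot <- function(lo, hi) milkshelf:::trapz_between(sp$ppm[o], sp$intensity[o], lo, hi)
  ratio <- tot(1.82, 2.02) / tot(-0.1, 0.1)
  expect_equal(ratio, (5e-4 * 3) / (1e-3 * 9), tolerance = 0.01)

  sp2 <- simulate_spectra(conc_table("a", "acetic", 1e-3), kb,
                          noise_sd = 0, ref_conc = 1e-3)[[1]]
  tot2 <- milkshelf:::trapz_between(sp2$ppm[o], sp2$intensity[o], 1.82, 2.02)
  # finite windows admit ~3e-5 of constant reference-tail background
  expect_equal(tot2, 2 * tot(1.82, 2.02), tolerance = 1e-4)
  expect_equal(milkshelf:::trapz_between(sp2$ppm[o], sp2$intensity[o], -0.1, 0.1),
               tot(-0.1, 0.1), tolerance = 1e-4)
})

test_that("spectrum integral equals the sum of multiplet areas up to tail truncation", {
  kb <- read_knowledge_base()
  smp <- rbind(conc_table("a", "acetic", 2e-4), conc_table("a", "lactic", 1e-4))
  sp <- simulate_spectra(smp, kb, noise_sd = 0, ref_conc = 1e-3)[[1]]
  o <- order(sp$ppm)
  total <- milkshelf:::trapz_between(sp$ppm[o], sp$intensity[o], -0.3, 9)
  expected <- 2e-4 * 3 + 1e-4 * 3 + 1e-3 * 9
  expect_equal(total, expected, tolerance = 0.01)  # Lorentzian tails leak ~0.1%
})

test_that("missing knowledge-base entries are rejected by name", {
  kb <- read_knowledge_base()
  expect_error(simulate_spectra(conc_table("a", "caffeine", 1e-4), kb),
               "caffeine")
})

test_that("concentration tables round-trip through CSV", {
  s <- simulate_concentrations(sim_config(seed = 9, n_batches = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_concentrations(s, f)
  s2 <- read_concentrations(f)
  expect_equal(s2$concentration_M, s$concentration_M, tolerance = 1e-12)
  expect_identical(s2$sample_id, s$sample_id)
  expect_error(read_concentrations(withr::local_tempfile(lines = "a,b\n1,2")),
               "missing column")
})
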