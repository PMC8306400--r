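test_that("spectrum constructor validates its axis", {
  expect_error(nmr_spectrum(c(1, 2, 2), c(0, 0, 0)), "monotone")
  expect_error(nmr_spectrum(c(1, 2), c(0, 0, 0)), "length")
  expect_error(nmr_spectrum(c(1, 2), c(0, NA)), "finite")
  sp <- nmr_spectrum(3:1, c(0, 1, 0), "x")   # descending is fine
  expect_s3_class(sp, "nmr_spectrum")
})

test_that("binning a flat spectrum gives uniform bins", {
  sp <- nmr_spectrum(seq(0, 1, by = 1e-3), rep(1, 1001))
  b <- bin_spectrum(sp, width = 0.01, range = c(0, 1), exclusions = list())
  expect_length(b, 100)
  expect_equal(unname(b), rep(0.01, 100), tolerance = 1e-12)
})

test_that("a narrow peak lands entirely in its own bin", {
  x <- seq(0, 1, by = 1e-4)
  y <- dnorm(x, 0.505, 5e-4)   # essentially inside [0.50, 0.51)
  b <- bin_spectrum(nmr_spectrum(x, y), width = 0.01, range = c(0, 1),
                    exclusions = list())
  expect_equal(unname(b[names(b) == "0.505"]), 1, tolerance = 1e-4)
  expect_lt(max(b[names(b) != "0.505"]), 1e-6)
})

test_that("bin sums conserve the direct quadrature integral", {
  set.seed(42)
  x <- seq(-0.2, 9.3, by = 7e-4)
  y <- abs(rnorm(length(x))) + sin(x * 3)^2
  sp <- nmr_spectrum(x, y)
  b <- bin_spectrum(sp, width = 0.01, range = c(0, 9), exclusions = list())
  direct <- milkshelf:::trapz_between(x, y, 0, 9)
  expect_equal(sum(b), direct, tolerance = 1e-9)
})

test_that("binning is linear and honors exclusion windows", {
  x <- seq(0, 2, by = 1e-3)
  s1 <- nmr_spectrum(x, sin(x)^2)
  s2 <- nmr_spectrum(x, cos(3 * x) + 2)
  comb <- nmr_spectrum(x, 2.5 * s1$intensity + s2$intensity)
  args <- list(width = 0.01, range = c(0, 2), exclusions = list())
  b <- do.call(bin_spectrum, c(list(comb), args))
  b12 <- 2.5 * do.call(bin_spectrum, c(list(s1), args)) +
    do.call(bin_spectrum, c(list(s2), args))
  expect_equal(b, b12, tolerance = 1e-12)

  bx <- bin_spectrum(comb, width = 0.01, range = c(0, 2),
                     exclusions = list(c(0.5, 0.6)))
  centers <- as.numeric(names(bx))
  expect_true(all(bx[centers > 0.5 & centers < 0.6] == 0))
  expect_equal(bx[centers < 0.49], b[centers < 0.49], tolerance = 1e-12)
})

test_that("binning rejects a range outside the axis", {
  sp <- nmr_spectrum(seq(0, 1, by = 0.01), rep(1, 101))
  expect_error(bin_spectrum(sp, range = c(5, 6)), "overlap")
})

test_that("trapezoid quadrature of a Lorentzian matches its closed form", {
  # closed form: fraction of unit area within +/- X of center is
  # (2/pi) * atan(2X / w)
  w <- 1 / 850
  x <- seq(-2, 2, by = 2e-5)
  y <- milkshelf:::lorentz_multiplet(x, 0, 1, w, "s", NA, 850)
  for (X in c(0.05, 0.5, 1.5)) {
    expect_equal(milkshelf:::trapz_between(x, y, -X, X),
                 2 / pi * atan(2 * X / w), tolerance = 1e-6)
  }
})

test_that("a noiseless singlet is quantified to 1e-6 relative", {
  kb <- read_knowledge_base()
  truth <- 4.2e-4
  sp <- simulate_spectra(conc_table("a", "acetic", truth), kb,
                         noise_sd = 0, ref_conc = 1e-3)[[1]]
  q <- quantify(sp, kb[kb$metabolite == "acetic", ], ref_conc = 1e-3)
  expect_identical(q$flag, "ok")
  expect_equal(q$concentration_M, truth, tolerance = 1e-6)
})

test_that("a noiseless doublet is quantified to 1e-6 relative", {
  kb <- read_knowledge_base()
  truth <- 2.7e-4
  sp <- simulate_spectra(conc_table("a", "lactic", truth), kb,
                         noise_sd = 0, ref_conc = 1e-3)[[1]]
  q <- quantify(sp, kb[kb$metabolite == "lactic", ], ref_conc = 1e-3)
  expect_equal(q$concentration_M, truth, tolerance = 1e-6)
})

test_that("an absent metabolite is never reported with negative concentration", {
  kb <- read_knowledge_base()
  # only the reference peak: every metabolite window holds baseline zeros
  sp <- simulate_spectra(conc_table("a", "acetic", 0), kb,
                         noise_sd = 0, ref_conc = 1e-3)[[1]]
  q <- quantify(sp, kb, ref_conc = 1e-3)
  expect_true(all(q$flag == "rejected" |
                    (!is.na(q$concentration_M) & q$concentration_M >= 0)))
  expect_true(all(is.na(q$concentration_M) | q$concentration_M >= 0))
})

test_that("quantification is invariant to overall spectrum scale", {
  kb <- read_knowledge_base()
  smp <- rbind(conc_table("a", "acetic", 3e-4), conc_table("a", "ethanol", 1e-4))
  sp <- simulate_spectra(smp, kb, noise_sd = 0, ref_conc = 1e-3)[[1]]
  spx <- nmr_spectrum(sp$ppm, sp$intensity * 37.4, sp$sample_id)
  q1 <- quantify(sp, kb, ref_conc = 1e-3)
  q2 <- quantify(spx, kb, ref_conc = 1e-3)
  ok <- q1$flag == "ok"
  expect_equal(q2$concentration_M[ok], q1$concentration_M[ok],
               tolerance = 1e-8)
})

test_that("a missing reference peak aborts the sample", {
  kb <- read_knowledge_base()
  x <- seq(-0.3, 9, by = 5e-4)
  sp <- nmr_spectrum(x, rep(0, length(x)), "empty")
  expect_error(quantify(sp, kb), "reference")
})

test_that("rejected fits carry a reason and calibration scales concentrations", {
  kb <- read_knowledge_base()
  sp <- simulate_spectra(conc_table("a", "acetic", 3e-4), kb,
                         noise_sd = 0, ref_conc = 1e-3)[[1]]
  q <- quantify(sp, kb[kb$metabolite == "formic", ], ref_conc = 1e-3)
  expect_identical(q$flag, "rejected")
  expect_gt(nchar(q$reason), 0)
  kb2 <- kb[kb$metabolite == "acetic", ]
  kb2$calib <- 2
  q2 <- quantify(sp, kb2, ref_conc = 1e-3)
  expect_equal(q2$concentration_M, 2 * 3e-4, tolerance = 1e-5)
})

test_that("spectrum TSV round-trips and the knowledge base is validated", {
  sp <- nmr_spectrum(seq(2, 0, by = -0.01), sin(seq(2, 0, by = -0.01)) + 1, "s1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, f)
  sp2 <- read_spectrum(f, sample_id = "s1")
  expect_equal(sp2$ppm, sp$ppm)
  expect_equal(sp2$intensity, sp$intensity, tolerance = 1e-12)

  bad <- withr::local_tempfile(
    lines = c("metabolite,shift_ppm,protons,pattern,J_Hz,calib,window_ppm",
              "x,1.0,0,s,,1.0,0.05"))
  expect_error(read_knowledge_base(bad), "proton")
  bad2 <- withr::local_tempfile(
    lines = c("metabolite,shift_ppm,protons,pattern,J_Hz,calib,window_ppm",
              "x,1.0,3,d,,1.0,0.05"))
  expect_error(read_knowledge_base(bad2), "coupling")
})
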