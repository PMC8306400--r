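#' NMR spectrum object
#'
#' A processed 1D spectrum: a strictly monotone ppm axis with matching
#' intensities. Stored as given (conventionally descending ppm); operations
#' reorder internally as needed.
#'
#' @param ppm chemical shift axis, ppm, strictly monotone.
#' @param intensity intensities, same length, finite.
#' @param sample_id identifier string.
#' @return an `nmr_spectrum` list.
#' @export
nmr_spectrum <- function(ppm, intensity, sample_id = "") {
  if (length(ppm) != length(intensity))
    stop("ppm and intensity must have the same length")
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0)))
    stop("ppm axis must be strictly monotone")
  if (!all(is.finite(ppm)) || !all(is.finite(intensity)))
    stop("spectrum values must be finite")
  structure(list(ppm = ppm, intensity = intensity, sample_id = sample_id),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum '%s': %d points, %.3f..%.3f ppm>\n",
              x$sample_id, length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Read / write a two-column spectrum file
#'
#' Plain TSV, columns ppm and intensity (header optional on read; written
#' with header, ppm descending).
#'
#' @param path file path.
#' @param sample_id identifier to attach; defaults to the file name.
#' @export
read_spectrum <- function(path, sample_id = sub("\\.[^.]*$", "", basename(path))) {
  first <- readLines(path, n = 1)
  header <- grepl("[A-Za-z]", first)
  d <- if (header) utils::read.table(path, header = TRUE, sep = "\t")
  else utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("ppm", "intensity"))
  nmr_spectrum(d[[1]], d[[2]], sample_id = sample_id)
}

#' @rdname read_spectrum
#' @param spec an `nmr_spectrum`.
#' @export
write_spectrum <- function(spec, path) {
  o <- order(spec$ppm, decreasing = TRUE)
  utils::write.table(
    data.frame(ppm = spec$ppm[o], intensity = spec$intensity[o]),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Relative line positions (ppm) and weights (summing to 1) of a multiplicity
# pattern. J in Hz, converted with the spectrometer frequency.
pattern_lines <- function(pattern, J_Hz, field) {
  j <- if (is.na(J_Hz[1]) || pattern == "s") 0 else J_Hz[1] / field
  switch(pattern,
    s  = list(off = 0, w = 1),
    d  = list(off = c(-j, j) / 2, w = c(1, 1) / 2),
    t  = list(off = c(-j, 0, j), w = c(1, 2, 1) / 4),
    q  = list(off = c(-1.5, -0.5, 0.5, 1.5) * j, w = c(1, 3, 3, 1) / 8),
    dd = {
      if (length(J_Hz) < 2 || is.na(J_Hz[2]))
        stop("'dd' pattern needs two coupling constants")
      j2 <- J_Hz[2] / field
      list(off = c(-j - j2, -j + j2, j - j2, j + j2) / 2, w = rep(1, 4) / 4)
    },
    stop("unknown multiplicity pattern: ", pattern)
  )
}

# Sum of Lorentzian lines of a multiplet: total area `area`, FWHM w_ppm.
lorentz_multiplet <- function(ppm, center, area, w_ppm, pattern, J_Hz, field) {
  li <- pattern_lines(pattern, J_Hz, field)
  hw <- w_ppm / 2
  y <- numeric(length(ppm))
  for (k in seq_along(li$off)) {
    a <- area * li$w[k]
    y <- y + a * hw / pi / ((ppm - (center + li$off[k]))^2 + hw^2)
  }
  y
}

#' Read a quantification knowledge base
#'
#' One row per multiplet: metabolite name, chemical shift (ppm), number of
#' contributing protons, multiplicity pattern (s/d/t/q/dd), coupling
#' constant(s) in Hz (second value after a semicolon for dd), calibration
#' factor, and the ppm half-window searched when fitting.
#'
#' @param path CSV path; default: the knowledge base shipped with the
#'   package (common milk metabolite multiplets, calibration factors 1.0).
#' @return data.frame with columns `metabolite`, `shift_ppm`, `protons`,
#'   `pattern`, `J_Hz`, `J2_Hz`, `calib`, `window_ppm`.
#' @export
read_knowledge_base <- function(path = system.file("extdata",
                                                   "knowledge_base.csv",
                                                   package = "milkshelf")) {
  kb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "shift_ppm", "protons", "pattern", "J_Hz", "calib",
            "window_ppm")
  miss <- setdiff(need, names(kb))
  if (length(miss) > 0)
    stop("knowledge base missing column(s): ", paste(miss, collapse = ", "))
  if (!("J2_Hz" %in% names(kb))) kb$J2_Hz <- NA_real_
  if (any(kb$protons < 1)) stop("proton counts must be >= 1")
  if (any(kb$calib <= 0)) stop("calibration factors must be > 0")
  ns <- kb$pattern != "s"
  if (any(ns & (is.na(kb$J_Hz) | kb$J_Hz <= 0)))
    stop("non-singlet multiplets need a positive coupling constant")
  kb
}

#' Bin a spectrum into fixed-width integrals
#'
#' Integrates the intensity over contiguous half-open bins
#' `[edge, edge + width)` by trapezoidal quadrature, the unit feature of
#' untargeted screening. Bins overlapping an exclusion interval (water,
#' reference) are zeroed.
#'
#' @param spec an `nmr_spectrum`.
#' @param width bin width, ppm (default 0.01).
#' @param range two-element ppm interval to bin; must overlap the axis.
#' @param exclusions list of two-element ppm intervals to zero out.
#' @return named numeric vector of bin integrals; names are bin centers. The
#'   number of bins is `ceiling(diff(range)/width)`.
#' @export
bin_spectrum <- function(spec, width = 0.01, range = c(0.5, 9.0),
                         exclusions = list(c(4.7, 4.9), c(-0.05, 0.05))) {
  stopifnot(width > 0, length(range) == 2, range[2] > range[1])
  o <- order(spec$ppm)
  x <- spec$ppm[o]; y <- spec$intensity[o]
  if (range[1] >= max(x) || range[2] <= min(x))
    stop("binning range does not overlap the spectrum axis")
  nbin <- ceiling((range[2] - range[1]) / width)
  edges <- range[1] + width * (0:nbin)
  Fc <- cumtrapz(x, y)
  f <- stats::approxfun(x, Fc, rule = 2)
  vals <- diff(f(edges))
  centers <- edges[-length(edges)] + width / 2
  for (ex in exclusions) {
    hit <- edges[-length(edges)] < ex[2] & edges[-1] > ex[1]
    vals[hit] <- 0
  }
  names(vals) <- sprintf("%.3f", centers)
  vals
}

#' Build a samples-by-bins matrix from spectra
#'
#' @param spectra list of `nmr_spectrum` objects.
#' @inheritParams bin_spectrum
#' @param normalize divide each row by its total integral (constant-sum
#'   normalization), removing overall intensity differences.
#' @return a `bin_matrix`: list with `values` (samples x bins),
#'   `bin_centers`, `sample_ids`, `width`.
#' @export
bin_matrix <- function(spectra, width = 0.01, range = c(0.5, 9.0),
                       exclusions = list(c(4.7, 4.9), c(-0.05, 0.05)),
                       normalize = FALSE) {
  rows <- lapply(spectra, bin_spectrum, width = width, range = range,
                 exclusions = exclusions)
  values <- do.call(rbind, rows)
  if (normalize) {
    tot <- rowSums(values)
    if (any(tot == 0)) stop("cannot normalize a zero-integral spectrum")
    values <- values / tot
  }
  centers <- as.numeric(colnames(values))
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  rownames(values) <- ids
  structure(list(values = values, bin_centers = centers, sample_ids = ids,
                 width = width),
            class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("<bin_matrix: %d samples x %d bins (width %.3g ppm)>\n",
              nrow(x$values), ncol(x$values), x$width))
  invisible(x)
}

# Least-squares fit of one pattern-constrained Lorentzian multiplet plus a
# local constant baseline (absorbing tails of distant peaks). Area and
# baseline are profiled out analytically (the model is linear in both),
# leaving a 2-D optimization over center and log-linewidth.
fit_multiplet <- function(ppm, intensity, center0, w0, pattern, J_Hz, field,
                          window) {
  sel <- ppm >= center0 - window & ppm <= center0 + window
  if (sum(sel) < 8) stop("too few points in fitting window")
  x <- ppm[sel]; y <- intensity[sel]
  n <- length(y); sy <- sum(y)
  shape <- function(c0, w) lorentz_multiplet(x, c0, 1, w, pattern, J_Hz, field)
  prof_ab <- function(f) {
    # least squares in (area, baseline); area clamped at 0
    sf <- sum(f); sff <- sum(f * f); sfy <- sum(f * y)
    den <- n * sff - sf * sf
    a <- if (den > 0) (n * sfy - sf * sy) / den else 0
    if (a < 0) a <- 0
    b <- (sy - a * sf) / n
    c(a, b)
  }
  prof <- function(par) {
    f <- shape(par[1], exp(par[2]))
    ab <- prof_ab(f)
    sum((y - ab[1] * f - ab[2])^2)
  }
  opt <- stats::optim(c(center0, log(w0)), prof, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 4000))
  c0 <- opt$par[1]; w <- exp(opt$par[2])
  f <- shape(c0, w)
  ab <- prof_ab(f)
  resid <- y - ab[1] * f - ab[2]
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(resid^2) / sst else 0
  list(center = c0, width = w, area = ab[1], baseline = ab[2], r2 = r2,
       converged = opt$convergence == 0)
}

#' Quantify metabolites from a spectrum using a knowledge base
#'
#' For each knowledge-base multiplet, fits center shift (within the search
#' window), a common linewidth and the amplitude of the pattern-constrained
#' Lorentzian sum by local least squares, then converts area to molar
#' concentration against the internal-standard singlet near 0 ppm:
#' `conc = (area / area_ref) * (9 / protons) * ref_conc * calib`.
#' Fits failing quality control (local R-squared below `qc_r2`, or fitted
#' shift off by more than `qc_shift` ppm) are flagged `rejected` with a
#' reason, never dropped. Metabolites with several multiplets report the
#' quality-weighted mean of the accepted multiplet estimates.
#'
#' @param spec an `nmr_spectrum`.
#' @param kb knowledge base data.frame, see [read_knowledge_base()].
#' @param ref_conc internal standard concentration, molar.
#' @param field spectrometer 1H frequency, MHz.
#' @param lw0 initial linewidth guess, Hz.
#' @param qc_r2 minimum local R-squared.
#' @param qc_shift maximum allowed |fitted - expected| shift, ppm.
#' @param ref_window half-window for the reference fit, ppm.
#' @return data.frame of class `quant_result`: `sample_id`, `metabolite`,
#'   `concentration_M`, `fit_quality`, `fitted_shift`, `flag`, `reason`.
#' @export
quantify <- function(spec, kb, ref_conc = 1e-3, field = 850, lw0 = 1.0,
                     qc_r2 = 0.8, qc_shift = 0.02, ref_window = 0.08) {
  o <- order(spec$ppm)
  x <- spec$ppm[o]; y <- spec$intensity[o]
  w0 <- lw0 / field
  ref <- tryCatch(
    fit_multiplet(x, y, 0, w0, "s", NA, field, ref_window),
    error = function(e) NULL)
  if (is.null(ref) || ref$area <= 0)
    stop("internal standard reference peak absent or has zero area in sample '",
         spec$sample_id, "'")
  out <- list()
  for (m in unique(kb$metabolite)) {
    rows <- kb[kb$metabolite == m, , drop = FALSE]
    est <- data.frame(conc = numeric(0), r2 = numeric(0), shift = numeric(0),
                      ok = logical(0), reason = character(0))
    for (j in seq_len(nrow(rows))) {
      J <- c(rows$J_Hz[j], rows$J2_Hz[j])
      fit <- tryCatch(
        fit_multiplet(x, y, rows$shift_ppm[j], w0, rows$pattern[j], J, field,
                      rows$window_ppm[j]),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        est <- rbind(est, data.frame(conc = NA, r2 = NA, shift = NA,
                                     ok = FALSE, reason = "no convergence"))
        next
      }
      conc <- (fit$area / ref$area) * (9 / rows$protons[j]) * ref_conc *
        rows$calib[j]
      bad <- c(if (fit$r2 < qc_r2) sprintf("R2 %.3f < %.2f", fit$r2, qc_r2),
               if (abs(fit$center - rows$shift_ppm[j]) > qc_shift)
                 sprintf("shift off by %.4f ppm",
                         abs(fit$center - rows$shift_ppm[j])))
      est <- rbind(est, data.frame(
        conc = conc, r2 = fit$r2, shift = fit$center,
        ok = length(bad) == 0,
        reason = if (length(bad) == 0) "" else paste(bad, collapse = "; ")))
    }
    okr <- est[est$ok, , drop = FALSE]
    if (nrow(okr) > 0) {
      wgt <- pmax(okr$r2, 0)
      if (sum(wgt) == 0) wgt <- rep(1, nrow(okr))
      out[[m]] <- data.frame(
        sample_id = spec$sample_id, metabolite = m,
        concentration_M = sum(okr$conc * wgt) / sum(wgt),
        fit_quality = max(okr$r2), fitted_shift = okr$shift[which.max(okr$r2)],
        flag = "ok", reason = "")
    } else {
      out[[m]] <- data.frame(
        sample_id = spec$sample_id, metabolite = m,
        concentration_M = NA_real_,
        fit_quality = if (all(is.na(est$r2))) NA_real_ else
          max(est$r2, na.rm = TRUE),
        fitted_shift = NA_real_, flag = "rejected",
        reason = paste(unique(est$reason), collapse = " | "))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("quant_result", "data.frame")
  res
}

#' Quantify a batch of spectra
#'
#' @param spectra list of `nmr_spectrum` objects.
#' @inheritParams quantify
#' @param ... passed to [quantify()].
#' @return row-bound `quant_result` data.frame.
#' @export
quantify_all <- function(spectra, kb, ...) {
  res <- do.call(rbind, lapply(spectra, quantify, kb = kb, ...))
  rownames(res) <- NULL
  class(res) <- c("quant_result", "data.frame")
  res
}
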