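#' Simulate a milk storage concentration experiment
#'
#' Generates a tidy table of metabolite concentrations for a multi-batch,
#' multi-temperature storage experiment. Citric acid decreases linearly in
#' time at an Arrhenius-controlled, temperature-dependent rate (truncated at
#' zero); fermentation products stay at their batch baseline during the lag
#' L(T) = A0 * exp(k * T) and grow exponentially afterwards; measurement
#' noise is multiplicative log-normal so concentrations remain positive.
#' Batch baselines are drawn once per batch (log-normal around the configured
#' means) and shared by all of that batch's samples. Actual storage days are
#' jittered around the schedule means (normal, truncated at 0). Butyric acid
#' optionally uses a mirrored temperature in the lag law, so it takes off
#' early at low temperatures and barely moves when warm.
#'
#' @param config a [sim_config()].
#' @return a data.frame of class `storage_samples` in long format with
#'   columns `sample_id`, `batch`, `temperature_C`, `storage_time_d`,
#'   `timepoint_index`, `metabolite`, `concentration_M`. Deterministic for a
#'   fixed `config$seed`.
#' @export
simulate_concentrations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mets <- names(config$baseline_means)
  ferm <- intersect(names(config$post_lag_rate), mets)

  # per-batch baselines, shared across temperatures and time points
  base <- matrix(NA_real_, config$n_batches, length(mets),
                 dimnames = list(NULL, mets))
  for (b in seq_len(config$n_batches))
    base[b, ] <- config$baseline_means *
      exp(stats::rnorm(length(mets), 0, config$baseline_batch_cv))

  tmin <- min(config$temperatures); tmax <- max(config$temperatures)
  rows <- list(); ri <- 0L; truncated <- 0L
  q10_rate <- function(r20, T)
    r20 * config$rate_q10^((T - config$rate_ref_temp) / 10)
  for (temp in config$temperatures) {
    sched <- config$schedule[[as.character(temp)]]
    lagT <- lag_time(temp, config$lag_amplitude, config$lag_decay)
    temp_mirror <- tmin + tmax - temp
    lag_inv <- lag_time(temp_mirror, config$lag_amplitude, config$lag_decay)
    r_cit <- arrhenius_rate(temp, config$citric_rate_ref, config$citric_Ea,
                            config$citric_ref_temp)
    for (ti in seq_len(nrow(sched))) {
      idx <- sched$timepoint_index[ti]
      for (b in seq_len(config$n_batches)) {
        for (bottle in seq_len(config$bottles_per_collection)) {
          t_d <- if (idx == 0) 0 else
            max(0, stats::rnorm(1, sched$mean_day[ti], sched$sd_day[ti]))
          conc <- numeric(length(mets)); names(conc) <- mets
          for (m in mets) {
            c0 <- base[b, m]
            mu <- if (m == "citric") {
              c0 - r_cit * t_d
            } else if (m %in% ferm) {
              inv <- m == "butyric" && config$butyric_temp_inverted
              L <- if (inv) lag_inv else lagT
              r <- q10_rate(config$post_lag_rate[[m]],
                            if (inv) temp_mirror else temp)
              if (t_d < L) c0 else
                c0 * min(exp(r * (t_d - L)), config$max_fold)
            } else c0
            if (mu < 0) { mu <- 0; truncated <- truncated + 1L }
            conc[m] <- mu * exp(stats::rnorm(1, 0, config$noise_cv))
          }
          ri <- ri + 1L
          rows[[ri]] <- data.frame(
            sample_id = sprintf("T%02d_tp%02d_b%d_r%d", temp, idx, b, bottle),
            batch = sprintf("B%d", b),
            temperature_C = temp,
            storage_time_d = t_d,
            timepoint_index = idx,
            metabolite = mets,
            concentration_M = unname(conc)
          )
        }
      }
    }
  }
  if (truncated > 0)
    warning(sprintf("%d concentration value(s) truncated at 0", truncated))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("storage_samples", "data.frame")
  out
}

#' Sample manifest of a simulated (or loaded) concentration table
#'
#' One row per physical sample with its design covariates; the unit of
#' observation for screening, ANOVA and the rank tests.
#'
#' @param samples long `storage_samples` data.frame.
#' @return data.frame with `sample_id`, `batch`, `temperature_C`,
#'   `storage_time_d`, `timepoint_index` (and `excluded` if present).
#' @export
sample_manifest <- function(samples) {
  keep <- intersect(
    c("sample_id", "batch", "temperature_C", "storage_time_d",
      "timepoint_index", "excluded"),
    names(samples))
  out <- unique(samples[, keep, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Wide sample-by-metabolite concentration matrix
#'
#' @param samples long `storage_samples` data.frame.
#' @return data.frame: manifest columns followed by one column per
#'   metabolite (molar).
#' @export
concentration_matrix <- function(samples) {
  man <- sample_manifest(samples)
  wide <- stats::reshape(
    as.data.frame(samples)[, c("sample_id", "metabolite", "concentration_M")],
    idvar = "sample_id", timevar = "metabolite", direction = "wide")
  names(wide) <- sub("^concentration_M\\.", "", names(wide))
  out <- merge(man, wide, by = "sample_id", sort = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read tidy concentration tables
#'
#' CSV with columns `sample_id`, `batch`, `temperature_C`, `storage_time_d`,
#' `timepoint_index`, `metabolite`, `concentration_M`.
#'
#' @param samples long `storage_samples` data.frame.
#' @param path CSV file path.
#' @export
write_concentrations <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_concentrations
#' @return `read_concentrations`: a `storage_samples` data.frame.
#' @export
read_concentrations <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "batch", "temperature_C", "storage_time_d",
            "timepoint_index", "metabolite", "concentration_M")
  miss <- setdiff(need, names(out))
  if (length(miss) > 0)
    stop("concentration table missing column(s): ", paste(miss, collapse = ", "))
  class(out) <- c("storage_samples", "data.frame")
  out
}

#' Simulate 1D 1H NMR spectra from a concentration table
#'
#' Forward model for the quantification stage: each spectrum is a sum of
#' Lorentzian multiplets, one set per knowledge-base entry, with total
#' multiplet area proportional to concentration times contributing protons,
#' plus a 9-proton internal-standard (TSP) singlet at 0.00 ppm whose area is
#' proportional to `ref_conc` * 9, plus additive Gaussian baseline noise.
#'
#' @param samples long `storage_samples` data.frame.
#' @param kb knowledge base, see [read_knowledge_base()].
#' @param lw Lorentzian full width at half maximum, Hz.
#' @param noise_sd additive baseline noise sd (intensity units).
#' @param ref_conc internal standard concentration, molar.
#' @param field spectrometer 1H frequency, MHz (converts Hz couplings to ppm).
#' @param ppm_range spectral window, ppm.
#' @param dppm axis resolution, ppm.
#' @return list of `nmr_spectrum` objects (ppm descending).
#' @export
simulate_spectra <- function(samples, kb, lw = 1.0, noise_sd = 0,
                             ref_conc = 1e-3, field = 850,
                             ppm_range = c(-0.3, 9.0), dppm = 5e-4) {
  mets <- unique(samples$metabolite)
  missing_kb <- setdiff(mets, kb$metabolite)
  if (length(missing_kb) > 0)
    stop("no knowledge base entry for metabolite(s): ",
         paste(missing_kb, collapse = ", "))
  ppm <- seq(ppm_range[1], ppm_range[2], by = dppm)
  w_ppm <- lw / field
  ids <- unique(samples$sample_id)
  lapply(ids, function(id) {
    rows <- samples[samples$sample_id == id, ]
    y <- numeric(length(ppm))
    for (i in seq_len(nrow(rows))) {
      m <- rows$metabolite[i]
      conc <- rows$concentration_M[i]
      for (j in which(kb$metabolite == m)) {
        area <- conc * kb$protons[j]
        y <- y + lorentz_multiplet(ppm, kb$shift_ppm[j], area, w_ppm,
                                   kb$pattern[j], kb$J_Hz[j], field)
      }
    }
    y <- y + lorentz_multiplet(ppm, 0, ref_conc * 9, w_ppm, "s", NA, field)
    if (noise_sd > 0) y <- y + stats::rnorm(length(ppm), 0, noise_sd)
    nmr_spectrum(rev(ppm), rev(y), sample_id = id)
  })
}
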