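#' Pipeline run configuration
#'
#' Collects every stage toggle and module parameter of a full analysis run.
#' Accepts either arguments or a JSON file (via [read_run_config()]).
#'
#' @param outdir output directory.
#' @param seed integer seed driving every stochastic stage.
#' @param concentrations optional path to a tidy concentration CSV; when
#'   given, the simulation stage is skipped and these concentrations are
#'   used.
#' @param spectra_dir optional directory of two-column TSV spectra plus a
#'   `manifest.csv`; enables the binning/screening and quantification stages
#'   on measured spectra.
#' @param stages character vector of stages to run, subset of
#'   `c("simulate", "spectra", "screen", "quantify", "anova", "kinetics")`.
#' @param sim a [sim_config()] for the simulation stage.
#' @param simulate_spectra also forward-simulate NMR spectra and run the
#'   quantification route (slower; off by default).
#' @param bin_width,q_level,alpha,transform,normalize module parameters.
#' @param ref_conc internal standard concentration, molar.
#' @param noise_sd spectral baseline noise for simulated spectra.
#' @return a `run_config` list.
#' @export
run_config <- function(outdir = "milkshelf_run", seed = 1L,
                       concentrations = NULL, spectra_dir = NULL,
                       stages = c("simulate", "screen", "anova", "kinetics"),
                       sim = sim_config(seed = seed),
                       simulate_spectra = FALSE,
                       bin_width = 0.01, q_level = 1e-4, alpha = 0.05,
                       transform = "log", normalize = TRUE,
                       ref_conc = 1e-3, noise_sd = 1e-3) {
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              concentrations = concentrations, spectra_dir = spectra_dir,
              stages = stages, sim = sim,
              simulate_spectra = isTRUE(simulate_spectra),
              bin_width = bin_width, q_level = q_level, alpha = alpha,
              transform = transform, normalize = isTRUE(normalize),
              ref_conc = ref_conc, noise_sd = noise_sd)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path JSON config path.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- raw$sim %||% list()
  if (!is.null(sim_args$schedule))
    sim_args$schedule <- lapply(sim_args$schedule, as.data.frame)
  raw$sim <- do.call(sim_config, sim_args)
  do.call(run_config, raw)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON serialization; changes iff the configuration
#' content changes.
#'
#' @param config a `run_config`.
#' @return hex string.
#' @export
config_hash <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (is.data.frame(x)) as.list(x) else unclass(x)
  }
  plain <- strip(config)
  js <- jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                         null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

stage_try <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full storage-analysis pipeline
#'
#' Executes the enabled stages in order — simulate (or load) concentrations,
#' optional spectrum simulation, binning + untargeted screening + PCA,
#' quantification, multifactor ANOVA with backward elimination, and the
#' kinetic models (linear rates + Arrhenius for citric acid, threshold times
#' + exponential decay for fermentation products) — writing each stage's
#' tables under `config$outdir` together with a run manifest (package
#' version, seed, config hash). Samples flagged `excluded` in the manifest
#' are dropped from every statistical stage. Deterministic stages are
#' byte-identical across reruns with the same config.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  log_msg <- function(...) message("[milkshelf] ", sprintf(...))

  # --- concentrations: simulate or load ----------------------------------
  if (!is.null(config$concentrations)) {
    samples <- stage_try("load", read_concentrations(config$concentrations))
    log_msg("loaded %d concentration rows", nrow(samples))
  } else if ("simulate" %in% config$stages) {
    samples <- stage_try("simulate", simulate_concentrations(config$sim))
    write_concentrations(samples, file.path(config$outdir,
                                            "concentrations.csv"))
    log_msg("simulated %d concentration rows", nrow(samples))
  } else stop("no concentration source: enable 'simulate' or supply a CSV")
  if ("excluded" %in% names(samples))
    samples <- samples[!samples$excluded, , drop = FALSE]
  out$samples <- samples
  man <- sample_manifest(samples)
  temps <- sort(unique(man$temperature_C))
  kb <- read_knowledge_base()

  # --- spectra: measured, simulated, or skipped --------------------------
  spectra <- NULL
  if (!is.null(config$spectra_dir)) {
    spectra <- stage_try("spectra", {
      sman <- utils::read.csv(file.path(config$spectra_dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
      if ("excluded" %in% names(sman))
        sman <- sman[!sman$excluded, , drop = FALSE]
      lapply(seq_len(nrow(sman)), function(i)
        read_spectrum(file.path(config$spectra_dir, sman$file[i]),
                      sample_id = sman$sample_id[i]))
    })
  } else if (config$simulate_spectra && "spectra" %in% config$stages) {
    spectra <- stage_try("spectra", {
      set.seed(config$seed + 1L)
      simulate_spectra(samples, kb, noise_sd = config$noise_sd,
                       ref_conc = config$ref_conc)
    })
    log_msg("simulated %d spectra", length(spectra))
  }

  # --- untargeted screen --------------------------------------------------
  if ("screen" %in% config$stages && !is.null(spectra)) {
    out$screen <- stage_try("screen", {
      bm <- bin_matrix(spectra, width = config$bin_width,
                       normalize = config$normalize)
      res <- do.call(rbind, lapply(temps, function(T)
        spearman_screen(bm, man, T, q_level = config$q_level)))
      utils::write.csv(res, file.path(config$outdir, "screen.csv"),
                       row.names = FALSE)
      utils::write.csv(
        do.call(rbind, lapply(split(res, res$temperature_C), volcano_table)),
        file.path(config$outdir, "volcano.csv"), row.names = FALSE)
      pca <- pca_screen(bm)
      jsonlite::write_json(
        list(explained = pca$explained[seq_len(min(5, length(pca$explained)))]),
        file.path(config$outdir, "pca.json"), auto_unbox = TRUE, digits = NA)
      res
    })
    log_msg("screened %d bins x %d temperatures",
            length(unique(out$screen$bin_center_ppm)), length(temps))
  }

  # --- targeted quantification -------------------------------------------
  if ("quantify" %in% config$stages && !is.null(spectra)) {
    out$quant <- stage_try("quantify", {
      q <- quantify_all(spectra, kb, ref_conc = config$ref_conc)
      utils::write.csv(q, file.path(config$outdir, "quant.csv"),
                       row.names = FALSE)
      q
    })
    log_msg("quantified %d spectra", length(spectra))
  }

  # --- multifactor ANOVA --------------------------------------------------
  wide <- concentration_matrix(samples)
  mets <- setdiff(names(wide), c("sample_id", "batch", "temperature_C",
                                 "storage_time_d", "timepoint_index",
                                 "excluded"))
  if ("anova" %in% config$stages) {
    out$anova <- stage_try("anova", {
      ad <- data.frame(time = wide$storage_time_d, temp = wide$temperature_C,
                       replicate = wide$batch)
      # keep only terms the design can estimate
      terms <- c("time", "temp", "replicate", "time2", "temp2", "time:temp",
                 "time:replicate", "temp:replicate")
      if (length(unique(ad$temp)) < 3)
        terms <- setdiff(terms, "temp2")
      if (length(unique(ad$time)) < 3)
        terms <- setdiff(terms, "time2")
      if (length(unique(ad$temp)) < 2)
        terms <- setdiff(terms, c("temp", "time:temp", "temp:replicate"))
      if (length(unique(ad$replicate)) < 2)
        terms <- setdiff(terms, c("replicate", "time:replicate",
                                  "temp:replicate"))
      full <- list(); elim <- list()
      for (m in mets) {
        ad$y <- wide[[m]]
        names(ad)[names(ad) == "y"] <- m
        full[[m]] <- fit_anova(ad, m, terms = terms,
                               transform = config$transform,
                               alpha = config$alpha)
        elim[[m]] <- backward_eliminate(ad, m, terms = terms,
                                        transform = config$transform,
                                        alpha = config$alpha)
        ad[[m]] <- NULL
      }
      ptab <- do.call(rbind, lapply(mets, function(m)
        cbind(metabolite = m, full[[m]]$table)))
      utils::write.csv(ptab, file.path(config$outdir, "anova_pvalues.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        lapply(elim, function(e) list(retained = e$terms, trace = e$trace)),
        file.path(config$outdir, "elimination.json"), auto_unbox = TRUE,
        digits = NA)
      list(full = full, eliminated = elim)
    })
    log_msg("fit ANOVA models for %d metabolites", length(mets))
  }

  # --- kinetics -----------------------------------------------------------
  if ("kinetics" %in% config$stages) {
    out$kinetics <- stage_try("kinetics", {
      cit <- samples[samples$metabolite == "citric", ]
      rates <- lapply(temps, function(T) {
        d <- cit[cit$temperature_C == T, ]
        linear_rate(d$storage_time_d, d$concentration_M, temperature = T)
      })
      rdf <- data.frame(
        temperature_C = temps,
        rate_M_d = vapply(rates, `[[`, numeric(1), "rate"),
        se = vapply(rates, `[[`, numeric(1), "se"),
        n = vapply(rates, `[[`, numeric(1), "n"))
      utils::write.csv(rdf, file.path(config$outdir, "rates.csv"),
                       row.names = FALSE)
      arr <- NULL
      if (length(temps) >= 3) {
        arr <- arrhenius(data.frame(temperature = rdf$temperature_C,
                                    rate = rdf$rate_M_d))
        jsonlite::write_json(
          list(Ea_kJ_mol = arr$Ea_kJ_mol, Ea_se_kJ_mol = arr$Ea_se_kJ_mol,
               ln_pre_exponential = arr$ln_pre_exponential,
               slope_K = arr$slope_K),
          file.path(config$outdir, "arrhenius.json"), auto_unbox = TRUE,
          digits = NA)
      } else log_msg("skipping Arrhenius fit: fewer than 3 temperatures")

      ferm <- setdiff(mets, "citric")
      thr <- list()
      for (m in ferm) for (T in temps) {
        d <- samples[samples$metabolite == m &
                       (samples$temperature_C == T |
                          samples$timepoint_index == 0), ]
        td <- data.frame(timepoint_index = d$timepoint_index,
                         storage_time_d = d$storage_time_d,
                         concentration = d$concentration_M)
        thr[[paste(m, T)]] <- threshold_time(td, alpha = config$alpha,
                                             metabolite = m, temperature = T)
      }
      tdf <- do.call(rbind, lapply(thr, function(x) data.frame(
        metabolite = x$metabolite, temperature_C = x$temperature,
        threshold_index = x$threshold_index, tau_d = x$tau,
        tau_sd_d = x$tau_sd, p = x$p, defined = x$defined)))
      rownames(tdf) <- NULL
      utils::write.csv(tdf, file.path(config$outdir, "thresholds.csv"),
                       row.names = FALSE)

      decays <- lapply(ferm, function(m) {
        dd <- tdf[tdf$metabolite == m & tdf$defined, ]
        if (nrow(dd) < 3) return(NULL)
        decay_fit(dd$temperature_C, dd$tau_d, metabolite = m)
      })
      decays <- Filter(Negate(is.null), decays)
      ddf <- do.call(rbind, lapply(decays, function(x) data.frame(
        metabolite = x$metabolite, A_d = x$A, k_per_C = x$k, k_se = x$k_se,
        k_ci_lo = x$k_ci[1], k_ci_hi = x$k_ci[2], n = x$n,
        fallback = x$fallback)))
      utils::write.csv(ddf, file.path(config$outdir, "decay.csv"),
                       row.names = FALSE)
      list(rates = rdf, arrhenius = arr, thresholds = tdf, decay = ddf)
    })
    log_msg("kinetics: %d thresholds defined%s",
            sum(out$kinetics$thresholds$defined),
            if (!is.null(out$kinetics$arrhenius))
              sprintf(", Ea = %.1f kJ/mol",
                      out$kinetics$arrhenius$Ea_kJ_mol) else "")
  }

  manifest <- list(
    package = "milkshelf",
    version = as.character(utils::packageVersion("milkshelf")),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = config$stages)
  jsonlite::write_json(manifest, file.path(config$outdir,
                                           "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
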