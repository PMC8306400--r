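# Build a bin_matrix directly from a values matrix (samples x bins), for
# screen-level tests that do not need spectra.
make_bin_matrix <- function(values, centers = seq_len(ncol(values)) / 100,
                            ids = sprintf("s%02d", seq_len(nrow(values)))) {
  colnames(values) <- sprintf("%.3f", centers)
  rownames(values) <- ids
  structure(list(values = values, bin_centers = centers, sample_ids = ids,
                 width = if (length(centers) > 1) diff(centers[1:2]) else 0.01),
            class = "bin_matrix")
}

# One-metabolite long concentration table (minimal storage_samples shape).
conc_table <- function(ids, metabolite, conc) {
  data.frame(sample_id = ids, metabolite = metabolite,
             concentration_M = conc)
}

noiseless_config <- function(...) {
  sim_config(noise_cv = 0, baseline_batch_cv = 0, ...)
}
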