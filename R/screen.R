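#' Untargeted Spearman screen of bins against storage time
#'
#' For one storage temperature, correlates every bin with storage time using
#' Spearman's rank correlation (average ranks for ties, p-value from the
#' t approximation), then adjusts p-values across all bins of that
#' temperature with the Benjamini-Hochberg procedure at level `q_level`.
#' Baseline (time point zero) samples are included in every temperature's
#' set, since each bottle's storage history starts at collection. Constant
#' bins have no defined correlation; they are flagged and reported as
#' non-significant rather than dropped.
#'
#' @param bins a `bin_matrix`.
#' @param manifest data.frame with `sample_id`, `temperature_C`,
#'   `storage_time_d`, `timepoint_index` (and optional logical `excluded`).
#' @param temperature storage temperature (degC) to screen.
#' @param q_level FDR level for significance calls (default 1e-4, i.e. FDR
#'   control at the 0.01% level).
#' @param include_baseline include timepoint-zero samples of every batch.
#' @return data.frame of class `screen_result`: `temperature_C`,
#'   `bin_center_ppm`, `rho`, `p`, `q`, `significant`, `direction`
#'   (increasing/decreasing/none), `flag` ("" or "constant").
#' @export
spearman_screen <- function(bins, manifest, temperature, q_level = 1e-4,
                            include_baseline = TRUE) {
  stopifnot(inherits(bins, "bin_matrix"))
  man <- manifest
  if ("excluded" %in% names(man)) man <- man[!man$excluded, , drop = FALSE]
  sel <- man$temperature_C == temperature
  if (include_baseline) sel <- sel | man$timepoint_index == 0
  ids <- intersect(man$sample_id[sel], bins$sample_ids)
  if (length(ids) < 3)
    stop("need at least 3 usable samples at ", temperature, " degC")
  rows <- match(ids, bins$sample_ids)
  tt <- man$storage_time_d[match(ids, man$sample_id)]
  V <- bins$values[rows, , drop = FALSE]
  n <- length(ids)
  rt <- avg_rank(tt)
  res <- apply(V, 2, function(v) {
    if (stats::sd(v) == 0 || stats::sd(tt) == 0) return(c(NA, NA))
    rho <- stats::cor(avg_rank(v), rt)
    if (abs(rho) >= 1) return(c(rho, 0))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    c(rho, 2 * stats::pt(-abs(tstat), n - 2))
  })
  rho <- res[1, ]; p <- res[2, ]
  q <- rep(NA_real_, length(p))
  usable <- !is.na(p)
  q[usable] <- stats::p.adjust(p[usable], method = "BH")
  sig <- !is.na(q) & q < q_level
  out <- data.frame(
    temperature_C = temperature,
    bin_center_ppm = bins$bin_centers,
    rho = rho, p = p, q = q, significant = sig,
    direction = ifelse(!sig, "none",
                       ifelse(rho > 0, "increasing", "decreasing")),
    flag = ifelse(is.na(p), "constant", "")
  )
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Volcano table of a screen result
#'
#' Effect size (Spearman rho) versus -log10 raw p per bin, the coordinates
#' of a volcano plot.
#'
#' @param res a `screen_result`.
#' @return data.frame: `bin_center_ppm`, `rho`, `neglog10_p`, `significant`,
#'   `direction`; one row per bin.
#' @export
volcano_table <- function(res) {
  stopifnot(inherits(res, "screen_result"))
  data.frame(
    bin_center_ppm = res$bin_center_ppm,
    rho = res$rho,
    neglog10_p = -log10(res$p),
    significant = res$significant,
    direction = res$direction
  )
}

#' PCA screening of a bin matrix
#'
#' Centered (optionally unit-variance scaled) principal component
#' decomposition of the samples-by-bins matrix, used to screen for dominant
#' storage effects before any supervised analysis.
#'
#' @param bins a `bin_matrix` (build with `normalize = TRUE` to remove
#'   total-intensity differences first).
#' @param scale scale bins to unit variance (constant bins are left
#'   unscaled).
#' @return `pca_summary`: list with `scores` (samples x components),
#'   `explained` (variance fractions, non-increasing, summing to 1 over the
#'   full decomposition), `sdev`, `sample_ids`.
#' @export
pca_screen <- function(bins, scale = FALSE) {
  stopifnot(inherits(bins, "bin_matrix"))
  X <- bins$values
  if (nrow(X) < 2) stop("PCA needs at least 2 samples")
  if (all(apply(X, 2, stats::sd) == 0)) stop("degenerate (constant) matrix")
  if (scale) {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    X <- sweep(X, 2, s, "/")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(scores = pc$x, explained = ev / sum(ev), sdev = pc$sdev,
                 sample_ids = bins$sample_ids),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat(sprintf("<pca_summary: %d samples, PC1 %.1f%%, PC2 %.1f%%>\n",
              nrow(x$scores), 100 * x$explained[1],
              100 * (x$explained[2] %||% 0)))
  invisible(x)
}
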