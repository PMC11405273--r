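#' Flag sample-level proteomic outliers
#'
#' Applies the standard NPX sample-QC rules: a sample is flagged when its
#' standardized first or second principal-component score lies further than
#' `sd_cutoff` standard deviations from the mean (`pc_outlier`), or when its
#' median NPX (`median_npx_outlier`) or IQR of NPX (`iqr_outlier`) across
#' assays lies more than `sd_cutoff` s.d. from the respective cohort mean.
#' The PCA is computed on standardized assays with missing cells mean-filled
#' (for the PCA only); zero-variance assays are dropped internally.
#'
#' @param cohort a [ProteomicCohort-class].
#' @param sd_cutoff flagging threshold in s.d. units (default 5).
#' @return A [QCReport-class]; `flagged(report)` lists one row per
#'   (sample, reason).
#' @examples
#' cohort <- simulateCohort(cohortConfig(n_samples = 100, n_assays = 20,
#'                                       n_panels = 2, causal_assays = 1L,
#'                                       beta_protein = 0,
#'                                       target_case_count = NA, seed = 2))
#' flagSampleOutliers(cohort)
#' @export
flagSampleOutliers <- function(cohort, sd_cutoff = 5) {
  stopifnot(is(cohort, "ProteomicCohort"))
  if (ncol(cohort) < 3) stop("at least 3 samples required")
  V <- t(npx(cohort))                       # samples x assays, NA = missing
  flags <- list()

  all_missing <- rowSums(!is.na(V)) == 0
  if (any(all_missing)) {
    warning("sample(s) with no observed values: ",
            paste(rownames(V)[all_missing], collapse = ", "))
    flags[[length(flags) + 1L]] <- data.frame(
      sample_id = rownames(V)[all_missing], reason = "median_npx_outlier")
  }

  zflag <- function(v) {
    z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    !is.na(z) & abs(z) > sd_cutoff
  }
  med <- apply(V, 1L, stats::median, na.rm = TRUE)
  iqr <- apply(V, 1L, stats::IQR, na.rm = TRUE)
  f <- zflag(med)
  if (any(f)) flags[[length(flags) + 1L]] <- data.frame(
    sample_id = rownames(V)[f], reason = "median_npx_outlier")
  f <- zflag(iqr)
  if (any(f)) flags[[length(flags) + 1L]] <- data.frame(
    sample_id = rownames(V)[f], reason = "iqr_outlier")

  ## PCA on standardized, mean-filled values
  mu <- colMeans(V, na.rm = TRUE)
  sd_ <- apply(V, 2L, stats::sd, na.rm = TRUE)
  keep <- !is.na(sd_) & sd_ > 0
  if (sum(keep) >= 2) {
    Z <- sweep(sweep(V[, keep, drop = FALSE], 2L, mu[keep]), 2L,
               sd_[keep], "/")
    Z[is.na(Z)] <- 0
    pcs <- stats::prcomp(Z, center = TRUE, scale. = FALSE, rank. = 2L)$x
    for (k in seq_len(min(2L, ncol(pcs)))) {
      f <- zflag(pcs[, k])
      if (any(f)) flags[[length(flags) + 1L]] <- data.frame(
        sample_id = rownames(V)[f], reason = "pc_outlier")
    }
  }

  flagged <- if (length(flags)) unique(do.call(rbind, flags))
             else data.frame(sample_id = character(), reason = character())
  rownames(flagged) <- NULL
  new("QCReport", flagged = flagged, sdCutoff = sd_cutoff)
}

#' @describeIn flagSampleOutliers flagged samples as a data.frame
#' @param report a [QCReport-class].
#' @export
flagged <- function(report) report@flagged

#' @export
#' @describeIn flagSampleOutliers report display
setMethod("show", "QCReport", function(object) {
  cat("QCReport:", nrow(object@flagged), "flag(s) at",
      object@sdCutoff, "s.d.\n")
  if (nrow(object@flagged)) print(object@flagged)
})
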