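#' Iterative random-forest imputation of missing protein values
#'
#' Fills masked NPX cells with a missForest-style loop, run separately per
#' panel (the default) with age and sex as extra predictors. Missing cells
#' are initialized with assay means; assays are visited in order of
#' ascending missingness; for each assay a random forest is grown on the
#' rows with observed values (predictors: the other assays of the panel
#' plus age and sex) and used to predict the missing rows. Trees are grown
#' on subsamples drawn without replacement. Iteration stops the first time
#' the relative sum of squared changes in the imputed values increases, and
#' the last matrix before degradation is returned. Observed cells are never
#' altered.
#'
#' Samples missing more than half of their protein values are not eligible
#' for imputation and trigger an error listing their ids, matching the
#' cohort-inclusion rule; an assay with no observed value at all is likewise
#' an error.
#'
#' @param cohort a [ProteomicCohort-class] with a nonempty missing mask.
#' @param trees_per_forest trees per forest (default 50).
#' @param max_iterations cap on missForest sweeps (default 10).
#' @param sampling without-replacement subsample fraction per tree.
#' @param per_panel impute each panel separately (default `TRUE`).
#' @param use_covariates include age and sex as predictors.
#' @param seed RNG seed; imputation is deterministic given seed and settings.
#' @return The cohort with masked cells replaced by imputed values and an
#'   all-`FALSE` mask; the original mask is kept in
#'   `metadata(x)$imputed_mask`.
#' @examples
#' cohort <- simulateCohort(cohortConfig(n_samples = 120, n_assays = 12,
#'                                       n_panels = 2, block_size = 6,
#'                                       block_rho = 0.6, causal_assays = 1L,
#'                                       beta_protein = 0,
#'                                       target_case_count = NA,
#'                                       missing_rate = 0.1, seed = 3))
#' imputed <- imputeProteins(cohort, seed = 3)
#' stopifnot(!any(missingMask(imputed)))
#' @export
imputeProteins <- function(cohort, trees_per_forest = 50L,
                           max_iterations = 10L, sampling = 0.632,
                           per_panel = TRUE, use_covariates = TRUE,
                           seed = 1L) {
  stopifnot(is(cohort, "ProteomicCohort"),
            trees_per_forest >= 1, sampling > 0, sampling <= 1)
  mask <- missingMask(cohort)
  if (!any(mask)) return(cohort)

  frac_sample <- colMeans(mask)
  bad <- names(which(frac_sample > 0.5))
  if (length(bad))
    stop("samples exceed 50% missing values: ", paste(bad, collapse = ", "))
  obs_per_assay <- rowSums(!mask)
  if (any(obs_per_assay == 0 & rowSums(mask) > 0))
    stop("assay(s) fully missing: ",
         paste(rownames(cohort)[obs_per_assay == 0], collapse = ", "))

  V <- t(SummarizedExperiment::assay(cohort, "npx"))   # samples x assays
  M <- t(mask)
  V[M] <- NA_real_
  covs <- clinicalData(cohort)
  extra <- if (use_covariates)
    data.frame(age = covs$age, sex = covs$sex) else NULL

  panels <- panelOf(cohort)
  groups <- if (per_panel) split(names(panels), panels)
            else list(all = names(panels))
  set.seed(seed)
  for (g in groups) {
    cols <- match(g, colnames(V))
    V[, cols] <- .missForestPanel(V[, cols, drop = FALSE],
                                  M[, cols, drop = FALSE], extra,
                                  trees_per_forest, max_iterations,
                                  sampling, seed)
  }

  out <- cohort
  SummarizedExperiment::assay(out, "npx") <- t(V)
  SummarizedExperiment::assay(out, "missing") <-
    matrix(FALSE, nrow(cohort), ncol(cohort), dimnames = dimnames(mask))
  S4Vectors::metadata(out)$imputed_mask <- mask
  out
}

## missForest sweep over one panel; X samples x assays with NA at masked
## cells, M the mask. Returns the last iterate before the stopping
## criterion (relative squared change) first increases.
.missForestPanel <- function(X, M, extra, ntree, max_iter, sampling, seed) {
  any_missing <- colSums(M) > 0
  if (!any(any_missing)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  filled <- X
  for (j in which(any_missing)) filled[M[, j], j] <- mu[j]

  order_j <- order(colSums(M))
  order_j <- order_j[colSums(M)[order_j] > 0]
  prev_diff <- Inf
  for (iter in seq_len(max_iter)) {
    before <- filled
    for (j in order_j) {
      pred <- filled[, -j, drop = FALSE]
      df <- if (is.null(extra)) as.data.frame(pred)
            else cbind(as.data.frame(pred), extra)
      colnames(df) <- make.names(colnames(df), unique = TRUE)
      obs <- !M[, j]
      if (ncol(df) == 0) next
      rf <- ranger::ranger(
        x = df[obs, , drop = FALSE], y = filled[obs, j],
        num.trees = ntree, replace = FALSE, sample.fraction = sampling,
        seed = seed + j + 131L * iter, num.threads = 1L)
      filled[M[, j], j] <-
        stats::predict(rf, df[M[, j], , drop = FALSE],
                       num.threads = 1L)$predictions
    }
    num <- sum((filled[M] - before[M])^2)
    den <- sum(filled[M]^2)
    diff <- if (den > 0) num / den else 0
    if (diff >= prev_diff) return(before)  # degradation: keep last iterate
    prev_diff <- diff
  }
  filled
}
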