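#' @import methods
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors metadata DataFrame
#' @useDynLib proteoRisk, .registration = TRUE
NULL

#' Configuration of a synthetic proteomic survival cohort
#'
#' A `CohortConfig` fixes every parameter of the synthetic-cohort generator:
#' cohort size, the block-correlation structure of the protein panel, the
#' sparse set of truly predictive assays and their log hazard ratios, the
#' clinical-covariate effects, the event-time law and its baseline rate,
#' administrative censoring, and missingness. Identical configurations
#' (including `seed`) produce bit-identical cohorts.
#'
#' @slot nSamples,nAssays,nPanels cohort dimensions; assays are split evenly
#'   across panels.
#' @slot blockSize number of assays per equicorrelated block within a panel;
#'   must divide the per-panel assay count.
#' @slot blockRho within-block correlation, in `[0, 1)`.
#' @slot causalAssays indices (1-based) of truly predictive assays.
#' @slot betaProtein log hazard ratio per causal assay (per 1 s.d. of NPX).
#' @slot betaClinical named log hazard ratios for `age` (per s.d.), `sex`
#'   (male vs female), `bmi` (per s.d.) and `smoking` (current vs not).
#' @slot baselineRate baseline hazard, events per person-year.
#' @slot adminCensorYears administrative censoring time (years; default 10).
#' @slot targetCaseCount if not `NA`, `baselineRate` is recalibrated by
#'   bisection so the expected incident case count matches this target.
#' @slot missingRate fraction of cells set missing (MCAR) at generation time.
#' @slot prevalentFrac fraction of samples marked as prevalent cases.
#' @slot dropoutRate exponential dropout hazard (0 = administrative
#'   censoring only).
#' @slot eventTimeLaw `"exponential"` or `"weibull"` proportional-hazards law.
#' @slot weibullShape shape parameter when `eventTimeLaw = "weibull"`.
#' @slot familyHistoryRate,familyHistoryAssoc marginal rate of the binary
#'   family-history flag and its association (log-odds per s.d. of the true
#'   linear predictor), making the flag an informative but non-causal proxy.
#' @slot seed integer RNG seed.
#' @seealso [cohortConfig()], [simulateCohort()]
#' @export
setClass("CohortConfig", slots = c(
  nSamples = "integer", nAssays = "integer", nPanels = "integer",
  blockSize = "integer", blockRho = "numeric",
  causalAssays = "integer", betaProtein = "numeric", betaClinical = "numeric",
  baselineRate = "numeric", adminCensorYears = "numeric",
  targetCaseCount = "integer", missingRate = "numeric",
  prevalentFrac = "numeric", dropoutRate = "numeric",
  eventTimeLaw = "character", weibullShape = "numeric",
  familyHistoryRate = "numeric", familyHistoryAssoc = "numeric",
  seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nSamples < 2L) msg <- c(msg, "nSamples must be >= 2")
  if (object@nAssays < 1L) msg <- c(msg, "nAssays must be >= 1")
  if (object@nAssays %% object@nPanels != 0L)
    msg <- c(msg, "nPanels must divide nAssays")
  else if ((object@nAssays %/% object@nPanels) %% object@blockSize != 0L)
    msg <- c(msg, "blockSize must divide the per-panel assay count")
  if (object@blockRho < 0 || object@blockRho >= 1)
    msg <- c(msg, "blockRho must lie in [0, 1)")
  if (length(object@causalAssays) &&
      (any(object@causalAssays < 1L) || any(object@causalAssays > object@nAssays)))
    msg <- c(msg, "causalAssays must be indices in 1..nAssays")
  if (length(object@betaProtein) != length(object@causalAssays))
    msg <- c(msg, "betaProtein must have one entry per causal assay")
  if (!all(c("age", "sex", "bmi", "smoking") %in% names(object@betaClinical)))
    msg <- c(msg, "betaClinical must name age, sex, bmi and smoking")
  if (object@baselineRate <= 0) msg <- c(msg, "baselineRate must be > 0")
  if (!is.na(object@targetCaseCount) &&
      object@targetCaseCount > object@nSamples)
    msg <- c(msg, "targetCaseCount exceeds nSamples")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (!object@eventTimeLaw %in% c("exponential", "weibull"))
    msg <- c(msg, "eventTimeLaw must be 'exponential' or 'weibull'")
  if (object@weibullShape <= 0) msg <- c(msg, "weibullShape must be > 0")
  if (length(msg)) msg else TRUE
})

#' Samples-by-assays proteomic cohort container
#'
#' `ProteomicCohort` extends [SummarizedExperiment::SummarizedExperiment]
#' with two assays: `"npx"`, the NPX-like log2 relative abundance matrix
#' (assays in rows, samples in columns), and `"missing"`, a logical mask of
#' the same shape. Values under the mask are preserved so imputation quality
#' can be scored against them. `rowData` carries the assay-to-panel map;
#' `colData` carries the clinical covariates (age, sex, bmi, ethnicity,
#' smoking, alcohol, family_history) and the outcome columns `time_years`,
#' `event` and `prevalent`; `metadata` carries the analysis horizon and, for
#' simulated cohorts, the [simulationTruth()] ground truth.
#'
#' @export
setClass("ProteomicCohort", contains = "SummarizedExperiment")

setValidity("ProteomicCohort", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("npx", "missing") %in% an))
    return("assays 'npx' and 'missing' are required")
  if (!"panel" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain a 'panel' column")
  cd <- SummarizedExperiment::colData(object)
  need <- c("time_years", "event", "prevalent")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, "colData must contain time_years, event and prevalent")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  m <- SummarizedExperiment::assay(object, "missing")
  v <- SummarizedExperiment::assay(object, "npx")
  if (!is.logical(m)) msg <- c(msg, "'missing' assay must be logical")
  else if (any(!is.finite(v[!m])))
    msg <- c(msg, "npx values must be finite wherever not masked missing")
  if (length(msg)) msg else TRUE
})

#' Sample-level quality-control report
#'
#' @slot flagged data.frame with columns `sample_id` and `reason`
#'   (one of `pc_outlier`, `median_npx_outlier`, `iqr_outlier`).
#' @slot sdCutoff the threshold used, in s.d. units.
#' @export
setClass("QCReport",
         slots = c(flagged = "data.frame", sdCutoff = "numeric"))

setValidity("QCReport", function(object) {
  ok <- c("pc_outlier", "median_npx_outlier", "iqr_outlier")
  if (!all(c("sample_id", "reason") %in% colnames(object@flagged)))
    return("flagged must have sample_id and reason columns")
  if (nrow(object@flagged) && !all(object@flagged$reason %in% ok))
    return("unknown flag reason")
  TRUE
})

#' Case-stratified split of a cohort into analysis stages
#'
#' Holds disjoint, exhaustive sample-id sets for feature selection, model
#' optimization and validation. With more than 800 incident cases the rule
#' is a 50/25/25 three-way split; otherwise a 70/30 two-way split where the
#' 70% part serves both selection and optimization.
#'
#' @slot rule `"three_way"` or `"two_way"`.
#' @slot selection,optimization,validation character vectors of sample ids;
#'   under `two_way`, `selection` and `optimization` are identical.
#' @export
setClass("SplitScheme", slots = c(
  rule = "character", selection = "character",
  optimization = "character", validation = "character"))

setValidity("SplitScheme", function(object) {
  if (!object@rule %in% c("three_way", "two_way"))
    return("rule must be 'three_way' or 'two_way'")
  if (object@rule == "three_way" &&
      length(intersect(object@selection, object@optimization)))
    return("three_way selection and optimization sets must be disjoint")
  if (length(intersect(object@validation,
                       union(object@selection, object@optimization))))
    return("validation set must be disjoint from training stages")
  TRUE
})

#' Aggregated stability-selection scores
#'
#' Per-assay selection scores accumulated over subsampled L1 fits: the score
#' is the sum of `|beta|` at the cross-validation-optimal penalty over all
#' iterations, and `times_selected` counts iterations with a nonzero
#' coefficient.
#'
#' @slot scores data.frame with `assay_id`, `score`, `times_selected`.
#' @slot nIterations number of subsample iterations aggregated.
#' @slot settings list of the selection settings used.
#' @export
setClass("SelectionScores", slots = c(
  scores = "data.frame", nIterations = "integer", settings = "list"))

setValidity("SelectionScores", function(object) {
  s <- object@scores
  if (!all(c("assay_id", "score", "times_selected") %in% colnames(s)))
    return("scores must have assay_id, score and times_selected")
  if (any(s$score < 0)) return("scores must be non-negative")
  if (any(s$times_selected > object@nIterations))
    return("times_selected cannot exceed nIterations")
  if (any(s$score == 0 & s$times_selected > 0))
    return("zero score implies zero times_selected")
  TRUE
})

#' A fitted (optionally penalized) Cox risk model
#'
#' Stores everything needed to reproduce predictions on new data: the
#' feature set, the penalized-Cox log hazard ratios on the standardized
#' scale, the tuned penalty, the per-feature standardization applied at fit
#' time, and the Breslow cumulative baseline hazard at the analysis horizon
#' (used to map linear predictors to absolute risks).
#'
#' @slot featureNames features, in coefficient order.
#' @slot beta log hazard ratios (standardized-feature scale).
#' @slot lambdaOpt tuned L1 penalty (0 when unpenalized).
#' @slot center,scale per-feature standardization parameters.
#' @slot penalized logical per feature: whether the L1 penalty applied.
#' @slot baselineCumHaz Breslow cumulative baseline hazard at the horizon.
#' @slot horizonYears analysis horizon in years.
#' @export
setClass("FittedRiskModel", slots = c(
  featureNames = "character", beta = "numeric", lambdaOpt = "numeric",
  center = "numeric", scale = "numeric", penalized = "logical",
  baselineCumHaz = "numeric", horizonYears = "numeric"))

setValidity("FittedRiskModel", function(object) {
  p <- length(object@featureNames)
  if (length(object@beta) != p || length(object@center) != p ||
      length(object@scale) != p || length(object@penalized) != p)
    return("beta, center, scale and penalized must match featureNames")
  if (object@baselineCumHaz < 0) return("baselineCumHaz must be >= 0")
  TRUE
})

#' Suite of benchmark and protein-augmented risk models
#'
#' The model family compared throughout: the clinical benchmark, the
#' clinical model augmented with the top 20/10/5 selected proteins, and the
#' top-5 proteins alone. All members share the training split and horizon.
#' `bestProteinModel` names the augmented member with the highest
#' validation-set C-index.
#'
#' @slot models named list of [FittedRiskModel-class] objects.
#' @slot validationC named numeric: validation C-index per member.
#' @slot bestProteinModel name of the retained protein signature model.
#' @slot horizonYears shared analysis horizon.
#' @export
setClass("ModelSuite", slots = c(
  models = "list", validationC = "numeric",
  bestProteinModel = "character", horizonYears = "numeric"))

#' Bootstrap distribution of Harrell's C
#' @slot cMean mean of the bootstrap distribution.
#' @slot cDist the B bootstrap C values.
#' @slot B number of bootstrap resamples.
#' @slot seed RNG seed used.
#' @export
setClass("BootstrapCResult", slots = c(
  cMean = "numeric", cDist = "numeric", B = "integer", seed = "integer"))

setValidity("BootstrapCResult", function(object) {
  if (length(object@cDist) != object@B)
    return("cDist must hold B values")
  if (any(object@cDist < 0 | object@cDist > 1, na.rm = TRUE))
    return("C values must lie in [0, 1]")
  TRUE
})

#' Paired-bootstrap C-index difference
#' @slot deltaMean mean of the per-replicate C differences (new - old).
#' @slot ciLow,ciHigh empirical 2.5th / 97.5th percentiles.
#' @slot significant `TRUE` iff the 95% CI excludes zero.
#' @export
setClass("DeltaCResult", slots = c(
  deltaMean = "numeric", ciLow = "numeric", ciHigh = "numeric",
  significant = "logical"))

setValidity("DeltaCResult", function(object) {
  want <- object@ciLow > 0 || object@ciHigh < 0
  if (!identical(object@significant, want))
    return("significant must equal 'CI excludes zero'")
  TRUE
})

#' Screening-curve table (detection rate vs false-positive rate)
#'
#' One row per target FPR: the score threshold (a control-score quantile),
#' the 2x2 confusion counts at that threshold, and the realized `fpr`, the
#' detection rate `dr = TP / (TP + FN)` and likelihood ratio `lr = dr / fpr`.
#'
#' @slot table data.frame with columns `fpr_target`, `threshold`, `TP`,
#'   `FP`, `TN`, `FN`, `fpr`, `dr`, `lr`.
#' @slot horizonYears horizon defining case/control status.
#' @export
setClass("ScreeningCurve",
         slots = c(table = "data.frame", horizonYears = "numeric"))

setValidity("ScreeningCurve", function(object) {
  tb <- object@table
  need <- c("fpr_target", "threshold", "TP", "FP", "TN", "FN",
            "fpr", "dr", "lr")
  if (!all(need %in% colnames(tb))) return("missing screening-curve columns")
  TRUE
})

#' Reclassification metrics between two risk models
#' @slot cnri category-free net reclassification improvement (in [-2, 2]).
#' @slot margin risk-difference margin for up/down movement (default 0.15).
#' @slot idi integrated discrimination improvement (in [-1, 1]).
#' @slot counts named integer vector of up/down movements by case status.
#' @slot horizonYears horizon defining case/control status.
#' @export
setClass("ReclassResult", slots = c(
  cnri = "numeric", margin = "numeric", idi = "numeric",
  counts = "integer", horizonYears = "numeric"))

setValidity("ReclassResult", function(object) {
  if (isTRUE(abs(object@cnri) > 2 + 1e-12))
    return("cnri must lie in [-2, 2]")
  if (isTRUE(abs(object@idi) > 1 + 1e-12))
    return("idi must lie in [-1, 1]")
  TRUE
})
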