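## Breslow cumulative baseline hazard at `horizon` from the training set.
.breslowCumHaz <- function(time, event, lp, horizon) {
  risk <- exp(lp)
  dt <- sort(unique(time[event == 1 & time <= horizon]))
  if (!length(dt)) return(0)
  sum(vapply(dt, function(t)
    sum(event == 1 & time == t) / sum(risk[time >= t]), numeric(1)))
}

## Standardize columns; constant columns get scale 1 (coefficient 0).
.standardize <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(X = sweep(sweep(X, 2L, ctr), 2L, scl, "/"), center = ctr, scale = scl)
}

#' Fit an L1-penalized Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood minus an L1 penalty applied to the
#' features flagged in `penalized`, with the penalty tuned over a
#' log-spaced grid by k-fold cross-validated partial-likelihood deviance.
#' Features are standardized internally and the standardization stored with
#' the model; tied event times use the Breslow approximation, and the
#' Breslow cumulative baseline hazard at the analysis horizon is stored so
#' absolute risks can be predicted. When no coefficient is penalized (or
#' the grid is exactly `0`) the fit reduces to an unpenalized Cox model.
#'
#' @param features numeric matrix, samples in rows, named columns.
#' @param time,event follow-up time (years) and event indicator.
#' @param cv_folds folds for penalty tuning (default 5).
#' @param lambda_grid penalty grid; `NULL` (default) derives a 50-value
#'   log-spaced grid from the data. A single `0` requests an unpenalized
#'   fit.
#' @param penalized logical per feature: whether the L1 penalty applies
#'   (clinical covariates are conventionally unpenalized).
#' @param horizon_years horizon at which the baseline hazard is stored.
#' @param seed RNG seed for fold assignment.
#' @return A [FittedRiskModel-class].
#' @examples
#' set.seed(1)
#' X <- cbind(x1 = rnorm(80), x2 = rnorm(80))
#' tt <- rexp(80, exp(0.7 * X[, 1]))
#' fit <- fitPenalizedCox(X, pmin(tt, 5), as.integer(tt <= 5),
#'                        horizon_years = 5, seed = 1)
#' coef(fit)
#' @export
fitPenalizedCox <- function(features, time, event, cv_folds = 5L,
                            lambda_grid = NULL,
                            penalized = rep(TRUE, ncol(features)),
                            horizon_years = max(time), seed = 1L) {
  stopifnot(is.matrix(features), !is.null(colnames(features)),
            length(time) == nrow(features),
            length(penalized) == ncol(features))
  if (sum(event) == 0) stop("no events in the training data")
  if (!is.null(lambda_grid) && length(lambda_grid) == 0)
    stop("empty lambda grid")
  if (sum(event) < cv_folds)
    stop("fewer events than cross-validation folds")
  std <- .standardize(features)
  Xs <- std$X
  unpen_only <- !any(penalized) ||
    (!is.null(lambda_grid) && length(lambda_grid) == 1L &&
       lambda_grid[1L] == 0)

  if (unpen_only) {
    fit <- survival::coxph(survival::Surv(time, event) ~ Xs,
                           ties = "breslow")
    beta <- as.numeric(stats::coef(fit))
    beta[is.na(beta)] <- 0
    lambda_opt <- 0
  } else {
    ysurv <- survival::Surv(time, event)
    pf <- as.numeric(penalized)
    if (is.null(lambda_grid)) {
      path <- glmnet::glmnet(Xs, ysurv, family = "cox", standardize = FALSE,
                             penalty.factor = pf, nlambda = 50L,
                             lambda.min.ratio = 1e-3)
      lambda_grid <- path$lambda
    }
    set.seed(seed)
    foldid <- sample(rep(seq_len(cv_folds), length.out = nrow(Xs)))
    dev <- matrix(NA_real_, cv_folds, length(lambda_grid))
    for (f in seq_len(cv_folds)) {
      tr <- foldid != f
      fold_fit <- glmnet::glmnet(Xs[tr, , drop = FALSE], ysurv[tr],
                                 family = "cox", standardize = FALSE,
                                 penalty.factor = pf, lambda = lambda_grid)
      B <- as.matrix(stats::coef(fold_fit, s = lambda_grid))
      lp_te <- Xs[!tr, , drop = FALSE] %*% B
      dev[f, ] <- vapply(seq_along(lambda_grid), function(k)
        tryCatch(glmnet::coxnet.deviance(pred = lp_te[, k], y = ysurv[!tr]),
                 error = function(e) NA_real_),
        numeric(1))
    }
    lambda_opt <- lambda_grid[which.min(colMeans(dev, na.rm = TRUE))]
    full <- glmnet::glmnet(Xs, ysurv, family = "cox", standardize = FALSE,
                           penalty.factor = pf, lambda = lambda_grid)
    beta <- as.numeric(stats::coef(full, s = lambda_opt))
  }
  lp <- as.numeric(Xs %*% beta)
  new("FittedRiskModel",
      featureNames = colnames(features), beta = beta,
      lambdaOpt = lambda_opt, center = std$center, scale = std$scale,
      penalized = as.logical(penalized),
      baselineCumHaz = .breslowCumHaz(time, event, lp, horizon_years),
      horizonYears = horizon_years)
}

#' @export
setMethod("coef", "FittedRiskModel", function(object, ...)
  stats::setNames(object@beta, object@featureNames))

#' @export
setMethod("show", "FittedRiskModel", function(object) {
  nz <- sum(object@beta != 0)
  cat(sprintf("FittedRiskModel: %d feature(s), %d nonzero | lambda = %.4g | H0(%.3gy) = %.4g\n",
              length(object@beta), nz, object@lambdaOpt,
              object@horizonYears, object@baselineCumHaz))
})

#' Predict linear predictors and absolute risks
#'
#' Applies the model's stored standardization to the supplied feature
#' matrix and returns the per-sample linear predictor `x'beta` together
#' with the absolute risk at the model horizon,
#' `1 - exp(-H0 * exp(x'beta))` with `H0` the stored Breslow cumulative
#' baseline hazard.
#'
#' @param model a [FittedRiskModel-class].
#' @param features numeric matrix containing every model feature as a
#'   named column (extra columns are ignored).
#' @return data.frame with columns `linear_predictor` and `absolute_risk`.
#' @export
predictRisk <- function(model, features) {
  stopifnot(is(model, "FittedRiskModel"), is.matrix(features))
  missing_feats <- setdiff(model@featureNames, colnames(features))
  if (length(missing_feats))
    stop("missing model feature(s): ", paste(missing_feats, collapse = ", "))
  X <- features[, model@featureNames, drop = FALSE]
  Xs <- sweep(sweep(X, 2L, model@center), 2L, model@scale, "/")
  lp <- as.numeric(Xs %*% model@beta)
  data.frame(linear_predictor = lp,
             absolute_risk = 1 - exp(-model@baselineCumHaz * exp(lp)),
             row.names = rownames(features))
}

#' Clinical covariate design matrix of a cohort
#'
#' One-hot encodes the categorical covariates (first level as reference)
#' and returns the numeric design used by the clinical benchmark model:
#' age, sex, bmi, ethnicity, smoking, alcohol and the family-history flag.
#'
#' @param cohort a [ProteomicCohort-class].
#' @return numeric matrix, samples in rows.
#' @export
clinicalDesign <- function(cohort) {
  cd <- clinicalData(cohort)
  mm <- stats::model.matrix(
    ~ age + sex + bmi + ethnicity + smoking + alcohol + family_history,
    data = cd)
  mm <- mm[, -1L, drop = FALSE]
  rownames(mm) <- rownames(cd)
  mm
}

#' Fit the benchmark and protein-augmented model suite
#'
#' Fits, on the optimization split (the combined selection/optimization set
#' under the two-way rule): the clinical benchmark; the clinical model
#' augmented with the top-20 selected proteins; sparser clinical + top-10
#' and clinical + top-5 models, where the sparser signatures are chosen by
#' [sparsifyByWeightProduct()] from the top-20 model; and the top-5
#' proteins alone without clinical covariates. Clinical covariates are
#' never penalized in augmented models. Validation C-indices are computed
#' on the held-out validation split and the best-performing protein
#' signature (highest validation C among 5/10/20) is recorded.
#'
#' @param cohort an imputed [ProteomicCohort-class].
#' @param split a [SplitScheme-class] from [makeSplits()].
#' @param scores a [SelectionScores-class] from [subsampledSelection()].
#' @param cv_folds folds for the Cox penalty tuning.
#' @param horizon_years analysis horizon (default: the cohort's).
#' @param seed RNG seed.
#' @return A [ModelSuite-class].
#' @export
fitModelSuite <- function(cohort, split, scores, cv_folds = 5L,
                          horizon_years = NULL, seed = 1L) {
  stopifnot(is(cohort, "ProteomicCohort"), is(split, "SplitScheme"),
            is(scores, "SelectionScores"))
  if (any(missingMask(cohort)))
    stop("cohort has missing values; run imputeProteins() first")
  if (is.null(horizon_years))
    horizon_years <- S4Vectors::metadata(cohort)$horizon_years
  clin <- clinicalDesign(cohort)
  prot <- t(SummarizedExperiment::assay(cohort, "npx"))
  o <- outcomeTable(cohort)
  rownames(o) <- o$sample_id
  top20 <- rankTopK(scores, 20L)

  fit_on <- function(ids, feat_names, pen) {
    X <- cbind(clin, prot)[ids, feat_names, drop = FALSE]
    fitPenalizedCox(X, o[ids, "time_years"], o[ids, "event"],
                    cv_folds = cv_folds, penalized = pen,
                    horizon_years = horizon_years, seed = seed)
  }
  opt_ids <- split@optimization
  cfeat <- colnames(clin)
  models <- list()
  models$clinical <- fit_on(opt_ids, cfeat, rep(FALSE, length(cfeat)))
  models$clinical_proteins_20 <- fit_on(
    opt_ids, c(cfeat, top20),
    c(rep(FALSE, length(cfeat)), rep(TRUE, length(top20))))
  top10 <- sparsifyByWeightProduct(models$clinical_proteins_20, scores, 10L)
  top5 <- sparsifyByWeightProduct(models$clinical_proteins_20, scores, 5L)
  models$clinical_proteins_10 <- fit_on(
    opt_ids, c(cfeat, top10),
    c(rep(FALSE, length(cfeat)), rep(TRUE, length(top10))))
  models$clinical_proteins_5 <- fit_on(
    opt_ids, c(cfeat, top5),
    c(rep(FALSE, length(cfeat)), rep(TRUE, length(top5))))
  models$proteins_only_5 <- fit_on(opt_ids, top5, rep(TRUE, length(top5)))

  val_ids <- split@validation
  Xval <- cbind(clin, prot)[val_ids, , drop = FALSE]
  vc <- vapply(models, function(m)
    harrellC(o[val_ids, "time_years"], o[val_ids, "event"],
             predictRisk(m, Xval)$linear_predictor), numeric(1))
  prot_members <- c("clinical_proteins_5", "clinical_proteins_10",
                    "clinical_proteins_20")
  best <- prot_members[which.max(vc[prot_members])]
  new("ModelSuite", models = models, validationC = vc,
      bestProteinModel = best, horizonYears = horizon_years)
}

#' @export
setMethod("show", "ModelSuite", function(object) {
  cat("ModelSuite (horizon", object@horizonYears, "years)\n")
  for (nm in names(object@models))
    cat(sprintf("  %-22s validation C = %.3f%s\n", nm,
                object@validationC[[nm]],
                if (nm == object@bestProteinModel) "  [best signature]"
                else ""))
})

#' @describeIn fitModelSuite extract one member model
#' @param suite a [ModelSuite-class].
#' @param name member name, e.g. `"clinical"` or `"clinical_proteins_5"`.
#' @export
suiteModel <- function(suite, name) {
  stopifnot(is(suite, "ModelSuite"))
  m <- suite@models[[name]]
  if (is.null(m)) stop("no model named '", name, "' in suite")
  m
}

#' Serialize a fitted risk model to JSON (and back)
#'
#' The JSON stores feature names, coefficients, the tuned penalty, the
#' standardization, the Breslow baseline and the horizon at full double
#' precision, so that a reloaded model yields bit-identical predictions —
#' the mechanism for transferring frozen weights to an external cohort.
#'
#' @param model a [FittedRiskModel-class].
#' @param path output (input) JSON file path.
#' @return `readRiskModel` returns the restored [FittedRiskModel-class].
#' @export
writeRiskModel <- function(model, path) {
  stopifnot(is(model, "FittedRiskModel"))
  jsonlite::write_json(list(
    feature_names = model@featureNames, beta = model@beta,
    lambda_opt = model@lambdaOpt, center = model@center,
    scale = model@scale, penalized = model@penalized,
    baseline_cumhaz = model@baselineCumHaz,
    horizon_years = model@horizonYears), path, digits = I(17))
  invisible(path)
}

#' @rdname writeRiskModel
#' @export
readRiskModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("FittedRiskModel",
      featureNames = j$feature_names, beta = as.numeric(j$beta),
      lambdaOpt = as.numeric(j$lambda_opt), center = as.numeric(j$center),
      scale = as.numeric(j$scale), penalized = as.logical(j$penalized),
      baselineCumHaz = as.numeric(j$baseline_cumhaz),
      horizonYears = as.numeric(j$horizon_years))
}
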