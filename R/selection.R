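#' Split a cohort into selection / optimization / validation stages
#'
#' With more than 800 incident cases the cohort is split 50/25/25 into
#' feature-selection, optimization and validation sets; otherwise 70/30,
#' where the 70% part serves both feature selection and optimization.
#' Splits are stratified by case status so each part's case fraction
#' matches the cohort's within rounding, and are deterministic given
#' `seed`. Cohorts with fewer than 80 incident cases are below the
#' inclusion floor and raise an error.
#'
#' @param x a [ProteomicCohort-class] already passed through
#'   [applyIncidenceFilters()], or its outcome data.frame.
#' @param seed RNG seed.
#' @return A [SplitScheme-class].
#' @export
makeSplits <- function(x, seed = 1L) {
  outcomes <- if (is(x, "ProteomicCohort")) outcomeTable(x) else x
  if (any(outcomes$prevalent == 1))
    stop("apply incidence filters before splitting")
  is_case <- outcomes$event == 1
  n_cases <- sum(is_case)
  if (n_cases < 80)
    stop("fewer than 80 incident cases (", n_cases,
         "): below the inclusion floor")
  rule <- if (n_cases > 800) "three_way" else "two_way"
  set.seed(seed)
  parts <- lapply(list(case = outcomes$sample_id[is_case],
                       control = outcomes$sample_id[!is_case]),
                  function(ids) {
    fr <- if (rule == "three_way") c(0.5, 0.25, 0.25) else c(0.7, 0.3)
    ids <- sample(ids)
    sizes <- floor(fr * length(ids))
    sizes[1L] <- length(ids) - sum(sizes[-1L])
    split(ids, rep(seq_along(fr), times = sizes))
  })
  grab <- function(k) sort(c(parts$case[[k]], parts$control[[k]]))
  if (rule == "three_way") {
    new("SplitScheme", rule = rule, selection = grab(1L),
        optimization = grab(2L), validation = grab(3L))
  } else {
    new("SplitScheme", rule = rule, selection = grab(1L),
        optimization = grab(1L), validation = grab(2L))
  }
}

#' @export
setMethod("show", "SplitScheme", function(object) {
  cat(sprintf("SplitScheme (%s): selection %d | optimization %d | validation %d\n",
              object@rule, length(object@selection),
              length(object@optimization), length(object@validation)))
})

#' Smoothed-bootstrap class rebalancing
#'
#' Generates a rebalanced sample in the style of random over-sampling with
#' kernel smoothing: each output row picks class 1 with probability `p`,
#' draws a seed row uniformly from that class, and adds Gaussian noise with
#' per-feature bandwidth
#' `h_j = kernel_shrink * sd_j,class * (4 / ((d + 2) * n_class))^(1 / (d + 4))`
#' where `d` is the feature count (the multivariate Silverman rule). With
#' `kernel_shrink = 0` the output rows are exact copies of input rows.
#'
#' @param features numeric matrix (rows = samples).
#' @param labels binary 0/1 vector, both classes present.
#' @param p target probability of class 1 (default 0.5).
#' @param n_out number of output rows (default `nrow(features)`).
#' @param kernel_shrink bandwidth multiplier, `>= 0`.
#' @param seed RNG seed.
#' @return list with elements `features` and `labels`.
#' @export
smoothedBootstrapRebalance <- function(features, labels, p = 0.5,
                                       n_out = nrow(features),
                                       kernel_shrink = 1, seed = 1L) {
  stopifnot(is.matrix(features), length(labels) == nrow(features),
            n_out >= 2, kernel_shrink >= 0)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  d <- ncol(features)
  set.seed(seed)
  cls_out <- stats::rbinom(n_out, 1L, p)
  out <- matrix(0, n_out, d, dimnames = list(NULL, colnames(features)))
  pooled_sd <- apply(features, 2L, stats::sd)
  for (cl in c(0L, 1L)) {
    rows <- which(labels == cl)
    take <- which(cls_out == cl)
    if (!length(take)) next
    idx <- rows[sample.int(length(rows), length(take), replace = TRUE)]
    out[take, ] <- features[idx, , drop = FALSE]
    if (kernel_shrink > 0) {
      if (length(rows) < 2L) {
        warning("class ", cl,
                " has a single member; pooled s.d. used for its bandwidth")
        sds <- pooled_sd
      } else {
        sds <- apply(features[rows, , drop = FALSE], 2L, stats::sd)
      }
      h <- kernel_shrink * sds *
        (4 / ((d + 2) * length(rows)))^(1 / (d + 4))
      noise <- matrix(stats::rnorm(length(take) * d), length(take), d)
      out[take, ] <- out[take, ] + sweep(noise, 2L, h, "*")
    }
  }
  list(features = out, labels = cls_out)
}

## 50-point log-spaced lambda grid from lambda_max (smallest penalty
## zeroing every coefficient of the standardized logistic problem).
.lambdaGrid <- function(X, y, n_lambda = 50L, min_ratio = 1e-3) {
  lmax <- max(abs(crossprod(X, y - mean(y)))) / length(y)
  lmax <- max(lmax, 1e-6)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

## Repeated k-fold CV of the binomial deviance over a fixed lambda grid.
.cvDeviance <- function(X, y, grid, cv_folds, cv_repeats) {
  dev <- matrix(0, cv_repeats * cv_folds, length(grid))
  row <- 0L
  for (r in seq_len(cv_repeats)) {
    foldid <- sample(rep(seq_len(cv_folds), length.out = length(y)))
    for (f in seq_len(cv_folds)) {
      tr <- foldid != f
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                            family = "binomial", lambda = grid,
                            standardize = FALSE, thresh = 1e-4)
      pr <- stats::predict(fit, X[!tr, , drop = FALSE], s = grid,
                           type = "response")
      pr <- pmin(pmax(pr, 1e-10), 1 - 1e-10)
      yy <- y[!tr]
      row <- row + 1L
      dev[row, ] <- colMeans(-2 * (yy * log(pr) + (1 - yy) * log(1 - pr)))
    }
  }
  colMeans(dev)
}

#' Subsampled L1 feature selection with rebalancing
#'
#' The stability-selection stage: over `n_iterations` subsamples (drawn
#' without replacement from the feature-selection split), classes are
#' rebalanced by [smoothedBootstrapRebalance()], features standardized on
#' the rebalanced subsample, the L1 penalty tuned by repeated k-fold
#' cross-validated deviance over a log-spaced grid, and the refit
#' coefficients at the optimal penalty aggregated: each assay's selection
#' score is the sum of `|beta|` across iterations, and `times_selected`
#' counts iterations with a nonzero coefficient. The default model family
#' is L1 logistic regression on the incident-within-horizon label;
#' `family = "cox"` switches to an L1 Cox fit on the (horizon-truncated)
#' survival outcome without rebalancing.
#'
#' @param cohort an imputed (no missing cells) [ProteomicCohort-class].
#' @param split a [SplitScheme-class]; its `selection` ids are used. May be
#'   `NULL` to use every sample.
#' @param n_iterations number of subsample iterations (default 200).
#' @param subsample_fraction fraction drawn per iteration, without
#'   replacement (default 0.8).
#' @param cv_folds,cv_repeats cross-validation design per iteration
#'   (defaults 5 and 3).
#' @param n_lambda,lambda_min_ratio penalty grid: `n_lambda` log-spaced
#'   values from the data-derived maximum down to `lambda_min_ratio` times
#'   it.
#' @param rebalance_p,kernel_shrink rebalancing target class probability
#'   and kernel bandwidth multiplier.
#' @param horizon_years horizon defining the binary label (default: the
#'   cohort's analysis horizon). Non-cases censored before the horizon are
#'   excluded from the selection label.
#' @param family `"binomial"` (default) or `"cox"`.
#' @param seed RNG seed; iterations are independently reproducible.
#' @return A [SelectionScores-class].
#' @export
subsampledSelection <- function(cohort, split = NULL, n_iterations = 200L,
                                subsample_fraction = 0.8, cv_folds = 5L,
                                cv_repeats = 3L, n_lambda = 50L,
                                lambda_min_ratio = 1e-3, rebalance_p = 0.5,
                                kernel_shrink = 1, horizon_years = NULL,
                                family = c("binomial", "cox"), seed = 1L) {
  family <- match.arg(family)
  stopifnot(is(cohort, "ProteomicCohort"), n_iterations >= 1)
  if (any(missingMask(cohort)))
    stop("cohort has missing values; run imputeProteins() first")
  if (is.null(horizon_years))
    horizon_years <- S4Vectors::metadata(cohort)$horizon_years
  ids <- if (is.null(split)) colnames(cohort) else split@selection
  sub <- cohort[, ids]
  X_all <- t(SummarizedExperiment::assay(sub, "npx"))
  o <- outcomeTable(sub)
  y_case <- o$event == 1 & o$time_years <= horizon_years
  is_control <- !y_case & o$time_years >= horizon_years
  keep <- y_case | is_control
  X_all <- X_all[keep, , drop = FALSE]
  y <- as.integer(y_case[keep])
  time <- o$time_years[keep]
  event <- o$event[keep]
  n <- nrow(X_all)
  m <- max(2L, floor(subsample_fraction * n))

  p <- ncol(X_all)
  score <- numeric(p)
  hits <- integer(p)
  for (it in seq_len(n_iterations)) {
    set.seed(seed + 7919L * it)
    beta <- NULL
    for (try in seq_len(20L)) {
      idx <- sample.int(n, m)
      if (sum(y[idx]) == 0L || sum(y[idx]) == length(idx)) next
      if (family == "binomial") {
        reb <- smoothedBootstrapRebalance(
          X_all[idx, , drop = FALSE], y[idx], p = rebalance_p,
          n_out = m, kernel_shrink = kernel_shrink,
          seed = seed + 7919L * it + try)
        if (length(unique(reb$labels)) < 2L) next
        Xs <- scale(reb$features)
        Xs[, attr(Xs, "scaled:scale") == 0] <- 0
        yy <- reb$labels
        grid <- .lambdaGrid(Xs, yy, n_lambda, lambda_min_ratio)
        cvm <- .cvDeviance(Xs, yy, grid, cv_folds, cv_repeats)
        lam <- grid[which.min(cvm)]
        fit <- glmnet::glmnet(Xs, yy, family = "binomial", lambda = grid,
                              standardize = FALSE, thresh = 1e-4)
        beta <- as.numeric(stats::coef(fit, s = lam))[-1L]
      } else {
        Xs <- scale(X_all[idx, , drop = FALSE])
        Xs[, attr(Xs, "scaled:scale") == 0] <- 0
        ysurv <- survival::Surv(pmin(time[idx], horizon_years),
                                as.integer(y[idx]))
        cvfit <- glmnet::cv.glmnet(Xs, ysurv, family = "cox",
                                   nfolds = cv_folds, standardize = FALSE,
                                   nlambda = n_lambda,
                                   lambda.min.ratio = lambda_min_ratio)
        beta <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
      }
      break
    }
    if (is.null(beta)) {
      warning("iteration ", it, " produced no usable subsample; skipped")
      next
    }
    score <- score + abs(beta)
    hits <- hits + as.integer(beta != 0)
  }
  new("SelectionScores",
      scores = data.frame(assay_id = colnames(X_all), score = score,
                          times_selected = hits, row.names = NULL),
      nIterations = as.integer(n_iterations),
      settings = list(family = family, subsample_fraction = subsample_fraction,
                      cv_folds = cv_folds, cv_repeats = cv_repeats,
                      rebalance_p = rebalance_p,
                      kernel_shrink = kernel_shrink,
                      horizon_years = horizon_years, seed = seed))
}

#' @rdname selectionScores
#' @param x a [SelectionScores-class].
#' @param ... unused.
#' @export
setMethod("selectionScores", "SelectionScores", function(x, ...) x@scores)

#' @export
setMethod("show", "SelectionScores", function(object) {
  s <- object@scores
  cat("SelectionScores over", object@nIterations, "iterations;",
      sum(s$score > 0), "of", nrow(s), "assays ever selected\n")
  print(utils::head(s[order(-s$score, s$assay_id), ], 5L), row.names = FALSE)
})

#' Rank assays by selection score
#'
#' Returns the `k` assays with the largest selection scores, descending,
#' ties broken by lexicographic assay id. If fewer than `k` assays have a
#' positive score, all positive-score assays are returned with a warning.
#'
#' @param scores a [SelectionScores-class].
#' @param k number of assays to return.
#' @return character vector of assay ids.
#' @export
rankTopK <- function(scores, k) {
  stopifnot(is(scores, "SelectionScores"), k >= 1)
  s <- scores@scores
  pos <- s[s$score > 0, , drop = FALSE]
  ord <- pos[order(-pos$score, pos$assay_id), , drop = FALSE]
  if (nrow(ord) < k) {
    warning("only ", nrow(ord), " assays have positive scores; returning all")
    return(ord$assay_id)
  }
  ord$assay_id[seq_len(k)]
}

#' Sparsify a fitted signature by the weight-times-score product
#'
#' To extract top-5/top-10 signatures from an optimized model on the top-20
#' features, penalized (protein) features are ranked by the product of the
#' absolute optimized model weight and the feature-selection score; the top
#' `k` are returned. Clinical covariates (unpenalized features) are never
#' ranked — they are always retained downstream.
#'
#' @param model a [FittedRiskModel-class] fit on clinical + top-k features.
#' @param scores the [SelectionScores-class] covering the protein features.
#' @param k number of features to keep (5 or 10 in the standard workflow).
#' @return character vector of the top `k` assay ids, descending product.
#' @export
sparsifyByWeightProduct <- function(model, scores, k) {
  stopifnot(is(model, "FittedRiskModel"), is(scores, "SelectionScores"),
            k >= 1)
  feats <- model@featureNames[model@penalized]
  tab <- scores@scores
  missing_feats <- setdiff(feats, tab$assay_id)
  if (length(missing_feats))
    stop("feature(s) missing from selection scores: ",
         paste(missing_feats, collapse = ", "))
  sc <- tab$score[match(feats, tab$assay_id)]
  w <- abs(model@beta[match(feats, model@featureNames)])
  prod <- w * sc
  ord <- order(-prod, feats)
  feats[ord][seq_len(min(k, length(feats)))]
}
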