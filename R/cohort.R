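#' Build a synthetic-cohort configuration
#'
#' Defaults describe the study conditions used throughout the package's
#' simulations: a cohort of 4,000 participants with 600 NPX-like assays in
#' four panels of equicorrelated 10-assay blocks (rho = 0.3), five truly
#' predictive assays with log hazard ratios spanning 0.5-1.5, modest
#' clinical effects, 10 years of follow-up under administrative censoring
#' and a baseline hazard calibrated so that about 400 incident cases are
#' expected (a rare-disease regime well above the 80-case inclusion floor).
#'
#' @param n_samples,n_assays,n_panels,block_size,block_rho cohort dimensions
#'   and correlation structure (see [CohortConfig-class]).
#' @param causal_assays indices of the truly predictive assays.
#' @param beta_protein log hazard ratios of the causal assays.
#' @param beta_clinical named log hazard ratios for age, sex, bmi, smoking.
#' @param baseline_rate baseline hazard (events per person-year); replaced
#'   by calibration when `target_case_count` is set.
#' @param admin_censor_years administrative censoring horizon.
#' @param target_case_count expected incident case count to calibrate to,
#'   or `NA` to use `baseline_rate` as given.
#' @param missing_rate MCAR missingness applied at generation time.
#' @param prevalent_frac fraction of samples marked prevalent.
#' @param dropout_rate exponential dropout hazard (0 disables dropout).
#' @param event_time_law `"exponential"` (default) or `"weibull"`.
#' @param weibull_shape Weibull shape (ignored for exponential).
#' @param family_history_rate,family_history_assoc marginal frequency of the
#'   family-history flag and its log-odds association with the true linear
#'   predictor (a non-causal risk proxy).
#' @param seed integer RNG seed.
#' @return A validated [CohortConfig-class] object.
#' @examples
#' cfg <- cohortConfig(n_samples = 500, n_assays = 40, n_panels = 2,
#'                     target_case_count = 60, causal_assays = c(3, 17),
#'                     beta_protein = c(0.8, 1.2), seed = 7)
#' @export
cohortConfig <- function(n_samples = 4000, n_assays = 600, n_panels = 4,
                         block_size = 10, block_rho = 0.3,
                         causal_assays = c(10L, 150L, 300L, 450L, 590L),
                         beta_protein = c(0.5, 0.75, 1.0, 1.25, 1.5),
                         beta_clinical = c(age = 0.35, sex = 0.25,
                                           bmi = 0.15, smoking = 0.30),
                         baseline_rate = 0.005, admin_censor_years = 10,
                         target_case_count = 400L, missing_rate = 0,
                         prevalent_frac = 0.02, dropout_rate = 0,
                         event_time_law = c("exponential", "weibull"),
                         weibull_shape = 1.2,
                         family_history_rate = 0.10,
                         family_history_assoc = 0.5,
                         seed = 1L) {
  new("CohortConfig",
      nSamples = as.integer(n_samples), nAssays = as.integer(n_assays),
      nPanels = as.integer(n_panels), blockSize = as.integer(block_size),
      blockRho = block_rho, causalAssays = as.integer(causal_assays),
      betaProtein = as.numeric(beta_protein),
      betaClinical = beta_clinical,
      baselineRate = baseline_rate,
      adminCensorYears = admin_censor_years,
      targetCaseCount = if (is.null(target_case_count) ||
                            is.na(target_case_count)) NA_integer_
                        else as.integer(target_case_count),
      missingRate = missing_rate, prevalentFrac = prevalent_frac,
      dropoutRate = dropout_rate,
      eventTimeLaw = match.arg(event_time_law),
      weibullShape = weibull_shape,
      familyHistoryRate = family_history_rate,
      familyHistoryAssoc = family_history_assoc,
      seed = as.integer(seed))
}

## Expected incident-case probability before the administrative horizon,
## per sample, at baseline rate r (closed form; exponential dropout folds
## into the exponential law only).
.expectedCaseProb <- function(r, lp, censor_years, law, shape, dropout) {
  lam <- r * exp(lp)
  if (law == "exponential") {
    if (dropout > 0)
      lam / (lam + dropout) * (1 - exp(-(lam + dropout) * censor_years))
    else 1 - exp(-lam * censor_years)
  } else {
    1 - exp(-lam * censor_years^shape)
  }
}

#' Calibrate the baseline hazard to an expected case count
#'
#' Bisection on the log baseline rate so that the expected number of
#' incident cases before the administrative horizon matches `target` to
#' within 1%. The expectation is the sum over samples of the closed-form
#' event probability under the proportional-hazards law.
#'
#' @param lp per-sample true log relative hazards.
#' @param target desired expected case count.
#' @param censor_years administrative horizon.
#' @param law,shape event-time law and Weibull shape.
#' @param dropout exponential dropout hazard.
#' @return the calibrated baseline rate (events per person-year).
#' @export
calibrateBaselineRate <- function(lp, target, censor_years = 10,
                                  law = "exponential", shape = 1.2,
                                  dropout = 0) {
  if (target > length(lp))
    stop("target case count exceeds the number of samples at risk")
  if (law == "weibull" && dropout > 0) {
    warning("dropout ignored in Weibull calibration")
    dropout <- 0
  }
  f <- function(logr)
    sum(.expectedCaseProb(exp(logr), lp, censor_years, law, shape, dropout)) -
      target
  lo <- -20; hi <- 5
  if (f(hi) < 0)
    stop("target case count unreachable at any baseline rate")
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (abs(f(mid)) <= 0.01 * target) break
  }
  exp((lo + hi) / 2)
}

#' Generate a synthetic proteomic survival cohort
#'
#' Draws a block-correlated Gaussian NPX-like matrix grouped in panels,
#' clinical covariates, and time-to-event outcomes from a proportional
#' hazards model with hazard `baseline_rate * exp(linear_predictor)`,
#' administratively censored at the configured horizon. The true sparse
#' coefficient vector and per-sample linear predictor are stored in the
#' cohort metadata for parameter-recovery checks. Fully reproducible from
#' the configuration seed.
#'
#' @param config a [CohortConfig-class] from [cohortConfig()].
#' @return A [ProteomicCohort-class]; `metadata()` holds `truth` (see
#'   [simulationTruth()]), the realized `baseline_rate` and the horizon.
#' @examples
#' cohort <- simulateCohort(cohortConfig(n_samples = 300, n_assays = 40,
#'                                       n_panels = 2, causal_assays = 5L,
#'                                       beta_protein = 1,
#'                                       target_case_count = 40, seed = 1))
#' cohort
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@nSamples
  p <- config@nAssays

  ## clinical covariates: middle-aged population-cohort marginals
  age <- pmin(pmax(stats::rnorm(n, 57, 8), 40), 70)
  sex <- stats::rbinom(n, 1L, 0.5)
  bmi <- pmin(pmax(stats::rnorm(n, 27.3, 4.6), 16), 50)
  ethnicity <- factor(sample(c("white", "asian", "black", "other"), n,
                             replace = TRUE, prob = c(.88, .06, .03, .03)),
                      levels = c("white", "asian", "black", "other"))
  smoking <- factor(sample(c("never", "former", "current"), n,
                           replace = TRUE, prob = c(.55, .35, .10)),
                    levels = c("never", "former", "current"))
  alcohol <- factor(sample(c("never", "moderate", "frequent"), n,
                           replace = TRUE, prob = c(.25, .55, .20)),
                    levels = c("never", "moderate", "frequent"))

  ## proteins: equicorrelated blocks nested in panels
  per_panel <- p %/% config@nPanels
  bs <- config@blockSize
  rho <- config@blockRho
  n_blocks <- p %/% bs
  shared <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
  X <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0) {
    for (b in seq_len(n_blocks)) {
      cols <- ((b - 1L) * bs + 1L):(b * bs)
      X[, cols] <- sqrt(rho) * shared[, b] + sqrt(1 - rho) * X[, cols]
    }
  }
  assay_ids <- sprintf("A%04d", seq_len(p))
  sample_ids <- sprintf("S%05d", seq_len(n))
  panel <- sprintf("panel_%d", ((seq_len(p) - 1L) %/% per_panel) + 1L)
  dimnames(X) <- list(sample_ids, assay_ids)

  ## true linear predictor
  bc <- config@betaClinical
  lp_clin <- bc[["age"]] * as.numeric(scale(age)) +
    bc[["sex"]] * sex +
    bc[["bmi"]] * as.numeric(scale(bmi)) +
    bc[["smoking"]] * (smoking == "current")
  beta_true <- numeric(p)
  beta_true[config@causalAssays] <- config@betaProtein
  lp <- as.numeric(X %*% beta_true) + lp_clin

  prevalent <- stats::rbinom(n, 1L, config@prevalentFrac)
  lp_z <- if (stats::sd(lp) > 0) as.numeric(scale(lp)) else numeric(n)
  fh <- stats::rbinom(n, 1L, stats::plogis(
    stats::qlogis(config@familyHistoryRate) +
      config@familyHistoryAssoc * lp_z))

  rate <- config@baselineRate
  if (!is.na(config@targetCaseCount)) {
    at_risk <- prevalent == 0L
    rate <- calibrateBaselineRate(lp[at_risk], config@targetCaseCount,
                                  config@adminCensorYears,
                                  config@eventTimeLaw, config@weibullShape,
                                  config@dropoutRate)
  }

  ## event times under the proportional-hazards law
  e_std <- stats::rexp(n)
  lam <- rate * exp(lp)
  t_event <- if (config@eventTimeLaw == "exponential") e_std / lam
             else (e_std / lam)^(1 / config@weibullShape)
  t_drop <- if (config@dropoutRate > 0) stats::rexp(n, config@dropoutRate)
            else rep(Inf, n)
  cens <- pmin(t_drop, config@adminCensorYears)
  time_years <- pmin(t_event, cens)
  event <- as.integer(t_event <= cens)
  time_years[prevalent == 1L] <- 0
  event[prevalent == 1L] <- 0L

  coldata <- S4Vectors::DataFrame(
    age = age, sex = sex, bmi = bmi, ethnicity = ethnicity,
    smoking = smoking, alcohol = alcohol, family_history = fh,
    time_years = time_years, event = event, prevalent = prevalent,
    row.names = sample_ids)
  truth <- list(beta_true = stats::setNames(beta_true, assay_ids),
                beta_clinical_true = bc,
                baseline_rate = rate,
                linear_predictor = stats::setNames(lp, sample_ids))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(npx = t(X),
                  missing = matrix(FALSE, p, n,
                                   dimnames = list(assay_ids, sample_ids))),
    rowData = S4Vectors::DataFrame(panel = panel, row.names = assay_ids),
    colData = coldata,
    metadata = list(truth = truth, baseline_rate = rate,
                    horizon_years = config@adminCensorYears,
                    config = config))
  cohort <- new("ProteomicCohort", se)
  if (config@missingRate > 0)
    cohort <- injectMissingness(cohort, config@missingRate, "MCAR",
                                seed = config@seed + 1L)
  cohort
}

#' Cohort accessors
#'
#' `npx()` returns the assays-by-samples NPX matrix with masked cells set to
#' `NA`; `npx(x, masked = FALSE)` returns the underlying complete values.
#' `missingMask()` returns the logical mask, `panelOf()` the named
#' assay-to-panel map, `clinicalData()` the covariate columns,
#' `outcomeTable()` a data.frame of `sample_id`, `time_years`, `event`,
#' `prevalent`, and `simulationTruth()` the generator's ground truth (or
#' `NULL` for cohorts read from files).
#'
#' @param x a [ProteomicCohort-class].
#' @param masked if `TRUE` (default) masked cells are returned as `NA`.
#' @param ... unused.
#' @name npx
#' @aliases missingMask panelOf clinicalData outcomeTable simulationTruth
NULL

#' @rdname npx
#' @export
setMethod("npx", "ProteomicCohort", function(x, masked = TRUE, ...) {
  v <- SummarizedExperiment::assay(x, "npx")
  if (masked) v[SummarizedExperiment::assay(x, "missing")] <- NA_real_
  v
})

#' @rdname npx
#' @export
setMethod("missingMask", "ProteomicCohort", function(x, ...)
  SummarizedExperiment::assay(x, "missing"))

#' @rdname npx
#' @export
setMethod("panelOf", "ProteomicCohort", function(x, ...)
  stats::setNames(SummarizedExperiment::rowData(x)$panel, rownames(x)))

#' @rdname npx
#' @export
setMethod("clinicalData", "ProteomicCohort", function(x, ...) {
  cd <- SummarizedExperiment::colData(x)
  keep <- setdiff(colnames(cd), c("time_years", "event", "prevalent"))
  as.data.frame(cd[, keep, drop = FALSE])
})

#' @rdname npx
#' @export
setMethod("outcomeTable", "ProteomicCohort", function(x, ...) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(sample_id = rownames(cd),
             time_years = cd$time_years, event = cd$event,
             prevalent = cd$prevalent, row.names = NULL)
})

#' @rdname npx
#' @export
setMethod("simulationTruth", "ProteomicCohort", function(x, ...)
  S4Vectors::metadata(x)$truth)

#' @export
#' @describeIn npx compact cohort display
setMethod("show", "ProteomicCohort", function(object) {
  o <- outcomeTable(object)
  cat("ProteomicCohort:", ncol(object), "samples x", nrow(object),
      "assays in", length(unique(panelOf(object))), "panels\n")
  cat(sprintf("  incident cases: %d | prevalent: %d | missing cells: %.1f%%\n",
              sum(o$event == 1 & o$prevalent == 0), sum(o$prevalent),
              100 * mean(missingMask(object))))
  cat(sprintf("  horizon: %s years\n",
              format(S4Vectors::metadata(object)$horizon_years)))
})

#' Exclude prevalent and early incident cases
#'
#' Removes prevalent cases (disease onset before or at baseline) and
#' incident cases recorded within the first `min_incident_months` of
#' follow-up (default 6), the cohort-inclusion rule applied before any
#' modeling. All other rows are unchanged.
#'
#' @param x a [ProteomicCohort-class], or a data.frame with columns
#'   `sample_id`, `time_years`, `event`, `prevalent`.
#' @param min_incident_months early-incident exclusion window, in months.
#' @param ... unused.
#' @return For a cohort, the filtered cohort with removal counts in
#'   `metadata(x)$filter_counts`; for a data.frame, a list with elements
#'   `outcomes` (the filtered table) and `removed` (named counts).
#' @examples
#' tab <- data.frame(sample_id = letters[1:4],
#'                   time_years = c(2, 0.3, 2, 10),
#'                   event = c(0, 1, 1, 0), prevalent = c(1, 0, 0, 0))
#' applyIncidenceFilters(tab)$outcomes
#' @name applyIncidenceFilters
NULL

.filterOutcomes <- function(outcomes, min_incident_months) {
  if (any(outcomes$time_years[outcomes$prevalent == 0] < 0))
    stop("negative follow-up time")
  drop_prev <- outcomes$prevalent == 1
  drop_early <- !drop_prev & outcomes$event == 1 &
    outcomes$time_years < min_incident_months / 12
  list(keep = !(drop_prev | drop_early),
       removed = c(prevalent = sum(drop_prev),
                   early_event = sum(drop_early)))
}

#' @rdname applyIncidenceFilters
#' @export
setMethod("applyIncidenceFilters", "data.frame",
          function(x, min_incident_months = 6, ...) {
  f <- .filterOutcomes(x, min_incident_months)
  list(outcomes = x[f$keep, , drop = FALSE], removed = f$removed)
})

#' @rdname applyIncidenceFilters
#' @export
setMethod("applyIncidenceFilters", "ProteomicCohort",
          function(x, min_incident_months = 6, ...) {
  f <- .filterOutcomes(outcomeTable(x), min_incident_months)
  out <- x[, f$keep]
  S4Vectors::metadata(out)$filter_counts <- f$removed
  out
})

#' Inject missingness into a cohort's protein matrix
#'
#' Marks cells missing without destroying the underlying values, so
#' imputation can later be scored against the truth. `MCAR` masks a uniform
#' random fraction of cells; `panel_block` masks whole panels for selected
#' samples, emulating failed plates.
#'
#' @param x a [ProteomicCohort-class].
#' @param rate target missing-cell fraction in `[0, 1)` (ignored when
#'   `samples` is given for `panel_block`).
#' @param mechanism `"MCAR"` or `"panel_block"`.
#' @param seed RNG seed.
#' @param samples for `panel_block`: sample ids to mask (optional).
#' @param panel for `panel_block`: the panel to mask (default: first panel).
#' @param ... unused.
#' @return The cohort with an updated missing mask.
#' @name injectMissingness
NULL

#' @rdname injectMissingness
#' @export
setMethod("injectMissingness", "ProteomicCohort",
          function(x, rate, mechanism = c("MCAR", "panel_block"),
                   seed = 1L, samples = NULL, panel = NULL, ...) {
  mechanism <- match.arg(mechanism)
  if (rate >= 1 || rate < 0) stop("rate must lie in [0, 1)")
  mask <- SummarizedExperiment::assay(x, "missing")
  set.seed(seed)
  if (mechanism == "MCAR") {
    ncell <- length(mask)
    idx <- which(stats::runif(ncell) < rate)
    mask[idx] <- TRUE
  } else {
    panels <- panelOf(x)
    if (is.null(panel)) panel <- unique(panels)[1L]
    rows <- which(panels == panel)
    if (!is.null(samples)) {
      mask[rows, samples] <- TRUE
    } else {
      target <- rate * length(mask)
      cols <- sample(ncol(mask))
      for (s in cols) {
        if (sum(mask) >= target) break
        mask[rows, s] <- TRUE
      }
    }
  }
  SummarizedExperiment::assay(x, "missing") <- mask
  x
})
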