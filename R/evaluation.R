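#' Harrell's concordance index
#'
#' Fraction of concordant pairs among comparable pairs. A pair is
#' comparable iff the member with the strictly earlier follow-up time had
#' the event; pairs with equal event times are not comparable; tied risk
#' scores on a comparable pair count 1/2.
#'
#' @param time follow-up times.
#' @param event event indicators (0/1).
#' @param score risk scores (higher = higher risk).
#' @return concordance in `[0, 1]`.
#' @examples
#' harrellC(c(1, 2, 3), c(1, 1, 1), c(3, 1, 2))  # 2/3
#' @export
harrellC <- function(time, event, score) {
  stopifnot(length(time) == length(event), length(time) == length(score))
  if (sum(event) < 1) stop("at least one event required")
  cc <- .concordance_counts(as.numeric(time), as.integer(event),
                            as.numeric(score))
  if (cc$comparable == 0) stop("no comparable pairs")
  (cc$concordant + 0.5 * cc$tied_score) / cc$comparable
}

## Bootstrap index matrix with >= 1 event per replicate (redrawn, bounded).
.bootIndices <- function(event, B) {
  n <- length(event)
  idx <- matrix(0L, B, n)
  for (b in seq_len(B)) {
    for (try in seq_len(100L)) {
      i <- sample.int(n, n, replace = TRUE)
      if (sum(event[i]) > 0) break
    }
    idx[b, ] <- i - 1L
  }
  idx
}

#' Paired-bootstrap comparison of two risk scores
#'
#' Computes the Harrell C of two score vectors over `B` bootstrap
#' resamples of the same validation samples, applying identical resample
#' indices to both models so the per-replicate difference
#' `C_new - C_old` is a coherent paired distribution. The 95% CI of the
#' differences is the empirical 2.5th/97.5th percentile interval, and the
#' improvement is significant iff that CI excludes zero. Replicates
#' without events are redrawn.
#'
#' @param scores_old,scores_new risk scores of the benchmark and the
#'   augmented model, aligned to the same samples.
#' @param time,event the samples' follow-up and event indicator.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return list with elements `old` and `new` ([BootstrapCResult-class])
#'   and `delta` ([DeltaCResult-class]).
#' @export
bootstrapCompare <- function(scores_old, scores_new, time, event,
                             B = 1000L, seed = 1L) {
  stopifnot(length(scores_old) == length(time),
            length(scores_new) == length(time))
  set.seed(seed)
  idx <- .bootIndices(event, B)
  bt <- .concordance_boot(as.numeric(time), as.integer(event),
                          as.numeric(scores_old), as.numeric(scores_new),
                          idx)
  cA <- bt$cA; cB <- bt$cB
  bad <- which(is.na(cA) | is.na(cB))
  for (b in bad) {                       # replicate had no comparable pairs
    for (try in seq_len(100L)) {
      i <- sample.int(length(time), length(time), replace = TRUE)
      one <- .concordance_boot(as.numeric(time), as.integer(event),
                               as.numeric(scores_old),
                               as.numeric(scores_new),
                               matrix(i - 1L, nrow = 1L))
      if (!is.na(one$cA[1]) && !is.na(one$cB[1])) {
        cA[b] <- one$cA[1]; cB[b] <- one$cB[1]; break
      }
    }
  }
  delta <- cB - cA
  ci <- unname(stats::quantile(delta, c(0.025, 0.975)))
  new_res <- function(cv) new("BootstrapCResult", cMean = mean(cv),
                              cDist = cv, B = as.integer(B),
                              seed = as.integer(seed))
  list(old = new_res(cA), new = new_res(cB),
       delta = new("DeltaCResult", deltaMean = mean(delta),
                   ciLow = ci[1], ciHigh = ci[2],
                   significant = ci[1] > 0 || ci[2] < 0))
}

#' @export
setMethod("show", "BootstrapCResult", function(object)
  cat(sprintf("BootstrapCResult: mean C = %.3f over B = %d (95%% range %.3f-%.3f)\n",
              object@cMean, object@B,
              stats::quantile(object@cDist, 0.025),
              stats::quantile(object@cDist, 0.975))))

#' @export
setMethod("show", "DeltaCResult", function(object)
  cat(sprintf("DeltaCResult: delta C = %.3f (95%% CI %.3f to %.3f)%s\n",
              object@deltaMean, object@ciLow, object@ciHigh,
              if (object@significant) "  *significant*" else "")))

## Case/control status at the horizon: case = incident event within the
## horizon; control = event-free with follow-up >= horizon (default) or
## every non-case; NA = excluded (censored early without event).
.statusAtHorizon <- function(time, event, horizon,
                             controls = c("followed", "all_noncases")) {
  controls <- match.arg(controls)
  case <- event == 1 & time <= horizon
  ctrl <- if (controls == "followed") !case & time >= horizon else !case
  status <- rep(NA_integer_, length(time))
  status[case] <- 1L
  status[ctrl] <- 0L
  status
}

#' Screening curve: detection rate and likelihood ratio across FPRs
#'
#' For each target false-positive rate, the positivity threshold is set at
#' the corresponding upper quantile of the control scores, and the 2x2
#' counts, realized FPR, detection rate `DR = TP/(TP + FN)` and likelihood
#' ratio `LR = DR/FPR` are tabulated. Cases are incident events within the
#' horizon; controls are event-free samples with follow-up reaching the
#' horizon (switchable to all non-cases).
#'
#' @param score risk scores.
#' @param time,event follow-up and event indicator.
#' @param horizon_years case/control horizon.
#' @param fpr_grid target FPRs (default 5% to 40% in 5% steps).
#' @param controls control definition (see [categoryFreeNRI()]).
#' @return A [ScreeningCurve-class].
#' @export
screeningCurve <- function(score, time, event, horizon_years,
                           fpr_grid = seq(0.05, 0.40, by = 0.05),
                           controls = c("followed", "all_noncases")) {
  status <- .statusAtHorizon(time, event, horizon_years, controls)
  keep <- !is.na(status)
  score <- score[keep]; status <- status[keep]
  n_ctrl <- sum(status == 0L)
  if (n_ctrl < 10) stop("fewer than 10 controls")
  if (sum(status == 1L) < 1) stop("no cases at the horizon")
  rows <- lapply(fpr_grid, function(f) {
    thr <- unname(stats::quantile(score[status == 0L], 1 - f, type = 1))
    pos <- score > thr
    TP <- sum(pos & status == 1L); FN <- sum(!pos & status == 1L)
    FP <- sum(pos & status == 0L); TN <- sum(!pos & status == 0L)
    fpr <- FP / (TN + FP); dr <- TP / (FN + TP)
    data.frame(fpr_target = f, threshold = thr, TP = TP, FP = FP,
               TN = TN, FN = FN, fpr = fpr, dr = dr,
               lr = if (fpr > 0) dr / fpr else Inf)
  })
  new("ScreeningCurve", table = do.call(rbind, rows),
      horizonYears = horizon_years)
}

#' @describeIn screeningCurve the curve as a data.frame
#' @param curve a [ScreeningCurve-class].
#' @export
screeningTable <- function(curve) curve@table

#' @export
setMethod("show", "ScreeningCurve", function(object) {
  cat("ScreeningCurve (horizon", object@horizonYears, "years)\n")
  print(object@table, row.names = FALSE, digits = 3)
})

#' Post-test probability from a likelihood ratio
#'
#' Converts a pre-test probability to the post-test probability of disease
#' given a positive test, via odds: `posterior odds = LR * prior odds`.
#'
#' @param lr positive likelihood ratio, `>= 0`.
#' @param pretest pre-test probability in `[0, 1)`.
#' @return post-test probability.
#' @examples
#' postTestProbability(8.08, 0.01)
#' @export
postTestProbability <- function(lr, pretest) {
  stopifnot(lr >= 0, pretest >= 0)
  if (any(pretest >= 1)) stop("pretest probability must be < 1")
  odds <- pretest / (1 - pretest)
  lr * odds / (1 + lr * odds)
}

#' Category-free net reclassification improvement
#'
#' With margin `m` (default 0.15 on the absolute-risk scale, the
#' conservative cut-off), a sample moves "up" when
#' `risk_new - risk_old > m` and "down" when `< -m`. The cNRI is
#' `[P(up|case) - P(down|case)] + [P(down|control) - P(up|control)]`,
#' with case/control status at the horizon as in [screeningCurve()].
#'
#' @param risk_old,risk_new absolute risks in `[0, 1]` from the benchmark
#'   and the augmented model.
#' @param time,event follow-up and event indicator.
#' @param horizon_years case/control horizon.
#' @param margin risk-difference cut-off (default 0.15).
#' @param controls control definition.
#' @return A [ReclassResult-class] (the `idi` slot is `NA`; see [idi()]).
#' @export
categoryFreeNRI <- function(risk_old, risk_new, time, event, horizon_years,
                            margin = 0.15,
                            controls = c("followed", "all_noncases")) {
  stopifnot(all(risk_old >= 0 & risk_old <= 1),
            all(risk_new >= 0 & risk_new <= 1))
  status <- .statusAtHorizon(time, event, horizon_years, controls)
  keep <- !is.na(status)
  d <- risk_new[keep] - risk_old[keep]
  status <- status[keep]
  if (!sum(status == 1L) || !sum(status == 0L))
    stop("both cases and controls required")
  up <- d > margin; down <- d < -margin
  p_up_case <- mean(up[status == 1L]); p_dn_case <- mean(down[status == 1L])
  p_up_ctrl <- mean(up[status == 0L]); p_dn_ctrl <- mean(down[status == 0L])
  new("ReclassResult",
      cnri = (p_up_case - p_dn_case) + (p_dn_ctrl - p_up_ctrl),
      margin = margin, idi = NA_real_,
      counts = c(up_case = sum(up & status == 1L),
                 down_case = sum(down & status == 1L),
                 up_control = sum(up & status == 0L),
                 down_control = sum(down & status == 0L)),
      horizonYears = horizon_years)
}

#' Integrated discrimination improvement
#'
#' `IDI = [mean(risk_new | case) - mean(risk_new | control)] -
#' [mean(risk_old | case) - mean(risk_old | control)]`: the change in
#' discrimination slope between the two models, with case/control status
#' at the horizon.
#'
#' @inheritParams categoryFreeNRI
#' @return A [ReclassResult-class] (the `cnri` slot is `NA`).
#' @export
idi <- function(risk_old, risk_new, time, event, horizon_years,
                controls = c("followed", "all_noncases")) {
  stopifnot(all(risk_old >= 0 & risk_old <= 1),
            all(risk_new >= 0 & risk_new <= 1))
  status <- .statusAtHorizon(time, event, horizon_years, controls)
  keep <- !is.na(status)
  ro <- risk_old[keep]; rn <- risk_new[keep]; status <- status[keep]
  if (!sum(status == 1L) || !sum(status == 0L))
    stop("both cases and controls required")
  slope <- function(r) mean(r[status == 1L]) - mean(r[status == 0L])
  new("ReclassResult", cnri = NA_real_, margin = NA_real_,
      idi = slope(rn) - slope(ro), counts = integer(),
      horizonYears = horizon_years)
}

#' @export
setMethod("show", "ReclassResult", function(object) {
  if (!is.na(object@cnri))
    cat(sprintf("cNRI = %.4f (margin %.2f)\n", object@cnri, object@margin))
  if (!is.na(object@idi))
    cat(sprintf("IDI = %.4f\n", object@idi))
})

#' Stratified bootstrap comparison of two models
#'
#' Repeats the paired-bootstrap protein-vs-clinical comparison within each
#' stratum (for example sex, or age of onset < 65 vs >= 65). Strata with
#' fewer than `min_cases` incident cases within the horizon are excluded
#' and reported as skipped. When exactly two strata are evaluable, the
#' between-stratum difference of the new model's bootstrap C distributions
#' is also reported, with the same CI-excludes-zero rule.
#'
#' @param scores_old,scores_new risk scores aligned to the samples.
#' @param time,event follow-up and event indicator.
#' @param strata factor (or vector) of stratum labels per sample.
#' @param horizon_years horizon defining incident cases.
#' @param min_cases minimum incident cases per stratum (default 20).
#' @param B,seed bootstrap settings.
#' @return list with `strata` (per-stratum [bootstrapCompare()] results),
#'   `skipped` (named reasons) and `between` (a [DeltaCResult-class] or
#'   `NULL`).
#' @export
stratifiedEval <- function(scores_old, scores_new, time, event, strata,
                           horizon_years, min_cases = 20L, B = 1000L,
                           seed = 1L) {
  stopifnot(length(strata) == length(time))
  strata <- as.factor(strata)
  res <- list(); skipped <- character(); newdist <- list()
  for (lev in levels(strata)) {
    in_s <- strata == lev
    n_cases <- sum(event[in_s] == 1 & time[in_s] <= horizon_years)
    if (n_cases < min_cases) {
      skipped[lev] <- sprintf("only %d incident cases (< %d)",
                              n_cases, min_cases)
      next
    }
    res[[lev]] <- bootstrapCompare(scores_old[in_s], scores_new[in_s],
                                   time[in_s], event[in_s], B = B,
                                   seed = seed)
    newdist[[lev]] <- res[[lev]]$new@cDist
  }
  if (!length(res)) stop("all strata skipped: too few incident cases")
  between <- NULL
  if (length(newdist) == 2L) {
    d <- newdist[[2L]] - newdist[[1L]]
    ci <- unname(stats::quantile(d, c(0.025, 0.975)))
    between <- new("DeltaCResult", deltaMean = mean(d), ciLow = ci[1],
                   ciHigh = ci[2], significant = ci[1] > 0 || ci[2] < 0)
  }
  list(strata = res, skipped = skipped, between = between)
}

#' Downsample incident cases
#'
#' Retains a uniform random subset of incident cases of the requested size
#' together with all non-cases — the sensitivity analysis used to check
#' that improvements are not inflated as case counts shrink.
#'
#' @param x a [ProteomicCohort-class] or an outcome data.frame.
#' @param target_cases number of cases to retain; must not exceed the
#'   observed case count.
#' @param seed RNG seed.
#' @return the downsampled cohort or outcome table.
#' @export
downsampleCases <- function(x, target_cases, seed = 1L) {
  outcomes <- if (is(x, "ProteomicCohort")) outcomeTable(x) else x
  case_ids <- outcomes$sample_id[outcomes$event == 1]
  if (target_cases > length(case_ids))
    stop("target_cases (", target_cases, ") exceeds observed cases (",
         length(case_ids), ")")
  set.seed(seed)
  keep_cases <- sample(case_ids, target_cases)
  keep <- outcomes$event == 0 | outcomes$sample_id %in% keep_cases
  if (is(x, "ProteomicCohort")) x[, keep]
  else x[keep, , drop = FALSE]
}
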