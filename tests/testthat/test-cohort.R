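test_that("identical configurations reproduce bit-identical cohorts", {
  cfg <- cohortConfig(n_samples = 300, n_assays = 40, n_panels = 2,
                      causal_assays = 3L, beta_protein = 1,
                      target_case_count = 50L, missing_rate = 0.05,
                      seed = 7)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(npx(a), npx(b))
  expect_identical(missingMask(a), missingMask(b))
  expect_identical(outcomeTable(a), outcomeTable(b))
  expect_identical(simulationTruth(a)$linear_predictor,
                   simulationTruth(b)$linear_predictor)
})

test_that("a fully null cohort carries no concordance signal", {
  cfg <- cohortConfig(n_samples = 5000, n_assays = 10, n_panels = 1,
                      block_size = 10, causal_assays = 1L,
                      beta_protein = 0, beta_clinical = zero_clinical,
                      target_case_count = 400L, prevalent_frac = 0,
                      seed = 21)
  co <- simulateCohort(cfg)
  o <- outcomeTable(co)
  score <- t(npx(co))[, 1L]           # any fixed score
  expect_lt(abs(harrellC(o$time_years, o$event, score) - 0.5), 0.02)
})

test_that("true-linear-predictor concordance matches the exponential-race closed form", {
  ## no censoring: every subject events; P(T_i < T_j) = 1/(1+exp(lp_j-lp_i))
  cfg <- cohortConfig(n_samples = 4000, n_assays = 10, n_panels = 1,
                      block_size = 10, causal_assays = 4L,
                      beta_protein = 1.0, beta_clinical = zero_clinical,
                      baseline_rate = 0.05, admin_censor_years = 1e6,
                      target_case_count = NA, prevalent_frac = 0, seed = 5)
  co <- simulateCohort(cfg)
  o <- outcomeTable(co)
  expect_true(all(o$event == 1))
  lp <- simulationTruth(co)$linear_predictor
  c_obs <- harrellC(o$time_years, o$event, lp)
  set.seed(99)
  i <- sample.int(length(lp), 1e6, replace = TRUE)
  j <- sample.int(length(lp), 1e6, replace = TRUE)
  keep <- lp[i] != lp[j]
  c_oracle <- mean(stats::plogis(abs(lp[i] - lp[j])[keep]))
  expect_lt(abs(c_obs - c_oracle), 0.01)
})

test_that("baseline-rate calibration hits the target incidence", {
  cfg <- cohortConfig(n_samples = 10000, n_assays = 20, n_panels = 2,
                      causal_assays = 1L, beta_protein = 0.5,
                      target_case_count = 500L, prevalent_frac = 0,
                      seed = 3)
  co <- simulateCohort(cfg)
  observed <- sum(outcomeTable(co)$event)
  expect_lt(abs(observed - 500), 3 * sqrt(500 * 0.95))
  expect_error(simulateCohort(cohortConfig(n_samples = 100, n_assays = 10,
                                           n_panels = 1, block_size = 10,
                                           causal_assays = 1L,
                                           beta_protein = 0,
                                           prevalent_frac = 0,
                                           target_case_count = 99L)),
               NA)  # 99 <= n is fine
  expect_error(cohortConfig(n_samples = 100, n_assays = 10, n_panels = 1,
                            block_size = 10, causal_assays = 1L,
                            beta_protein = 0, target_case_count = 101L),
               "targetCaseCount")
})

test_that("raising a causal log hazard ratio raises the case count at fixed seed", {
  base <- function(b) {
    cfg <- cohortConfig(n_samples = 2000, n_assays = 10, n_panels = 1,
                        block_size = 10, causal_assays = 5L,
                        beta_protein = b, baseline_rate = 0.01,
                        target_case_count = NA, prevalent_frac = 0,
                        seed = 17)
    sum(outcomeTable(simulateCohort(cfg))$event)
  }
  expect_gt(base(1.5), base(0.5))
  expect_gt(base(0.5), base(0))
})

test_that("incidence filters apply the exclusion rules exactly", {
  tab <- data.frame(sample_id = c("a", "b", "c", "d"),
                    time_years = c(2, 0.3, 2, 10),
                    event = c(0L, 1L, 1L, 0L),
                    prevalent = c(1L, 0L, 0L, 0L))
  out <- applyIncidenceFilters(tab)
  expect_identical(out$outcomes$sample_id, c("c", "d"))
  expect_identical(out$removed, c(prevalent = 1L, early_event = 1L))

  ## zero window and no prevalent rows: identity
  tab2 <- tab[tab$prevalent == 0, ]
  expect_identical(applyIncidenceFilters(tab2, 0)$outcomes, tab2)

  ## random table vs brute-force row-by-row oracle
  set.seed(8)
  big <- data.frame(sample_id = sprintf("s%03d", 1:100),
                    time_years = round(stats::runif(100, 0, 10), 2),
                    event = stats::rbinom(100, 1, 0.4),
                    prevalent = stats::rbinom(100, 1, 0.15))
  got <- applyIncidenceFilters(big, 6)$outcomes
  keep <- vapply(seq_len(100), function(i) {
    r <- big[i, ]
    !(r$prevalent == 1 || (r$event == 1 && r$time_years < 0.5))
  }, logical(1))
  expect_identical(got, big[keep, ])
  expect_error(applyIncidenceFilters(
    data.frame(sample_id = "x", time_years = -1, event = 0L,
               prevalent = 0L)), "negative")
})

test_that("missingness injection follows the requested mechanism", {
  cfg <- cohortConfig(n_samples = 500, n_assays = 200, n_panels = 2,
                      causal_assays = 1L, beta_protein = 0,
                      target_case_count = NA, seed = 9)
  co <- simulateCohort(cfg)

  expect_identical(missingMask(injectMissingness(co, 0, "MCAR", seed = 1)),
                   missingMask(co))

  m <- injectMissingness(co, 0.1, "MCAR", seed = 2)
  frac <- mean(missingMask(m))
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 1e5))
  ## values preserved under the mask
  expect_identical(SummarizedExperiment::assay(m, "npx"),
                   SummarizedExperiment::assay(co, "npx"))

  victims <- colnames(co)[1:5]
  pb <- injectMissingness(co, 0, "panel_block", seed = 3,
                          samples = victims, panel = "panel_2")
  mask <- missingMask(pb)
  in_panel <- panelOf(co) == "panel_2"
  expect_true(all(mask[in_panel, victims]))
  expect_false(any(mask[, setdiff(colnames(co), victims)]))
  expect_false(any(mask[!in_panel, ]))

  expect_error(injectMissingness(co, 1, "MCAR"), "rate")
})

test_that("cohort configurations validate their structure", {
  expect_error(cohortConfig(n_assays = 601), "divide")
  expect_error(cohortConfig(block_rho = 1), "blockRho")
  expect_error(cohortConfig(causal_assays = 700L, beta_protein = 1),
               "causalAssays")
  expect_error(cohortConfig(causal_assays = c(1L, 2L), beta_protein = 1),
               "betaProtein")
})

test_that("cohorts round-trip through plain-text files", {
  cfg <- cohortConfig(n_samples = 60, n_assays = 10, n_panels = 2,
                      block_size = 5, causal_assays = 2L, beta_protein = 1,
                      target_case_count = NA, missing_rate = 0.1, seed = 4)
  co <- simulateCohort(cfg)
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  back <- readCohort(dir)
  expect_identical(missingMask(back), missingMask(co))
  keep <- !missingMask(co)
  expect_equal(SummarizedExperiment::assay(back, "npx")[keep],
               SummarizedExperiment::assay(co, "npx")[keep],
               tolerance = 1e-12)
  expect_equal(outcomeTable(back), outcomeTable(co))
  expect_equal(simulationTruth(back)$beta_true,
               simulationTruth(co)$beta_true)
})
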