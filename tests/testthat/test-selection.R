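make_outcomes <- function(n, n_cases) {
  data.frame(sample_id = sprintf("s%05d", seq_len(n)),
             time_years = c(rep(4, n_cases), rep(10, n - n_cases)),
             event = c(rep(1L, n_cases), rep(0L, n - n_cases)),
             prevalent = 0L)
}

test_that("splits follow the 800-case rule and stay stratified and exhaustive", {
  big <- make_outcomes(10000, 900)
  sp <- makeSplits(big, seed = 1)
  expect_identical(sp@rule, "three_way")
  all_ids <- sort(c(sp@selection, sp@optimization, sp@validation))
  expect_identical(all_ids, sort(big$sample_id))
  expect_length(intersect(sp@selection, sp@optimization), 0)
  expect_length(intersect(sp@selection, sp@validation), 0)
  expect_equal(length(sp@selection) / 10000, 0.50, tolerance = 0.001)
  expect_equal(length(sp@optimization) / 10000, 0.25, tolerance = 0.001)
  ## stratification: case fraction preserved within rounding
  case_ids <- big$sample_id[big$event == 1]
  expect_equal(mean(sp@selection %in% case_ids), 0.09, tolerance = 0.001)
  expect_equal(mean(sp@validation %in% case_ids), 0.09, tolerance = 0.001)

  small <- make_outcomes(2000, 400)
  sp2 <- makeSplits(small, seed = 1)
  expect_identical(sp2@rule, "two_way")
  expect_identical(sp2@selection, sp2@optimization)
  expect_equal(length(sp2@selection) / 2000, 0.70, tolerance = 0.001)
  expect_equal(length(sp2@validation) / 2000, 0.30, tolerance = 0.001)

  expect_identical(makeSplits(big, seed = 5)@selection,
                   makeSplits(big, seed = 5)@selection)
  expect_error(makeSplits(make_outcomes(1000, 79)), "80 incident cases")
})

test_that("smoothed-bootstrap rebalancing matches its kernel contract", {
  set.seed(1)
  X <- matrix(rnorm(120 * 3), 120, 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- rep(c(0L, 1L), c(100, 20))

  ## degenerate kernel: every output row is an exact input row of its class
  reb <- smoothedBootstrapRebalance(X, y, p = 0.5, n_out = 200,
                                    kernel_shrink = 0, seed = 2)
  key <- function(M) apply(M, 1L, paste, collapse = "|")
  for (cl in 0:1)
    expect_true(all(key(reb$features[reb$labels == cl, ]) %in%
                      key(X[y == cl, ])))

  ## class-1 fraction is binomial around p
  reb2 <- smoothedBootstrapRebalance(X, y, p = 0.5, n_out = 10000, seed = 3)
  expect_lt(abs(mean(reb2$labels) - 0.5), 3 * sqrt(0.25 / 10000))

  ## convolution variance: var(out) ~ sigma^2 + h^2 for d = 1
  x1 <- matrix(rnorm(200, sd = 2), ncol = 1)
  y1 <- rep(c(0L, 1L), each = 100)
  h <- 2 * (4 / ((1 + 2) * 100))^(1 / (1 + 4))
  out <- smoothedBootstrapRebalance(x1, y1, p = 0.5, n_out = 20000,
                                    kernel_shrink = 1, seed = 4)
  v_emp <- stats::var(out$features[out$labels == 1L, 1])
  sigma2 <- stats::var(x1[y1 == 1L, 1])
  expect_lt(abs(v_emp - (sigma2 + h^2)) / (sigma2 + h^2), 0.10)

  ## singleton class falls back to the pooled bandwidth with a warning
  ys <- c(rep(0L, 119), 1L)
  expect_warning(smoothedBootstrapRebalance(X, ys, n_out = 50, seed = 5),
                 "single member")
  expect_error(smoothedBootstrapRebalance(X, rep(0L, 120)), "both classes")
})

test_that("a single selection iteration has definitional score structure", {
  fx <- signal_fixture()
  sc1 <- subsampledSelection(fx$cohort, fx$split, n_iterations = 1L,
                             cv_repeats = 1L, seed = 3)
  tab <- selectionScores(sc1)
  expect_true(all(tab$times_selected %in% c(0L, 1L)))
  expect_true(all(tab$score >= 0))
  expect_true(all(tab$times_selected[tab$score == 0] == 0L))
  expect_true(all(tab$score[tab$times_selected == 0L] == 0))
  ## iterations are independently reproducible
  sc1b <- subsampledSelection(fx$cohort, fx$split, n_iterations = 1L,
                              cv_repeats = 1L, seed = 3)
  expect_identical(tab, selectionScores(sc1b))
})

test_that("a strong causal assay dominates the selection scores", {
  cfg <- cohortConfig(n_samples = 800, n_assays = 60, n_panels = 2,
                      block_size = 10, block_rho = 0.3,
                      causal_assays = 17L, beta_protein = 1.5,
                      target_case_count = 150L, seed = 31)
  co <- applyIncidenceFilters(simulateCohort(cfg))
  sp <- makeSplits(co, seed = 31)
  sc <- subsampledSelection(co, sp, n_iterations = 6L, cv_repeats = 1L,
                            seed = 31)
  tab <- selectionScores(sc)
  expect_identical(tab$assay_id[which.max(tab$score)], "A0017")
})

test_that("null cohorts produce no stable selection winner", {
  tops <- vapply(1:4, function(s) {
    cfg <- cohortConfig(n_samples = 500, n_assays = 40, n_panels = 2,
                        block_size = 10, causal_assays = 1L,
                        beta_protein = 0, beta_clinical = zero_clinical,
                        target_case_count = 100L, prevalent_frac = 0,
                        seed = 100 + s)
    co <- applyIncidenceFilters(simulateCohort(cfg))
    sp <- makeSplits(co, seed = s)
    sc <- subsampledSelection(co, sp, n_iterations = 2L, cv_repeats = 1L,
                              seed = s)
    rankTopK(sc, 1L)
  }, character(1))
  expect_gt(length(unique(tops)), 1L)
})

test_that("selection scores respond monotonically to the true effect size", {
  score_of <- function(b) {
    cfg <- cohortConfig(n_samples = 600, n_assays = 3, n_panels = 1,
                        block_size = 1, block_rho = 0, causal_assays = 2L,
                        beta_protein = b, target_case_count = 120L,
                        prevalent_frac = 0, seed = 77)
    co <- applyIncidenceFilters(simulateCohort(cfg))
    sc <- subsampledSelection(co, NULL, n_iterations = 4L,
                              cv_repeats = 1L, seed = 77)
    selectionScores(sc)$score[2L]
  }
  expect_gte(score_of(1.2), score_of(0.3))
})

test_that("top-k ranking matches a full-sort oracle and its tie rule", {
  mk <- function(ids, s) new("SelectionScores",
                             scores = data.frame(assay_id = ids, score = s,
                                                 times_selected =
                                                   as.integer(s > 0)),
                             nIterations = 1L, settings = list())
  expect_identical(rankTopK(mk(c("A", "B", "C"), c(10, 5, 1)), 2), c("A", "B"))
  expect_identical(rankTopK(mk(c("B", "A"), c(3, 3)), 1), "A")

  set.seed(6)
  ids <- sprintf("P%03d", 1:50)
  s <- round(stats::runif(50), 3)
  got <- rankTopK(mk(ids, s), 20)
  oracle <- ids[order(-s, ids)][1:20]
  expect_identical(got, oracle)

  expect_warning(out <- rankTopK(mk(c("A", "B", "C"), c(1, 0, 0)), 2),
                 "positive")
  expect_identical(out, "A")
})

test_that("weight-by-score sparsification ranks by the exact product", {
  mk_model <- function(feats, beta, pen) new(
    "FittedRiskModel", featureNames = feats, beta = beta,
    lambdaOpt = 0.1, center = numeric(length(feats)),
    scale = rep(1, length(feats)), penalized = pen,
    baselineCumHaz = 0.05, horizonYears = 10)
  mk_scores <- function(ids, s) new(
    "SelectionScores",
    scores = data.frame(assay_id = ids, score = s,
                        times_selected = as.integer(s > 0)),
    nIterations = 1L, settings = list())

  m <- mk_model(c("age", "A", "B"), c(0.5, 0.1, 0.4), c(FALSE, TRUE, TRUE))
  sc <- mk_scores(c("A", "B"), c(10, 5))
  expect_identical(sparsifyByWeightProduct(m, sc, 1), "B")  # 2.0 > 1.0

  m0 <- mk_model(c("A", "B"), c(0, 0.01), c(TRUE, TRUE))
  expect_identical(sparsifyByWeightProduct(m0, mk_scores(c("A", "B"),
                                                         c(100, 1)), 1), "B")

  set.seed(7)
  feats <- sprintf("F%02d", 1:20)
  beta <- stats::rnorm(20)
  s <- stats::runif(20)
  m2 <- mk_model(feats, beta, rep(TRUE, 20))
  got <- sparsifyByWeightProduct(m2, mk_scores(feats, s), 5)
  oracle <- feats[order(-(abs(beta) * s), feats)][1:5]
  expect_identical(got, oracle)

  expect_error(sparsifyByWeightProduct(m, mk_scores("A", 1), 1),
               "missing from selection scores: B")
})
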