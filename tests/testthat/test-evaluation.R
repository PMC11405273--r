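test_that("harrellC matches hand counts and the brute-force pair oracle", {
  expect_identical(harrellC(c(5, 3, 1), c(1, 1, 1), c(-5, -3, -1)), 1)
  expect_equal(harrellC(c(1, 2, 3), c(1, 1, 1), c(3, 1, 2)), 2 / 3)
  set.seed(1)
  for (k in 1:25) {
    n <- sample(20:120, 1)
    time <- round(stats::rexp(n, 0.2), 2)
    event <- stats::rbinom(n, 1, 0.7)
    score <- if (k %% 2) stats::rnorm(n) else round(stats::rnorm(n), 1)
    if (sum(event) == 0) event[1] <- 1L
    expect_equal(harrellC(time, event, score),
                 brute_force_c(time, event, score), tolerance = 1e-12)
  }
  ## random scores carry no signal
  set.seed(2)
  tt <- stats::rexp(2000, 0.1)
  expect_lt(abs(harrellC(pmin(tt, 10), as.integer(tt <= 10),
                         stats::rnorm(2000)) - 0.5), 0.02)
  expect_error(harrellC(c(1, 1), c(1, 1), c(1, 2)), "comparable")
})

test_that("paired bootstrap comparison is coherent and reproducible", {
  set.seed(3)
  n <- 300
  tt <- stats::rexp(n, 0.1)
  time <- pmin(tt, 10); event <- as.integer(tt <= 10)
  s <- stats::rnorm(n)

  self <- bootstrapCompare(s, s, time, event, B = 200, seed = 4)
  expect_identical(self$delta@deltaMean, 0)
  expect_true(self$delta@ciLow <= 0 && self$delta@ciHigh >= 0)
  expect_false(self$delta@significant)

  ## an informative score beats noise
  set.seed(5)
  n <- 1000
  lp <- stats::rnorm(n)
  tt <- stats::rexp(n, 0.03 * exp(lp))
  time <- pmin(tt, 10); event <- as.integer(tt <= 10)
  cmp <- bootstrapCompare(stats::rnorm(n), lp, time, event, B = 200,
                          seed = 6)
  expect_true(cmp$delta@significant)
  expect_gt(cmp$delta@deltaMean, 0)

})

test_that("bootstrap comparison is deterministic under a fixed seed", {
  set.seed(7)
  n <- 250
  tt <- stats::rexp(n, 0.1)
  time <- pmin(tt, 10); event <- as.integer(tt <= 10)
  a <- stats::rnorm(n); b <- stats::rnorm(n)
  r1 <- bootstrapCompare(a, b, time, event, B = 150, seed = 8)
  r2 <- bootstrapCompare(a, b, time, event, B = 150, seed = 8)
  expect_identical(r1$old@cDist, r2$old@cDist)
  expect_identical(r1$delta@ciLow, r2$delta@ciLow)
})

test_that("screening curves respect their counting identities", {
  set.seed(9)
  n_ctrl <- 2000; n_case <- 300
  time <- c(rep(10, n_ctrl), rep(4, n_case))
  event <- c(rep(0L, n_ctrl), rep(1L, n_case))

  ## null score: DR tracks FPR, LR ~ 1
  s0 <- stats::rnorm(n_ctrl + n_case)
  cv <- screeningTable(screeningCurve(s0, time, event, 10))
  for (i in seq_len(nrow(cv))) {
    f <- cv$fpr_target[i]
    expect_lt(abs(cv$dr[i] - f), 3 * sqrt(f * (1 - f) / n_case))
    ## LR = DR/FPR exactly, from the counts
    dr <- cv$TP[i] / (cv$TP[i] + cv$FN[i])
    fpr <- cv$FP[i] / (cv$FP[i] + cv$TN[i])
    expect_identical(cv$lr[i], dr / fpr)
  }
  expect_true(all(diff(cv$dr) >= 0))       # monotone in FPR

  ## perfect separation detects every case at any positive FPR
  s1 <- c(stats::rnorm(n_ctrl), stats::rnorm(n_case) + 100)
  cv1 <- screeningTable(screeningCurve(s1, time, event, 10))
  expect_true(all(cv1$dr == 1))

  expect_error(screeningCurve(stats::rnorm(12), rep(4, 12), rep(1L, 12), 10),
               "controls")
})

test_that("post-test probability follows the odds arithmetic", {
  expect_identical(postTestProbability(1, 0.2), 0.2)
  expect_identical(postTestProbability(0, 0.2), 0)
  odds <- 0.01 / 0.99
  expect_equal(postTestProbability(8.08, 0.01),
               8.08 * odds / (1 + 8.08 * odds), tolerance = 1e-15)
  expect_error(postTestProbability(2, 1), "pretest")
})

test_that("category-free NRI counts movements as enumerated by hand", {
  time <- c(rep(3, 4), rep(10, 6))
  event <- c(rep(1L, 4), rep(0L, 6))
  old <- c(0.10, 0.20, 0.30, 0.40, 0.10, 0.20, 0.30, 0.40, 0.50, 0.60)
  new <- c(0.30, 0.10, 0.50, 0.45, 0.30, 0.40, 0.10, 0.42, 0.80, 0.55)
  ## cases: up = {1 (+.20), 3 (+.20)}, down = {} at margin 0.15 -> 2/4
  ## controls: up = {5 (+.20), 6 (+.20), 9 (+.30)}, down = {7 (-.20)} -> -2/6
  r <- categoryFreeNRI(old, new, time, event, 10, margin = 0.15)
  expect_equal(r@cnri, (2 / 4 - 0) + (1 / 6 - 3 / 6), tolerance = 1e-12)
  expect_identical(unname(r@counts),
                   c(2L, 0L, 3L, 1L))

  ## identity and an unreachable margin give exactly zero
  expect_identical(categoryFreeNRI(old, old, time, event, 10)@cnri, 0)
  expect_identical(categoryFreeNRI(old, new, time, event, 10,
                                   margin = 0.9)@cnri, 0)
  ## antisymmetry under old/new swap
  r_swap <- categoryFreeNRI(new, old, time, event, 10, margin = 0.15)
  expect_equal(r_swap@cnri, -r@cnri, tolerance = 1e-12)
})

test_that("IDI equals the change in discrimination slope", {
  time <- c(rep(2, 3), rep(10, 5))
  event <- c(rep(1L, 3), rep(0L, 5))
  old <- c(0.5, 0.4, 0.3, 0.2, 0.1, 0.3, 0.2, 0.2)
  new <- c(0.6, 0.5, 0.5, 0.1, 0.1, 0.2, 0.3, 0.1)
  ## slopes: old = mean(.5,.4,.3) - mean(.2,.1,.3,.2,.2) = .4 - .2 = .2
  ##         new = mean(.6,.5,.5) - mean(.1,.1,.2,.3,.1) = .5333... - .16
  hand <- (mean(c(.6, .5, .5)) - mean(c(.1, .1, .2, .3, .1))) - 0.2
  r <- idi(old, new, time, event, 10)
  expect_equal(r@idi, hand, tolerance = 1e-12)
  expect_identical(idi(old, old, time, event, 10)@idi, 0)
  ## shifting every case up by 0.1 moves the IDI by exactly 0.1
  shifted <- old + 0.1 * (event == 1L)
  expect_equal(idi(old, shifted, time, event, 10)@idi, 0.1,
               tolerance = 1e-12)
  expect_equal(idi(new, old, time, event, 10)@idi, -r@idi,
               tolerance = 1e-12)
})

test_that("stratified evaluation skips thin strata and is reproducible", {
  set.seed(10)
  n <- 600
  strata <- rep(c("men", "women"), c(450, 150))
  lp <- stats::rnorm(n)
  tt <- stats::rexp(n, 0.04 * exp(lp))
  time <- pmin(tt, 10); event <- as.integer(tt <= 10)
  ## force the second stratum under the case floor
  idx_w <- which(strata == "women")
  event[idx_w] <- 0L
  event[idx_w[1:12]] <- 1L
  time[idx_w[1:12]] <- 4
  noise <- stats::rnorm(n)
  out <- stratifiedEval(noise, lp, time, event, strata, 10,
                        min_cases = 20, B = 100, seed = 11)
  expect_named(out$skipped, "women")
  expect_match(out$skipped[["women"]], "12 incident cases")
  expect_named(out$strata, "men")
  out2 <- stratifiedEval(noise, lp, time, event, strata, 10,
                         min_cases = 20, B = 100, seed = 11)
  expect_identical(out$strata$men$delta@deltaMean,
                   out2$strata$men$delta@deltaMean)
  expect_error(stratifiedEval(lp, lp, time, event, strata, 10,
                              min_cases = 1000), "skipped")
})

test_that("case downsampling retains exact counts and all controls", {
  set.seed(12)
  tab <- data.frame(sample_id = sprintf("s%04d", 1:500),
                    time_years = stats::runif(500, 0, 10),
                    event = stats::rbinom(500, 1, 0.4), prevalent = 0L)
  n_cases <- sum(tab$event)
  down <- downsampleCases(tab, 80, seed = 13)
  expect_identical(sum(down$event), 80L)
  expect_identical(sum(down$event == 0), sum(tab$event == 0))
  same <- downsampleCases(tab, n_cases, seed = 13)
  expect_setequal(same$sample_id, tab$sample_id)
  expect_error(downsampleCases(tab, n_cases + 1), "exceeds")
})

test_that("a shorter horizon re-evaluates the same scores on 5-year cases", {
  set.seed(14)
  n <- 1500
  lp <- stats::rnorm(n)
  tt <- stats::rexp(n, 0.05 * exp(lp))
  time <- pmin(tt, 10); event <- as.integer(tt <= 10)
  cv5 <- screeningTable(screeningCurve(lp, time, event, 5))
  n_cases5 <- sum(event == 1 & time <= 5)
  expect_identical(cv5$TP[1] + cv5$FN[1], n_cases5)
  ## controls at 5 years include the later cases (still disease-free at 5)
  expect_identical(cv5$FP[1] + cv5$TN[1], sum(time >= 5))
})
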