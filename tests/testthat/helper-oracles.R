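## Independent oracles used to check package computations. These are
## deliberately naive (exhaustive enumeration, textbook Newton-Raphson)
## and share no code with the implementation.

## Harrell's C by exhaustive pair enumeration.
brute_force_c <- function(time, event, score) {
  n <- length(time)
  con <- dis <- tie <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (time[i] == time[j]) next
      a <- if (time[i] < time[j]) i else j
      b <- if (time[i] < time[j]) j else i
      if (event[a] != 1) next
      if (score[a] > score[b]) con <- con + 1
      else if (score[a] < score[b]) dis <- dis + 1
      else tie <- tie + 1
    }
  }
  if (con + dis + tie == 0) stop("no comparable pairs")
  (con + 0.5 * tie) / (con + dis + tie)
}

## Unpenalized Cox partial-likelihood maximization (Breslow ties) by
## Newton-Raphson.
newton_cox <- function(X, time, event, tol = 1e-12, max_iter = 100L) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    w <- as.numeric(exp(X %*% beta))
    g <- rep(0, p)
    H <- matrix(0, p, p)
    for (t in unique(time[event == 1])) {
      D <- which(event == 1 & time == t)
      R <- which(time >= t)
      wr <- w[R]
      sw <- sum(wr)
      xbar <- colSums(X[R, , drop = FALSE] * wr) / sw
      g <- g + colSums(X[D, , drop = FALSE]) - length(D) * xbar
      xx <- crossprod(X[R, , drop = FALSE] * sqrt(wr)) / sw
      H <- H - length(D) * (xx - tcrossprod(xbar))
    }
    step <- solve(H, g)
    beta <- beta - step
    if (max(abs(step)) < tol) break
  }
  beta
}

## Two-sided Fisher exact p by hypergeometric enumeration: sum of the
## probabilities of all tables as or less probable than the observed one.
fisher_p_oracle <- function(a, b, c_, d) {
  m <- a + c_
  n2 <- b + d
  k <- a + b
  support <- max(0L, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p0 <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

## NRMSE over masked cells against the pre-masking truth.
nrmse_on_mask <- function(imputed, truth, mask) {
  sqrt(mean((imputed[mask] - truth[mask])^2)) / stats::sd(truth[mask])
}

## Mean-imputation baseline: per-assay observed means (assays in rows).
mean_impute <- function(values, mask) {
  out <- values
  out[mask] <- NA_real_
  mu <- rowMeans(out, na.rm = TRUE)
  for (i in seq_len(nrow(out)))
    out[i, mask[i, ]] <- mu[i]
  out
}

## Minimal ProteomicCohort around an explicit samples-x-assays matrix.
cohort_from_matrix <- function(V, panels = NULL, time = NULL, event = NULL) {
  n <- nrow(V)
  p <- ncol(V)
  if (is.null(rownames(V))) rownames(V) <- sprintf("S%04d", seq_len(n))
  if (is.null(colnames(V))) colnames(V) <- sprintf("A%04d", seq_len(p))
  if (is.null(panels)) panels <- rep("panel_1", p)
  if (is.null(time)) time <- rep(10, n)
  if (is.null(event)) event <- rep(0L, n)
  cd <- S4Vectors::DataFrame(
    age = rep(55, n), sex = rep(0L, n), bmi = rep(25, n),
    ethnicity = factor(rep("white", n)),
    smoking = factor(rep("never", n)),
    alcohol = factor(rep("never", n)),
    family_history = rep(0L, n),
    time_years = time, event = event, prevalent = rep(0L, n),
    row.names = rownames(V))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(npx = t(V),
                  missing = matrix(FALSE, p, n,
                                   dimnames = list(colnames(V),
                                                   rownames(V)))),
    rowData = S4Vectors::DataFrame(panel = panels,
                                   row.names = colnames(V)),
    colData = cd, metadata = list(horizon_years = 10))
  new("ProteomicCohort", se)
}

## Null clinical effects, for cohorts where every coefficient is zero.
zero_clinical <- c(age = 0, sex = 0, bmi = 0, smoking = 0)
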