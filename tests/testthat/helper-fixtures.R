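## Shared mid-sized signal cohort with a fitted model suite, built once
## per test run and reused across test files.
.fixture_env <- new.env(parent = emptyenv())

signal_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  cfg <- cohortConfig(n_samples = 1000, n_assays = 60, n_panels = 2,
                      block_size = 10, block_rho = 0.3,
                      causal_assays = c(5L, 35L),
                      beta_protein = c(1.0, 1.4),
                      target_case_count = 150L, seed = 42)
  co <- applyIncidenceFilters(simulateCohort(cfg))
  sp <- makeSplits(co, seed = 42)
  sc <- subsampledSelection(co, sp, n_iterations = 4L, cv_repeats = 1L,
                            seed = 42)
  suite <- fitModelSuite(co, sp, sc, seed = 42)
  o <- outcomeTable(co)
  rownames(o) <- o$sample_id
  X <- cbind(clinicalDesign(co),
             t(SummarizedExperiment::assay(co, "npx")))
  .fixture_env$fx <- list(cohort = co, split = sp, scores = sc,
                          suite = suite, o = o, X = X)
  .fixture_env$fx
}
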