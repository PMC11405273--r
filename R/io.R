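#' Write / read a cohort as plain-text files
#'
#' `writeCohort` writes four files into `dir`: `proteins.tsv` (samples in
#' rows, assays in columns, empty cell = missing), `panels.tsv`
#' (`assay_id`, `panel`), `covariates.csv` and `outcomes.csv`; for
#' simulated cohorts the ground truth goes to `truth.json`. `readCohort`
#' reconstructs a [ProteomicCohort-class] from such a directory (masked
#' cells read back as missing; their underlying values are not
#' recoverable from files).
#'
#' @param cohort a [ProteomicCohort-class].
#' @param dir directory (created if needed).
#' @return `readCohort` returns the restored cohort.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "ProteomicCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  V <- t(npx(cohort))                               # samples x assays, NA
  df <- data.frame(sample_id = rownames(V), V, check.names = FALSE)
  utils::write.table(df, file.path(dir, "proteins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(
    data.frame(assay_id = rownames(cohort),
               panel = SummarizedExperiment::rowData(cohort)$panel),
    file.path(dir, "panels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  cov <- clinicalData(cohort)
  utils::write.csv(cbind(sample_id = rownames(cov), cov),
                   file.path(dir, "covariates.csv"), row.names = FALSE)
  utils::write.csv(outcomeTable(cohort), file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  tr <- simulationTruth(cohort)
  if (!is.null(tr))
    jsonlite::write_json(
      list(beta_true = as.list(tr$beta_true),
           beta_clinical_true = as.list(tr$beta_clinical_true),
           baseline_rate = tr$baseline_rate,
           linear_predictor = as.list(tr$linear_predictor),
           horizon_years = S4Vectors::metadata(cohort)$horizon_years),
      file.path(dir, "truth.json"), digits = I(17), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  V <- utils::read.delim(file.path(dir, "proteins.tsv"),
                         check.names = FALSE)
  sample_ids <- V$sample_id
  V <- as.matrix(V[, -1L, drop = FALSE])
  rownames(V) <- sample_ids
  mask <- is.na(V)
  V[mask] <- 0                                    # placeholder under mask
  panels <- utils::read.delim(file.path(dir, "panels.tsv"))
  cov <- utils::read.csv(file.path(dir, "covariates.csv"))
  out <- utils::read.csv(file.path(dir, "outcomes.csv"))
  stopifnot(identical(as.character(cov$sample_id),
                      as.character(out$sample_id)))
  for (col in c("ethnicity", "smoking", "alcohol"))
    if (col %in% colnames(cov)) cov[[col]] <- factor(cov[[col]])
  cd <- S4Vectors::DataFrame(cov[, -1L, drop = FALSE],
                             out[, c("time_years", "event", "prevalent")],
                             row.names = sample_ids)
  md <- list()
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    j <- jsonlite::read_json(tf, simplifyVector = TRUE)
    md$truth <- list(beta_true = unlist(j$beta_true),
                     beta_clinical_true = unlist(j$beta_clinical_true),
                     baseline_rate = j$baseline_rate,
                     linear_predictor = unlist(j$linear_predictor))
    md$baseline_rate <- j$baseline_rate
    md$horizon_years <- j$horizon_years
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(npx = t(V), missing = t(mask)),
    rowData = S4Vectors::DataFrame(panel = panels$panel,
                                   row.names = panels$assay_id),
    colData = cd, metadata = md)
  new("ProteomicCohort", se)
}

#' Write selection scores as TSV
#'
#' Three columns: `assay_id`, `score`, `times_selected`.
#'
#' @param scores a [SelectionScores-class].
#' @param path output TSV file.
#' @export
writeSelectionScores <- function(scores, path) {
  stopifnot(is(scores, "SelectionScores"))
  utils::write.table(scores@scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a screening curve as TSV
#' @param curve a [ScreeningCurve-class].
#' @param path output TSV file.
#' @export
writeScreeningCurve <- function(curve, path) {
  stopifnot(is(curve, "ScreeningCurve"))
  utils::write.table(curve@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
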