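#' Annotation enrichment of a selected assay set
#'
#' For every annotation label (tissue class, pathway, panel, ...) builds
#' the 2x2 table of selected/non-selected by labelled/unlabelled assays
#' over the given background and computes the two-sided Fisher exact
#' p-value together with the sample odds ratio `ad/bc` (Haldane 0.5
#' correction when any cell is zero). P-values are Benjamini-Hochberg
#' adjusted across labels.
#'
#' @param selected character vector of selected assay ids (nonempty).
#' @param background character vector of all candidate assay ids;
#'   `selected` must be a subset.
#' @param annotations data.frame with columns `assay_id` and `label`
#'   (one row per assignment; assays may carry several labels or none).
#' @return data.frame with columns `label`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_value`, `q_value`, ordered by `p_value`.
#' @examples
#' ann <- data.frame(assay_id = c("A1", "A2", "B1"),
#'                   label = c("liver", "liver", "brain"))
#' fisherEnrichment(c("A1", "A2"), c("A1", "A2", "B1", "B2"), ann)
#' @export
fisherEnrichment <- function(selected, background, annotations) {
  if (!length(selected)) stop("empty selected set")
  if (!all(selected %in% background))
    stop("selected must be a subset of background")
  stopifnot(all(c("assay_id", "label") %in% colnames(annotations)))
  background <- unique(background)
  selected <- unique(selected)
  ann <- annotations[annotations$assay_id %in% background, , drop = FALSE]
  labels <- sort(unique(ann$label))
  if (!length(labels)) stop("no annotation labels on the background")
  rows <- lapply(labels, function(lb) {
    labelled <- unique(ann$assay_id[ann$label == lb])
    a <- sum(selected %in% labelled)
    b <- length(selected) - a
    c_ <- sum(!(background %in% selected) & background %in% labelled)
    d <- length(background) - length(selected) - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2L),
                            alternative = "two.sided")$p.value
    orr <- if (any(c(a, b, c_, d) == 0))
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    else (a * d) / (b * c_)
    data.frame(label = lb, a = a, b = b, c = c_, d = d,
               odds_ratio = orr, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bhAdjust(out$p_value)
  out[order(out$p_value, out$label), , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving with the input.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted q-values, same order as `p`.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cross-disease predictor sharing summary
#'
#' Given the per-disease sparse signatures (assay ids with model weights)
#' and a disease-to-clinical-specialty map, summarizes each assay's reach:
#' the number of diseases selecting it, the number of distinct
#' specialties, and its mean weight normalized within each disease to that
#' disease's top predictor. An assay is flagged `disease_specific` when it
#' is selected for exactly one disease with a normalized weight above 0.6.
#'
#' @param signatures named list (per disease) of data.frames with columns
#'   `assay_id` and `weight`; at least two diseases.
#' @param specialty_map named character vector mapping every disease name
#'   in `signatures` to a clinical specialty.
#' @return data.frame with one row per assay: `assay_id`, `n_diseases`,
#'   `n_specialties`, `mean_norm_weight`, `disease_specific`.
#' @export
predictorSharingSummary <- function(signatures, specialty_map) {
  stopifnot(is.list(signatures), length(signatures) >= 2,
            !is.null(names(signatures)))
  unmapped <- setdiff(names(signatures), names(specialty_map))
  if (length(unmapped))
    stop("disease(s) without specialty label: ",
         paste(unmapped, collapse = ", "))
  long <- do.call(rbind, lapply(names(signatures), function(ds) {
    s <- signatures[[ds]]
    top <- max(abs(s$weight))
    data.frame(disease = ds, assay_id = s$assay_id,
               norm_weight = if (top > 0) abs(s$weight) / top
                             else rep(0, nrow(s)))
  }))
  long$specialty <- specialty_map[long$disease]
  out <- do.call(rbind, lapply(split(long, long$assay_id), function(g)
    data.frame(assay_id = g$assay_id[1L],
               n_diseases = length(unique(g$disease)),
               n_specialties = length(unique(g$specialty)),
               mean_norm_weight = mean(g$norm_weight))))
  out$disease_specific <- out$n_diseases == 1L & out$mean_norm_weight > 0.6
  rownames(out) <- NULL
  out[order(-out$n_diseases, out$assay_id), , drop = FALSE]
}
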