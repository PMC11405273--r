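#' @rdname npx
#' @export
setGeneric("npx", function(x, ...) standardGeneric("npx"))

#' @rdname npx
#' @export
setGeneric("missingMask", function(x, ...) standardGeneric("missingMask"))

#' @rdname npx
#' @export
setGeneric("panelOf", function(x, ...) standardGeneric("panelOf"))

#' @rdname npx
#' @export
setGeneric("clinicalData", function(x, ...) standardGeneric("clinicalData"))

#' @rdname npx
#' @export
setGeneric("outcomeTable", function(x, ...) standardGeneric("outcomeTable"))

#' @rdname npx
#' @export
setGeneric("simulationTruth",
           function(x, ...) standardGeneric("simulationTruth"))

#' @rdname applyIncidenceFilters
#' @export
setGeneric("applyIncidenceFilters", function(x, min_incident_months = 6, ...)
  standardGeneric("applyIncidenceFilters"))

#' @rdname injectMissingness
#' @export
setGeneric("injectMissingness",
           function(x, rate, mechanism = c("MCAR", "panel_block"),
                    seed = 1L, ...)
             standardGeneric("injectMissingness"))

#' Selection-score table accessor
#'
#' Returns the per-assay score table (`assay_id`, `score`,
#' `times_selected`) of a [SelectionScores-class].
#'
#' @param x a [SelectionScores-class].
#' @param ... unused.
#' @rdname selectionScores
#' @export
setGeneric("selectionScores", function(x, ...)
  standardGeneric("selectionScores"))
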