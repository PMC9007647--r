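#' Accessors for cohort and report objects
#'
#' \code{exprMatrix} returns the log2 expression matrix, \code{betaMatrix} the
#' methylation beta matrix, \code{probeAnnotation} the probe annotation table,
#' \code{clinicalData} the clinical table, \code{cohortTruth} the ground-truth
#' list of a synthetic cohort, and \code{sampleIds} the shared sample ids.
#'
#' @param object a \linkS4class{MethylImmuneCohort} or \linkS4class{MimgReport}.
#' @return The requested component.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("exprMatrix", function(object) standardGeneric("exprMatrix"))
#' @rdname cohort-accessors
#' @export
setGeneric("betaMatrix", function(object) standardGeneric("betaMatrix"))
#' @rdname cohort-accessors
#' @export
setGeneric("probeAnnotation", function(object) standardGeneric("probeAnnotation"))
#' @rdname cohort-accessors
#' @export
setGeneric("clinicalData", function(object) standardGeneric("clinicalData"))
#' @rdname cohort-accessors
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))
#' @rdname cohort-accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname cohort-accessors
#' @export
setMethod("exprMatrix", "MethylImmuneCohort", function(object) object@expression)
#' @rdname cohort-accessors
#' @export
setMethod("betaMatrix", "MethylImmuneCohort", function(object) object@methylation)
#' @rdname cohort-accessors
#' @export
setMethod("probeAnnotation", "MethylImmuneCohort", function(object) object@annotation)
#' @rdname cohort-accessors
#' @export
setMethod("clinicalData", "MethylImmuneCohort", function(object) object@clinical)
#' @rdname cohort-accessors
#' @export
setMethod("cohortTruth", "MethylImmuneCohort", function(object) object@truth)
#' @rdname cohort-accessors
#' @export
setMethod("sampleIds", "MethylImmuneCohort", function(object) colnames(object@expression))

#' Accessors for pipeline reports
#'
#' @param object a \linkS4class{MimgReport}.
#' @return The requested report component.
#' @name report-accessors
NULL

#' @rdname report-accessors
#' @export
setGeneric("scoreTable", function(object) standardGeneric("scoreTable"))
#' @rdname report-accessors
#' @export
setGeneric("mimgPairs", function(object) standardGeneric("mimgPairs"))
#' @rdname report-accessors
#' @export
setGeneric("funnelCounts", function(object) standardGeneric("funnelCounts"))
#' @rdname report-accessors
#' @export
setGeneric("screenTable", function(object) standardGeneric("screenTable"))

#' @rdname report-accessors
#' @export
setMethod("scoreTable", "MimgReport", function(object) object@scores)
#' @rdname report-accessors
#' @export
setMethod("mimgPairs", "MimgReport", function(object) object@mimg)
#' @rdname report-accessors
#' @export
setMethod("funnelCounts", "MimgReport", function(object) object@counts)
#' @rdname report-accessors
#' @export
setMethod("screenTable", "MimgReport", function(object) object@screen)

#' Gene sets of an immune panel
#'
#' @param object an \linkS4class{ImmunePanel}.
#' @return \code{panelSets}: named list of gene sets; \code{panelCategories}:
#'   set -> category map; \code{panelSigns}: category sign weights.
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
setGeneric("panelSets", function(object) standardGeneric("panelSets"))
#' @rdname panel-accessors
#' @export
setGeneric("panelCategories", function(object) standardGeneric("panelCategories"))
#' @rdname panel-accessors
#' @export
setGeneric("panelSigns", function(object) standardGeneric("panelSigns"))

#' @rdname panel-accessors
#' @export
setMethod("panelSets", "ImmunePanel", function(object) object@sets)
#' @rdname panel-accessors
#' @export
setMethod("panelCategories", "ImmunePanel", function(object) object@categories)
#' @rdname panel-accessors
#' @export
setMethod("panelSigns", "ImmunePanel", function(object) object@signs)

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nSamples, "samples,",
      object@nBackgroundGenes, "background genes,",
      object@nPlantedPairs, "planted pairs",
      sprintf("(%.0f%% trans), coupling %.2f, seed %d\n",
              100 * object@transFraction, object@couplingStrength,
              object@seed))
})

setMethod("show", "ImmunePanel", function(object) {
  cat("ImmunePanel with", length(object@sets), "gene sets in",
      length(object@signs), "categories\n")
  for (cat_ in .PANEL_CATEGORIES) {
    s <- names(object@categories)[object@categories == cat_]
    cat(sprintf("  %-14s (%+d): %s\n", cat_, as.integer(object@signs[cat_]),
                paste(s, collapse = ", ")))
  }
})

setMethod("show", "MethylImmuneCohort", function(object) {
  cat("MethylImmuneCohort:", ncol(object@expression), "samples;",
      nrow(object@expression), "genes;",
      nrow(object@methylation), "probes\n")
  if (nrow(object@clinical))
    cat("  clinical columns:", paste(colnames(object@clinical), collapse = ", "), "\n")
  if (length(object@truth))
    cat("  synthetic cohort with ground truth:",
        paste(names(object@truth), collapse = ", "), "\n")
})

setMethod("show", "MimgReport", function(object) {
  cat("MimgReport\n  funnel:",
      paste(sprintf("%s=%d", names(object@counts), object@counts),
            collapse = ", "), "\n")
  if (nrow(object@screen))
    cat("  prognostic screen:", nrow(object@screen), "markers,",
        sum(object@screen$significant, na.rm = TRUE), "significant\n")
})
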