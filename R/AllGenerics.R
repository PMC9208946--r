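#' Accessors for neurofuzz containers
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object a neurofuzz S4 object.
#' @return The slot content named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("phantomImage", function(object) standardGeneric("phantomImage"))
#' @rdname accessors
#' @export
setGeneric("trueLabels", function(object) standardGeneric("trueLabels"))
#' @rdname accessors
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setGeneric("membershipMatrix",
           function(object) standardGeneric("membershipMatrix"))
#' @rdname accessors
#' @export
setGeneric("clusterCenters", function(object) standardGeneric("clusterCenters"))
#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setGeneric("nIterations", function(object) standardGeneric("nIterations"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setGeneric("seriesData", function(object) standardGeneric("seriesData"))
#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(object) standardGeneric("repetitionTime"))
#' @rdname accessors
#' @export
setGeneric("brainMask", function(object) standardGeneric("brainMask"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setGeneric("alffBand", function(object) standardGeneric("alffBand"))
#' @rdname accessors
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setGeneric("rocAUC", function(object) standardGeneric("rocAUC"))
#' @rdname accessors
#' @export
setGeneric("youdenCutoff", function(object) standardGeneric("youdenCutoff"))

#' @rdname accessors
#' @export
setMethod("phantomImage", "TissuePhantom", function(object) object@image)
#' @rdname accessors
#' @export
setMethod("trueLabels", "TissuePhantom", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("labelMap", "FuzzySegmentation", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("membershipMatrix", "FuzzySegmentation",
          function(object) object@membership)
#' @rdname accessors
#' @export
setMethod("clusterCenters", "FuzzySegmentation",
          function(object) object@centers)
#' @rdname accessors
#' @export
setMethod("objectiveTrace", "FuzzySegmentation",
          function(object) object@objectiveTrace)
#' @rdname accessors
#' @export
setMethod("nIterations", "FuzzySegmentation", function(object) object@nIter)
#' @rdname accessors
#' @export
setMethod("isConverged", "FuzzySegmentation",
          function(object) object@converged)
#' @rdname accessors
#' @export
setMethod("seriesData", "BoldSeries", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("repetitionTime", "BoldSeries", function(object) object@tr)
#' @rdname accessors
#' @export
setMethod("brainMask", "BoldSeries", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("mapValues", "ALFFMap", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("alffBand", "ALFFMap", function(object) object@band)
#' @rdname accessors
#' @export
setMethod("brainMask", "ALFFMap", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("mapValues", "ZALFFMap", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("alffBand", "ZALFFMap", function(object) object@band)
#' @rdname accessors
#' @export
setMethod("brainMask", "ZALFFMap", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("rocPoints", "ROCCurve", function(object) object@points)
#' @rdname accessors
#' @export
setMethod("rocAUC", "ROCCurve", function(object) object@auc)
#' @rdname accessors
#' @export
setMethod("youdenCutoff", "ROCCurve", function(object) object@youdenCutoff)

setMethod("show", "TissuePhantom", function(object) {
  cat("TissuePhantom:", paste(dim(object@image), collapse = " x "),
      "grid,", length(object@tissueMeans), "tissue classes\n")
  cat("  class means:", paste(object@tissueMeans, collapse = ", "),
      " (sd ", object@tissueSd, ")\n", sep = "")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "BoldSeries", function(object) {
  d <- dim(object@data)
  nt <- d[length(d)]
  cat("BoldSeries:", paste(d[-length(d)], collapse = " x "), "voxels x",
      nt, "volumes, TR =", object@tr, "s\n")
  cat("  mask:", sum(object@mask), "of", length(object@mask),
      "voxels in brain\n")
})

setMethod("show", "ALFFMap", function(object) {
  v <- object@values[object@mask]
  cat("ALFFMap:", paste(dim(object@values), collapse = " x "),
      sprintf("grid, band %.3f-%.3f Hz\n", object@band[1], object@band[2]))
  cat(sprintf("  in-mask ALFF: mean %.4g, range [%.4g, %.4g]\n",
              mean(v), min(v), max(v)))
})

setMethod("show", "ZALFFMap", function(object) {
  cat("ZALFFMap:", paste(dim(object@values), collapse = " x "),
      sprintf("grid, band %.3f-%.3f Hz\n", object@band[1], object@band[2]))
  cat(sprintf("  source mean %.4g, source SD %.4g (in-mask z: mean 0, SD 1)\n",
              object@sourceMean, object@sourceSd))
})

setMethod("show", "FuzzySegmentation", function(object) {
  cat("FuzzySegmentation:", length(object@centers), "clusters,",
      paste(dim(object@labels), collapse = " x "), "grid\n")
  cat("  centers:", paste(sprintf("%.3f", object@centers), collapse = ", "),
      "\n")
  cat(sprintf("  %d iterations (%s), final J = %.6g, init = %s\n",
              object@nIter,
              if (object@converged) "converged" else "iteration cap",
              utils::tail(object@objectiveTrace, 1), object@init))
})

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve: AUC = %.4f (%s)\n", object@auc, object@direction))
  cat(sprintf("  Youden cut-off %.4f: sensitivity %.3f, specificity %.3f\n",
              object@youdenCutoff, object@sensAtCutoff, object@specAtCutoff))
})
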