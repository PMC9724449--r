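#' @name accessors
#' @title Accessors for modsig data classes
#' @description Slot access for the S4 containers; user code should use these
#'   rather than \code{@}.
#' @param x An object of the documented class.
NULL

#' @rdname accessors
#' @export
setGeneric("mutationCounts", function(x) standardGeneric("mutationCounts"))

#' @rdname accessors
#' @export
setMethod("mutationCounts", "MutationCatalog", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "MutationCatalog", function(x) rownames(x@counts))

#' @rdname accessors
#' @export
setGeneric("cancerType", function(x) standardGeneric("cancerType"))

#' @rdname accessors
#' @export
setMethod("cancerType", "MutationCatalog", function(x) x@cancerType)

#' @rdname accessors
#' @export
setGeneric("signatureProfiles",
           function(x) standardGeneric("signatureProfiles"))

#' @rdname accessors
#' @export
setMethod("signatureProfiles", "SignatureSet", function(x) x@profiles)

#' @rdname accessors
#' @export
setGeneric("signatureIds", function(x) standardGeneric("signatureIds"))

#' @rdname accessors
#' @export
setMethod("signatureIds", "SignatureSet", function(x) rownames(x@profiles))

#' @rdname accessors
#' @export
setGeneric("modProfile", function(x) standardGeneric("modProfile"))

#' @rdname accessors
#' @export
setMethod("modProfile", "ModulatoryFit", function(x) x@r)

#' @rdname accessors
#' @export
setMethod("modProfile", "ModSigFit", function(x) x@modulatory@r)

#' @rdname accessors
#' @export
setGeneric("modActivities", function(x) standardGeneric("modActivities"))

#' @rdname accessors
#' @export
setMethod("modActivities", "ModulatoryFit", function(x) x@c)

#' @rdname accessors
#' @export
setMethod("modActivities", "ModSigFit", function(x) x@modulatory@c)

#' @rdname accessors
#' @export
setGeneric("residualValues", function(x) standardGeneric("residualValues"))

#' @rdname accessors
#' @export
setMethod("residualValues", "ResidualMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("residualFlavour", function(x) standardGeneric("residualFlavour"))

#' @rdname accessors
#' @export
setMethod("residualFlavour", "ResidualMatrix", function(x) x@flavour)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("sampleOrdering", function(x) standardGeneric("sampleOrdering"))

#' @rdname accessors
#' @export
setMethod("sampleOrdering", "ClusterAssignment", function(x) x@ordering)

#' @rdname accessors
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))

#' @rdname accessors
#' @export
setMethod("activities", "ModSigFit", function(x) x@activities)

#' @rdname accessors
#' @export
setGeneric("additiveActivities",
           function(x) standardGeneric("additiveActivities"))

#' @rdname accessors
#' @export
setMethod("additiveActivities", "ModSigFit", function(x) x@additiveActivities)

#' @rdname accessors
#' @export
setGeneric("modulatoryFit", function(x) standardGeneric("modulatoryFit"))

#' @rdname accessors
#' @export
setMethod("modulatoryFit", "ModSigFit", function(x) x@modulatory)

#' @rdname accessors
#' @export
setGeneric("logLikGain", function(x) standardGeneric("logLikGain"))

#' @rdname accessors
#' @export
setMethod("logLikGain", "ModSigFit", function(x) x@gain)

#' Log-likelihood of a fitted model
#'
#' @param object A \linkS4class{ModSigFit}.
#' @param ... Ignored.
#' @return The maximised extended-model Poisson log-likelihood (with the
#'   \code{log(X!)} constant dropped).
#' @export
setMethod("logLik", "ModSigFit", function(object, ...) object@logLik)

# ------------------------------------------------------------------- show ----

setMethod("show", "MutationCatalog", function(object) {
  n <- nrow(object@counts)
  cat("MutationCatalog:", n, "sample(s) x 96 channels;",
      format(sum(object@counts), big.mark = ","), "total mutations\n")
  if (length(object@cancerType)) {
    tt <- sort(table(object@cancerType), decreasing = TRUE)
    cat("  cancer types:", paste0(names(tt), " (", tt, ")",
                                  collapse = ", "), "\n")
  }
})

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet:", nrow(object@profiles), "signature(s) x 96 channels\n")
  cat("  ids:", paste(rownames(object@profiles), collapse = ", "), "\n")
})

setMethod("show", "ModulatoryFit", function(object) {
  cat("ModulatoryFit: profile over", length(object@r), "channel(s),",
      length(object@c), "sample activit(ies)\n")
  cat(sprintf("  max|r| = %.4g; c in [%.3g, %.3g]\n", max(abs(object@r)),
              if (length(object@c)) min(object@c) else NA,
              if (length(object@c)) max(object@c) else NA))
})

setMethod("show", "ResidualMatrix", function(object) {
  cat("ResidualMatrix (", object@flavour, "): ", nrow(object@values),
      " sample(s) x ", ncol(object@values), " channels\n", sep = "")
})

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment:", length(object@labels), "samples in",
      length(unique(object@labels)), "cluster(s) at correlation threshold",
      object@threshold, "\n")
})

setMethod("show", "ModSigFit", function(object) {
  cat("ModSigFit:", nrow(object@activities), "sample(s),",
      ncol(object@activities), "signature(s)\n")
  cat(sprintf("  logLik = %.4f (additive %.4f, gain %.4f)\n",
              object@logLik, object@additiveLogLik, object@gain))
  cat("  converged:", object@converged,
      "| restarts used:", object@nRestarts, "\n")
})
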