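#' @import methods
NULL

# ---------------------------------------------------------------- catalog ----

#' MutationCatalog: samples x 96 SBS mutation counts
#'
#' Holds observed single-base-substitution counts for a set of samples over
#' the canonical 96 trinucleotide-context channels, optionally with a cancer
#' type label per sample. Counts are stored samples x channels with channels
#' in canonical order (see \code{\link{sbsChannels}}).
#'
#' @slot counts Numeric matrix, samples x 96, non-negative; row names are
#'   sample identifiers, column names the canonical channel labels.
#' @slot cancerType Character vector of per-sample labels (length 0 when
#'   absent, otherwise one per sample).
#' @export
setClass("MutationCatalog",
         representation(counts = "matrix", cancerType = "character"))

setValidity("MutationCatalog", function(object) {
  x <- object@counts
  if (!is.numeric(x)) return("counts must be a numeric matrix")
  if (is.null(colnames(x)) || !identical(colnames(x), sbsChannels())) {
    return("counts columns must be the 96 canonical channels in order")
  }
  if (is.null(rownames(x))) return("counts must carry sample ids as rownames")
  if (anyDuplicated(rownames(x))) return("duplicate sample ids")
  if (any(!is.finite(x))) return("counts must be finite")
  if (any(x < 0)) return("counts must be non-negative")
  nt <- length(object@cancerType)
  if (nt != 0L && nt != nrow(x)) {
    return("cancerType must be empty or one label per sample")
  }
  TRUE
})

#' Construct a MutationCatalog
#'
#' @param counts Numeric matrix of non-negative counts. Either orientation is
#'   accepted; the 96 channel labels on one dimension decide which axis is
#'   which, and channels are reordered to the canonical scheme.
#' @param cancerType Optional character vector of per-sample labels.
#' @return A \linkS4class{MutationCatalog}.
#' @export
#' @examples
#' m <- matrix(rpois(96 * 3, 50), nrow = 3,
#'             dimnames = list(paste0("S", 1:3), sbsChannels()))
#' MutationCatalog(m)
MutationCatalog <- function(counts, cancerType = character()) {
  counts <- .orientToSamplesByChannels(counts)
  new("MutationCatalog", counts = counts,
      cancerType = as.character(cancerType))
}

## internal: accept samples x channels or channels x samples, return the
## former with channels permuted to canonical order
.orientToSamplesByChannels <- function(m) {
  m <- as.matrix(m)
  canon <- sbsChannels()
  if (!is.null(colnames(m)) && all(canon %in% colnames(m)) &&
      ncol(m) == 96L) {
    m <- m[, .channelPermutation(colnames(m)), drop = FALSE]
  } else if (!is.null(rownames(m)) && all(canon %in% rownames(m)) &&
             nrow(m) == 96L) {
    m <- t(m[.channelPermutation(rownames(m)), , drop = FALSE])
  } else {
    # raise the informative error (missing/duplicate/unknown labels)
    labs <- if (ncol(m) == 96L) colnames(m) else rownames(m)
    if (is.null(labs)) stop("no channel labels found on either dimension")
    .channelPermutation(labs)
    stop("matrix has no axis matching the 96-channel scheme")
  }
  if (is.null(rownames(m))) {
    rownames(m) <- paste0("sample", seq_len(nrow(m)))
  }
  storage.mode(m) <- "double"
  m
}

# ------------------------------------------------------------- signatures ----

#' SignatureSet: additive mutational signature profiles
#'
#' Each signature is a probability distribution over the 96 channels
#' (rows sum to one).
#'
#' @slot profiles Numeric matrix, signatures x 96; row names are signature
#'   identifiers, column names the canonical channel labels.
#' @export
setClass("SignatureSet", representation(profiles = "matrix"))

setValidity("SignatureSet", function(object) {
  p <- object@profiles
  if (!is.numeric(p)) return("profiles must be numeric")
  if (is.null(colnames(p)) || !identical(colnames(p), sbsChannels())) {
    return("profile columns must be the 96 canonical channels in order")
  }
  if (is.null(rownames(p)) || anyDuplicated(rownames(p))) {
    return("profiles must carry unique signature ids as rownames")
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    return("profile entries must be finite and non-negative")
  }
  if (any(abs(rowSums(p) - 1) > 1e-9)) {
    return("every signature must sum to 1 (within 1e-9)")
  }
  TRUE
})

#' Construct a SignatureSet
#'
#' Rows within 1e-6 of unit sum are renormalised exactly; larger deviations
#' are an error.
#'
#' @param profiles Numeric matrix of signature profiles; either orientation,
#'   channels identified by the 96 labels.
#' @return A \linkS4class{SignatureSet}.
#' @export
SignatureSet <- function(profiles) {
  p <- .orientToSamplesByChannels(profiles)
  if (any(p < 0)) stop("negative signature profile entries")
  s <- rowSums(p)
  bad <- abs(s - 1) > 1e-6
  if (any(bad)) {
    stop("signature profile(s) not summing to 1 (beyond 1e-6): ",
         paste(rownames(p)[bad], collapse = ", "))
  }
  new("SignatureSet", profiles = p / s)
}

# ---------------------------------------------------------- modulatory fit ----

#' ModulatoryFit: a modulatory process and its per-sample activities
#'
#' A global modulatory profile \code{r} (one multiplier per channel) together
#' with non-negative per-sample activities \code{c}; the induced per-sample
#' modulation factors are \code{p[k, j] = 1 + c[k] * r[j]}, which must be
#' non-negative (feasibility).
#'
#' @slot r Numeric vector over channels, the modulatory profile.
#' @slot c Numeric vector of per-sample activities, all \code{>= 0}.
#' @export
setClass("ModulatoryFit", representation(r = "numeric", c = "numeric"))

setValidity("ModulatoryFit", function(object) {
  r <- object@r; cc <- object@c
  if (!length(r)) return("r must be non-empty")
  if (any(!is.finite(r)) || any(!is.finite(cc))) {
    return("r and c must be finite")
  }
  if (any(cc < 0)) return("modulatory activities c must be non-negative")
  if (length(cc) && min(1 + outer(cc, r)) < -1e-8) {
    return("infeasible fit: some 1 + c*r < 0")
  }
  TRUE
})

#' Construct a ModulatoryFit
#'
#' @param r Numeric modulatory profile (typically length 96, named by
#'   channel).
#' @param c Numeric non-negative per-sample activities (possibly empty when
#'   the object only carries a profile).
#' @param gauge If \code{TRUE}, apply the gauge fix (\code{max(abs(r)) == 1})
#'   before constructing.
#' @return A \linkS4class{ModulatoryFit}.
#' @export
#' @examples
#' fit <- ModulatoryFit(r = c(0.5, -0.25), c = 2, gauge = TRUE)
#' modProfile(fit)
ModulatoryFit <- function(r, c = numeric(), gauge = FALSE) {
  obj <- new("ModulatoryFit",
             r = structure(as.numeric(r), names = names(r)),
             c = structure(as.numeric(c), names = names(c)))
  if (gauge) gaugeFix(obj) else obj
}

# --------------------------------------------------------------- residuals ----

#' ResidualMatrix: per-sample residual profiles
#'
#' Additive residuals are observed minus predicted counts; multiplicative
#' residuals are the ratio of (pseudo-counted) observed over predicted.
#'
#' @slot flavour Either \code{"additive"} or \code{"multiplicative"}.
#' @slot values Numeric matrix, samples x 96.
#' @export
setClass("ResidualMatrix",
         representation(flavour = "character", values = "matrix"))

setValidity("ResidualMatrix", function(object) {
  if (!object@flavour %in% c("additive", "multiplicative")) {
    return("flavour must be 'additive' or 'multiplicative'")
  }
  v <- object@values
  if (!is.numeric(v) || any(!is.finite(v))) return("values must be finite")
  if (object@flavour == "multiplicative" && any(v <= 0)) {
    return("multiplicative residuals must be strictly positive")
  }
  TRUE
})

# ------------------------------------------------------ cluster assignment ----

#' ClusterAssignment: flat clusters from residual-correlation clustering
#'
#' @slot labels Integer cluster id per sample (named by sample id).
#' @slot threshold The correlation threshold at which the dendrogram was cut.
#' @slot ordering Integer permutation of samples induced by the dendrogram
#'   leaf order (for heat-map rendering).
#' @slot tree The underlying \code{hclust} object.
#' @export
setClass("ClusterAssignment",
         representation(labels = "integer", threshold = "numeric",
                        ordering = "integer", tree = "ANY"))

setValidity("ClusterAssignment", function(object) {
  n <- length(object@labels)
  if (any(is.na(object@labels))) return("every sample must get a cluster")
  if (!identical(sort(object@ordering), seq_len(n))) {
    return("ordering must be a permutation of the samples")
  }
  TRUE
})

# -------------------------------------------------------------- fit result ----

#' ModSigFit: result of the alternating maximum-likelihood fit
#'
#' @slot activities Samples x signatures matrix of additive activities under
#'   the extended (modulated) model.
#' @slot additiveActivities The plain additive refit (modulation inactive).
#' @slot modulatory The fitted, gauged \linkS4class{ModulatoryFit}.
#' @slot logLik Maximised extended-model Poisson log-likelihood (the
#'   \code{log(X!)} constant dropped).
#' @slot additiveLogLik Maximised additive-model log-likelihood (same
#'   constant dropped).
#' @slot gain \code{logLik - additiveLogLik}; non-negative up to optimizer
#'   tolerance.
#' @slot converged Whether every optimisation step reported convergence.
#' @slot nRestarts Total number of random restarts consumed.
#' @slot trace Recorded log-likelihood after each half-step of the
#'   alternating loop.
#' @export
setClass("ModSigFit",
         representation(activities = "matrix", additiveActivities = "matrix",
                        modulatory = "ModulatoryFit", logLik = "numeric",
                        additiveLogLik = "numeric", gain = "numeric",
                        converged = "logical", nRestarts = "integer",
                        trace = "numeric"))
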