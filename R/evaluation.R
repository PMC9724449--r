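#' Cosine similarity
#'
#' @param u,v Numeric vectors of equal length, at least one entry non-zero
#'   each.
#' @return \code{sum(u*v) / (||u|| * ||v||)}, in [-1, 1].
#' @export
#' @examples
#' cosineSimilarity(c(1, 1), c(1, 0))  # 1/sqrt(2)
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vector")
  sum(u * v) / (nu * nv)
}

#' Mean squared error
#'
#' @param estimate,truth Numeric vectors or matrices of identical shape.
#' @return Mean of squared element-wise differences.
#' @export
mse <- function(estimate, truth) {
  if (!identical(dim(estimate), dim(truth)) ||
      length(estimate) != length(truth)) {
    stop("shape mismatch")
  }
  mean((as.numeric(estimate) - as.numeric(truth))^2)
}

#' Modulation impact profile
#'
#' The channel-wise mean modulation factor over samples,
#' \code{<1 + c_k * r_j>_k} — how much, on average, each channel's additive
#' prediction is rescaled. All ones when the process is inactive. Invariant
#' under re-gauging.
#'
#' @param fit A \linkS4class{ModulatoryFit}.
#' @return Named numeric vector over channels, entries \code{>= 0}.
#' @export
impactProfile <- function(fit) {
  stopifnot(is(fit, "ModulatoryFit"))
  if (!length(modActivities(fit))) {
    stop("fit carries no sample activities")
  }
  colMeans(modulationFactors(fit))
}

#' Per-group fit report
#'
#' Summarises one fitted extended model per group (typically per cancer
#' type): total log-likelihood gain, gain normalised by the group's mutation
#' count, the modulation impact profile, and the MSE of predicted vs observed
#' counts under the additive and extended models (computed on raw counts, as
#' the likelihood is). Groups are sorted descending by normalised gain.
#'
#' @param observed A \linkS4class{MutationCatalog} covering all samples.
#' @param signatures The \linkS4class{SignatureSet} used for the fits.
#' @param fits Named list of \linkS4class{ModSigFit}, one per group; names
#'   are the group labels.
#' @param groups Per-sample group labels aligned with \code{observed}.
#' @return A list with \code{table} (data.frame: \code{group},
#'   \code{nSamples}, \code{gain}, \code{gainPerMutation},
#'   \code{mseAdditive}, \code{mseExtended}, \code{mseRatio}, sorted
#'   descending by \code{gainPerMutation}), \code{impact} (groups x 96
#'   matrix) and \code{mseByClass} (list of per-base-class additive/extended
#'   MSE matrices, 6 x 2 per group).
#' @export
groupReport <- function(observed, signatures, fits, groups) {
  X <- .countsOf(observed)
  if (length(groups) != nrow(X)) stop("groups must align with samples")
  if (is.null(names(fits)) || !all(names(fits) %in% unique(groups))) {
    stop("fits must be a named list keyed by group label")
  }
  mu <- .sigProfiles(signatures)
  cls <- channelBaseClass(colnames(X))
  rows <- list(); impact <- list(); mseByClass <- list()
  for (g in names(fits)) {
    fit <- fits[[g]]
    if (!is(fit, "ModSigFit")) stop("no fit for group ", g)
    Xg <- X[groups == g, , drop = FALSE]
    addPred <- additiveReconstruction(additiveActivities(fit), mu)
    extPred <- additiveReconstruction(activities(fit), mu) *
      modulationFactors(modulatoryFit(fit))
    mseAdd <- mse(addPred, Xg)
    mseExt <- mse(extPred, Xg)
    nMut <- sum(Xg)
    rows[[g]] <- data.frame(group = g, nSamples = nrow(Xg),
                            gain = logLikGain(fit),
                            gainPerMutation = logLikGain(fit) / nMut,
                            mseAdditive = mseAdd, mseExtended = mseExt,
                            mseRatio = mseExt / mseAdd)
    impact[[g]] <- impactProfile(modulatoryFit(fit))
    mseByClass[[g]] <- t(vapply(sbsBaseClasses(), function(b) {
      j <- cls == b
      c(additive = mse(addPred[, j, drop = FALSE], Xg[, j, drop = FALSE]),
        extended = mse(extPred[, j, drop = FALSE], Xg[, j, drop = FALSE]))
    }, numeric(2L)))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$gainPerMutation), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, impact = do.call(rbind, impact),
       mseByClass = mseByClass)
}

#' Cluster per-group modulatory profiles
#'
#' Complete-linkage clustering of group-level modulatory profiles on the
#' distance \code{1 - correlation}, for comparing modulatory signatures
#' across cancer types.
#'
#' @param profiles Groups x channels matrix of modulatory profiles.
#' @return An \code{hclust} object.
#' @export
clusterModulatoryProfiles <- function(profiles) {
  if (nrow(profiles) < 2L) stop("need at least 2 profiles")
  stats::hclust(stats::as.dist(1 - stats::cor(t(profiles))),
                method = "complete")
}
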