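#' Sample-by-sample correlation of residual profiles
#'
#' Pearson (default) or Spearman correlation between the per-sample residual
#' profiles, the similarity used for residual clustering. Samples with a
#' constant residual profile have undefined correlations; those pairs are set
#' to 0 with a warning.
#'
#' @param residuals A \linkS4class{ResidualMatrix} (or samples x channels
#'   matrix).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return Symmetric samples x samples correlation matrix with unit diagonal.
#' @export
residualCorrelationMatrix <- function(residuals,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- if (is(residuals, "ResidualMatrix")) residualValues(residuals)
       else as.matrix(residuals)
  if (nrow(v) < 2L) stop("need at least 2 samples")
  sds <- apply(v, 1L, stats::sd)
  cm <- suppressWarnings(stats::cor(t(v), method = method))
  if (any(sds == 0)) {
    warning("constant residual profile(s); correlations involving them set ",
            "to 0")
    cm[sds == 0, ] <- 0
    cm[, sds == 0] <- 0
  }
  diag(cm) <- 1
  cm
}

#' Cluster samples by residual correlation
#'
#' Complete-linkage (farthest neighbour) hierarchical clustering on the
#' distance \code{1 - correlation}; flat clusters are cut at the distance
#' corresponding to the correlation \code{threshold} (so threshold 0.75 cuts
#' at height 0.25). Clustering uses the unclipped correlations; clipping to
#' [0, 1] is a display concern only.
#'
#' @param corr Symmetric correlation matrix as from
#'   \code{\link{residualCorrelationMatrix}}.
#' @param threshold Correlation threshold for the flat cut, default 0.75.
#' @return A \linkS4class{ClusterAssignment} with per-sample labels and the
#'   dendrogram leaf ordering (for heat-map rendering).
#' @export
clusterByResidualCorrelation <- function(corr, threshold = 0.75) {
  corr <- as.matrix(corr)
  if (!isSymmetric(unname(corr), tol = 1e-8)) {
    stop("correlation matrix must be symmetric")
  }
  d <- stats::as.dist(1 - corr)
  tree <- stats::hclust(d, method = "complete")
  labels <- stats::cutree(tree, h = 1 - threshold)
  new("ClusterAssignment",
      labels = structure(as.integer(labels), names = rownames(corr)),
      threshold = threshold, ordering = as.integer(tree$order), tree = tree)
}

#' Entropy summary of residual-correlation clusters
#'
#' For every cluster with at least \code{minSize} samples, computes the label
#' entropy \code{S = -sum(p_i * log(p_i))} over the cancer-type frequencies
#' inside the cluster. \code{S = 0} iff a single type is present; low-entropy
#' clusters are the cancer-type-specific ones.
#'
#' @param assignment A \linkS4class{ClusterAssignment}.
#' @param labels Per-sample cancer-type labels, aligned with the samples that
#'   were clustered.
#' @param minSize Minimum cluster size to report (default 10).
#' @param base Logarithm base for the entropy; default \code{exp(1)}
#'   (natural log).
#' @param residuals Optional \linkS4class{ResidualMatrix} (or list of them);
#'   if given, mean residual profiles per cluster are attached as the
#'   \code{"meanResidualProfiles"} attribute.
#' @return A \code{data.frame} with one row per qualifying cluster — columns
#'   \code{cluster}, \code{size}, \code{entropy} and a list-column
#'   \code{composition} (named label counts) — sorted ascending by entropy.
#' @export
clusterEntropy <- function(assignment, labels, minSize = 10,
                           base = exp(1), residuals = NULL) {
  stopifnot(is(assignment, "ClusterAssignment"))
  cl <- clusterLabels(assignment)
  if (length(labels) != length(cl)) {
    stop("labels must align with the clustered samples")
  }
  labels <- as.character(labels)
  ids <- sort(unique(cl))
  rows <- lapply(ids, function(id) {
    in_cl <- cl == id
    if (sum(in_cl) < minSize) return(NULL)
    freq <- table(labels[in_cl])
    p <- as.numeric(freq) / sum(freq)
    S <- -sum(p * log(p, base = base))
    list(cluster = id, size = sum(in_cl), entropy = S,
         composition = list(structure(as.integer(freq), names = names(freq))))
  })
  rows <- Filter(Negate(is.null), rows)
  out <- data.frame(cluster = vapply(rows, `[[`, 0L, "cluster"),
                    size = vapply(rows, `[[`, 0L, "size"),
                    entropy = vapply(rows, `[[`, 0, "entropy"))
  out$composition <- lapply(rows, function(r) r$composition[[1L]])
  out <- out[order(out$entropy), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(residuals)) {
    if (is(residuals, "ResidualMatrix")) residuals <- list(residuals)
    attr(out, "meanResidualProfiles") <- lapply(residuals, function(res) {
      v <- residualValues(res)
      t(vapply(out$cluster, function(id) colMeans(v[cl == id, , drop = FALSE]),
               numeric(ncol(v))))
    })
  }
  out
}
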