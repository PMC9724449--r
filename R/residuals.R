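#' Residuals between observed and model-predicted catalogues
#'
#' Additive residuals are \code{X - Xt}; multiplicative residuals are
#' \code{(X + pc) / (Xt + pc)} with a pseudo-count \code{pc} added to both
#' numerator and denominator so the ratio stays finite and positive.
#'
#' @param observed A \linkS4class{MutationCatalog} or count matrix.
#' @param predicted Samples x channels matrix of model-predicted counts.
#' @param flavour \code{"additive"} or \code{"multiplicative"}.
#' @param pseudocount Pseudo-count for the multiplicative flavour (default 1;
#'   ignored for additive residuals).
#' @return A \linkS4class{ResidualMatrix}.
#' @export
#' @examples
#' sigs <- SignatureSet(matrix(1 / 96, 1, 96,
#'                             dimnames = list("flat", sbsChannels())))
#' X <- matrix(rpois(96, 10), 1, dimnames = list("s1", sbsChannels()))
#' pred <- additiveReconstruction(matrix(sum(X), 1, 1), sigs)
#' computeResiduals(MutationCatalog(X), pred, "multiplicative")
computeResiduals <- function(observed, predicted,
                             flavour = c("additive", "multiplicative"),
                             pseudocount = 1) {
  flavour <- match.arg(flavour)
  X <- .countsOf(observed)
  Xt <- as.matrix(predicted)
  if (!identical(dim(X), dim(Xt))) stop("shape mismatch")
  v <- if (flavour == "additive") {
    X - Xt
  } else {
    if (pseudocount <= 0 && any(Xt <= 0)) {
      stop("zero predicted value in multiplicative residual without a ",
           "pseudo-count")
    }
    (X + pseudocount) / (Xt + pseudocount)
  }
  dimnames(v) <- dimnames(X)
  new("ResidualMatrix", flavour = flavour, values = v)
}

#' Poisson-resampled null-control catalogue
#'
#' Redraws every count from a Poisson distribution whose rate is the observed
#' count, emulating a model that explains the data perfectly up to counting
#' noise. Residuals of such a control against its own generating rates carry
#' essentially no correlation structure, giving the null for the residual
#' clustering.
#'
#' @param catalog A \linkS4class{MutationCatalog}.
#' @param seed Integer seed for reproducibility.
#' @return A new \linkS4class{MutationCatalog} of resampled counts.
#' @export
poissonResampleControl <- function(catalog, seed) {
  stopifnot(is(catalog, "MutationCatalog"))
  X <- mutationCounts(catalog)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  Y <- matrix(stats::rpois(length(X), lambda = X), nrow(X), ncol(X),
              dimnames = dimnames(X))
  new("MutationCatalog", counts = Y, cancerType = cancerType(catalog))
}
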