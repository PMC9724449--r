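## Core model: additive reconstruction, Poisson log-likelihood of the
## extended (modulated) model, its analytic gradients and the gauge fix.
##
## Model: X[k, j] ~ Pois(p[k, j] * Xt[k, j]) with
##   Xt[k, j] = sum_i a[k, i] * mu[i, j]   (additive reconstruction)
##   p[k, j]  = 1 + c[k] * r[j]            (modulation factors)
## The log(X!) term is an additive constant in the parameters and is dropped
## from all reported log-likelihoods; likelihood *gains* are unaffected.

.RATE_EPS <- 1e-9

## internal: pull the count matrix out of a catalog or pass a matrix through
.countsOf <- function(observed) {
  if (is(observed, "MutationCatalog")) mutationCounts(observed)
  else as.matrix(observed)
}

#' Additive reconstruction of a mutation catalogue
#'
#' Computes the additive (NMF-style) predicted counts
#' \code{Xt = activities \%*\% profiles}.
#'
#' @param activities Samples x signatures matrix of non-negative activities.
#' @param signatures A \linkS4class{SignatureSet} (or a signatures x channels
#'   probability matrix).
#' @return Samples x channels matrix of predicted counts, all \code{>= 0}.
#' @export
#' @examples
#' sigs <- SignatureSet(matrix(1 / 96, 1, 96,
#'                             dimnames = list("flat", sbsChannels())))
#' additiveReconstruction(matrix(96, 1, 1), sigs)[1, 1:3]
additiveReconstruction <- function(activities, signatures) {
  mu <- if (is(signatures, "SignatureSet")) signatureProfiles(signatures)
        else as.matrix(signatures)
  a <- as.matrix(activities)
  if (ncol(a) != nrow(mu)) {
    stop("activities (", ncol(a), " signatures) do not conform with the ",
         "signature set (", nrow(mu), ")")
  }
  if (any(a < 0)) stop("activities must be non-negative")
  a %*% mu
}

#' Modulation factor matrix of a fit
#'
#' @param fit A \linkS4class{ModulatoryFit}.
#' @return Samples x channels matrix \code{p[k, j] = 1 + c[k] * r[j]}, all
#'   entries non-negative.
#' @export
modulationFactors <- function(fit) {
  stopifnot(is(fit, "ModulatoryFit"))
  p <- 1 + outer(modActivities(fit), modProfile(fit))
  if (min(p) < -1e-8) stop("infeasible fit: some 1 + c*r < 0")
  pmax(p, 0)
}

#' Poisson log-likelihood of the extended model
#'
#' \code{sum_k sum_j [-p*Xt + X*log(p*Xt)]}, the \code{log(X!)} constant
#' dropped. Cells with \code{X = 0} contribute only \code{-p*Xt}. A zero rate
#' under a positive count is an error (the likelihood is \code{-Inf} there).
#'
#' @param observed A \linkS4class{MutationCatalog} or count matrix.
#' @param additive Samples x channels matrix of additive predictions
#'   \code{Xt}.
#' @param fit A \linkS4class{ModulatoryFit}, or \code{NULL} for the plain
#'   additive model (all \code{p = 1}).
#' @return A single number.
#' @export
logLikelihood <- function(observed, additive, fit = NULL) {
  X <- .countsOf(observed)
  Xt <- as.matrix(additive)
  if (!identical(dim(X), dim(Xt))) stop("shape mismatch")
  rate <- if (is.null(fit)) Xt else modulationFactors(fit) * Xt
  pos <- X > 0
  if (any(rate[pos] <= 0)) {
    stop("zero model rate with positive observed count: log-likelihood is ",
         "-Inf")
  }
  -sum(rate) + sum(X[pos] * log(rate[pos]))
}

## internal: clamped log-likelihood used inside optimizers (keeps the
## objective finite near the feasibility boundary without materially moving
## the optimum; cells with X = 0 and rate 0 are exact)
.logLikClamped <- function(X, rate) {
  rate <- pmax(rate, .RATE_EPS)
  -sum(rate) + sum(X[X > 0] * log(rate[X > 0]))
}

#' Analytic gradient of the log-likelihood w.r.t. the additive activities
#'
#' \code{dL/da[k, i] = sum_j (X*mu/Xt - p*mu)}.
#'
#' @param observed Catalog or count matrix.
#' @param signatures A \linkS4class{SignatureSet} or profile matrix.
#' @param activities Samples x signatures activity matrix at which to
#'   evaluate.
#' @param fit \linkS4class{ModulatoryFit} or \code{NULL} (no modulation).
#' @return Samples x signatures gradient matrix.
#' @export
gradActivities <- function(observed, signatures, activities, fit = NULL) {
  X <- .countsOf(observed)
  mu <- if (is(signatures, "SignatureSet")) signatureProfiles(signatures)
        else as.matrix(signatures)
  Xt <- additiveReconstruction(activities, mu)
  p <- if (is.null(fit)) matrix(1, nrow(X), ncol(X)) else
    modulationFactors(fit)
  ratio <- X / pmax(Xt, .RATE_EPS)
  if (any(X > 0 & Xt <= 0)) {
    stop("zero additive prediction with positive observed count")
  }
  ratio %*% t(mu) - p %*% t(mu)
}

#' Analytic gradient w.r.t. the modulatory profile r
#'
#' \code{dL/dr[j] = sum_k (X*c/p - c*Xt)}.
#'
#' @param observed Catalog or count matrix.
#' @param additive Samples x channels additive prediction \code{Xt}.
#' @param fit A \linkS4class{ModulatoryFit}.
#' @return Gradient vector over channels.
#' @export
gradModulatoryProfile <- function(observed, additive, fit) {
  X <- .countsOf(observed)
  Xt <- as.matrix(additive)
  cc <- modActivities(fit)
  p <- pmax(1 + outer(cc, modProfile(fit)), .RATE_EPS)
  colSums(cc * (X / p)) - colSums(cc * Xt)
}

#' Analytic gradient w.r.t. the modulatory activities c
#'
#' \code{dL/dc[k] = sum_j (X*r/p - r*Xt)}. At the feasibility boundary
#' (\code{p = 0} with \code{X = 0}) the term-wise limit \code{-r*Xt} applies.
#'
#' @inheritParams gradModulatoryProfile
#' @return Gradient vector over samples.
#' @export
gradModulatoryActivity <- function(observed, additive, fit) {
  X <- .countsOf(observed)
  Xt <- as.matrix(additive)
  r <- modProfile(fit)
  p <- pmax(1 + outer(modActivities(fit), r), .RATE_EPS)
  as.vector((X / p) %*% r) - as.vector(Xt %*% r)
}

#' Gauge fixing of a modulatory fit
#'
#' Only the product \code{c * r} enters the model, so (r, c) carry a scale
#' degeneracy. The gauge divides \code{r}, and multiplies \code{c}, by
#' \code{max(abs(r))}, leaving every modulation factor \code{p} (and hence the
#' likelihood) unchanged while enforcing \code{max(abs(r)) == 1}. An
#' identically zero profile is returned with all activities forced to 0.
#'
#' @param fit A \linkS4class{ModulatoryFit}.
#' @return The gauged \linkS4class{ModulatoryFit}.
#' @export
#' @examples
#' f <- ModulatoryFit(r = c(0.5, -0.25), c = 2)
#' g <- gaugeFix(f)
#' modProfile(g); modActivities(g)
gaugeFix <- function(fit) {
  stopifnot(is(fit, "ModulatoryFit"))
  r <- modProfile(fit); cc <- modActivities(fit)
  m <- max(abs(r))
  if (m == 0) {
    return(new("ModulatoryFit", r = r, c = cc * 0))
  }
  new("ModulatoryFit", r = r / m, c = cc * m)
}
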