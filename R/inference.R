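## Maximum-likelihood fitting.
##
## fitActivities : per-sample bound-constrained (a >= 0) quasi-Newton ascent
##                 of the Poisson log-likelihood (signatures held fixed).
## fitModulatory : joint bound-constrained ascent over (r, c), r in [-1, 1],
##                 c >= 0, with the gauge re-applied between optimizer rounds.
## alternatingFit: coordinate ascent alternating the two, with random
##                 restarts on failed convergence.
##
## All optimizers are L-BFGS-B (a bound-constrained quasi-Newton method) fed
## the analytic gradients of model.R.

#' Fitting configuration
#'
#' @param maxRestarts Maximum random restarts for a failed optimisation
#'   (default 100).
#' @param nAlternations Alternating activity / modulatory rounds (default 3).
#' @param gradientTolerance Convergence tolerance passed to the optimizer
#'   (\code{pgtol}).
#' @param seed Integer seed; every stochastic step of a fit derives from it.
#' @param maxit Iteration cap per optimizer call.
#' @param minGainImprovement Early-stop threshold for the outer loop: stop
#'   when an alternation improves the log-likelihood by less than this.
#' @return A list of class \code{"fitConfig"}.
#' @export
fitConfig <- function(maxRestarts = 100L, nAlternations = 3L,
                      gradientTolerance = 1e-6, seed = 1L, maxit = 500L,
                      minGainImprovement = 1e-4) {
  stopifnot(maxRestarts >= 1L, nAlternations >= 1L)
  structure(list(maxRestarts = as.integer(maxRestarts),
                 nAlternations = as.integer(nAlternations),
                 gradientTolerance = gradientTolerance,
                 seed = as.integer(seed), maxit = as.integer(maxit),
                 minGainImprovement = minGainImprovement),
            class = "fitConfig")
}

.sigProfiles <- function(signatures) {
  if (is(signatures, "SignatureSet")) signatureProfiles(signatures)
  else as.matrix(signatures)
}

## internal: one per-sample activity optimisation with restarts.
## x: 96 counts; mu: nsig x 96; p: 96 modulation factors; a0: init.
.fitActivitiesSample <- function(x, mu, p, a0, config) {
  nsig <- nrow(mu)
  if (all(x == 0)) {
    return(list(a = numeric(nsig), converged = TRUE, restarts = 0L))
  }
  fn <- function(a) {
    Xt <- as.vector(a %*% mu)
    -.logLikClamped(x, p * Xt)
  }
  gr <- function(a) {
    Xt <- pmax(as.vector(a %*% mu), .RATE_EPS)
    -(as.vector(mu %*% (x / Xt)) - as.vector(mu %*% p))
  }
  init <- pmax(a0, 0)
  restarts <- 0L
  repeat {
    o <- stats::optim(init, fn, gr, method = "L-BFGS-B", lower = 0,
                      control = list(maxit = config$maxit,
                                     pgtol = config$gradientTolerance))
    if (o$convergence == 0L || restarts >= config$maxRestarts) break
    restarts <- restarts + 1L
    init <- stats::runif(nsig) * sum(x) / nsig
  }
  # L-BFGS-B can sit a rounding error below the bound
  list(a = pmax(o$par, 0), converged = o$convergence == 0L,
       restarts = restarts)
}

#' Refit additive signature activities
#'
#' Maximises the Poisson log-likelihood over the non-negative per-sample
#' activities with the signature profiles held fixed — the plain additive
#' refit when \code{modulatory} is \code{NULL}, or the activity half-step of
#' the extended model when a modulatory fit is supplied. Samples are
#' independent.
#'
#' @param observed A \linkS4class{MutationCatalog} or count matrix.
#' @param signatures A \linkS4class{SignatureSet}.
#' @param modulatory A \linkS4class{ModulatoryFit} fixed during this step, or
#'   \code{NULL}.
#' @param config A \code{\link{fitConfig}}.
#' @param init Optional warm-start activity matrix; by default a non-negative
#'   least-squares fit of the pseudo-counted catalogue.
#' @return Samples x signatures activity matrix, with attributes
#'   \code{"converged"} (logical) and \code{"restarts"} (integer).
#' @export
fitActivities <- function(observed, signatures, modulatory = NULL,
                          config = fitConfig(), init = NULL) {
  X <- .countsOf(observed)
  mu <- .sigProfiles(signatures)
  nS <- nrow(X); nsig <- nrow(mu)
  P <- if (is.null(modulatory)) matrix(1, nS, ncol(X)) else
    modulationFactors(modulatory)
  A <- matrix(0, nS, nsig, dimnames = list(rownames(X), rownames(mu)))
  conv <- TRUE; restarts <- 0L
  muT <- t(mu)
  for (k in seq_len(nS)) {
    a0 <- if (is.null(init)) {
      pracma::lsqnonneg(muT, (X[k, ] + 1) / pmax(P[k, ], .RATE_EPS))$x
    } else init[k, ]
    res <- .fitActivitiesSample(X[k, ], mu, P[k, ], a0, config)
    A[k, ] <- res$a
    conv <- conv && res$converged
    restarts <- restarts + res$restarts
  }
  structure(A, converged = conv, restarts = restarts)
}

#' Fit the modulatory process given fixed activities
#'
#' Joint bound-constrained gradient ascent over the modulatory profile
#' \code{r} (box \code{[-1, 1]}) and activities \code{c >= 0}, maximising the
#' extended-model Poisson log-likelihood with the additive reconstruction
#' held fixed. The gauge is re-applied between optimizer rounds, and the
#' returned fit is gauged (\code{max(abs(r)) == 1}, or \code{r = 0} with all
#' \code{c = 0}). Initialisation is the centred mean multiplicative residual
#' of the current additive fit (gauged), with \code{c = 0.5}; failed
#' convergence triggers uniform random restarts.
#'
#' @param observed A \linkS4class{MutationCatalog} or count matrix.
#' @param signatures A \linkS4class{SignatureSet}.
#' @param activities Samples x signatures activity matrix, fixed during this
#'   step.
#' @param config A \code{\link{fitConfig}}.
#' @param init Optional \linkS4class{ModulatoryFit} warm start.
#' @return A gauged \linkS4class{ModulatoryFit} with attributes
#'   \code{"converged"}, \code{"restarts"} and \code{"logLik"}.
#' @export
fitModulatory <- function(observed, signatures, activities,
                          config = fitConfig(), init = NULL) {
  X <- .countsOf(observed)
  mu <- .sigProfiles(signatures)
  Xt <- additiveReconstruction(activities, mu)
  nS <- nrow(X); nC <- ncol(X)

  fn <- function(th) {
    p <- 1 + outer(th[(nC + 1):(nC + nS)], th[1:nC])
    -.logLikClamped(X, p * Xt)
  }
  gr <- function(th) {
    r <- th[1:nC]; cc <- th[(nC + 1):(nC + nS)]
    p <- pmax(1 + outer(cc, r), .RATE_EPS)
    grad_r <- colSums(cc * (X / p)) - colSums(cc * Xt)
    grad_c <- as.vector((X / p) %*% r) - as.vector(Xt %*% r)
    -c(grad_r, grad_c)
  }

  if (is.null(init)) {
    mres <- colMeans((X + 1) / (Xt + 1))
    r0 <- mres - mean(mres)
    if (max(abs(r0)) > 0) r0 <- r0 / max(abs(r0))
    c0 <- rep(0.5, nS)
  } else {
    r0 <- pmin(pmax(modProfile(init), -1), 1)
    c0 <- modActivities(init)
  }

  lower <- c(rep(-1, nC), rep(0, nS))
  upper <- c(rep(1, nC), rep(Inf, nS))
  restarts <- 0L
  repeat {
    th <- c(r0, c0)
    ok <- TRUE
    # re-gauge between optimizer rounds to keep r on its natural scale
    for (round in 1:5) {
      o <- stats::optim(th, fn, gr, method = "L-BFGS-B", lower = lower,
                        upper = upper,
                        control = list(maxit = config$maxit,
                                       pgtol = config$gradientTolerance))
      ok <- o$convergence == 0L
      r <- o$par[1:nC]; cc <- o$par[(nC + 1):(nC + nS)]
      m <- max(abs(r))
      if (m == 0) { cc <- cc * 0 } else { r <- r / m; cc <- cc * m }
      # project back into the feasible set (the clamp lets the optimizer
      # drift into 1 + c*r < 0 only across cells with zero counts)
      if (min(r) < 0) cc <- pmin(cc, (1 - 1e-9) / (-min(r)))
      if (abs(m - 1) < 1e-8) { th <- c(r, cc); break }
      th <- c(r, cc)
    }
    if (ok || restarts >= config$maxRestarts) break
    restarts <- restarts + 1L
    r0 <- stats::runif(nC, -1, 1)
    c0 <- stats::runif(nS)
  }
  fit <- new("ModulatoryFit",
             r = structure(th[1:nC], names = colnames(X)),
             c = structure(pmax(th[(nC + 1):(nC + nS)], 0),
                           names = rownames(X)))
  fit <- gaugeFix(fit)
  structure(fit, converged = ok, restarts = restarts, logLik = -o$value)
}

#' Alternating maximum-likelihood fit of the extended model
#'
#' Coordinate ascent: refit the additive activities, then the modulatory
#' process, alternating \code{nAlternations} times (each half-step maximises
#' its own block, so the recorded log-likelihood trace is non-decreasing up
#' to optimizer tolerance). The plain additive refit obtained before any
#' modulation is kept for model comparison; if the extended fit fails to
#' improve on it the additive solution is returned with a null modulatory
#' process (the models are nested through \code{c = 0}). Deterministic given
#' \code{config$seed}.
#'
#' @param observed A \linkS4class{MutationCatalog} or count matrix.
#' @param signatures A \linkS4class{SignatureSet}.
#' @param config A \code{\link{fitConfig}}.
#' @return A \linkS4class{ModSigFit}.
#' @export
alternatingFit <- function(observed, signatures, config = fitConfig()) {
  X <- .countsOf(observed)
  mu <- .sigProfiles(signatures)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  A_add <- fitActivities(X, mu, NULL, config)
  llAdd <- logLikelihood(X, additiveReconstruction(A_add, mu), NULL)
  conv <- attr(A_add, "converged"); restarts <- attr(A_add, "restarts")

  A <- A_add
  fit <- NULL
  trace <- llAdd
  llPrev <- llAdd
  for (alt in seq_len(config$nAlternations)) {
    fit <- fitModulatory(X, mu, A, config, init = fit)
    conv <- conv && attr(fit, "converged")
    restarts <- restarts + attr(fit, "restarts")
    trace <- c(trace, logLikelihood(X, additiveReconstruction(A, mu), fit))
    A <- fitActivities(X, mu, fit, config, init = A)
    conv <- conv && attr(A, "converged")
    restarts <- restarts + attr(A, "restarts")
    ll <- logLikelihood(X, additiveReconstruction(A, mu), fit)
    trace <- c(trace, ll)
    if (ll - llPrev < config$minGainImprovement && alt > 1L) break
    llPrev <- ll
  }
  llExt <- trace[length(trace)]

  if (llExt < llAdd) {
    # nested fallback: modulation off
    fit <- new("ModulatoryFit",
               r = structure(numeric(ncol(X)), names = colnames(X)),
               c = structure(numeric(nrow(X)), names = rownames(X)))
    A <- A_add
    llExt <- llAdd
  }
  new("ModSigFit", activities = unclassAttr(A),
      additiveActivities = unclassAttr(A_add),
      modulatory = ModulatoryFit(r = modProfile(fit),
                                 c = modActivities(fit)),
      logLik = llExt, additiveLogLik = llAdd, gain = llExt - llAdd,
      converged = conv, nRestarts = as.integer(restarts), trace = trace)
}

## strip the bookkeeping attributes from an activity matrix
unclassAttr <- function(A) {
  attr(A, "converged") <- NULL
  attr(A, "restarts") <- NULL
  A
}

#' Additive vs extended model comparison
#'
#' The extended model adds 96 profile parameters plus one activity per
#' sample. \code{deltaBIC = 2 * gain - (96 + nSamples) * log(nObs)} with
#' \code{nObs} the number of observation cells (samples x channels); positive
#' values favour the extended model. Also reports the gain per mutation.
#'
#' @param result A \linkS4class{ModSigFit}.
#' @param observed The catalogue the model was fitted to.
#' @return A one-row \code{data.frame} with columns \code{gain},
#'   \code{deltaBIC}, \code{gainPerMutation}, \code{nSamples},
#'   \code{nMutations}.
#' @export
modelComparison <- function(result, observed) {
  stopifnot(is(result, "ModSigFit"))
  X <- .countsOf(observed)
  nS <- nrow(X); nC <- ncol(X)
  nObs <- nS * nC
  nMut <- sum(X)
  gain <- result@gain
  data.frame(gain = gain,
             deltaBIC = 2 * gain - (nC + nS) * log(nObs),
             gainPerMutation = gain / nMut,
             nSamples = nS, nMutations = nMut)
}
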