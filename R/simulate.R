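## Synthetic-catalogue simulator: the package's test bed and benchmark.
##
## Per dataset: a pool of 10 COSMIC-like signatures, 100 samples each with 4
## active signatures and log-normal activities, one structured modulatory
## profile r (two base classes modulated with opposite signs, U(0,1)
## magnitudes, N(0, 0.05) channel noise, gauged), per-sample activities
## c ~ U(0,1), and Poisson draws from rates (1 + c*r) * (a %*% mu).

#' Simulation configuration
#'
#' Defaults reproduce the benchmark protocol: 50 datasets of 100 samples,
#' 10-signature pools with 4 active per sample, log-normal activities with
#' sdlog 1.5, structured modulatory profiles with channel noise sd 0.05 and
#' activities c from U(0, 1).
#'
#' The location of the activity distribution (\code{activityMeanLog}) is set
#' so that the expected per-sample burden, \code{nActivePerSample *
#' exp(activityMeanLog + activitySdLog^2 / 2)}, matches the PCAWG average of
#' about 17,366 SBS per whole genome (48,276,930 mutations over 2,780
#' samples) — the corpus the simulator emulates.
#'
#' @param nDatasets Number of independent benchmark datasets (default 50).
#' @param nSamples Samples per dataset (default 100).
#' @param nSignaturesPool Signatures per pool (default 10).
#' @param nActivePerSample Active signatures per sample (default 4).
#' @param activityMeanLog Mean of the underlying normal for activities;
#'   default anchored to the PCAWG mean burden (see Details).
#' @param activitySdLog Sd of the underlying normal (default 1.5).
#' @param modulationNoiseSd Sd of the Gaussian channel noise added to the
#'   structured modulatory profile (default 0.05).
#' @param concentration Symmetric Dirichlet concentration for synthetic
#'   signature pools; values below 1 give the sparse, peaked profiles
#'   characteristic of COSMIC signatures (default 0.25).
#' @param seed Integer seed.
#' @param signatureSource \code{"synthetic"} (Dirichlet pools, no downloads)
#'   or \code{"file"} (draw the pool from a COSMIC-style signature TSV).
#' @param signatureFile Path to the signature TSV when
#'   \code{signatureSource = "file"}.
#' @return A list of class \code{"simulationConfig"}.
#' @export
simulationConfig <- function(nDatasets = 50L, nSamples = 100L,
                             nSignaturesPool = 10L, nActivePerSample = 4L,
                             activityMeanLog = log(17366 / 4) - 1.5^2 / 2,
                             activitySdLog = 1.5, modulationNoiseSd = 0.05,
                             concentration = 0.25, seed = 1L,
                             signatureSource = c("synthetic", "file"),
                             signatureFile = NULL) {
  signatureSource <- match.arg(signatureSource)
  stopifnot(nActivePerSample <= nSignaturesPool, activitySdLog > 0,
            modulationNoiseSd >= 0, concentration > 0)
  structure(list(nDatasets = as.integer(nDatasets),
                 nSamples = as.integer(nSamples),
                 nSignaturesPool = as.integer(nSignaturesPool),
                 nActivePerSample = as.integer(nActivePerSample),
                 activityMeanLog = activityMeanLog,
                 activitySdLog = activitySdLog,
                 modulationNoiseSd = modulationNoiseSd,
                 concentration = concentration, seed = as.integer(seed),
                 signatureSource = signatureSource,
                 signatureFile = signatureFile),
            class = "simulationConfig")
}

#' Draw a signature pool
#'
#' Synthetic mode draws sparse-peaked random probability profiles from a
#' symmetric Dirichlet with concentration below 1, emulating the peakedness
#' of COSMIC signatures without requiring the COSMIC file; file mode samples
#' a uniform subset (without replacement) of a supplied signature TSV.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return A \linkS4class{SignatureSet} with \code{nSignaturesPool} rows.
#' @export
sampleSignaturePool <- function(config = simulationConfig()) {
  n <- config$nSignaturesPool
  if (config$signatureSource == "file") {
    sigs <- readSignatures(config$signatureFile)
    prof <- signatureProfiles(sigs)
    if (nrow(prof) < n) {
      stop("signature file has fewer than ", n, " signatures")
    }
    keep <- sort(sample.int(nrow(prof), n))
    return(SignatureSet(prof[keep, , drop = FALSE]))
  }
  m <- matrix(stats::rgamma(n * 96L, shape = config$concentration), n, 96L)
  # guard against an (astronomically unlikely) all-zero draw
  m[rowSums(m) == 0, 1L] <- 1
  m <- m / rowSums(m)
  dimnames(m) <- list(paste0("SynSig", seq_len(n)), sbsChannels())
  SignatureSet(m)
}

#' Simulate a structured modulatory profile
#'
#' Picks two distinct SBS base classes; channels of one receive positive
#' U(0, 1) magnitudes, channels of the other negative ones; Gaussian noise
#' (sd \code{noiseSd}) is added to all 96 channels; the profile is gauged to
#' \code{max(abs(r)) == 1}.
#'
#' @param noiseSd Channel noise sd (default 0.05).
#' @return Named numeric 96-vector \code{r}, gauged.
#' @export
simulateModulatoryProcess <- function(noiseSd = 0.05) {
  classes <- channelBaseClass()
  chosen <- sample(sbsBaseClasses(), 2L)
  r <- stats::rnorm(96L, 0, noiseSd)
  up <- classes == chosen[1L]
  dn <- classes == chosen[2L]
  r[up] <- r[up] + stats::runif(sum(up))
  r[dn] <- r[dn] - stats::runif(sum(dn))
  r <- r / max(abs(r))
  names(r) <- sbsChannels()
  r
}

#' Simulate one benchmark dataset
#'
#' Per sample: \code{nActivePerSample} signatures drawn uniformly from the
#' pool, their activities from the configured log-normal, a modulatory
#' activity \code{c ~ U(0, 1)}; \code{(r, c)} are gauged jointly and any
#' \code{c} violating feasibility (\code{1 + c*r >= 0}) is redrawn (at most
#' 100 times, then truncated). Counts are Poisson draws from
#' \code{(1 + c*r) * (a \%*\% mu)}.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param pool Optional \linkS4class{SignatureSet} pool; drawn from
#'   \code{config} when missing.
#' @param r Optional modulatory profile; simulated when missing. Pass a zero
#'   vector for purely additive data.
#' @return A list with elements \code{catalog}
#'   (\linkS4class{MutationCatalog}), \code{signatures}, \code{trueActivities}
#'   (samples x pool matrix), \code{trueModulatory}
#'   (\linkS4class{ModulatoryFit}, gauged), \code{activeMask} (logical
#'   samples x pool) and \code{rates}.
#' @export
simulateDataset <- function(config = simulationConfig(), pool = NULL,
                            r = NULL) {
  if (is.null(pool)) pool <- sampleSignaturePool(config)
  if (is.null(r)) r <- simulateModulatoryProcess(config$modulationNoiseSd)
  r <- structure(as.numeric(r), names = sbsChannels())
  mu <- signatureProfiles(pool)
  nS <- config$nSamples; npool <- nrow(mu)
  A <- matrix(0, nS, npool,
              dimnames = list(sprintf("sample%03d", seq_len(nS)),
                              rownames(mu)))
  mask <- matrix(FALSE, nS, npool, dimnames = dimnames(A))
  for (k in seq_len(nS)) {
    act <- sample.int(npool, config$nActivePerSample)
    mask[k, act] <- TRUE
    A[k, act] <- stats::rlnorm(config$nActivePerSample,
                               meanlog = config$activityMeanLog,
                               sdlog = config$activitySdLog)
  }
  cc <- stats::runif(nS)
  # joint gauge: r may arrive ungauged
  m <- max(abs(r))
  if (m > 0) { r <- r / m; cc <- cc * m } else cc <- cc * 0
  rmin <- min(r)
  if (rmin < 0) {
    for (k in seq_len(nS)) {
      tries <- 0L
      while (1 + cc[k] * rmin < 0 && tries < 100L) {
        cc[k] <- stats::runif(1L) * m
        tries <- tries + 1L
      }
      if (1 + cc[k] * rmin < 0) cc[k] <- -1 / rmin
    }
  }
  fit <- ModulatoryFit(r = r, c = structure(cc, names = rownames(A)))
  Xt <- A %*% mu
  rates <- modulationFactors(fit) * Xt
  X <- matrix(stats::rpois(length(rates), rates), nS, 96L,
              dimnames = dimnames(rates))
  list(catalog = new("MutationCatalog", counts = X,
                     cancerType = character()),
       signatures = pool, trueActivities = A, trueModulatory = fit,
       activeMask = mask, rates = rates)
}

#' Run the simulation benchmark
#'
#' For each of \code{nDatasets} datasets: simulate, run
#' \code{\link{alternatingFit}}, and score the recovery of the modulatory
#' profile (cosine similarity of inferred vs true \code{r}), of the
#' modulatory activities (squared error of inferred vs true \code{c}) and
#' the stability of the additive activities (per-sample cosine between the
#' additive-only and extended-model refits). Each dataset is simulated and
#' fitted under its own derived seed, so per-dataset results are independent
#' of execution order and the whole benchmark is a pure function of
#' \code{config$seed}.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param fitCfg A \code{\link{fitConfig}} template (its seed is overridden
#'   per dataset).
#' @param verbose Print per-dataset progress.
#' @return A list: \code{perDataset} (data.frame with one row per dataset:
#'   \code{cosineR}, \code{mseC}, \code{activityCosine}, \code{gain},
#'   \code{gainPerMutation}, \code{nMutations}, \code{converged}),
#'   \code{meanCosineR}, \code{mseC} (pooled over all samples of all
#'   datasets), \code{meanActivityCosine}, and \code{config}.
#' @export
runBenchmark <- function(config = simulationConfig(), fitCfg = fitConfig(),
                         verbose = FALSE) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, config$nDatasets)

  rows <- vector("list", config$nDatasets)
  sqerr <- vector("list", config$nDatasets)
  acos <- vector("list", config$nDatasets)
  for (d in seq_len(config$nDatasets)) {
    set.seed(seeds[d])
    sim <- simulateDataset(config)
    cfg_d <- fitCfg; cfg_d$seed <- seeds[d]
    fit <- alternatingFit(sim$catalog, sim$signatures, cfg_d)

    csR <- cosineSimilarity(modProfile(fit), modProfile(sim$trueModulatory))
    se <- (modActivities(fit) - modActivities(sim$trueModulatory))^2
    ac <- .perSampleCosine(activities(fit), additiveActivities(fit))
    nMut <- sum(mutationCounts(sim$catalog))
    rows[[d]] <- data.frame(dataset = d, cosineR = csR, mseC = mean(se),
                            activityCosine = mean(ac, na.rm = TRUE),
                            gain = logLikGain(fit),
                            gainPerMutation = logLikGain(fit) / nMut,
                            nMutations = nMut, converged = fit@converged)
    sqerr[[d]] <- se
    acos[[d]] <- ac
    if (verbose) {
      message(sprintf("dataset %d/%d: cosine(r) = %.3f, mse(c) = %.4f",
                      d, config$nDatasets, csR, mean(se)))
    }
  }
  perDataset <- do.call(rbind, rows)
  list(perDataset = perDataset,
       meanCosineR = mean(perDataset$cosineR),
       mseC = mean(unlist(sqerr)),
       meanActivityCosine = mean(unlist(acos), na.rm = TRUE),
       config = config)
}

## per-sample cosine between two activity matrices (NA for zero rows)
.perSampleCosine <- function(A, B) {
  vapply(seq_len(nrow(A)), function(k) {
    na <- sqrt(sum(A[k, ]^2)); nb <- sqrt(sum(B[k, ]^2))
    if (na == 0 || nb == 0) return(NA_real_)
    sum(A[k, ] * B[k, ]) / (na * nb)
  }, numeric(1L))
}
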