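# Fixture builders shared across the suite. Everything is generated in code;
# no files are shipped.

# a catalog with given counts laid over the canonical channels
makeCatalog <- function(counts, cancerType = character()) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 96L)
  colnames(counts) <- sbsChannels()
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  }
  MutationCatalog(counts, cancerType = cancerType)
}

# n signatures: flat, or Dirichlet-peaked
makeSignatures <- function(n = 2, peaked = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- if (peaked) {
    matrix(rgamma(n * 96, shape = 0.25), n, 96)
  } else {
    matrix(1, n, 96)
  }
  m <- m / rowSums(m)
  dimnames(m) <- list(paste0("Sig", seq_len(n)), sbsChannels())
  SignatureSet(m)
}

# two signatures with disjoint channel support (first/second half)
makeDisjointSignatures <- function() {
  m <- matrix(0, 2, 96)
  m[1, 1:48] <- 1 / 48
  m[2, 49:96] <- 1 / 48
  dimnames(m) <- list(c("SigA", "SigB"), sbsChannels())
  SignatureSet(m)
}

# a random strictly feasible model instance for gradient / likelihood checks;
# kept small so finite differences stay numerically clean
randomInstance <- function(nS = 4, nsig = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sigs <- makeSignatures(nsig, peaked = TRUE)
  A <- matrix(rlnorm(nS * nsig, log(20), 0.5), nS, nsig)
  r <- runif(96, -1, 1) * 0.8
  r <- r / max(abs(r))
  cc <- runif(nS, 0.05, 0.9)     # p = 1 + c*r >= 0.1, safely interior
  fit <- ModulatoryFit(r = r, c = cc)
  Xt <- additiveReconstruction(A, sigs)
  rates <- modulationFactors(fit) * Xt
  X <- matrix(rpois(length(rates), rates), nS, 96)
  list(catalog = makeCatalog(X), signatures = sigs, activities = A,
       fit = fit, additive = Xt, rates = rates)
}

# central finite differences, the oracle for the analytic gradients
fdGradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  }, numeric(1))
}

relErr <- function(analytic, numeric_) {
  max(abs(analytic - numeric_) / (1 + abs(analytic)))
}

writeTSV <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
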