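test_that("residuals follow the additive and multiplicative definitions", {
  obs <- makeCatalog(matrix(10, 1, 96))
  pred <- matrix(7, 1, 96)
  addres <- computeResiduals(obs, pred, "additive")
  expect_equal(unname(residualValues(addres)), matrix(3, 1, 96))

  pred4 <- matrix(4, 1, 96)
  mul <- computeResiduals(obs, pred4, "multiplicative")
  expect_equal(unname(residualValues(mul)), matrix(11 / 5, 1, 96))

  # identity case: X == Xt
  same <- computeResiduals(obs, matrix(10, 1, 96), "additive")
  expect_true(all(residualValues(same) == 0))
  same_m <- computeResiduals(obs, matrix(10, 1, 96), "multiplicative")
  expect_true(all(residualValues(same_m) == 1))

  expect_error(computeResiduals(obs, matrix(7, 2, 96), "additive"),
               "shape")
  expect_error(computeResiduals(obs, matrix(0, 1, 96), "multiplicative",
                                pseudocount = 0),
               "pseudo-count")
})

test_that("Poisson resampling is reproducible and concentrates at its rates", {
  set.seed(10)
  rates <- matrix(rpois(96 * 3, 30), 3, 96)
  rates[1, ] <- 0            # degenerate rows stay zero
  rates[2, 1] <- 10000
  ct <- makeCatalog(rates)
  a <- poissonResampleControl(ct, seed = 99)
  b <- poissonResampleControl(ct, seed = 99)
  expect_identical(mutationCounts(a), mutationCounts(b))
  expect_true(all(mutationCounts(a)[1, ] == 0))
  # Poisson concentration: within 5 sd of a large rate
  expect_lt(abs(mutationCounts(a)[2, 1] - 10000), 5 * sqrt(10000))
  # different seed, different draw
  expect_false(identical(mutationCounts(a),
                         mutationCounts(poissonResampleControl(ct, 100))))
})

test_that("residual correlation matrices are valid similarity matrices", {
  set.seed(11)
  v <- matrix(rnorm(5 * 96), 5, 96)
  v[2, ] <- -v[1, ]                      # exact negation
  res <- new("ResidualMatrix", flavour = "additive", values = v)
  cm <- residualCorrelationMatrix(res)
  expect_true(isSymmetric(cm))
  expect_equal(unname(diag(cm)), rep(1, 5))
  expect_true(all(cm >= -1 - 1e-12 & cm <= 1 + 1e-12))
  expect_equal(cm[1, 2], -1)

  # constant profile: correlation undefined, reported as 0 with a warning
  v2 <- v; v2[3, ] <- 2
  expect_warning(
    cm2 <- residualCorrelationMatrix(
      new("ResidualMatrix", flavour = "additive", values = v2)),
    "constant")
  expect_true(all(cm2[3, -3] == 0))

  # two independent 96-vectors are weakly correlated with high probability:
  # Monte-Carlo bound over many pairs
  set.seed(12)
  cors <- replicate(2000, cor(rnorm(96), rnorm(96)))
  expect_lt(mean(abs(cors) > 0.5), 0.001)
})

test_that("complete-linkage clustering at the correlation threshold", {
  # two blocks of perfectly correlated samples, uncorrelated across
  blockCorr <- function(sizes, within = 1, across = 0) {
    n <- sum(sizes)
    m <- matrix(across, n, n)
    at <- cumsum(c(0, sizes))
    for (b in seq_along(sizes)) {
      idx <- (at[b] + 1):at[b + 1]
      m[idx, idx] <- within
    }
    dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
    m
  }
  two <- clusterByResidualCorrelation(blockCorr(c(3, 4)), threshold = 0.75)
  expect_equal(length(unique(clusterLabels(two))), 2L)

  one <- clusterByResidualCorrelation(blockCorr(7), threshold = 0.75)
  expect_equal(length(unique(clusterLabels(one))), 1L)

  iden <- diag(6); dimnames(iden) <- list(paste0("s", 1:6), paste0("s", 1:6))
  singletons <- clusterByResidualCorrelation(iden, threshold = 0.75)
  expect_equal(length(unique(clusterLabels(singletons))), 6L)
  expect_equal(sort(sampleOrdering(singletons)), 1:6)

  expect_error(clusterByResidualCorrelation(matrix(c(1, .2, .4, 1), 2)),
               "symmetric")
})

test_that("clustering is invariant to sample order up to relabelling", {
  set.seed(13)
  inst <- randomInstance(nS = 12, seed = 13)
  res <- computeResiduals(inst$catalog, inst$additive, "multiplicative")
  cm <- residualCorrelationMatrix(res)
  cl1 <- clusterLabels(clusterByResidualCorrelation(cm, 0.5))
  perm <- sample(nrow(cm))
  cl2 <- clusterLabels(clusterByResidualCorrelation(cm[perm, perm], 0.5))
  # same partition: co-membership matrices agree after undoing the permutation
  co1 <- outer(cl1, cl1, "==")
  co2 <- outer(cl2, cl2, "==")[order(perm), order(perm)]
  expect_equal(unname(co1), unname(co2))
})

test_that("cluster entropy follows the label composition", {
  labels <- c(rep("Liver-HCC", 18), rep("Skin-Melanoma", 5), rep("CNS", 5),
              rep("Lung", 9))
  cl <- c(rep(1L, 18), rep(2L, 10), rep(3L, 9))
  assign <- new("ClusterAssignment",
                labels = structure(cl, names = paste0("s", seq_along(cl))),
                threshold = 0.75, ordering = seq_along(cl), tree = NULL)
  out <- clusterEntropy(assign, labels, minSize = 10)
  # the 9-sample cluster is excluded
  expect_equal(nrow(out), 2L)
  expect_false(3L %in% out$cluster)
  # single-label cluster has zero entropy; balanced two-label has log 2
  expect_equal(out$entropy[out$cluster == 1L], 0)
  expect_equal(out$entropy[out$cluster == 2L], log(2))
  # ascending order
  expect_equal(out$entropy, sort(out$entropy))
  # base-2 option
  out2 <- clusterEntropy(assign, labels, minSize = 10, base = 2)
  expect_equal(out2$entropy[out2$cluster == 2L], 1)
})
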