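test_that("activity refitting recovers generating activities", {
  set.seed(31)
  dis <- makeDisjointSignatures()
  # huge counts concentrated on one signature: MLE within 1% of truth
  a_true <- c(1e6, 0)
  rates <- additiveReconstruction(matrix(a_true, 1, 2), dis)
  X <- makeCatalog(matrix(rpois(96, rates), 1, 96))
  A <- fitActivities(X, dis)
  expect_lt(abs(A[1, 1] - 1e6) / 1e6, 0.01)
  expect_lt(A[1, 2] / 1e6, 0.01)

  # the all-zero sample sits at the boundary optimum a = 0
  zero <- makeCatalog(matrix(0, 1, 96))
  expect_equal(unname(fitActivities(zero, dis)), matrix(0, 1, 2),
               ignore_attr = TRUE)

  # log-normal activities at >= 1e4 mutations: per-sample cosine >= 0.95
  sigs <- makeSignatures(5, peaked = TRUE, seed = 32)
  A_true <- matrix(rlnorm(6 * 5, log(3000), 0.6), 6, 5)
  rates <- additiveReconstruction(A_true, sigs)
  X2 <- makeCatalog(matrix(rpois(length(rates), rates), 6, 96))
  expect_true(all(rowSums(mutationCounts(X2)) >= 1e4))
  A_hat <- fitActivities(X2, sigs)
  cs <- vapply(1:6, function(k) cosineSimilarity(A_hat[k, ], A_true[k, ]),
               numeric(1))
  expect_true(all(cs >= 0.95))
})

test_that("modulatory fitting is gauged and honest on unmodulated data", {
  set.seed(33)
  cfg <- simulationConfig(nSamples = 40, seed = 33)
  sim <- simulateDataset(cfg, r = rep(0, 96))   # purely additive data
  A <- fitActivities(sim$catalog, sim$signatures)
  fit <- fitModulatory(sim$catalog, sim$signatures, A)
  # gauge postcondition
  expect_true(max(abs(modProfile(fit))) == 1 ||
                all(modProfile(fit) == 0))
  # honesty: the fitted modulation only absorbs counting noise — the typical
  # channel impact stays near 1 and the log-likelihood gain per mutation is
  # negligible (the maximum-likelihood overfit is bounded by ~half the added
  # degrees of freedom, (96 + nSamples) / 2)
  expect_lt(mean(abs(impactProfile(fit) - 1)), 0.02)
  add_ll <- logLikelihood(sim$catalog, additiveReconstruction(A, sim$signatures))
  overfit <- attr(fit, "logLik") - add_ll
  expect_lt(overfit / sum(mutationCounts(sim$catalog)), 1e-3)
  expect_lt(overfit, 3 * (96 + cfg$nSamples) / 2)
})

test_that("the alternating fit is monotone, deterministic and nested", {
  set.seed(34)
  cfg <- simulationConfig(nSamples = 25, seed = 34)
  sim <- simulateDataset(cfg)
  fc <- fitConfig(seed = 7)
  fit <- alternatingFit(sim$catalog, sim$signatures, fc)

  # coordinate-ascent monotonicity of the recorded half-step trace
  tr <- fit@trace
  tol <- 1e-6 * (1 + abs(tr[1]))
  expect_true(all(diff(tr) > -tol))

  # nesting: extended model can never do worse than the additive refit
  expect_gte(logLikGain(fit), -1e-6)

  # determinism: same seed gives a bitwise-identical result
  fit2 <- alternatingFit(sim$catalog, sim$signatures, fitConfig(seed = 7))
  expect_identical(activities(fit), activities(fit2))
  expect_identical(modProfile(fit), modProfile(fit2))
  expect_identical(modActivities(fit), modActivities(fit2))
  expect_identical(logLik(fit), logLik(fit2))

  # on modulated data the gain is material and the profile is recovered
  expect_gt(logLikGain(fit) / sum(mutationCounts(sim$catalog)), 1e-3)
  expect_gt(cosineSimilarity(modProfile(fit),
                             modProfile(sim$trueModulatory)), 0.8)
})

test_that("additive-only data yields a negligible per-mutation gain", {
  set.seed(35)
  cfg <- simulationConfig(nSamples = 25, seed = 35)
  sim <- simulateDataset(cfg, r = rep(0, 96))
  fit <- alternatingFit(sim$catalog, sim$signatures, fitConfig(seed = 5))
  expect_gte(logLikGain(fit), -1e-6)
  expect_lt(logLikGain(fit) / sum(mutationCounts(sim$catalog)), 1e-3)
})

test_that("model comparison applies the BIC with 96 + n_samples extra df", {
  sim <- simulateDataset(simulationConfig(nSamples = 100, seed = 36))
  skel <- alternatingFit(
    mutationCounts(sim$catalog)[1:3, , drop = FALSE],
    sim$signatures, fitConfig(seed = 1, nAlternations = 1))

  # arithmetic contract on a synthetic result
  fake <- skel
  fake@gain <- 1e4
  mc <- modelComparison(fake, sim$catalog)
  expect_equal(mc$deltaBIC, 2e4 - 196 * log(9600))
  expect_equal(mc$gainPerMutation, 1e4 / sum(mutationCounts(sim$catalog)))

  # zero gain: the extended model is penalised
  fake@gain <- 0
  expect_lt(modelComparison(fake, sim$catalog)$deltaBIC, 0)
})
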