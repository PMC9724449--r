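test_that("additive reconstruction is the activity-weighted signature sum", {
  flat <- makeSignatures(1)
  rec <- additiveReconstruction(matrix(100, 1, 1), flat)
  expect_equal(unname(rec), matrix(100 / 96, 1, 96))

  expect_equal(unname(additiveReconstruction(matrix(0, 1, 1), flat)),
               matrix(0, 1, 96))

  # disjoint-support signatures verified channel-wise by hand multiplication
  dis <- makeDisjointSignatures()
  rec2 <- additiveReconstruction(matrix(c(10, 20), 1, 2), dis)
  expect_equal(unname(rec2[1, ]),
               c(rep(10 / 48, 48), rep(20 / 48, 48)))

  expect_error(additiveReconstruction(matrix(1, 1, 3), dis), "conform")
  expect_error(additiveReconstruction(matrix(-1, 1, 2), dis),
               "non-negative")
})

test_that("modulation factors are 1 + c*r with feasibility enforced", {
  fit <- ModulatoryFit(r = rep(1, 96), c = c(0, 2.5))
  p <- modulationFactors(fit)
  expect_equal(unname(p[1, ]), rep(1, 96))    # inactive sample
  expect_equal(unname(p[2, ]), rep(3.5, 96))

  # boundary-feasible: p = 0 allowed
  f0 <- ModulatoryFit(r = c(-0.5, rep(0.1, 95)), c = 2)
  expect_equal(unname(modulationFactors(f0))[1, 1], 0)

  expect_error(ModulatoryFit(r = c(-0.5, rep(0, 95)), c = 3), "infeasible")
})

test_that("log-likelihood matches closed forms and nests the additive model", {
  # all-zero counts: ll = -sum(rates)
  zero <- makeCatalog(matrix(0, 2, 96))
  R <- matrix(runif(2 * 96, 1, 5), 2, 96)
  expect_equal(logLikelihood(zero, R), -sum(R))

  # single informative cell: X = 3 at rate 3 contributes -3 + 3 log 3
  X <- matrix(0, 1, 96); X[1] <- 3
  R1 <- matrix(0.001, 1, 96); R1[1] <- 3
  expect_equal(logLikelihood(makeCatalog(X), R1),
               (-3 + 3 * log(3)) - 0.001 * 95)

  # c = 0 reduces to the additive likelihood (nesting identity)
  inst <- randomInstance(seed = 21)
  off <- ModulatoryFit(r = modProfile(inst$fit),
                       c = rep(0, nrow(inst$additive)))
  expect_equal(logLikelihood(inst$catalog, inst$additive, off),
               logLikelihood(inst$catalog, inst$additive))

  # zero rate under a positive count is an explicit error
  Rbad <- R1; Rbad[1] <- 0
  expect_error(logLikelihood(makeCatalog(X), Rbad), "zero model rate")
})

test_that("gauge fixing rescales without changing the model", {
  f <- ModulatoryFit(r = c(0.5, -0.25, rep(0, 94)), c = 2)
  g <- gaugeFix(f)
  expect_equal(modProfile(g)[1:2], c(1, -0.5), ignore_attr = TRUE)
  expect_equal(modActivities(g), 1, ignore_attr = TRUE)
  expect_equal(modulationFactors(g), modulationFactors(f))
  # idempotence
  expect_equal(gaugeFix(g), g)
  # zero profile: activities forced to zero
  z <- gaugeFix(ModulatoryFit(r = rep(0, 96), c = c(1, 2)))
  expect_equal(modActivities(z), c(0, 0), ignore_attr = TRUE)
})

test_that("the likelihood is gauge invariant: r/alpha, c*alpha", {
  set.seed(22)
  for (i in 1:20) {
    inst <- randomInstance(nS = 3)
    ll0 <- logLikelihood(inst$catalog, inst$additive, inst$fit)
    alpha <- runif(1, 0.2, 5)
    resc <- ModulatoryFit(r = modProfile(inst$fit) / alpha,
                          c = modActivities(inst$fit) * alpha)
    expect_equal(logLikelihood(inst$catalog, inst$additive, resc), ll0,
                 tolerance = 1e-10)
    # and the canonical gauge leaves it unchanged too
    expect_equal(logLikelihood(inst$catalog, inst$additive,
                               gaugeFix(inst$fit)),
                 ll0, tolerance = 1e-10)
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(23)
  for (i in 1:10) {
    inst <- randomInstance(nS = 3, nsig = 3)
    X <- mutationCounts(inst$catalog)
    mu <- signatureProfiles(inst$signatures)
    r <- modProfile(inst$fit); cc <- modActivities(inst$fit)

    ga <- gradActivities(X, mu, inst$activities, inst$fit)
    fa <- fdGradient(function(av) {
      logLikelihood(X, additiveReconstruction(matrix(av, 3, 3), mu),
                    inst$fit)
    }, as.vector(inst$activities))
    expect_lt(relErr(as.vector(ga), fa), 1e-6)

    gright <- gradModulatoryProfile(X, inst$additive, inst$fit)
    fr <- fdGradient(function(rv) {
      logLikelihood(X, inst$additive, ModulatoryFit(r = rv, c = cc))
    }, r)
    expect_lt(relErr(gright, fr), 1e-6)

    gc <- gradModulatoryActivity(X, inst$additive, inst$fit)
    fc <- fdGradient(function(cv) {
      logLikelihood(X, inst$additive, ModulatoryFit(r = r, c = cv))
    }, cc)
    expect_lt(relErr(gc, fc), 1e-6)
  }
})

test_that("gradients vanish where the model is exactly stationary", {
  # r = 0 makes the c-gradient vanish; c = 0 makes the r-gradient vanish
  inst <- randomInstance(seed = 24)
  X <- mutationCounts(inst$catalog)
  nS <- nrow(X)
  rzero <- ModulatoryFit(r = rep(0, 96), c = rep(0.7, nS))
  expect_equal(gradModulatoryActivity(X, inst$additive, rzero), rep(0, nS))
  czero <- ModulatoryFit(r = modProfile(inst$fit), c = rep(0, nS))
  expect_equal(unname(gradModulatoryProfile(X, inst$additive, czero)),
               rep(0, 96))

  # noiseless construction: treating the rates as real-valued counts, the
  # activity gradient is zero at the generating parameters
  g <- gradActivities(inst$rates, signatureProfiles(inst$signatures),
                      inst$activities, inst$fit)
  expect_lt(max(abs(g)) / (1 + sum(inst$rates)), 1e-10)
})

test_that("the likelihood is unimodal along c for fixed a and r", {
  inst <- randomInstance(seed = 25, nS = 1)
  X <- mutationCounts(inst$catalog)
  r <- modProfile(inst$fit)
  cmax <- if (min(r) < 0) -1 / min(r) else 3
  grid <- seq(0, cmax * 0.999, length.out = 400)
  ll <- vapply(grid, function(cv) {
    logLikelihood(X, inst$additive, ModulatoryFit(r = r, c = cv))
  }, numeric(1))
  # concave in c: the sequence of differences changes sign at most once
  d <- diff(ll)
  expect_lte(sum(diff(sign(d[d != 0])) != 0), 1L)
})
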