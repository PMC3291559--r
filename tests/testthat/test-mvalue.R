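test_that("configuration prior matches the beta-binomial closed form and normalises", {
  # uniform prior, single study: P(c = 1) = 1/2
  expect_equal(logConfigPrior(1, EffectPrior(), n = 1), log(1 / 2))
  # two studies, uniform prior: asymmetric configs 1/6, symmetric 1/3
  expect_equal(exp(logConfigPrior(c(1, 0))), 1 / 6)
  expect_equal(exp(logConfigPrior(c(0, 1))), 1 / 6)
  expect_equal(exp(logConfigPrior(c(1, 1))), 1 / 3)
  expect_equal(exp(logConfigPrior(c(0, 0))), 1 / 3)
  total2 <- exp(logConfigPrior(c(1, 0))) + exp(logConfigPrior(c(0, 1))) +
    exp(logConfigPrior(c(1, 1))) + exp(logConfigPrior(c(0, 0)))
  expect_equal(total2, 1)
  # non-uniform shapes, n = 4: the 16 configurations still sum to one
  pr <- EffectPrior(alpha = 2, beta = 1)
  B <- as.matrix(expand.grid(rep(list(0:1), 4)))
  expect_equal(sum(apply(B, 1, function(b) exp(logConfigPrior(b, pr)))), 1)
  # length mismatch is rejected
  expect_error(logConfigPrior(c(1, 0), n = 3), "does not match")
})

test_that("marginal likelihood: closed form equals adaptive quadrature", {
  p2 <- MetaPanel(beta = c(0.30, 0.25), se = c(0.10, 0.10))
  quad <- integrate(function(mu) dnorm(0.30, mu, 0.1) * dnorm(0.25, mu, 0.1) *
                      dnorm(mu, 0, 0.2), -Inf, Inf, rel.tol = 1e-12)$value
  expect_equal(logMarginalLikelihood(p2, c(1, 1)), log(quad),
               tolerance = 1e-8)
  # random panels up to 10 studies, random configurations
  for (seed in 1:5) {
    n <- 2 + (seed %% 9)
    pan <- randomPanel(n, seed)
    bits <- as.integer(runif(n) < 0.6)
    got <- logMarginalLikelihood(pan, bits)
    beta <- effectSizes(pan); se <- stdErrors(pan); on <- bits == 1
    ll <- sum(dnorm(beta[!on], 0, se[!on], log = TRUE))
    if (any(on)) {
      integrand <- function(mu) vapply(mu, function(m)
        prod(dnorm(beta[on], m, se[on])) * dnorm(m, 0, 0.2), numeric(1))
      ll <- ll + log(integrate(integrand, -Inf, Inf, rel.tol = 1e-12)$value)
    }
    expect_equal(got, ll, tolerance = 1e-8)
  }
})

test_that("marginal likelihood limits: empty effect set and sigma -> 0", {
  pan <- randomPanel(4, 11)
  nullLL <- sum(dnorm(effectSizes(pan), 0, stdErrors(pan), log = TRUE))
  expect_equal(logMarginalLikelihood(pan, rep(0, 4)), nullLL)
  # as the effect-size prior collapses to zero, every configuration's
  # density approaches the pure null density
  expect_equal(logMarginalLikelihood(pan, rep(1, 4), EffectPrior(1e-10)),
               nullLL, tolerance = 1e-6)
})

test_that("exact m-values: exchangeability, prior recovery, oracle equivalence", {
  # identical studies get identical m-values
  pp <- MetaPanel(beta = c(0.3, 0.3), se = c(0.1, 0.1))
  m <- mvalues(mvaluesExact(pp))
  expect_equal(unname(m[1]), unname(m[2]))
  # sigma -> 0: likelihood no longer depends on the configuration, so the
  # posterior returns the prior marginal P(c_i = 1) = 1/2
  m0 <- mvalues(mvaluesExact(pp, EffectPrior(sigma = 1e-9)))
  expect_equal(unname(m0), c(0.5, 0.5), tolerance = 1e-6)
  # 8-study panels vs brute-force enumeration + quadrature
  for (seed in c(1, 21)) {
    pan <- randomPanel(8, seed)
    expect_equal(unname(mvalues(mvaluesExact(pan))), bruteForceMvalues(pan),
                 tolerance = 1e-6)
  }
  # posterior over configurations normalises
  pan <- randomPanel(6, 5)
  cp <- binmeta:::.configLogPosterior(pan, EffectPrior())
  logZ <- binmeta:::.logSumExp(cp$lp)
  expect_equal(sum(exp(cp$lp - logZ)), 1)
  # enumeration limit is enforced
  big <- MetaPanel(beta = rnorm(25), se = rep(0.1, 25))
  expect_error(mvaluesExact(big, limit = 20), "mvaluesMCMC")
})

test_that("m-value responds monotonically to effect size and precision", {
  # growing |beta| in the consensus direction cannot lower that study's m
  base <- c(0.25, 0.25, 0.25, 0)
  se <- rep(0.08, 4)
  ms <- vapply(seq(0, 0.4, 0.05), function(b4) {
    mvalues(mvaluesExact(MetaPanel(beta = c(base[1:3], b4), se = se)))[4]
  }, numeric(1))
  expect_true(all(diff(ms) >= -1e-12))
  # a null study's m-value is non-increasing in its precision: a large
  # null study is confidently "no effect", a small one stays ambiguous
  ms2 <- vapply(c(0.5, 0.2, 0.1, 0.05, 0.02), function(s4) {
    mvalues(mvaluesExact(MetaPanel(beta = c(0.25, 0.25, 0.25, 0),
                                   se = c(0.08, 0.08, 0.08, s4))))[4]
  }, numeric(1))
  expect_true(all(diff(ms2) <= 1e-12))
})

test_that("MCMC m-values agree with exact enumeration and are reproducible", {
  covered <- 0L
  checks <- 0L
  for (seed in 1:6) {
    pan <- randomPanel(8, seed + 100)
    ex <- mvalues(mvaluesExact(pan))
    mc <- mvaluesMCMC(pan, burnin = 500, samples = 8000, seed = seed)
    covered <- covered + sum(abs(mvalues(mc) - ex) <= 3 * mcError(mc))
    checks <- checks + 8L
    expect_true(all(mvalues(mc) >= 0 & mvalues(mc) <= 1))
  }
  # 3 mc_se coverage should hold for the overwhelming majority of studies
  expect_gte(covered / checks, 0.95)
  # determinism under a fixed seed
  pan <- randomPanel(8, 3)
  r1 <- mvaluesMCMC(pan, burnin = 100, samples = 2000, seed = 7)
  r2 <- mvaluesMCMC(pan, burnin = 100, samples = 2000, seed = 7)
  expect_identical(mvalues(r1), mvalues(r2))
  # feasible well beyond the enumeration limit
  big <- MetaPanel(beta = rnorm(30, 0, 0.1), se = rep(0.08, 30))
  r30 <- mvaluesMCMC(big, burnin = 200, samples = 1500, seed = 1)
  expect_length(mvalues(r30), 30)
  expect_true(all(mvalues(r30) >= 0 & mvalues(r30) <= 1))
})

test_that("study classification applies the prediction thresholds", {
  lab <- classifyStudies(c(0.95, 0.5, 0.05, 0.9, 0.1))
  expect_equal(as.character(lab),
               c("predicted-effect", "ambiguous", "predicted-no-effect",
                 "predicted-effect", "predicted-no-effect"))
  expect_error(classifyStudies(0.5, upper = 0.2, lower = 0.3), "lower")
  # figure regions match the classification for every plotted point
  pan <- randomPanel(6, 9)
  mres <- mvaluesExact(pan)
  pts <- pmPoints(pan, mres)
  expect_equal(pts$region, as.character(classifyStudies(mres)))
})

test_that("configuration objects expose their index sets", {
  cfg <- Configuration(c(1, 0, 1, 1, 0))
  expect_equal(configBits(cfg), c(1L, 0L, 1L, 1L, 0L))
  expect_equal(configOnes(cfg), c(1L, 3L, 4L))
  expect_equal(configZeros(cfg), c(2L, 5L))
  expect_equal(countOnes(cfg), 3)
  expect_true(all(sort(c(configOnes(cfg), configZeros(cfg))) == 1:5))
  expect_error(Configuration(c(1, 2)), "0s and 1s")
  # Configuration and plain vectors are interchangeable in the operations
  pan <- randomPanel(5, 55)
  expect_identical(logMarginalLikelihood(pan, cfg),
                   logMarginalLikelihood(pan, c(1, 0, 1, 1, 0)))
  expect_identical(logConfigPrior(cfg), logConfigPrior(c(1, 0, 1, 1, 0)))
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(MetaPanel(beta = c(0, 0), se = c(0.1, 0)), "se")
  expect_error(MetaPanel(beta = 0.3, se = 0.1), "at least 2")
  expect_error(EffectPrior(sigma = -1), "sigma")
  expect_error(logMarginalLikelihood(randomPanel(3, 1), c(1, 0)), "match")
})
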