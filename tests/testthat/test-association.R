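test_that("study weights resolve by scheme and validate their inputs", {
  pan <- MetaPanel(beta = c(0.2, 0.1), se = c(0.10, 0.05),
                   n = c(8000, 2000), maf = c(0.3, 0.3))
  w <- studyWeights(pan)                       # auto -> sqrt_n
  expect_equal(w[1] / w[2], 2)
  wm <- studyWeights(pan, "maf_adjusted")
  expect_equal(wm[1] / wm[2], 2)
  wp <- studyWeights(pan, "precision")
  expect_equal(wp[1] / wp[2], 0.5)
  expect_equal(mean(studyWeights(pan, c(3, 1))), 1)  # normalised custom
  noN <- MetaPanel(beta = c(0.2, 0.1), se = c(0.1, 0.05))
  expect_equal(studyWeights(noN), studyWeights(noN, "precision"))
  expect_error(studyWeights(noN, "sqrt_n"), "sample size")
  expect_error(studyWeights(pan, c(1, -1)), "positive")
})

test_that("fixed-effects weighted-z: identities and inverse-variance equivalence", {
  # equal weights, identical z-scores: Z = sqrt(K) z0
  K <- 6; z0 <- 1.7
  pan <- MetaPanel(beta = rep(z0 * 0.1, K), se = rep(0.1, K))
  expect_equal(testStatistic(feWeightedZ(pan)), sqrt(K) * z0)
  # all z = 0 gives p = 1
  null <- MetaPanel(beta = rep(0, 4), se = rep(0.1, 4))
  expect_equal(pValue(feWeightedZ(null)), 1)
  expect_equal(pValueSe(feWeightedZ(null)), 0)
  # precision weights reproduce the inverse-variance FE test
  pan2 <- randomPanel(7, 31)
  ivZ <- sum(effectSizes(pan2) / stdErrors(pan2)^2) /
    sqrt(sum(1 / stdErrors(pan2)^2))
  fe <- feWeightedZ(pan2, "precision")
  expect_equal(testStatistic(fe), ivZ)
  expect_equal(pValue(fe), 2 * pnorm(-abs(ivZ)))
})

test_that("random-effects LRT: boundary reduction and grid-search oracle", {
  # homogeneous panel: tau^2 estimate 0, statistic = FE chi-square
  ph <- MetaPanel(beta = rep(0.2, 4), se = rep(0.1, 4))
  re <- reHanEskin(ph)
  expect_equal(re@extra$tau2, 0)
  feChi2 <- (sum(effectSizes(ph) / stdErrors(ph)^2) /
               sqrt(sum(1 / stdErrors(ph)^2)))^2
  expect_equal(testStatistic(re), feChi2, tolerance = 1e-8)
  # dense two-stage grid-search oracle on random panels
  gridMax <- function(x, v, muR, t2R, len = 200) {
    g <- expand.grid(mu = seq(muR[1], muR[2], length.out = len),
                     t2 = seq(max(0, t2R[1]), t2R[2], length.out = len))
    ll <- mapply(function(mu, t2)
      sum(dnorm(x, mu, sqrt(v + t2), log = TRUE)), g$mu, g$t2)
    g$ll <- ll
    g[which.max(ll), ]
  }
  for (seed in c(2, 12, 22)) {
    pan <- randomPanel(5, seed)
    x <- effectSizes(pan); v <- stdErrors(pan)^2
    coarse <- gridMax(x, v, c(-0.6, 0.8), c(0, 0.4))
    dm <- 1.4 / 199; dt <- 0.4 / 199
    fine <- gridMax(x, v, c(coarse$mu - dm, coarse$mu + dm),
                    c(coarse$t2 - dt, coarse$t2 + dt))
    ll0 <- sum(dnorm(x, 0, sqrt(v), log = TRUE))
    oracle <- max(0, 2 * (fine$ll - ll0))
    expect_lt(abs(testStatistic(reHanEskin(pan)) - oracle), 1e-4)
  }
})

test_that("random-effects test controls (conservatively) the type-I error", {
  # With few studies the asymptotic mixture null is conservative, so the
  # empirical rate must not exceed the nominal level but may fall below it.
  set.seed(202)
  R <- 4000
  beta <- se <- matrix(0, 5, R)
  for (j in 1:5) {
    s <- binmeta:::.simStudyMat(1000, 0.3, 1, R)
    beta[j, ] <- s$beta; se[j, ] <- s$se
  }
  pRE <- binmeta:::.rePvalsMat(beta, se^2, refineNear = 0.05)
  rate <- mean(pRE <= 0.05)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / R))
  expect_gte(rate, 0.01)
})

test_that("Wakefield asymptotic Bayes factor matches its closed form and quadrature", {
  # z = 0: data at the null favour H0
  expect_equal(abfWakefield(StudyEffect(0, 0.1), sigma = 0.2),
               sqrt(0.01 / (0.01 + 0.04)))
  expect_lt(abfWakefield(StudyEffect(0, 0.1)), 1)
  # sigma -> 0: hypotheses indistinguishable
  expect_equal(abfWakefield(StudyEffect(0.3, 0.1), sigma = 1e-8), 1,
               tolerance = 1e-6)
  # quadrature oracle: BF = P(X|H1)/P(X|H0) with H1 marginalised over mu
  st <- StudyEffect(0.3, 0.1)
  num <- integrate(function(mu) dnorm(0.3, mu, 0.1) * dnorm(mu, 0, 0.2),
                   -Inf, Inf, rel.tol = 1e-12)$value
  expect_equal(abfWakefield(st, 0.2), num / dnorm(0.3, 0, 0.1),
               tolerance = 1e-8)
  # vectorised over a panel
  pan <- randomPanel(4, 8)
  expect_length(abfWakefield(pan), 4)
})

test_that("binary effects statistic: reductions and direct re-evaluation", {
  pan <- randomPanel(5, 41)
  fe <- testStatistic(feWeightedZ(pan))
  # all m = 1 reduces to the FE statistic
  expect_equal(beStatistic(pan, rep(1, 5)), fe)
  # any constant m reduces to the FE statistic too
  expect_equal(beStatistic(pan, rep(0.3, 5)), fe)
  # m_j = 0 drops study j entirely
  sub <- MetaPanel(beta = effectSizes(pan)[-2], se = stdErrors(pan)[-2])
  expect_equal(beStatistic(pan, c(1, 0, 1, 1, 1)),
               beStatistic(sub, rep(1, 4), studyWeights(pan)[-2]))
  # matches an independent hand evaluation with exact m-values
  m <- mvalues(mvaluesExact(pan))
  w <- studyWeights(pan)
  z <- effectSizes(pan) / stdErrors(pan)
  expect_equal(beStatistic(pan, m),
               sum(m * w * z) / sqrt(sum((m * w)^2)))
  expect_error(beStatistic(pan, rep(0, 5)), "undefined")
})

test_that("importance-sampled BE p-value is unbiased against plain Monte Carlo", {
  pan <- simulatePanel(rep(1000, 5), rr = c(1.25, 1.25, 1.25, 1, 1),
                       seed = 11)
  r <- bePvalue(pan, nSamples = 20000, seed = 5)
  mc <- plainMcBeP(pan, testStatistic(r), 4e5)
  combined <- sqrt(pValueSe(r)^2 + mc["se"]^2)
  expect_lt(abs(pValue(r) - mc["p"]), 3 * combined)
  # a panel with every observed effect exactly zero sits at the centre of
  # the null: tail probability 1
  flat <- MetaPanel(beta = rep(0, 5), se = rep(0.07, 5))
  expect_equal(pValue(bePvalue(flat, nSamples = 500, seed = 1)), 1)
  # determinism under a fixed seed
  expect_identical(pValue(bePvalue(pan, nSamples = 1000, seed = 3)),
                   pValue(bePvalue(pan, nSamples = 1000, seed = 3)))
})

test_that("BE p-value standard error shrinks as 1/sqrt(samples)", {
  pan <- simulatePanel(rep(1000, 5), rr = c(1.25, 1.25, 1.25, 1, 1),
                       seed = 11)
  set.seed(9)
  sds <- vapply(c(1000, 4000, 16000), function(N)
    sd(replicate(12, pValue(bePvalue(pan, nSamples = N)))), numeric(1))
  # each 4x sample increase should roughly halve the spread; allow wide
  # slack for the 12-replicate estimate of the sd itself
  expect_lt(sds[2] / sds[1], 1)
  expect_lt(sds[3] / sds[2], 1)
  expect_lt(sds[3] / sds[1], 0.45)
  # the reported standard error tracks the observed run-to-run spread
  reps <- replicate(20, {
    r <- bePvalue(pan, nSamples = 2000)
    c(pValue(r), pValueSe(r))
  })
  expect_gt(mean(reps[2, ]), 0.3 * sd(reps[1, ]))
  expect_lt(mean(reps[2, ]), 3 * sd(reps[1, ]))
})

test_that("adaptive BE sampling promotes significant panels and matches direct runs", {
  nullPan <- simulatePanel(rep(1000, 5), rr = 1, seed = 21)
  r1 <- beAdaptive(nullPan, nSmall = 500, nLarge = 5000,
                   promoteThreshold = 0.01, seed = 2)
  expect_identical(r1@extra$stage, 1L)
  expect_equal(r1@nSamples, 500)
  strong <- simulatePanel(rep(2000, 5), rr = c(1.4, 1.4, 1.4, 1, 1),
                          seed = 22)
  r2 <- beAdaptive(strong, nSmall = 500, nLarge = 5000,
                   promoteThreshold = 0.01, seed = 2)
  expect_identical(r2@extra$stage, 2L)
  direct <- bePvalue(strong, nSamples = 5000, seed = 2)
  expect_identical(pValue(r2), pValue(direct))
  expect_error(beAdaptive(nullPan, nSmall = 500, nLarge = 500), "nSmall")
})
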