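test_that("case/control allele frequencies follow the small-prevalence closed form", {
  expect_equal(unname(caseControlMaf(0.3, 1)["case"]), 0.3)
  expect_equal(unname(caseControlMaf(0.3, 1.3)["case"]), 0.39 / 1.09)
  # strictly increasing in the relative risk
  cases <- vapply(seq(1, 2, 0.1), function(r)
    unname(caseControlMaf(0.3, r)["case"]), numeric(1))
  expect_true(all(diff(cases) > 0))
  expect_error(caseControlMaf(1.2, 1.3), "maf")
  expect_error(caseControlMaf(0.3, -1), "rr")
})

test_that("simulated studies are calibrated under the null and at rr = 1.3", {
  set.seed(77)
  R <- 10000
  s <- binmeta:::.simStudyMat(2000, 0.3, 1, R)
  z <- s$beta / s$se
  # mean log OR centred at zero
  expect_lt(abs(mean(s$beta)), 3 * sd(s$beta) / sqrt(R))
  # Wald test holds its size
  rate <- mean(2 * pnorm(-abs(z)) <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / R) + 0.005)
  # z-scores asymptotically standard normal under the null
  # allele counts are discrete, so jitter-free ties trigger a KS warning
  expect_gt(suppressWarnings(stats::ks.test(z, "pnorm"))$p.value, 1e-3)
  # with an effect, the mean log OR matches the closed-form target
  s2 <- binmeta:::.simStudyMat(2000, 0.3, 1.3, R)
  fc <- unname(caseControlMaf(0.3, 1.3)["case"])
  target <- log(fc / (1 - fc)) - log(0.3 / 0.7)
  expect_lt(abs(mean(s2$beta) - target), 3 * sd(s2$beta) / sqrt(R))
})

test_that("simulateStudy validates input and is deterministic under a seed", {
  expect_error(simulateStudy(5, 0.3, 1), "even")
  s1 <- simulateStudy(2000, 0.3, 1.3, seed = 4, label = "A")
  s2 <- simulateStudy(2000, 0.3, 1.3, seed = 4, label = "A")
  expect_identical(effectSizes(s1), effectSizes(s2))
  expect_identical(stdErrors(s1), stdErrors(s2))
  expect_gt(stdErrors(s1), 0)
  p1 <- simulatePanel(rep(1000, 5), rr = 1.2, seed = 9)
  p2 <- simulatePanel(rep(1000, 5), rr = 1.2, seed = 9)
  expect_identical(effectSizes(p1), effectSizes(p2))
})

test_that("false-positive-rate harness validates its design and reproduces", {
  expect_error(fprExperiment(replicates = 0), "positive")
  expect_error(fprExperiment(replicates = 100, thresholds = 1e-4),
               "infeasible")
  r1 <- fprExperiment(replicates = 3000, thresholds = 0.05,
                      methods = c("FE", "RE"), seed = 3)
  r2 <- fprExperiment(replicates = 3000, thresholds = 0.05,
                      methods = c("FE", "RE"), seed = 3)
  expect_identical(r1@table, r2@table)
  expect_true(all(r1@table$rate >= 0 & r1@table$rate <= 1))
  expect_true(all(r1@table$se > 0))
  feRate <- r1@table$rate[r1@table$method == "FE"]
  expect_lt(abs(feRate - 0.05), 3 * sqrt(0.05 * 0.95 / 3000))
})

test_that("histogram experiment filter and summaries behave", {
  r <- mvalueHistogramExperiment(nSets = 60, seed = 12)
  tab <- r@table
  expect_setequal(tab$type, c("large-effect", "small-effect", "large-null",
                              "small-null"))
  expect_true(all(tab$fracAboveUpper >= 0 & tab$fracAboveUpper <= 1))
  expect_equal(tab$fracAboveUpper + tab$fracBelowLower + tab$fracAmbiguous,
               rep(1, 4))
  expect_true(all(dim(r@details$mvalues) == c(8, 60)))
  # large effect studies concentrate high, large nulls low, small studies
  # mostly ambiguous (underpowered either way)
  expect_gt(tab$meanM[tab$type == "large-effect"], 0.9)
  expect_lt(tab$meanM[tab$type == "large-null"], 0.35)
  expect_gt(tab$fracAmbiguous[tab$type == "small-null"], 0.5)
  expect_gt(tab$fracAmbiguous[tab$type == "small-effect"], 0.4)
  # an unsatisfiable filter aborts rather than spinning
  expect_error(
    mvalueHistogramExperiment(nSets = 5, largeN = 50, smallN = 10, rr = 1.01,
                              seed = 1, maxCandidates = 6000),
    "candidates")
})

test_that("ROC experiment flags the degenerate all-effect design", {
  r <- rocExperiment(nSets = 30, kRange = 10, seed = 2, maxCandidates = 3e5)
  expect_true(r@details$degenerate)
  expect_true(all(is.na(r@table$auc[r@table$objective == "absence"])))
})

test_that("power harness reports rates in [0,1] with binomial errors", {
  r <- powerExperiment("binary", grid = c(5, 3), replicates = 120,
                       isSamples = 300, seed = 8)
  expect_equal(nrow(r@table), 6)
  expect_true(all(r@table$power >= 0 & r@table$power <= 1))
  expect_true(all(r@table$se >= 0))
  # strong heterogeneous signal: BE beats FE when 3 of 5 carry the effect
  p3 <- r@table[r@table$condition == 3, ]
  expect_gt(p3$power[p3$method == "BE"], p3$power[p3$method == "FE"])
})
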