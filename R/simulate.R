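#' Expected case and control allele frequencies under a relative risk
#'
#' Multiplicative per-allele risk model in the small-prevalence limit: the
#' control frequency stays at the population frequency and the case
#' frequency is
#' \deqn{f_{case} = f\,rr / (f\,rr + 1 - f).}
#'
#' @param maf population minor allele frequency, in (0, 1).
#' @param rr per-allele relative risk (> 0); 1 means no effect.
#' @return named numeric c(case = , control = ).
#' @examples
#' caseControlMaf(0.3, 1.3)  # case frequency ~0.3578
#' @export
caseControlMaf <- function(maf, rr) {
  if (!all(maf > 0 & maf < 1)) stop("'maf' must lie in (0, 1)", call. = FALSE)
  if (!all(rr > 0)) stop("'rr' must be > 0", call. = FALSE)
  c(case = maf * rr / (maf * rr + 1 - maf), control = maf + 0 * rr)
}

# allele counts for one arm: normal approximation to Binomial(a, f),
# rounded and clipped to [0, a]. 'a' is the allele count of the arm.
.simAlleleCount <- function(draws, a, f) {
  pmin(pmax(round(rnorm(draws, a * f, sqrt(a * f * (1 - f)))), 0), a)
}

# vectorized study simulator: R replicates of one study design.
# n and rr may be length 1 or R (per-replicate sizes / effect sizes).
# Returns list(beta, se), each length R.
.simStudyMat <- function(n, maf, rr, R) {
  a <- n                                # n/2 case individuals = n alleles
  fCase <- maf * rr / (maf * rr + 1 - maf)
  x1 <- .simAlleleCount(R, a, fCase)
  x0 <- .simAlleleCount(R, a, maf)
  # Haldane-Anscombe correction when any cell of the 2x2 allele table is 0
  zero <- x1 == 0 | x1 == a | x0 == 0 | x0 == a
  c11 <- x1 + 0.5 * zero; c12 <- a - x1 + 0.5 * zero
  c21 <- x0 + 0.5 * zero; c22 <- a - x0 + 0.5 * zero
  list(beta = log(c11 * c22 / (c12 * c21)),
       se = sqrt(1 / c11 + 1 / c12 + 1 / c21 + 1 / c22))
}

#' Simulate one case-control study's summary statistic
#'
#' Draws the minor allele counts of n/2 cases and n/2 controls from the
#' normal approximation to the binomial (rounded, clipped at the possible
#' range), forms the 2x2 allele table, and returns the log allele-count odds
#' ratio with its Woolf standard error (0.5 added to every cell when any
#' cell is zero).
#'
#' @param n total sample size (cases + controls), even and >= 4.
#' @param maf population minor allele frequency.
#' @param rr per-allele relative risk (1 = null).
#' @param seed optional integer seed.
#' @param label study name.
#' @return a \code{StudyEffect} carrying beta, se, n and maf.
#' @examples
#' simulateStudy(2000, maf = 0.3, rr = 1.3, seed = 1)
#' @export
simulateStudy <- function(n, maf = 0.3, rr = 1, seed = NULL,
                          label = NA_character_) {
  if (n < 4 || n %% 2 != 0) stop("'n' must be even and >= 4", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s <- .simStudyMat(n, maf, rr, 1L)
  StudyEffect(beta = s$beta, se = s$se, n = n, maf = maf, label = label)
}

#' Simulate a meta-analysis panel
#'
#' Convenience wrapper stacking \code{\link{simulateStudy}} draws into a
#' \code{MetaPanel}.
#'
#' @param sizes per-study total sample sizes (even, >= 4).
#' @param maf minor allele frequency shared by all studies.
#' @param rr per-study relative risks (recycled).
#' @param seed optional integer seed.
#' @param snpId variant identifier for the panel.
#' @return a \code{MetaPanel}.
#' @examples
#' simulatePanel(rep(1000, 5), rr = c(1.3, 1.3, 1.3, 1, 1), seed = 7)
#' @export
simulatePanel <- function(sizes, maf = 0.3, rr = 1, seed = NULL,
                          snpId = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  rr <- rep_len(rr, length(sizes))
  if (any(sizes < 4 | sizes %% 2 != 0))
    stop("all sizes must be even and >= 4", call. = FALSE)
  beta <- se <- numeric(length(sizes))
  for (j in seq_along(sizes)) {
    s <- .simStudyMat(sizes[j], maf, rr[j], 1L)
    beta[j] <- s$beta; se[j] <- s$se
  }
  MetaPanel(beta = beta, se = se, n = sizes, maf = rep(maf, length(sizes)),
            snpId = snpId)
}

# ---- vectorized RE over many panels ----------------------------------------

# grid-maximised RE LRT for a batch of panels; X, V are k x R matrices.
# Slightly conservative (grid misses the exact max); callers refine panels
# near a decision boundary with the scalar .reLRT.
.reLRTGridMat <- function(X, V, gridSize = 40L) {
  k <- nrow(X)
  ll0 <- colSums(dnorm(X, 0, sqrt(V), log = TRUE))
  hi <- max(X^2, 10 * V)
  grid <- c(0, exp(seq(log(hi * 1e-6), log(hi * 1.5),
                       length.out = gridSize - 1L)))
  best <- rep(-Inf, ncol(X))
  for (t2 in grid) {
    A <- 1 / (V + t2)
    mu <- colSums(X * A) / colSums(A)
    ll <- colSums(-0.5 * log(2 * pi * (V + t2)) -
                    0.5 * (X - rep(mu, each = k))^2 * A)
    best <- pmax(best, ll)
  }
  pmax(0, 2 * (best - ll0))
}

# RE p-values for a batch, with scalar refinement of panels whose grid
# p-value sits near any of 'refineNear' (within a factor of 4)
.rePvalsMat <- function(X, V, refineNear = numeric()) {
  p <- .reMixP(.reLRTGridMat(X, V))
  if (length(refineNear)) {
    idx <- unique(unlist(lapply(refineNear, function(t)
      which(p >= t / 4 & p <= t * 4))))
    for (j in idx)
      p[j] <- .reMixP(.reLRT(X[, j], V[, j])$stat)
  }
  p
}

.newReport <- function(name, table, replicates, seed, details = list()) {
  new("ExperimentReport", name = name, table = table,
      replicates = as.numeric(replicates),
      seed = as.numeric(if (is.null(seed)) NA else seed), details = details)
}

# ---- experiment harnesses ---------------------------------------------------

#' Null-panel false positive rate of the meta-analysis tests
#'
#' Simulates null meta-analysis panels (all relative risks 1) and reports,
#' for each method and significance threshold, the fraction of panels whose
#' p-value falls at or below the threshold, its binomial standard error, and
#' the ratio of the rate to the threshold.
#'
#' @param nStudies studies per panel.
#' @param sampleSize per-study total sample size.
#' @param replicates number of null panels; each reported threshold must
#'   satisfy threshold * replicates >= 50, otherwise the pairing is refused.
#' @param thresholds significance thresholds to report.
#' @param methods subset of c("FE", "RE", "BE").
#' @param isSamples importance samples per BE p-value.
#' @param maf minor allele frequency.
#' @param prior \code{EffectPrior} for BE.
#' @param seed integer seed.
#' @param chunkSize panels simulated per vectorised chunk.
#' @return an \code{ExperimentReport}; its table has one row per method x
#'   threshold.
#' @examples
#' fprExperiment(replicates = 2000, thresholds = 0.05, methods = "FE",
#'               seed = 1)
#' @export
fprExperiment <- function(nStudies = 5, sampleSize = 1000, replicates = 1e5,
                          thresholds = c(0.05, 1e-2, 1e-3),
                          methods = c("FE", "RE", "BE"), isSamples = 1000L,
                          maf = 0.3, prior = EffectPrior(), seed = NULL,
                          chunkSize = 1e5) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (replicates < 1) stop("'replicates' must be positive", call. = FALSE)
  if (any(thresholds * replicates < 50))
    stop("infeasible pairing: need threshold * replicates >= 50 for every ",
         "threshold (smallest gives ", min(thresholds) * replicates, ")",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  hits <- matrix(0, nrow = length(methods), ncol = length(thresholds),
                 dimnames = list(methods, NULL))
  done <- 0
  w <- rep(1, nStudies)           # equal sizes: sqrt(N) weights are equal
  while (done < replicates) {
    R <- min(chunkSize, replicates - done)
    beta <- se <- matrix(0, nStudies, R)
    for (j in seq_len(nStudies)) {
      s <- .simStudyMat(sampleSize, maf, 1, R)
      beta[j, ] <- s$beta; se[j, ] <- s$se
    }
    z <- beta / se
    if ("FE" %in% methods) {
      pFE <- 2 * pnorm(-abs(colSums(w * z) / sqrt(sum(w^2))))
      hits["FE", ] <- hits["FE", ] +
        vapply(thresholds, function(t) sum(pFE <= t), numeric(1))
    }
    if ("RE" %in% methods) {
      pRE <- .rePvalsMat(beta, se^2, refineNear = thresholds)
      hits["RE", ] <- hits["RE", ] +
        vapply(thresholds, function(t) sum(pRE <= t), numeric(1))
    }
    if ("BE" %in% methods) {
      pBE <- vapply(seq_len(R), function(r) {
        pn <- MetaPanel(beta = beta[, r], se = se[, r],
                        n = rep(sampleSize, nStudies))
        pValue(bePvalue(pn, prior, nSamples = isSamples))
      }, numeric(1))
      hits["BE", ] <- hits["BE", ] +
        vapply(thresholds, function(t) sum(pBE <= t), numeric(1))
    }
    done <- done + R
  }
  rate <- hits / replicates
  tab <- data.frame(
    method = rep(methods, times = length(thresholds)),
    threshold = rep(thresholds, each = length(methods)),
    rate = as.vector(rate),
    se = as.vector(.binomSe(rate, replicates)),
    ratio = as.vector(sweep(rate, 2, thresholds, "/")))
  .newReport("false-positive-rate", tab, replicates, seed,
             details = list(hits = hits, nStudies = nStudies,
                            sampleSize = sampleSize))
}

#' Four-study-type m-value histogram experiment
#'
#' Simulates meta-analysis sets of eight studies, two of each type: large
#' and small sample size crossed with effect present and absent. A set is
#' accepted only when no single study reaches genome-wide significance but
#' the random-effects meta-analysis does -- the regime where heterogeneity
#' interpretation matters. Exact m-values are computed for each accepted
#' set and summarised per study type.
#'
#' @param nSets accepted meta-analysis sets to collect.
#' @param largeN,smallN total sample sizes of the large and small studies.
#' @param rr relative risk of the effect-carrying studies.
#' @param maf minor allele frequency.
#' @param prior \code{EffectPrior} for the m-values.
#' @param gwThreshold genome-wide significance level for the acceptance
#'   filter.
#' @param upper,lower m-value prediction thresholds.
#' @param seed integer seed.
#' @param maxCandidates abort (with diagnostics) if this many candidate sets
#'   fail to yield \code{nSets} acceptances, or if the running acceptance
#'   rate falls below 1e-4.
#' @return an \code{ExperimentReport}: the table gives, per study type, the
#'   fraction of studies above \code{upper} and below \code{lower} (with
#'   binomial SEs); details carry the full m-value matrix, histogram counts
#'   and the acceptance rate.
#' @export
mvalueHistogramExperiment <- function(nSets = 1000, largeN = 2000,
                                      smallN = 200, rr = 1.3, maf = 0.3,
                                      prior = EffectPrior(),
                                      gwThreshold = 5e-8, upper = 0.9,
                                      lower = 0.1, seed = NULL,
                                      maxCandidates = 2e6) {
  if (!is.null(seed)) set.seed(seed)
  types <- c("large-effect", "large-effect", "small-effect", "small-effect",
             "large-null", "large-null", "small-null", "small-null")
  sizes <- c(largeN, largeN, smallN, smallN, largeN, largeN, smallN, smallN)
  rrs <- c(rr, rr, rr, rr, 1, 1, 1, 1)
  acc <- .collectAcceptedSets(nSets, sizes, maf, rrs, gwThreshold,
                              maxCandidates)
  M <- vapply(seq_len(nSets), function(i) {
    mvaluesExact(MetaPanel(beta = acc$beta[, i], se = acc$se[, i]), prior)@m
  }, numeric(length(types)))
  typeLevels <- unique(types)
  tab <- do.call(rbind, lapply(typeLevels, function(tp) {
    m <- as.vector(M[types == tp, ])
    data.frame(type = tp, studies = length(m),
               meanM = mean(m),
               fracAboveUpper = mean(m >= upper),
               fracBelowLower = mean(m <= lower),
               fracAmbiguous = mean(m > lower & m < upper),
               seAbove = .binomSe(mean(m >= upper), length(m)),
               seBelow = .binomSe(mean(m <= lower), length(m)))
  }))
  hist <- lapply(setNames(typeLevels, typeLevels), function(tp)
    table(cut(as.vector(M[types == tp, ]), breaks = seq(0, 1, 0.05),
              include.lowest = TRUE)))
  .newReport("mvalue-histogram", tab, nSets, seed,
             details = list(mvalues = M, types = types,
                            histograms = hist,
                            acceptanceRate = acc$rate,
                            candidates = acc$candidates))
}

# rejection-sample meta-analysis sets: keep a set iff no single-study
# p-value passes gwThreshold but the RE meta-analysis p-value does.
# The design is either fixed (sizes + rrs vectors) or drawn per candidate
# by 'designSampler', a function(R) returning list(sizes = k x R,
# rr = k x R).
.collectAcceptedSets <- function(nSets, sizes, maf, rrs, gwThreshold,
                                 maxCandidates, batch = 2000L,
                                 designSampler = NULL, k = length(sizes)) {
  got <- 0
  candidates <- 0
  beta <- se <- truth <- matrix(NA_real_, k, nSets)
  while (got < nSets) {
    if (candidates >= maxCandidates)
      stop("rejection sampler exhausted ", maxCandidates, " candidates with ",
           got, " acceptances (rate ", signif(got / candidates, 3),
           "); the filter may be unsatisfiable for this design",
           call. = FALSE)
    if (is.null(designSampler)) {
      rrMat <- matrix(rrs, k, batch)
      sizeMat <- matrix(sizes, k, batch)
    } else {
      d <- designSampler(batch)
      rrMat <- d$rr
      sizeMat <- d$sizes
    }
    b <- s <- matrix(0, k, batch)
    for (j in seq_len(k)) {
      sim <- .simStudyMat(sizeMat[j, ], maf, rrMat[j, ], batch)
      b[j, ] <- sim$beta; s[j, ] <- sim$se
    }
    candidates <- candidates + batch
    pSingle <- 2 * pnorm(-abs(b / s))
    pass1 <- colSums(pSingle <= gwThreshold) == 0
    keep <- which(pass1)
    if (length(keep)) {
      pRE <- .rePvalsMat(b[, keep, drop = FALSE], s[, keep, drop = FALSE]^2,
                         refineNear = gwThreshold)
      keep <- keep[pRE <= gwThreshold]
    }
    if (length(keep)) {
      take <- keep[seq_len(min(length(keep), nSets - got))]
      idx <- got + seq_along(take)
      beta[, idx] <- b[, take]
      se[, idx] <- s[, take]
      truth[, idx] <- rrMat[, take] != 1
      got <- got + length(take)
    }
    if (candidates >= 5e4 && got / candidates < 1e-4)
      stop("acceptance rate ", signif(got / candidates, 3),
           " below 1e-4 after ", candidates, " candidates; aborting",
           call. = FALSE)
  }
  list(beta = beta, se = se, truth = truth, rate = got / candidates,
       candidates = candidates)
}

# rank-based AUC (probability a positive outranks a negative)
.auc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# threshold-sweep ROC points
.rocPoints <- function(score, positive) {
  o <- order(score, decreasing = TRUE)
  tpr <- cumsum(positive[o]) / sum(positive)
  fpr <- cumsum(!positive[o]) / sum(!positive)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' ROC comparison of p-value, m-value and asymptotic Bayes factor
#'
#' Simulates meta-analyses of \code{nStudies} studies in which a random
#' subset carries the effect, keeps the sets that pass the same acceptance
#' filter as the histogram experiment, and evaluates how well the per-study
#' p-value, m-value and Wakefield asymptotic Bayes factor predict which
#' studies truly carry the effect (and which do not), as ROC curves over all
#' studies pooled across sets.
#'
#' @param nSets accepted meta-analysis sets.
#' @param nStudies studies per set.
#' @param sizeRange range of per-study total sample sizes (drawn uniformly,
#'   rounded to even).
#' @param kRange possible numbers of effect-carrying studies (drawn
#'   uniformly).
#' @param rr relative risk where the effect is present.
#' @param maf minor allele frequency.
#' @param prior \code{EffectPrior}; its sigma is also used for the Bayes
#'   factor.
#' @param gwThreshold genome-wide threshold for the acceptance filter.
#' @param seed integer seed.
#' @param maxCandidates rejection-sampler budget.
#' @return an \code{ExperimentReport}: the table holds AUCs per objective
#'   (presence/absence of effect) and statistic; details carry ROC points
#'   and the per-study table.
#' @export
rocExperiment <- function(nSets = 1000, nStudies = 10,
                          sizeRange = c(500, 2000), kRange = 1:9, rr = 1.3,
                          maf = 0.3, prior = EffectPrior(),
                          gwThreshold = 5e-8, seed = NULL,
                          maxCandidates = 5e6) {
  if (!is.null(seed)) set.seed(seed)
  designSampler <- function(R) {
    rrMat <- vapply(seq_len(R), function(i) {
      kk <- if (length(kRange) == 1) kRange else sample(kRange, 1)
      rrv <- rep(1, nStudies)
      rrv[sample.int(nStudies, kk)] <- rr
      rrv
    }, numeric(nStudies))
    sizeMat <- matrix(2 * round(runif(nStudies * R, sizeRange[1],
                                      sizeRange[2]) / 2),
                      nStudies, R)
    list(rr = rrMat, sizes = sizeMat)
  }
  acc <- .collectAcceptedSets(nSets, NULL, maf, NULL, gwThreshold,
                              maxCandidates, designSampler = designSampler,
                              k = nStudies)
  M <- vapply(seq_len(nSets), function(i) {
    mvaluesExact(MetaPanel(beta = acc$beta[, i], se = acc$se[, i]), prior)@m
  }, numeric(nStudies))
  pvals <- 2 * pnorm(-abs(acc$beta / acc$se))
  lbf <- matrix(abfWakefield(MetaPanel(beta = as.vector(acc$beta),
                                       se = as.vector(acc$se)),
                             sigma = prior@sigma, log = TRUE),
                nStudies, nSets)
  truth <- acc$truth == 1
  m <- as.vector(M); p <- as.vector(pvals); b <- as.vector(lbf)
  hasEffect <- as.vector(truth)
  degenerate <- all(hasEffect) || !any(hasEffect)
  tab <- data.frame(
    objective = rep(c("presence", "absence"), each = 3),
    statistic = rep(c("mvalue", "abf", "pvalue"), 2),
    auc = c(.auc(m, hasEffect), .auc(b, hasEffect), .auc(-p, hasEffect),
            .auc(-m, !hasEffect), .auc(-b, !hasEffect), .auc(p, !hasEffect)))
  rocs <- if (degenerate) list() else list(
    presence = list(mvalue = .rocPoints(m, hasEffect),
                    abf = .rocPoints(b, hasEffect),
                    pvalue = .rocPoints(-p, hasEffect)),
    absence = list(mvalue = .rocPoints(-m, !hasEffect),
                   abf = .rocPoints(-b, !hasEffect),
                   pvalue = .rocPoints(p, !hasEffect)))
  .newReport("roc-comparison", tab, nSets, seed,
             details = list(roc = rocs, degenerate = degenerate,
                            perStudy = data.frame(m = m, p = p, logBF = b,
                                                  hasEffect = hasEffect),
                            acceptanceRate = acc$rate))
}

#' Power of FE, RE and BE under binary or normally-distributed heterogeneity
#'
#' In \code{binary} mode, a fixed number of the studies carries the effect
#' (swept over \code{grid}, by default 5 down to 2 of 5 studies, with the
#' relative risk rising as fewer studies carry it so power stays in a
#' comparable range). In \code{lognormal} mode all studies carry an effect
#' whose log relative risk is drawn per study from a normal distribution
#' with mean log(meanRR) and standard deviation hetRatio * log(meanRR),
#' sweeping \code{grid} over hetRatio. Power is the fraction of replicates
#' whose meta-analysis p-value reaches \code{gwThreshold}.
#'
#' @param mode "binary" or "lognormal".
#' @param grid conditions to sweep: numbers of effect studies (binary;
#'   default 5:2) or heterogeneity ratios (lognormal; default 0, 0.25, ...,
#'   1).
#' @param replicates meta-analysis sets per condition.
#' @param nStudies,sampleSize,maf panel design.
#' @param rrLadder named relative risks per number-of-effect-studies
#'   (binary mode).
#' @param meanRR mean relative risk (lognormal mode).
#' @param gwThreshold genome-wide significance level.
#' @param isSamples importance samples per BE p-value.
#' @param prior \code{EffectPrior} for BE.
#' @param seed integer seed.
#' @return an \code{ExperimentReport}; the table has one row per condition
#'   x method with the power and its binomial SE.
#' @export
powerExperiment <- function(mode = c("binary", "lognormal"), grid = NULL,
                            replicates = 1000, nStudies = 5,
                            sampleSize = 1000, maf = 0.3,
                            rrLadder = c("5" = 1.3, "4" = 1.35, "3" = 1.45,
                                         "2" = 1.6),
                            meanRR = 1.3, gwThreshold = 5e-8,
                            isSamples = 1000L, prior = EffectPrior(),
                            seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(grid))
    grid <- if (mode == "binary") nStudies:2 else seq(0, 1, 0.25)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (g in grid) {
    beta <- se <- matrix(0, nStudies, replicates)
    if (mode == "binary") {
      rrv <- rep(1, nStudies)
      rrv[seq_len(g)] <- rrLadder[as.character(g)]
      if (anyNA(rrv)) stop("rrLadder has no entry for ", g, call. = FALSE)
      for (j in seq_len(nStudies)) {
        s <- .simStudyMat(sampleSize, maf, rrv[j], replicates)
        beta[j, ] <- s$beta; se[j, ] <- s$se
      }
    } else {
      sdLog <- g * log(meanRR)
      for (j in seq_len(nStudies)) {
        rrj <- exp(rnorm(replicates, log(meanRR), sdLog))
        s <- .simStudyMat(sampleSize, maf, rrj, replicates)
        beta[j, ] <- s$beta; se[j, ] <- s$se
      }
    }
    z <- beta / se
    pFE <- 2 * pnorm(-abs(colSums(z) / sqrt(nStudies)))
    pRE <- .rePvalsMat(beta, se^2, refineNear = gwThreshold)
    pBE <- vapply(seq_len(replicates), function(r) {
      pn <- MetaPanel(beta = beta[, r], se = se[, r],
                      n = rep(sampleSize, nStudies))
      pValue(bePvalue(pn, prior, nSamples = isSamples))
    }, numeric(1))
    for (meth in c("FE", "RE", "BE")) {
      p <- switch(meth, FE = pFE, RE = pRE, BE = pBE)
      pw <- mean(p <= gwThreshold)
      rows[[length(rows) + 1]] <- data.frame(
        condition = g, method = meth, power = pw,
        se = .binomSe(pw, replicates))
    }
  }
  .newReport(paste0("power-", mode), do.call(rbind, rows), replicates, seed,
             details = list(mode = mode, grid = grid,
                            gwThreshold = gwThreshold))
}
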