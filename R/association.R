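#' Resolve per-study weights for the weighted-z statistics
#'
#' @param panel a \code{MetaPanel}.
#' @param scheme a \code{WeightScheme}, a mode name ("auto", "sqrt_n",
#'   "maf_adjusted", "precision") or a numeric vector of custom positive
#'   weights.
#' @return numeric weights, one per study, normalised to mean 1 (the
#'   weighted-z statistics are invariant to the scale of the weights).
#' @examples
#' p <- MetaPanel(beta = c(0.2, 0.1), se = c(0.1, 0.1), n = c(2000, 500))
#' studyWeights(p)               # sqrt(N) weights
#' studyWeights(p, "precision")  # 1/se weights
#' @export
studyWeights <- function(panel, scheme = WeightScheme()) {
  panel <- .asPanel(panel)
  k <- nStudies(panel)
  if (is.numeric(scheme)) scheme <- WeightScheme("custom", weights = scheme)
  if (is.character(scheme)) scheme <- WeightScheme(scheme)
  validObject(scheme)
  mode <- scheme@mode
  if (mode == "auto")
    mode <- if (all(is.finite(panel@n))) "sqrt_n" else "precision"
  w <- switch(mode,
    sqrt_n = {
      if (!all(is.finite(panel@n)))
        stop("sqrt_n weighting needs a sample size for every study",
             call. = FALSE)
      sqrt(panel@n)
    },
    maf_adjusted = {
      if (!all(is.finite(panel@n)) || !all(is.finite(panel@maf)))
        stop("maf_adjusted weighting needs n and maf for every study",
             call. = FALSE)
      sqrt(2 * panel@maf * (1 - panel@maf) * panel@n)
    },
    precision = 1 / panel@se,
    custom = {
      if (length(scheme@weights) != k)
        stop("custom weights must match the number of studies", call. = FALSE)
      scheme@weights
    })
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be finite and strictly positive", call. = FALSE)
  w / mean(w)
}

#' Fixed-effects meta-analysis: weighted sum of z-scores
#'
#' \deqn{Z = \sum_i w_i z_i / \sqrt{\sum_i w_i^2}}
#' with z_i = beta_i / se_i, compared against the standard normal
#' (two-sided). With precision weights this is equivalent to the
#' inverse-variance fixed-effects test.
#'
#' @inheritParams studyWeights
#' @return a \code{TestResult} with method "FE".
#' @examples
#' p <- MetaPanel(beta = c(0.3, 0.25), se = c(0.1, 0.1))
#' feWeightedZ(p)
#' @export
feWeightedZ <- function(panel, scheme = WeightScheme()) {
  panel <- .asPanel(panel)
  w <- studyWeights(panel, scheme)
  z <- panel@beta / panel@se
  Z <- sum(w * z) / sqrt(sum(w^2))
  p <- 2 * pnorm(-abs(Z))
  new("TestResult", statistic = Z, pvalue = max(p, 1e-300), method = "FE")
}

# profile log-likelihood of the random-effects model at a given tau^2
.reProfile <- function(tau2, x, v) {
  a <- 1 / (v + tau2)
  mu <- sum(x * a) / sum(a)
  sum(dnorm(x, mu, sqrt(v + tau2), log = TRUE))
}

# accurate RE likelihood-ratio statistic for one panel: coarse grid over
# tau^2 followed by local optimize(); the boundary tau^2 = 0 is always
# considered
.reLRT <- function(x, v) {
  ll0 <- sum(dnorm(x, 0, sqrt(v), log = TRUE))
  hi <- max(max(x^2), 10 * max(v))
  grid <- c(0, exp(seq(log(hi * 1e-6), log(hi * 1.5), length.out = 40)))
  prof <- vapply(grid, .reProfile, numeric(1), x = x, v = v)
  i <- which.max(prof)
  lo <- grid[max(1, i - 1)]
  up <- grid[min(length(grid), i + 1)]
  best <- prof[i]
  if (up > lo) {
    opt <- optimize(.reProfile, c(lo, up), x = x, v = v, maximum = TRUE,
                    tol = .Machine$double.eps^0.5)
    if (opt$objective > best) {
      best <- opt$objective
      i <- NA
      tau2 <- opt$maximum
    } else tau2 <- grid[i]
  } else tau2 <- grid[i]
  a <- 1 / (v + tau2)
  list(stat = max(0, 2 * (best - ll0)), tau2 = tau2,
       mu = sum(x * a) / sum(a))
}

# p-value from the boundary-corrected null mixture 0.5 chi2_1 + 0.5 chi2_2
.reMixP <- function(q) {
  0.5 * pchisq(q, 1, lower.tail = FALSE) + 0.5 * pchisq(q, 2, lower.tail = FALSE)
}

#' Random-effects meta-analysis test of Han and Eskin
#'
#' Likelihood-ratio test of association allowing heterogeneity: the observed
#' effects X_i ~ N(mu, V_i + tau^2) are maximised over the mean effect mu
#' and the between-study variance tau^2 >= 0, against the null mu = tau^2
#' = 0. Because tau^2 sits on the boundary under the null, the statistic is
#' referred to the mixture 0.5 chi^2(1) + 0.5 chi^2(2). This asymptotic null
#' is used as-is; the tabulated small-study correction of the original
#' method is not applied, which can matter at very stringent thresholds with
#' few studies.
#'
#' @param panel a \code{MetaPanel}.
#' @return a \code{TestResult} with method "RE"; \code{extra} carries the
#'   estimates \code{mu} and \code{tau2}.
#' @examples
#' p <- MetaPanel(beta = c(0.35, 0.30, 0.02), se = c(0.08, 0.09, 0.08))
#' reHanEskin(p)
#' @export
reHanEskin <- function(panel) {
  panel <- .asPanel(panel)
  fit <- .reLRT(panel@beta, panel@se^2)
  if (!is.finite(fit$stat))
    stop("random-effects maximisation failed: non-finite statistic for SNP ",
         panel@snpId, " (beta = ", paste(signif(panel@beta, 3), collapse = ","),
         ")", call. = FALSE)
  new("TestResult", statistic = fit$stat,
      pvalue = max(.reMixP(fit$stat), 1e-300), method = "RE",
      extra = list(mu = fit$mu, tau2 = fit$tau2))
}

#' Wakefield's asymptotic Bayes factor for one study
#'
#' Compares H1: true effect ~ N(0, sigma^2) against H0: no effect, using
#' only the study's estimate and standard error:
#' \deqn{BF = \sqrt{V/(V+\sigma^2)}\; \exp\!\big(z^2 \sigma^2 / (2 (V+\sigma^2))\big)}
#' with V = se^2 and z = beta/se. Values above 1 favour the presence of an
#' effect.
#'
#' @param study a \code{StudyEffect} (or a \code{MetaPanel}, returning one
#'   BF per study).
#' @param sigma prior SD of the effect size under H1.
#' @param log return the log Bayes factor.
#' @return numeric Bayes factor(s).
#' @examples
#' abfWakefield(StudyEffect(beta = 0.3, se = 0.1))
#' @export
abfWakefield <- function(study, sigma = 0.2, log = FALSE) {
  if (!(is.numeric(sigma) && length(sigma) == 1 && sigma > 0))
    stop("'sigma' must be a single value > 0", call. = FALSE)
  if (is(study, "MetaPanel")) {
    beta <- study@beta; se <- study@se
  } else if (is(study, "StudyEffect")) {
    beta <- study@beta; se <- study@se
  } else stop("'study' must be a StudyEffect or MetaPanel", call. = FALSE)
  V <- se^2
  z2 <- (beta / se)^2
  lbf <- 0.5 * (log(V) - log(V + sigma^2)) + z2 * sigma^2 / (2 * (V + sigma^2))
  if (log) lbf else exp(lbf)
}

#' Binary effects model statistic
#'
#' The weighted sum of z-scores with each study's weight multiplied by its
#' m-value, so studies predicted to carry the effect dominate and studies
#' predicted not to carry it drop out:
#' \deqn{S = \sum_i m_i w_i z_i / \sqrt{\sum_i (m_i w_i)^2}.}
#' When all m_i are equal it reduces to the fixed-effects weighted-z
#' statistic.
#'
#' @param panel a \code{MetaPanel}.
#' @param m an \code{MValueResult} or numeric vector of m-values for the
#'   same panel.
#' @param scheme weight scheme, as in \code{\link{studyWeights}}.
#' @return the statistic (single numeric).
#' @examples
#' p <- MetaPanel(beta = c(0.3, 0.28, 0.0), se = c(0.08, 0.09, 0.07))
#' beStatistic(p, mvaluesExact(p))
#' @export
beStatistic <- function(panel, m, scheme = WeightScheme()) {
  panel <- .asPanel(panel)
  mv <- if (is(m, "MValueResult")) m@m else as.numeric(m)
  if (length(mv) != nStudies(panel))
    stop("m-values must match the panel's studies", call. = FALSE)
  if (any(mv < 0 | mv > 1)) stop("m-values must lie in [0, 1]", call. = FALSE)
  if (all(mv == 0))
    stop("all m-values are zero: the binary effects statistic is undefined",
         call. = FALSE)
  w <- studyWeights(panel, scheme)
  z <- panel@beta / panel@se
  sum(mv * w * z) / sqrt(sum((mv * w)^2))
}

# m-values for many draws at once, exact enumeration vectorized over draws.
# se (and hence the configuration precisions) fixed; Xmat is n x ndraws.
# Returns an n x ndraws matrix of m-values.
.mvaluesForDraws <- function(se, Xmat, prior) {
  n <- length(se)
  w <- 1 / se^2
  B <- .configMatrix(n)
  W <- as.vector(B %*% w)
  k <- as.vector(B %*% rep(1, n))
  lprior <- .logConfigPriorByCount(n, prior)[k + 1]
  S <- B %*% (w * Xmat)
  LP <- (-0.5 * log1p(prior@sigma^2 * W) + lprior) +
    0.5 * S^2 / (W + 1 / prior@sigma^2)
  cmax <- LP[cbind(max.col(t(LP)), seq_len(ncol(LP)))]
  P <- exp(sweep(LP, 2, cmax))
  M <- crossprod(B, P)
  sweep(M, 2, colSums(P), "/")
}

# Importance-sampling proposal for the BE null tail. The tail event
# |S_null| >= s can be reached through many heterogeneity patterns: all n
# z-scores moderately large, or a few studies very large (the m-value
# weighting makes such draws score highly). The proposal is therefore a
# defensive mixture: a fraction eps of plain null draws, and for each
# subset scale k (1..n, thinned for large n) and each sign, a component
# that tilts every coordinate independently with probability k/n by
# +/- s/sqrt(k) (the per-study shift that puts a typical k-subset draw at
# statistic s). Component densities are products of per-coordinate
# two-point normal mixtures, so the exact mixture density -- and hence an
# unbiased, bounded (<= 1/eps) importance weight -- is cheap to evaluate.
# Returns the draws, their weights, and the per-stratum allocation.
.beImportanceDraws <- function(n, nSamples, s, eps = 0.2) {
  kSet <- if (n <= 6) seq_len(n) else
    unique(round(exp(seq(log(1), log(n), length.out = 6))))
  comps <- rbind(expand.grid(k = kSet, sign = c(1, -1)),
                 data.frame(k = 0, sign = 0))       # last = defensive null
  nc <- nrow(comps)
  counts <- rep(0L, nc)
  counts[nc] <- max(2L, round(eps * nSamples))
  tilted <- nSamples - counts[nc]
  counts[-nc] <- tilted %/% (nc - 1L)
  rem <- tilted - sum(counts[-nc])
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  prop <- counts / nSamples

  Z <- matrix(rnorm(n * nSamples), nrow = n)
  off <- 0L
  for (j in seq_len(nc - 1L)) {
    if (counts[j] == 0L) next
    k <- comps$k[j]
    cols <- off + seq_len(counts[j])
    shift <- comps$sign[j] * (s / sqrt(k)) *
      (matrix(runif(n * counts[j]), n) < k / n)
    Z[, cols] <- Z[, cols] + shift
    off <- off + counts[j]
  }

  logNull <- colSums(dnorm(Z, log = TRUE))
  # log density of each product-mixture component, all draws at once
  logComp <- matrix(-Inf, nc, nSamples)
  for (j in seq_len(nc - 1L)) {
    k <- comps$k[j]
    ck <- comps$sign[j] * s / sqrt(k)
    rho <- k / n
    # per-coordinate: (1-rho) phi(z) + rho phi(z - ck)
    lr <- ck * Z - ck^2 / 2                      # log phi(z-ck) - log phi(z)
    logComp[j, ] <- logNull +
      colSums(log1p(rho * expm1(lr)))
  }
  logComp[nc, ] <- logNull
  lmix <- log(prop) + logComp
  hi <- lmix[1, ]
  for (r in 2:nc) hi <- pmax(hi, lmix[r, ])
  logMix <- hi + log(colSums(exp(sweep(lmix, 2, hi))))
  list(Z = Z, weight = exp(logNull - logMix), counts = counts)
}

# m-values for the draws of the null sampler, honouring the enumeration
# limit: exact for n <= exactLimit, reduced-sample MCMC beyond
.nullDrawMvalues <- function(se, Xmat, prior, exactLimit = 14L,
                             mcmcSamples = 2000L) {
  n <- length(se)
  if (n <= exactLimit) return(.mvaluesForDraws(se, Xmat, prior))
  vapply(seq_len(ncol(Xmat)), function(j) {
    p <- MetaPanel(beta = Xmat[, j], se = se)
    mvaluesMCMC(p, prior, burnin = 200L, samples = mcmcSamples)@m
  }, numeric(n))
}

#' Binary effects p-value by importance sampling
#'
#' The BE statistic depends on the data twice (through the z-scores and
#' through the m-values), so its null distribution is not normal and the
#' p-value P(|S_null| >= |S_obs|) is estimated by sampling: null panels draw
#' z_i ~ N(0,1) with the observed standard errors and weights, and the
#' m-values are recomputed for every draw.
#'
#' Sampling uses exponential tilting with a defensive mixture: draws come
#' from z ~ N(+delta, 1) and z ~ N(-delta, 1) (40\% each) and from the null
#' N(0, 1) itself (20\%), with the tilt delta proportional to the per-study
#' weights and scaled so the proposal's mean fixed-effects statistic equals
#' |S_obs|; each draw is reweighted by the ratio of the null density to the
#' three-component mixture density (balance heuristic). The defensive null
#' component bounds the importance weights at 5, which keeps the empirical
#' standard error of the estimate honest. The estimator is unbiased for the
#' plain Monte-Carlo tail probability, and its standard error is reported.
#'
#' @param panel a \code{MetaPanel}.
#' @param prior an \code{EffectPrior} for the m-values.
#' @param scheme weight scheme, as in \code{\link{studyWeights}}.
#' @param nSamples number of importance samples (>= 100).
#' @param seed integer seed; NULL leaves the RNG state alone.
#' @param exactLimit largest study count for which the per-draw m-values are
#'   enumerated exactly (beyond it a reduced-sample MCMC is used).
#' @return a \code{TestResult} with method "BE"; \code{extra} carries the
#'   observed m-values, the adaptive stage (if any) and an \code{unstable}
#'   flag raised when fewer than 10 draws landed in the tail.
#' @examples
#' p <- MetaPanel(beta = c(0.3, 0.28, 0.0), se = c(0.08, 0.09, 0.07))
#' bePvalue(p, nSamples = 1000, seed = 1)
#' @seealso \code{\link{beAdaptive}} for the two-stage screening version.
#' @export
bePvalue <- function(panel, prior = EffectPrior(), scheme = WeightScheme(),
                     nSamples = 10000L, seed = NULL, exactLimit = 14L) {
  panel <- .asPanel(panel)
  prior <- .asPrior(prior)
  if (nSamples < 100) stop("need at least 100 samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nStudies(panel)
  w <- studyWeights(panel, scheme)
  se <- panel@se

  mObs <- if (n <= exactLimit) mvaluesExact(panel, prior)
          else mvaluesMCMC(panel, prior, burnin = 500L, samples = 2000L)
  sObs <- beStatistic(panel, mObs, w)

  is <- .beImportanceDraws(n, nSamples, abs(sObs))
  Z <- is$Z

  M <- .nullDrawMvalues(se, Z * se, prior, exactLimit)
  num <- colSums(M * (w * Z))
  den <- sqrt(colSums((M * w)^2))
  sNull <- ifelse(den > 0, num / den, 0)

  terms <- is$weight * (abs(sNull) >= abs(sObs))
  counts <- is$counts
  strata <- rep(seq_along(counts), counts)
  means <- vapply(seq_along(counts), function(s)
    mean(terms[strata == s]), numeric(1))
  vars <- vapply(seq_along(counts), function(s) {
    x <- terms[strata == s]
    if (length(x) < 2) 0 else stats::var(x)
  }, numeric(1))
  prop <- counts / nSamples
  pHat <- sum(prop * means)
  pSe <- sqrt(sum(prop^2 * vars / pmax(counts, 1)))
  nTail <- sum(abs(sNull) >= abs(sObs))
  new("TestResult", statistic = sObs,
      pvalue = min(1, max(pHat, 1e-300)), method = "BE",
      nSamples = nSamples, pSe = max(pSe, 1e-300),
      extra = list(mvalues = mObs, unstable = nTail < 10, rawP = pHat,
                   tailHits = nTail))
}

#' Adaptive two-stage binary effects p-value
#'
#' Screens with a small importance-sampling run and re-estimates with a
#' large one only when the first-stage p-value is at most
#' \code{promoteThreshold}. This is the economical way to run the BE test
#' over many loci: most null loci stop at stage 1.
#'
#' @inheritParams bePvalue
#' @param nSmall,nLarge stage-1 and stage-2 sample counts, nSmall < nLarge.
#' @param promoteThreshold first-stage p-value at or below which stage 2 is
#'   run.
#' @return a \code{TestResult}; \code{extra$stage} records which stage
#'   produced it. A promoted result is identical to calling
#'   \code{bePvalue(..., nSamples = nLarge)} with the same seed.
#' @export
beAdaptive <- function(panel, prior = EffectPrior(), scheme = WeightScheme(),
                       nSmall = 1000L, nLarge = 10000L,
                       promoteThreshold = 0.01, seed = NULL,
                       exactLimit = 14L) {
  if (!(nSmall < nLarge)) stop("need nSmall < nLarge", call. = FALSE)
  r1 <- bePvalue(panel, prior, scheme, nSamples = nSmall, seed = seed,
                 exactLimit = exactLimit)
  if (pValue(r1) > promoteThreshold) {
    r1@extra$stage <- 1L
    return(r1)
  }
  r2 <- bePvalue(panel, prior, scheme, nSamples = nLarge, seed = seed,
                 exactLimit = exactLimit)
  r2@extra$stage <- 2L
  r2
}
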