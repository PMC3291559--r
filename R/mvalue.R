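#' Log prior probability of an effect configuration
#'
#' Prior on the binary vector c saying which studies carry the effect,
#' obtained by integrating the per-study Bernoulli probability p over its
#' Beta(alpha, beta) prior:
#' \deqn{P(c) = B(k + \alpha, n - k + \beta) / B(\alpha, \beta)}
#' where k is the number of 1s in c and B the beta function. The 2^n
#' configuration probabilities sum to one.
#'
#' @param config a \code{Configuration} or plain 0/1 vector of length
#'   \code{n}.
#' @param prior an \code{EffectPrior}; only the beta shapes are used.
#' @param n number of studies; defaults to the configuration length.
#' @return the log prior probability (a single numeric).
#' @examples
#' exp(logConfigPrior(c(1, 0), EffectPrior()))  # 1/6 under the uniform prior
#' @export
logConfigPrior <- function(config, prior = EffectPrior(), n = NULL) {
  bits <- .asBits(config)
  prior <- .asPrior(prior)
  if (is.null(n)) n <- length(bits)
  if (length(bits) != n)
    stop("configuration length ", length(bits), " does not match n = ", n,
         call. = FALSE)
  k <- sum(bits)
  lbeta(k + prior@alpha, n - k + prior@beta) - lbeta(prior@alpha, prior@beta)
}

# log prior for every count 0..n (internal, reused by enumeration)
.logConfigPriorByCount <- function(n, prior) {
  k <- 0:n
  lbeta(k + prior@alpha, n - k + prior@beta) - lbeta(prior@alpha, prior@beta)
}

# The collapsed likelihood term of the "ones" set. With precisions w_i = 1/V_i
# restricted to the studies carrying the effect, W = sum w_i and S = sum
# w_i X_i, integrating the shared effect mu over N(0, sigma^2) gives
#   integral = [prod_i N(X_i; 0, V_i)] * g(W, S)  with
#   log g(W, S) = -0.5 log(1 + sigma^2 W) + 0.5 S^2 / (W + 1/sigma^2),
# so the full panel log marginal likelihood is
#   sum_i log N(X_i; 0, V_i) + log g(W_ones, S_ones).
# (Complete-the-square over mu; the empty set gives log g(0,0) = 0.)
.logG <- function(W, S, sigma) {
  -0.5 * log1p(sigma^2 * W) + 0.5 * S^2 / (W + 1 / sigma^2)
}

#' Log marginal likelihood of a panel under an effect configuration
#'
#' P(X | c): studies without the effect contribute a N(0, V_i) density for
#' their observed effect X_i; studies with the effect contribute the closed
#' form of the integral over the shared true effect,
#' \deqn{\int \prod_{i \in ones} N(X_i; \mu, V_i)\, N(\mu; 0, \sigma^2)\, d\mu,}
#' evaluated analytically via the precisions w_i = 1/V_i. The value is a
#' proper joint density over the observed effect sizes.
#'
#' @param panel a \code{MetaPanel}.
#' @param config a \code{Configuration} or 0/1 vector matching the panel.
#' @param prior an \code{EffectPrior}; sigma is the prior SD of the shared
#'   effect.
#' @return the log density (single numeric).
#' @examples
#' p <- MetaPanel(beta = c(0.30, 0.25), se = c(0.10, 0.10))
#' logMarginalLikelihood(p, c(1, 1))
#' logMarginalLikelihood(p, c(0, 0))  # pure null density
#' @export
logMarginalLikelihood <- function(panel, config, prior = EffectPrior()) {
  panel <- .asPanel(panel)
  prior <- .asPrior(prior)
  bits <- .asBits(config)
  if (length(bits) != nStudies(panel))
    stop("configuration length does not match the number of studies",
         call. = FALSE)
  V <- panel@se^2
  w <- 1 / V
  nullTerm <- sum(dnorm(panel@beta, 0, panel@se, log = TRUE))
  on <- bits == 1L
  W <- sum(w[on])
  S <- sum((w * panel@beta)[on])
  nullTerm + .logG(W, S, prior@sigma)
}

# Joint log posterior (up to the evidence) over all 2^n configurations,
# vectorized. Returns list(B = config matrix, lp = log posterior weights).
.configLogPosterior <- function(panel, prior) {
  n <- nStudies(panel)
  w <- 1 / panel@se^2
  B <- .configMatrix(n)
  W <- as.vector(B %*% w)
  S <- as.vector(B %*% (w * panel@beta))
  k <- as.vector(B %*% rep(1, n))
  lp <- .logG(W, S, prior@sigma) + .logConfigPriorByCount(n, prior)[k + 1]
  list(B = B, lp = lp)
}

#' Exact m-values by configuration enumeration
#'
#' Computes the posterior probability that each study carries the effect by
#' enumerating all 2^n effect configurations:
#' \deqn{m_i = \sum_{c: c_i = 1} P(X|c) P(c) \Big/ \sum_c P(X|c) P(c),}
#' with all arithmetic in log space. Enumeration is refused above
#' \code{limit} studies (default 20, about a million configurations);
#' use \code{\link{mvaluesMCMC}} beyond that.
#'
#' @param panel a \code{MetaPanel}.
#' @param prior an \code{EffectPrior}.
#' @param limit largest study count enumerated exactly.
#' @return an \code{MValueResult} with method "exact".
#' @examples
#' p <- MetaPanel(beta = c(0.3, 0.28, 0.01), se = c(0.08, 0.09, 0.07))
#' mvalues(mvaluesExact(p))
#' @seealso \code{\link{mvaluesMCMC}}, \code{\link{classifyStudies}}
#' @export
mvaluesExact <- function(panel, prior = EffectPrior(), limit = 20L) {
  panel <- .asPanel(panel)
  prior <- .asPrior(prior)
  n <- nStudies(panel)
  if (n > limit)
    stop("exact enumeration over 2^", n, " configurations refused ",
         "(limit ", limit, "); use mvaluesMCMC() for this many studies",
         call. = FALSE)
  cp <- .configLogPosterior(panel, prior)
  logZ <- .logSumExp(cp$lp)
  post <- exp(cp$lp - logZ)
  m <- as.vector(crossprod(cp$B, post))
  m <- pmin(pmax(m, 0), 1)
  new("MValueResult", m = m, method = "exact", mcSe = rep(0, n),
      prior = prior, labels = panel@labels)
}

#' m-values by Metropolis-Hastings sampling over configurations
#'
#' Random-walk sampler on the space of binary effect configurations. From the
#' current configuration, a move is picked uniformly between flipping one
#' random study's bit and shuffling (uniformly permuting) the whole bit
#' vector; both proposals are symmetric, so the acceptance probability is the
#' plain posterior ratio. The shuffle move lets the chain jump between modes
#' when observed effect directions conflict. m_i is the fraction of retained
#' samples in which study i carries the effect; its Monte-Carlo standard
#' error is the binomial SE computed on an autocorrelation-adjusted effective
#' sample size.
#'
#' @param panel a \code{MetaPanel}.
#' @param prior an \code{EffectPrior}.
#' @param burnin discarded initial steps (>= 0).
#' @param samples retained steps (>= 1).
#' @param seed integer seed for reproducibility; NULL leaves the RNG state
#'   alone.
#' @return an \code{MValueResult} with method "mcmc".
#' @examples
#' p <- MetaPanel(beta = c(0.3, 0.28, 0.01), se = c(0.08, 0.09, 0.07))
#' r <- mvaluesMCMC(p, burnin = 200, samples = 2000, seed = 1)
#' mvalues(r)
#' @export
mvaluesMCMC <- function(panel, prior = EffectPrior(), burnin = 1000L,
                        samples = 10000L, seed = NULL) {
  panel <- .asPanel(panel)
  prior <- .asPrior(prior)
  stopifnot(burnin >= 0, samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nStudies(panel)
  w <- 1 / panel@se^2
  wx <- w * panel@beta
  lpriorByK <- .logConfigPriorByCount(n, prior)
  sigma <- prior@sigma

  logPost <- function(bits) {
    on <- bits == 1L
    lp <- .logG(sum(w[on]), sum(wx[on]), sigma) + lpriorByK[sum(bits) + 1]
    if (!is.finite(lp) && lp != -Inf) {
      bad <- panel@labels[which(!is.finite(dnorm(panel@beta, 0, panel@se,
                                                 log = TRUE)))]
      stop("non-finite posterior; check study ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    lp
  }

  bits <- as.integer(runif(n) < 0.5)
  lp <- logPost(bits)
  hits <- numeric(n)
  trace <- matrix(NA_real_, nrow = samples, ncol = n)
  total <- burnin + samples
  for (step in seq_len(total)) {
    if (runif(1) < 0.5) {            # flip one study's bit
      j <- sample.int(n, 1)
      prop <- bits
      prop[j] <- 1L - prop[j]
    } else {                         # shuffle: uniform permutation (symmetric)
      prop <- bits[sample.int(n)]
    }
    lpProp <- logPost(prop)
    if (log(runif(1)) < lpProp - lp) {
      bits <- prop
      lp <- lpProp
    }
    if (step > burnin) {
      hits <- hits + bits
      trace[step - burnin, ] <- bits
    }
  }
  m <- hits / samples
  mcSe <- vapply(seq_len(n), function(i) {
    x <- trace[, i]
    # effective sample size from the initial positive autocorrelations
    if (stats::var(x) == 0) {
      ess <- samples
    } else {
      rho <- as.vector(acf(x, lag.max = min(200L, samples - 1L),
                           plot = FALSE)$acf)[-1]
      firstNeg <- which(rho <= 0)[1]
      if (!is.na(firstNeg)) rho <- rho[seq_len(firstNeg - 1L)]
      ess <- max(1, min(samples, samples / (1 + 2 * sum(rho))))
    }
    # continuity-corrected proportion so the SE never collapses to zero
    pTilde <- (hits[i] + 0.5) / (samples + 1)
    sqrt(pTilde * (1 - pTilde) / ess)
  }, numeric(1))
  new("MValueResult", m = m, method = "mcmc", mcSe = mcSe, prior = prior,
      labels = panel@labels)
}

#' Classify studies by their m-values
#'
#' Applies the prediction thresholds: a study is predicted to have the effect
#' when its m-value is at least \code{upper}, predicted to have no effect
#' when at most \code{lower}, and ambiguous in between. Ambiguity typically
#' reflects an underpowered (small) study rather than evidence either way.
#'
#' @param m an \code{MValueResult} or plain numeric vector of m-values.
#' @param upper,lower prediction thresholds, 0 <= lower < upper <= 1.
#' @return a named factor with levels "predicted-effect", "ambiguous",
#'   "predicted-no-effect".
#' @examples
#' classifyStudies(c(0.95, 0.5, 0.05))
#' @export
classifyStudies <- function(m, upper = 0.9, lower = 0.1) {
  if (!(lower >= 0 && upper <= 1 && lower < upper))
    stop("need 0 <= lower < upper <= 1", call. = FALSE)
  mv <- if (is(m, "MValueResult")) mvalues(m) else m
  lab <- ifelse(mv >= upper, "predicted-effect",
                ifelse(mv <= lower, "predicted-no-effect", "ambiguous"))
  factor(setNames(lab, names(mv)),
         levels = c("predicted-no-effect", "ambiguous", "predicted-effect"))
}
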