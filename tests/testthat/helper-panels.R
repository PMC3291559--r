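# shared fixture builders (all generated in code, fixed seeds)

# random panel with moderate, mixed effects
randomPanel <- function(n, seed, sdBeta = 0.2, seRange = c(0.05, 0.3)) {
  set.seed(seed)
  MetaPanel(beta = rnorm(n, 0, sdBeta),
            se = runif(n, seRange[1], seRange[2]))
}

# brute-force m-values: enumerate every configuration, evaluating the
# effect-set integral by adaptive quadrature instead of the closed form
bruteForceMvalues <- function(panel, prior = EffectPrior()) {
  n <- nStudies(panel)
  beta <- effectSizes(panel)
  se <- stdErrors(panel)
  B <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  lp <- apply(B, 1, function(bits) {
    on <- bits == 1
    ll <- sum(dnorm(beta[!on], 0, se[!on], log = TRUE))
    if (any(on)) {
      integrand <- function(mu) vapply(mu, function(m)
        prod(dnorm(beta[on], m, se[on])) * dnorm(m, 0, prior@sigma),
        numeric(1))
      ll <- ll + log(integrate(integrand, -Inf, Inf, rel.tol = 1e-12)$value)
    }
    ll + logConfigPrior(bits, prior)
  })
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  as.vector(crossprod(B, w))
}

# plain Monte-Carlo BE tail probability (independent of the importance path)
plainMcBeP <- function(panel, sObs, nDraws, prior = EffectPrior()) {
  n <- nStudies(panel)
  se <- stdErrors(panel)
  w <- studyWeights(panel)
  hits <- 0
  done <- 0
  while (done < nDraws) {
    R <- min(2e5, nDraws - done)
    Z <- matrix(rnorm(n * R), n)
    M <- binmeta:::.mvaluesForDraws(se, Z * se, prior)
    S <- colSums(M * (w * Z)) / sqrt(colSums((M * w)^2))
    hits <- hits + sum(abs(S) >= abs(sObs))
    done <- done + R
  }
  c(p = hits / nDraws, se = sqrt(hits) / nDraws)
}
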