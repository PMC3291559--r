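#' @import methods
#' @importFrom stats dnorm pnorm pchisq qnorm rnorm optimize integrate acf
#'   runif setNames var
#' @importFrom utils read.table write.table head globalVariables
#' @importFrom tools file_ext
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Prior on effect size and on the probability that an effect exists
#'
#' Bundles the two priors of the binary-effects model: a zero-centred normal
#' prior with standard deviation \code{sigma} on the shared true effect size
#' (log odds ratio scale), and a Beta(\code{alpha}, \code{beta}) prior on the
#' probability that any given study carries the effect.
#'
#' The default \code{sigma = 0.2} is the conventional choice for small
#' complex-trait effects (0.4 would suit large effects); the default
#' \code{alpha = beta = 1} is the uniform prior on the probability of effect.
#'
#' @slot sigma numeric(1), prior SD of the true log odds ratio; > 0.
#' @slot alpha numeric(1), first Beta shape; > 0.
#' @slot beta numeric(1), second Beta shape; > 0.
#' @export
setClass("EffectPrior",
  representation(sigma = "numeric", alpha = "numeric", beta = "numeric"),
  prototype(sigma = 0.2, alpha = 1, beta = 1))

setValidity("EffectPrior", function(object) {
  msg <- character()
  for (s in c("sigma", "alpha", "beta")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single finite value > 0", s))
  }
  if (length(msg)) msg else TRUE
})

#' @param sigma prior SD of the true effect size (log odds ratio), > 0.
#' @param alpha,beta Beta shape parameters of the prior on the probability
#'   that a study has an effect, both > 0.
#' @return An \code{EffectPrior} object.
#' @examples
#' EffectPrior()                 # sigma 0.2, uniform beta prior
#' EffectPrior(sigma = 0.4)      # large-effect prior
#' @rdname EffectPrior-class
#' @export
EffectPrior <- function(sigma = 0.2, alpha = 1, beta = 1) {
  new("EffectPrior", sigma = as.numeric(sigma), alpha = as.numeric(alpha),
      beta = as.numeric(beta))
}

#' One study's summary statistic
#'
#' Holds a single study's observed effect size (log odds ratio), its standard
#' error and optional metadata. The variance \code{se^2} is treated as known,
#' and the effect estimate as normally distributed around the true effect,
#' which is the usual large-sample approximation for GWAS summary data.
#'
#' @slot beta numeric(1), observed log odds ratio.
#' @slot se numeric(1), standard error of \code{beta}; > 0.
#' @slot n numeric(1), optional total sample size (cases + controls; NA if
#'   unknown).
#' @slot maf numeric(1), optional minor allele frequency in (0, 0.5]; NA if
#'   unknown.
#' @slot label character(1), study name.
#' @export
setClass("StudyEffect",
  representation(beta = "numeric", se = "numeric", n = "numeric",
                 maf = "numeric", label = "character"),
  prototype(n = NA_real_, maf = NA_real_, label = NA_character_))

setValidity("StudyEffect", function(object) {
  msg <- character()
  if (length(object@beta) != 1L || !is.finite(object@beta))
    msg <- c(msg, "'beta' must be a single finite value")
  if (length(object@se) != 1L || !is.finite(object@se) || object@se <= 0)
    msg <- c(msg, "'se' must be a single finite value > 0")
  if (!is.na(object@maf) && (object@maf <= 0 || object@maf > 0.5))
    msg <- c(msg, "'maf' must lie in (0, 0.5]")
  if (!is.na(object@n) && object@n <= 0)
    msg <- c(msg, "'n' must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param beta observed log odds ratio.
#' @param se standard error of \code{beta}, > 0.
#' @param n optional total sample size.
#' @param maf optional minor allele frequency in (0, 0.5].
#' @param label study name.
#' @return A \code{StudyEffect}.
#' @rdname StudyEffect-class
#' @export
StudyEffect <- function(beta, se, n = NA_real_, maf = NA_real_,
                        label = NA_character_) {
  new("StudyEffect", beta = as.numeric(beta), se = as.numeric(se),
      n = as.numeric(n), maf = as.numeric(maf), label = as.character(label))
}

#' A meta-analysis panel: one SNP across several studies
#'
#' The unit of analysis: aligned per-study effect sizes and standard errors
#' for one variant. All studies are assumed to report the effect on the same
#' allele and the same (log odds ratio) scale; harmonising allele orientation
#' is the caller's responsibility.
#'
#' @slot beta numeric, per-study log odds ratios.
#' @slot se numeric, per-study standard errors; all > 0.
#' @slot n numeric, per-study total sample sizes (NA allowed).
#' @slot maf numeric, per-study minor allele frequencies (NA allowed).
#' @slot labels character, study names.
#' @slot snpId character(1), variant identifier.
#' @export
setClass("MetaPanel",
  representation(beta = "numeric", se = "numeric", n = "numeric",
                 maf = "numeric", labels = "character", snpId = "character"),
  prototype(snpId = NA_character_))

setValidity("MetaPanel", function(object) {
  k <- length(object@beta)
  msg <- character()
  if (k < 2L)
    msg <- c(msg, "a meta-analysis panel needs at least 2 studies")
  if (length(object@se) != k || length(object@n) != k ||
      length(object@maf) != k || length(object@labels) != k)
    msg <- c(msg, "'beta', 'se', 'n', 'maf' and 'labels' must have equal length")
  if (any(!is.finite(object@beta)))
    msg <- c(msg, "all 'beta' must be finite")
  if (any(!is.finite(object@se)) || any(object@se <= 0))
    msg <- c(msg, "all 'se' must be finite and > 0 (a zero standard error is rejected, not treated as infinite precision)")
  if (length(msg)) msg else TRUE
})

#' @param beta numeric vector of per-study log odds ratios (or a list of
#'   \code{StudyEffect} objects, in which case the other arguments are
#'   ignored apart from \code{snpId}).
#' @param se numeric vector of standard errors, all > 0.
#' @param n optional numeric vector of total sample sizes.
#' @param maf optional numeric vector of minor allele frequencies.
#' @param labels study names; defaults to \code{study1, study2, ...}.
#' @param snpId variant identifier.
#' @return A \code{MetaPanel}.
#' @examples
#' MetaPanel(beta = c(0.30, 0.25, -0.01), se = c(0.10, 0.12, 0.05))
#' @rdname MetaPanel-class
#' @export
MetaPanel <- function(beta, se = NULL, n = NULL, maf = NULL, labels = NULL,
                      snpId = NA_character_) {
  if (is.list(beta) && all(vapply(beta, is, logical(1), "StudyEffect"))) {
    studies <- beta
    beta <- vapply(studies, slot, numeric(1), "beta")
    se <- vapply(studies, slot, numeric(1), "se")
    n <- vapply(studies, slot, numeric(1), "n")
    maf <- vapply(studies, slot, numeric(1), "maf")
    labels <- vapply(studies, slot, character(1), "label")
  }
  k <- length(beta)
  if (is.null(labels) || all(is.na(labels))) labels <- paste0("study", seq_len(k))
  if (is.null(n)) n <- rep(NA_real_, k)
  if (is.null(maf)) maf <- rep(NA_real_, k)
  new("MetaPanel", beta = as.numeric(beta), se = as.numeric(se),
      n = as.numeric(n), maf = as.numeric(maf), labels = as.character(labels),
      snpId = as.character(snpId))
}

#' A binary effect configuration
#'
#' A vector c over the studies of a panel with c_i = 1 when study i carries
#' the effect and 0 otherwise. The space of all 2^n such vectors is what the
#' posterior over "which studies have the effect" is defined on.
#'
#' @slot bits integer vector of 0/1.
#' @export
setClass("Configuration", representation(bits = "integer"))

setValidity("Configuration", function(object) {
  if (length(object@bits) < 1L || !all(object@bits %in% c(0L, 1L)))
    "'bits' must be a non-empty vector of 0s and 1s" else TRUE
})

#' @param bits a vector coercible to 0/1 (logical or integer).
#' @return A \code{Configuration}.
#' @rdname Configuration-class
#' @export
Configuration <- function(bits) new("Configuration", bits = as.integer(bits))

#' Per-study posterior probabilities of effect (m-values)
#'
#' @slot m numeric in [0, 1], one per study.
#' @slot method "exact", "mcmc" or "approx".
#' @slot mcSe per-study Monte-Carlo standard error (all 0 for exact).
#' @slot prior the \code{EffectPrior} used.
#' @slot labels study names.
#' @export
setClass("MValueResult",
  representation(m = "numeric", method = "character", mcSe = "numeric",
                 prior = "EffectPrior", labels = "character"))

setValidity("MValueResult", function(object) {
  msg <- character()
  if (any(object@m < -1e-12 | object@m > 1 + 1e-12))
    msg <- c(msg, "all m-values must lie in [0, 1]")
  if (!object@method %in% c("exact", "mcmc", "approx"))
    msg <- c(msg, "'method' must be one of exact, mcmc, approx")
  if (object@method == "exact" && any(object@mcSe != 0))
    msg <- c(msg, "exact m-values must have zero Monte-Carlo error")
  if (length(object@mcSe) != length(object@m))
    msg <- c(msg, "'mcSe' must match 'm' in length")
  if (length(msg)) msg else TRUE
})

#' Result of a meta-analysis association test
#'
#' @slot statistic the test statistic.
#' @slot pvalue its p-value, in (0, 1].
#' @slot method "FE", "RE", "BE" or "ABF".
#' @slot nSamples Monte-Carlo sample count (0 when analytic).
#' @slot pSe standard error of the p-value estimate (0 when analytic).
#' @slot extra list of method-specific detail (e.g. RE's mu and tau2
#'   estimates, BE's adaptive stage).
#' @export
setClass("TestResult",
  representation(statistic = "numeric", pvalue = "numeric",
                 method = "character", nSamples = "numeric", pSe = "numeric",
                 extra = "list"),
  prototype(nSamples = 0, pSe = 0, extra = list()))

setValidity("TestResult", function(object) {
  msg <- character()
  if (!(object@pvalue > 0 && object@pvalue <= 1))
    msg <- c(msg, "'pvalue' must lie in (0, 1]")
  if ((object@pSe == 0) != (object@nSamples == 0))
    msg <- c(msg, "'pSe' must be 0 exactly when the p-value is analytic (nSamples == 0)")
  if (length(msg)) msg else TRUE
})

#' How studies are weighted in the weighted-z statistics
#'
#' \code{sqrt_n} is the popular sqrt(sample size) weighting; \code{maf_adjusted}
#' uses sqrt(2 f (1 - f) N), the form the sqrt-N weight approximates when
#' allele frequencies differ between studies; \code{precision} uses 1/se;
#' \code{custom} takes explicit positive weights; \code{auto} (the default)
#' resolves to \code{sqrt_n} when sample sizes are available and
#' \code{precision} otherwise.
#'
#' @slot mode one of "auto", "sqrt_n", "maf_adjusted", "precision", "custom".
#' @slot weights numeric, used only for mode "custom".
#' @export
setClass("WeightScheme",
  representation(mode = "character", weights = "numeric"),
  prototype(mode = "auto", weights = numeric()))

setValidity("WeightScheme", function(object) {
  msg <- character()
  if (!object@mode %in% c("auto", "sqrt_n", "maf_adjusted", "precision", "custom"))
    msg <- c(msg, "unknown weighting mode")
  if (object@mode == "custom" &&
      (length(object@weights) == 0 || any(!is.finite(object@weights)) ||
       any(object@weights <= 0)))
    msg <- c(msg, "custom weights must be finite and strictly positive")
  if (length(msg)) msg else TRUE
})

#' @param mode weighting mode, see slots.
#' @param weights positive weights for mode "custom".
#' @return A \code{WeightScheme}.
#' @rdname WeightScheme-class
#' @export
WeightScheme <- function(mode = c("auto", "sqrt_n", "maf_adjusted",
                                  "precision", "custom"),
                         weights = numeric()) {
  new("WeightScheme", mode = match.arg(mode), weights = as.numeric(weights))
}

#' Report of a simulation experiment
#'
#' @slot name experiment name.
#' @slot table per-condition summary (data.frame of rates, powers, AUCs...).
#' @slot replicates replicate count behind the summary.
#' @slot seed the seed used.
#' @slot details list of experiment-specific extras (histograms, ROC points,
#'   per-study tables).
#' @export
setClass("ExperimentReport",
  representation(name = "character", table = "data.frame",
                 replicates = "numeric", seed = "numeric", details = "list"),
  prototype(details = list()))

#' Container for a table of GWAS summary statistics
#'
#' A \code{SummarizedExperiment} with SNPs as rows and studies as columns,
#' carrying at least \code{beta} and \code{se} assays (NA marks a study
#' missing for a SNP) and optionally \code{n} and \code{maf} assays.
#'
#' @export
setClass("MetaSet", contains = "SummarizedExperiment")

setValidity("MetaSet", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("beta", "se") %in% an))
    msg <- c(msg, "a MetaSet needs 'beta' and 'se' assays")
  else {
    se <- SummarizedExperiment::assay(object, "se")
    if (any(se[!is.na(se)] <= 0))
      msg <- c(msg, "all non-missing standard errors must be > 0")
  }
  if (length(msg)) msg else TRUE
})
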