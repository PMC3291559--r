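# internal numerical helpers

# log(sum(exp(x))) without overflow; x may contain -Inf
.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# 0/1 matrix of all 2^n configurations (rows), column i = study i's bit.
# Row order: index idx (0-based) has bit i set iff bitwAnd(idx, 2^(i-1)).
.configMatrix <- function(n) {
  stopifnot(n >= 1, n <= 25)
  idx <- 0:(2^n - 1)
  vapply(seq_len(n), function(i) as.numeric(bitwAnd(idx, 2^(i - 1)) > 0),
         numeric(2^n))
}

# coerce a Configuration or plain 0/1 vector to an integer bit vector
.asBits <- function(config) {
  if (is(config, "Configuration")) return(config@bits)
  bits <- as.integer(config)
  if (length(bits) < 1L || anyNA(bits) || !all(bits %in% c(0L, 1L)))
    stop("a configuration must be a vector of 0s and 1s", call. = FALSE)
  bits
}

.asPanel <- function(panel) {
  if (!is(panel, "MetaPanel"))
    stop("'panel' must be a MetaPanel", call. = FALSE)
  validObject(panel)
  panel
}

.asPrior <- function(prior) {
  if (!is(prior, "EffectPrior"))
    stop("'prior' must be an EffectPrior", call. = FALSE)
  validObject(prior)
  prior
}

# deterministic 31-bit seed from a master seed and a string key
.deriveSeed <- function(master, key) {
  h <- as.numeric(master) %% 2147483647
  for (ch in utf8ToInt(as.character(key)))
    h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# binomial standard error of a proportion
.binomSe <- function(p, n) sqrt(pmax(p * (1 - p), 0) / n)
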