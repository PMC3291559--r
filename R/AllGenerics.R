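#' @rdname accessors
#' @export
setGeneric("effectSizes", function(x) standardGeneric("effectSizes"))
#' @rdname accessors
#' @export
setGeneric("stdErrors", function(x) standardGeneric("stdErrors"))
#' @rdname accessors
#' @export
setGeneric("sampleSizes", function(x) standardGeneric("sampleSizes"))
#' @rdname accessors
#' @export
setGeneric("mafValues", function(x) standardGeneric("mafValues"))
#' @rdname accessors
#' @export
setGeneric("studyLabels", function(x) standardGeneric("studyLabels"))
#' @rdname accessors
#' @export
setGeneric("nStudies", function(x) standardGeneric("nStudies"))
#' @rdname accessors
#' @export
setGeneric("snpId", function(x) standardGeneric("snpId"))
#' @rdname accessors
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))

#' @rdname mvalue-accessors
#' @export
setGeneric("mvalues", function(x) standardGeneric("mvalues"))
#' @rdname mvalue-accessors
#' @export
setGeneric("mcError", function(x) standardGeneric("mcError"))

#' @rdname config-accessors
#' @export
setGeneric("configBits", function(x) standardGeneric("configBits"))
#' @rdname config-accessors
#' @export
setGeneric("configOnes", function(x) standardGeneric("configOnes"))
#' @rdname config-accessors
#' @export
setGeneric("configZeros", function(x) standardGeneric("configZeros"))
#' @rdname config-accessors
#' @export
setGeneric("countOnes", function(x) standardGeneric("countOnes"))

#' @rdname test-accessors
#' @export
setGeneric("testStatistic", function(x) standardGeneric("testStatistic"))
#' @rdname test-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname test-accessors
#' @export
setGeneric("pValueSe", function(x) standardGeneric("pValueSe"))

#' @rdname metaPanels
#' @export
setGeneric("metaPanels", function(x, ...) standardGeneric("metaPanels"))

# ---- accessor methods -------------------------------------------------------

#' Accessors for meta-analysis panels
#'
#' @param x a \code{MetaPanel} or \code{StudyEffect}.
#' @return the corresponding slot; \code{zScores} returns beta/se.
#' @name accessors
NULL

#' @rdname accessors
setMethod("effectSizes", "MetaPanel", function(x) setNames(x@beta, x@labels))
#' @rdname accessors
setMethod("stdErrors", "MetaPanel", function(x) setNames(x@se, x@labels))
#' @rdname accessors
setMethod("sampleSizes", "MetaPanel", function(x) setNames(x@n, x@labels))
#' @rdname accessors
setMethod("mafValues", "MetaPanel", function(x) setNames(x@maf, x@labels))
#' @rdname accessors
setMethod("studyLabels", "MetaPanel", function(x) x@labels)
#' @rdname accessors
setMethod("nStudies", "MetaPanel", function(x) length(x@beta))
#' @rdname accessors
setMethod("snpId", "MetaPanel", function(x) x@snpId)
#' @rdname accessors
setMethod("zScores", "MetaPanel", function(x) setNames(x@beta / x@se, x@labels))

#' @rdname accessors
setMethod("effectSizes", "StudyEffect", function(x) x@beta)
#' @rdname accessors
setMethod("stdErrors", "StudyEffect", function(x) x@se)
#' @rdname accessors
setMethod("sampleSizes", "StudyEffect", function(x) x@n)
#' @rdname accessors
setMethod("mafValues", "StudyEffect", function(x) x@maf)
#' @rdname accessors
setMethod("studyLabels", "StudyEffect", function(x) x@label)
#' @rdname accessors
setMethod("zScores", "StudyEffect", function(x) x@beta / x@se)

#' Accessors for m-value results
#'
#' @param x an \code{MValueResult}.
#' @name mvalue-accessors
NULL

#' @rdname mvalue-accessors
setMethod("mvalues", "MValueResult", function(x) setNames(x@m, x@labels))
#' @rdname mvalue-accessors
setMethod("mcError", "MValueResult", function(x) setNames(x@mcSe, x@labels))
#' @rdname mvalue-accessors
setMethod("studyLabels", "MValueResult", function(x) x@labels)

#' Accessors for configurations
#'
#' @param x a \code{Configuration}.
#' @name config-accessors
NULL

#' @rdname config-accessors
setMethod("configBits", "Configuration", function(x) x@bits)
#' @rdname config-accessors
setMethod("configOnes", "Configuration", function(x) which(x@bits == 1L))
#' @rdname config-accessors
setMethod("configZeros", "Configuration", function(x) which(x@bits == 0L))
#' @rdname config-accessors
setMethod("countOnes", "Configuration", function(x) sum(x@bits))

#' Accessors for test results
#'
#' @param x a \code{TestResult}.
#' @name test-accessors
NULL

#' @rdname test-accessors
setMethod("testStatistic", "TestResult", function(x) x@statistic)
#' @rdname test-accessors
setMethod("pValue", "TestResult", function(x) x@pvalue)
#' @rdname test-accessors
setMethod("pValueSe", "TestResult", function(x) x@pSe)

# ---- show methods -----------------------------------------------------------

setMethod("show", "EffectPrior", function(object) {
  cat(sprintf("EffectPrior: effect size ~ N(0, %.3g^2), P(effect) ~ Beta(%.3g, %.3g)\n",
              object@sigma, object@alpha, object@beta))
})

setMethod("show", "StudyEffect", function(object) {
  cat(sprintf("StudyEffect %s: beta = %.4g (se %.4g), z = %.3g\n",
              ifelse(is.na(object@label), "<unnamed>", object@label),
              object@beta, object@se, object@beta / object@se))
})

setMethod("show", "MetaPanel", function(object) {
  cat(sprintf("MetaPanel%s with %d studies\n",
              ifelse(is.na(object@snpId), "", paste0(" [", object@snpId, "]")),
              length(object@beta)))
  df <- data.frame(study = object@labels, beta = object@beta, se = object@se,
                   z = round(object@beta / object@se, 3), n = object@n,
                   maf = object@maf)
  print(head(df, 10), row.names = FALSE)
  if (nrow(df) > 10) cat("...", nrow(df) - 10, "more studies\n")
})

setMethod("show", "Configuration", function(object) {
  cat("Configuration:", paste(object@bits, collapse = ""),
      sprintf("(%d of %d with effect)\n", sum(object@bits), length(object@bits)))
})

setMethod("show", "MValueResult", function(object) {
  cat(sprintf("MValueResult (%s) for %d studies\n", object@method,
              length(object@m)))
  df <- data.frame(study = object@labels, m = round(object@m, 4))
  if (object@method != "exact") df$mcSe <- signif(object@mcSe, 3)
  print(head(df, 10), row.names = FALSE)
  if (nrow(df) > 10) cat("...", nrow(df) - 10, "more studies\n")
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g", object@method,
              object@statistic, object@pvalue))
  if (object@nSamples > 0)
    cat(sprintf(" (Monte Carlo, %g samples, se %.3g)", object@nSamples,
                object@pSe))
  cat("\n")
})

setMethod("show", "ExperimentReport", function(object) {
  cat(sprintf("ExperimentReport '%s' (%g replicates, seed %s)\n", object@name,
              object@replicates, format(object@seed)))
  print(object@table, row.names = FALSE)
})
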