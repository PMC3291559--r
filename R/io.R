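#' Construct a MetaSet from assay matrices
#'
#' @param beta,se numeric matrices, SNPs x studies; NA marks a study missing
#'   for a SNP.
#' @param n,maf optional matrices of the same shape.
#' @param snpIds,studyLabels row and column names; defaults derived from the
#'   matrices.
#' @return a \code{MetaSet}.
#' @export
MetaSet <- function(beta, se, n = NULL, maf = NULL, snpIds = rownames(beta),
                    studyLabels = colnames(beta)) {
  beta <- as.matrix(beta); se <- as.matrix(se)
  if (is.null(snpIds)) snpIds <- paste0("snp", seq_len(nrow(beta)))
  if (is.null(studyLabels)) studyLabels <- paste0("study", seq_len(ncol(beta)))
  assays <- list(beta = beta, se = se)
  if (!is.null(n)) assays$n <- as.matrix(n)
  if (!is.null(maf)) assays$maf <- as.matrix(maf)
  assays <- lapply(assays, function(a) {
    dimnames(a) <- list(snpIds, studyLabels)
    a
  })
  se0 <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(label = studyLabels,
                                   row.names = studyLabels))
  methods::as(se0, "MetaSet")
}

#' Read a table of per-study GWAS summary statistics
#'
#' Expects a whitespace- or tab-delimited file with a header: a SNP
#' identifier column (named \code{SNP}, \code{RSID} or simply the first
#' column) followed by paired \code{BETA<i>}/\code{SE<i>} columns, one pair
#' per study, and optionally \code{N<i>} and \code{MAF<i>} columns. "NA"
#' marks a study missing at a SNP; missingness is per study, not per SNP.
#' Effect sizes must be log odds ratios; callers holding odds ratios must
#' log-transform first.
#'
#' @param path file to read.
#' @param studyLabels optional study names; defaults to \code{study<i>}.
#' @return a \code{MetaSet}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tBETA1\tSE1\tBETA2\tSE2",
#'              "rs1\t0.30\t0.10\t0.25\t0.12"), tf)
#' readMetaTable(tf)
#' @export
readMetaTable <- function(path, studyLabels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (nrow(df) == 0) stop("empty input table: ", path, call. = FALSE)
  cn <- toupper(names(df))
  idCol <- which(cn %in% c("SNP", "RSID", "MARKER", "ID"))[1]
  if (is.na(idCol)) idCol <- 1L
  snpIds <- as.character(df[[idCol]])
  grab <- function(prefix) {
    cols <- grep(paste0("^", prefix, "[0-9]+$"), cn)
    if (!length(cols)) return(NULL)
    ord <- order(as.integer(sub(prefix, "", cn[cols])))
    as.matrix(df[, cols[ord], drop = FALSE])
  }
  asNum <- function(mat, what) {
    if (is.null(mat)) return(NULL)
    num <- suppressWarnings(matrix(as.numeric(mat), nrow(mat), ncol(mat),
                                   dimnames = dimnames(mat)))
    chr <- matrix(as.character(mat), nrow(mat), ncol(mat))
    malformed <- which(is.na(num) & !is.na(chr) &
                         !(toupper(trimws(chr)) %in% c("NA", "")),
                       arr.ind = TRUE)
    if (nrow(malformed) > 0)
      stop("malformed ", what, " value at line ", malformed[1, 1] + 1,
           " of ", path, call. = FALSE)
    num
  }
  beta <- asNum(grab("BETA"), "BETA"); se <- asNum(grab("SE"), "SE")
  if (is.null(beta) || is.null(se))
    stop("no BETA<i>/SE<i> column pairs found in ", path, call. = FALSE)
  if (ncol(beta) != ncol(se))
    stop("unequal numbers of BETA and SE columns in ", path, call. = FALSE)
  badSe <- which(!is.na(se) & se <= 0, arr.ind = TRUE)
  if (nrow(badSe) > 0)
    stop("non-positive standard error for SNP ", snpIds[badSe[1, 1]],
         ", study ", badSe[1, 2], call. = FALSE)
  k <- ncol(beta)
  if (is.null(studyLabels)) studyLabels <- paste0("study", seq_len(k))
  MetaSet(beta, se, n = asNum(grab("N"), "N"),
          maf = asNum(grab("MAF"), "MAF"), snpIds = snpIds,
          studyLabels = studyLabels)
}

#' Write a MetaSet (or list of panels) to a tab-delimited table
#'
#' Inverse of \code{\link{readMetaTable}}; beta/se are written at full
#' precision so a round-trip is exact.
#'
#' @param x a \code{MetaSet} or a list of \code{MetaPanel}s sharing one
#'   study layout.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMetaTable <- function(x, path) {
  if (is.list(x)) {
    labels <- studyLabels(x[[1]])
    beta <- t(vapply(x, function(p) effectSizes(p)[labels], numeric(length(labels))))
    se <- t(vapply(x, function(p) stdErrors(p)[labels], numeric(length(labels))))
    rownames(beta) <- vapply(x, snpId, character(1))
    x <- MetaSet(beta, se, studyLabels = labels)
  }
  stopifnot(is(x, "MetaSet"))
  k <- ncol(x)
  out <- data.frame(SNP = rownames(x), stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    out[[paste0("BETA", j)]] <-
      sprintf("%.17g", SummarizedExperiment::assay(x, "beta")[, j])
    out[[paste0("SE", j)]] <-
      sprintf("%.17g", SummarizedExperiment::assay(x, "se")[, j])
  }
  an <- SummarizedExperiment::assayNames(x)
  for (extra in intersect(c("n", "maf"), an))
    for (j in seq_len(k))
      out[[paste0(toupper(extra), j)]] <-
        SummarizedExperiment::assay(x, extra)[, j]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract per-SNP meta-analysis panels from a MetaSet
#'
#' Studies missing (NA) at a SNP are dropped from that SNP's panel; SNPs
#' left with fewer than two usable studies are skipped with a warning.
#'
#' @param x a \code{MetaSet}.
#' @param ... unused.
#' @return a named list of \code{MetaPanel}s.
#' @rdname metaPanels
#' @export
setMethod("metaPanels", "MetaSet", function(x, ...) {
  beta <- SummarizedExperiment::assay(x, "beta")
  se <- SummarizedExperiment::assay(x, "se")
  an <- SummarizedExperiment::assayNames(x)
  nMat <- if ("n" %in% an) SummarizedExperiment::assay(x, "n") else NULL
  mafMat <- if ("maf" %in% an) SummarizedExperiment::assay(x, "maf") else NULL
  labels <- colnames(beta)
  panels <- list()
  skipped <- character()
  for (i in seq_len(nrow(beta))) {
    ok <- which(!is.na(beta[i, ]) & !is.na(se[i, ]))
    if (length(ok) < 2) {
      skipped <- c(skipped, rownames(beta)[i])
      next
    }
    panels[[rownames(beta)[i]]] <- MetaPanel(
      beta = beta[i, ok], se = se[i, ok],
      n = if (is.null(nMat)) NULL else nMat[i, ok],
      maf = if (is.null(mafMat)) NULL else mafMat[i, ok],
      labels = labels[ok], snpId = rownames(beta)[i])
  }
  if (length(skipped))
    warning("skipped ", length(skipped),
            " SNP(s) with fewer than 2 usable studies: ",
            paste(head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "", call. = FALSE)
  panels
})

#' Run the full meta-analysis pipeline over a summary-statistics table
#'
#' For every SNP: FE and RE p-values, the BE statistic with its
#' importance-sampled p-value, per-study m-values (exact up to
#' \code{exactLimit} studies, MCMC beyond) and prediction labels. Per-SNP
#' randomness is seeded reproducibly from the master seed and the SNP
#' identifier, so results do not depend on row order.
#'
#' @param input a \code{MetaSet}, a list of \code{MetaPanel}s, or a path
#'   readable by \code{\link{readMetaTable}}.
#' @param prior \code{EffectPrior}.
#' @param scheme weight scheme, as in \code{\link{studyWeights}}.
#' @param upper,lower m-value prediction thresholds.
#' @param beSamples importance samples per BE p-value (0 skips the BE
#'   p-value and reports only the statistic).
#' @param adaptive use \code{\link{beAdaptive}} two-stage sampling with
#'   \code{beSamples} stage-1 and 10x stage-2 samples.
#' @param exactLimit largest panel enumerated exactly for m-values.
#' @param seed master seed.
#' @return a list with \code{tests} (one row per SNP: statistics and
#'   p-values) and \code{mvalues} (one row per SNP x study: m-value, region,
#'   single-study p-value).
#' @examples
#' panels <- list(simulatePanel(rep(1000, 5), rr = c(1.4, 1.4, 1.4, 1, 1),
#'                              seed = 3, snpId = "rs1"))
#' out <- runPipeline(panels, beSamples = 500, seed = 1)
#' out$tests
#' @export
runPipeline <- function(input, prior = EffectPrior(),
                        scheme = WeightScheme(), upper = 0.9, lower = 0.1,
                        beSamples = 1000L, adaptive = FALSE,
                        exactLimit = 20L, seed = 1L) {
  panels <- if (is.character(input)) metaPanels(readMetaTable(input))
            else if (is(input, "MetaSet")) metaPanels(input)
            else if (is.list(input)) input
            else stop("'input' must be a path, MetaSet or list of panels",
                      call. = FALSE)
  if (length(panels) == 0) stop("no usable panels in input", call. = FALSE)
  testRows <- list()
  mRows <- list()
  promoted <- 0L
  for (i in seq_along(panels)) {
    panel <- panels[[i]]
    id <- if (is.na(snpId(panel))) paste0("snp", i) else snpId(panel)
    snpSeed <- .deriveSeed(seed, id)
    fe <- feWeightedZ(panel, scheme)
    re <- reHanEskin(panel)
    mres <- if (nStudies(panel) <= exactLimit) mvaluesExact(panel, prior)
            else mvaluesMCMC(panel, prior, seed = snpSeed)
    be <- if (beSamples > 0) {
      if (adaptive)
        beAdaptive(panel, prior, scheme, nSmall = beSamples,
                   nLarge = 10L * beSamples, seed = snpSeed)
      else bePvalue(panel, prior, scheme, nSamples = beSamples,
                    seed = snpSeed)
    } else NULL
    if (!is.null(be) && identical(be@extra$stage, 2L))
      promoted <- promoted + 1L
    testRows[[id]] <- data.frame(
      snp = id, nStudies = nStudies(panel),
      feStat = testStatistic(fe), feP = pValue(fe),
      reStat = testStatistic(re), reP = pValue(re),
      beStat = if (is.null(be)) beStatistic(panel, mres, scheme)
               else testStatistic(be),
      beP = if (is.null(be)) NA_real_ else pValue(be),
      bePSe = if (is.null(be)) NA_real_ else pValueSe(be),
      beSamples = if (is.null(be)) 0 else be@nSamples,
      stringsAsFactors = FALSE)
    pts <- pmPoints(panel, mres, upper = upper, lower = lower)
    pts$snp <- id
    pts$mcSe <- mcError(mres)
    mRows[[id]] <- pts[, c("snp", "study", "mvalue", "mcSe", "pvalue",
                           "region")]
  }
  message(sprintf("analysed %d panel(s); %d promoted to large sampling",
                  length(panels), promoted))
  list(tests = do.call(rbind, c(testRows, list(make.row.names = FALSE))),
       mvalues = do.call(rbind, c(mRows, list(make.row.names = FALSE))))
}
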