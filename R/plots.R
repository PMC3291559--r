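#' Assemble P-M plot points
#'
#' Pairs each study's m-value with its single-study p-value (two-sided Wald
#' from beta/se unless supplied) and labels the prediction region.
#'
#' @param panel a \code{MetaPanel}.
#' @param m an \code{MValueResult} or numeric m-values for the panel.
#' @param pvalues optional per-study p-values; computed from the panel's
#'   z-scores when NULL.
#' @param upper,lower prediction thresholds, as in
#'   \code{\link{classifyStudies}}.
#' @return a data.frame with columns study, mvalue, pvalue, region.
#' @export
pmPoints <- function(panel, m, pvalues = NULL, upper = 0.9, lower = 0.1) {
  panel <- .asPanel(panel)
  mv <- if (is(m, "MValueResult")) m@m else as.numeric(m)
  if (length(mv) != nStudies(panel))
    stop("m-values must match the panel's studies", call. = FALSE)
  if (is.null(pvalues))
    pvalues <- 2 * pnorm(-abs(panel@beta / panel@se))
  data.frame(study = panel@labels, mvalue = mv, pvalue = pvalues,
             region = as.character(classifyStudies(mv, upper, lower)),
             stringsAsFactors = FALSE)
}

# write a ggplot to PNG or SVG depending on the file extension
.writeFigure <- function(plot, file, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(file))
  dir <- dirname(file)
  if (!dir.exists(dir))
    stop("cannot write figure: directory '", dir, "' does not exist",
         call. = FALSE)
  dev <- switch(ext, png = grDevices::png, svg = grDevices::svg,
                stop("unsupported figure format '.", ext,
                     "'; use .png or .svg", call. = FALSE))
  if (ext == "png") dev(file, width = width, height = height, units = "in",
                        res = 150)
  else dev(file, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(file)
}

#' P-M plot
#'
#' Plots each study's m-value (x, the posterior probability that the effect
#' exists in that study) against its -log10 single-study p-value (y). The
#' plane is divided into three shaded prediction regions by dotted vertical
#' lines at the two m-value thresholds -- predicted no effect (left),
#' ambiguous (middle), predicted effect (right) -- and a dashed horizontal
#' line marks the genome-wide significance threshold. Studies with a
#' non-significant p-value can still sit firmly in the predicted-effect
#' region, which is exactly the information a p-value alone cannot give.
#'
#' @param points a data.frame from \code{\link{pmPoints}} (columns study,
#'   mvalue, pvalue), or a \code{MetaPanel} (m-values are then computed
#'   exactly with \code{prior}).
#' @param upper,lower m-value prediction thresholds.
#' @param gwThreshold genome-wide significance level for the horizontal
#'   line.
#' @param file optional output path ending in .png or .svg; when NULL the
#'   ggplot object is only returned.
#' @param prior \code{EffectPrior} used when \code{points} is a panel.
#' @param regionColors fill colours of the no-effect / ambiguous / effect
#'   regions.
#' @return the ggplot object, invisibly when a file is written.
#' @examples
#' p <- MetaPanel(beta = c(0.32, 0.30, 0.01, 0.2), se = c(0.06, 0.07, 0.05, 0.2),
#'                labels = c("A", "B", "C", "D"))
#' pmPlot(p)
#' @export
pmPlot <- function(points, upper = 0.9, lower = 0.1, gwThreshold = 5e-8,
                   file = NULL, prior = EffectPrior(),
                   regionColors = c("#AEDFF2", "#CBEFCB", "#F9C8D9")) {
  if (is(points, "MetaPanel"))
    points <- pmPoints(points, mvaluesExact(points, prior), upper = upper,
                       lower = lower)
  if (!all(c("study", "mvalue", "pvalue") %in% names(points)) ||
      nrow(points) < 1)
    stop("'points' needs at least one row with study, mvalue and pvalue",
         call. = FALSE)
  points$logp <- -log10(pmax(points$pvalue, 1e-300))
  ymax <- max(points$logp, -log10(gwThreshold)) * 1.15 + 0.3
  regions <- data.frame(xmin = c(0, lower, upper), xmax = c(lower, upper, 1),
                        fill = factor(c("no-effect", "ambiguous", "effect"),
                                      levels = c("no-effect", "ambiguous",
                                                 "effect")))
  gg <- ggplot2::ggplot() +
    ggplot2::geom_rect(data = regions,
                       ggplot2::aes(xmin = xmin, xmax = xmax,
                                    ymin = 0, ymax = ymax,
                                    fill = fill),
                       alpha = 0.45, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = setNames(regionColors,
                                                 levels(regions$fill))) +
    ggplot2::geom_vline(xintercept = c(lower, upper), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log10(gwThreshold),
                        linetype = "dashed") +
    ggplot2::geom_point(data = points,
                        ggplot2::aes(x = mvalue, y = logp),
                        size = 2) +
    ggplot2::geom_text(data = points,
                       ggplot2::aes(x = mvalue, y = logp,
                                    label = study),
                       vjust = -0.9, size = 3) +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "m-value (posterior probability of effect)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_classic()
  if (!is.null(file)) {
    .writeFigure(gg, file)
    return(invisible(gg))
  }
  gg
}

#' Forest plot of a meta-analysis panel
#'
#' Per-study observed log odds ratios with Wald confidence intervals and a
#' zero reference line; the classical companion view to the P-M plot.
#'
#' @param panel a \code{MetaPanel}.
#' @param level confidence level, in (0, 1).
#' @param file optional .png/.svg output path.
#' @return the ggplot object, invisibly when a file is written.
#' @examples
#' forestPlot(MetaPanel(beta = c(0.3, 0.1), se = c(0.1, 0.08)))
#' @export
forestPlot <- function(panel, level = 0.95, file = NULL) {
  panel <- .asPanel(panel)
  if (!(level > 0 && level < 1)) stop("'level' must lie in (0, 1)",
                                      call. = FALSE)
  q <- qnorm(1 - (1 - level) / 2)
  df <- data.frame(study = factor(panel@labels, levels = rev(panel@labels)),
                   beta = panel@beta,
                   lo = panel@beta - q * panel@se,
                   hi = panel@beta + q * panel@se)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = beta, y = study)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = lo, xmax = hi),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "log odds ratio", y = NULL) +
    ggplot2::theme_classic()
  if (!is.null(file)) {
    .writeFigure(gg, file)
    return(invisible(gg))
  }
  gg
}

#' Export P-M plot points as a tab-delimited table
#'
#' @param points data.frame from \code{\link{pmPoints}}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writePmPoints <- function(points, file) {
  write.table(points, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

utils::globalVariables(c("xmin", "xmax", "fill", "mvalue", "logp", "study",
                         "beta", "lo", "hi"))
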