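test_that("P-M plot points carry regions consistent with classification", {
  pan <- MetaPanel(beta = c(0.32, 0.01, 0.15), se = c(0.06, 0.05, 0.2),
                   labels = c("big1", "big0", "small"))
  mres <- mvaluesExact(pan)
  pts <- pmPoints(pan, mres)
  expect_equal(pts$region, as.character(classifyStudies(mres)))
  expect_true(all(pts$pvalue > 0 & pts$pvalue <= 1))
  # explicit p-values are honoured
  pts2 <- pmPoints(pan, c(0.95, 0.05, 0.5), pvalues = c(1e-9, 0.3, 0.04))
  expect_equal(pts2$region,
               c("predicted-effect", "predicted-no-effect", "ambiguous"))
})

test_that("P-M and forest plots render to png and svg files", {
  pan <- simulatePanel(rep(1000, 10), rr = rep(c(1.3, 1), 5), seed = 17)
  png <- tempfile(fileext = ".png")
  pmPlot(pan, file = png)
  expect_true(file.exists(png) && file.size(png) > 1000)
  svg <- tempfile(fileext = ".svg")
  forestPlot(pan, file = svg)
  expect_true(file.exists(svg) && file.size(svg) > 1000)
  expect_error(pmPlot(pan, file = file.path(tempdir(), "nope", "x.png")),
               "directory")
  expect_error(pmPlot(pan, file = tempfile(fileext = ".pdf")), "format")
  expect_error(pmPlot(data.frame()), "at least one")
})

test_that("forest plot intervals follow the normal quantile and scale with se", {
  pan <- MetaPanel(beta = c(0, 0), se = c(0.1, 0.2))
  gg <- forestPlot(pan, level = 0.95)
  df <- gg$data
  expect_equal(df$lo, c(-1, -2) * qnorm(0.975) * 0.1, tolerance = 1e-12)
  expect_equal(df$hi - df$lo, 2 * qnorm(0.975) * c(0.1, 0.2))
  expect_error(forestPlot(pan, level = 1.2), "level")
})

test_that("exported point tables round-trip through TSV", {
  pan <- randomPanel(4, 3)
  pts <- pmPoints(pan, mvaluesExact(pan))
  tf <- tempfile(fileext = ".tsv")
  writePmPoints(pts, tf)
  back <- read.delim(tf)
  expect_equal(back$region, pts$region)
  expect_equal(back$mvalue, pts$mvalue, tolerance = 1e-12)
})
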