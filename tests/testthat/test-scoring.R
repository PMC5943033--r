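test_that("GFP-total is the mean normalized intensity of the islet", {
  m <- data.frame(normalized_gfp = c(0.2, 0.4, 0.6, 0.8))
  expect_equal(gfpTotalThreshold(m), 0.5)
  expect_equal(gfpTotalThreshold(data.frame(normalized_gfp = rep(0.3, 7))),
               0.3)
  set.seed(2)
  v <- runif(1000)
  expect_equal(gfpTotalThreshold(data.frame(normalized_gfp = v)),
               sum(v) / length(v))
  expect_error(gfpTotalThreshold(data.frame(normalized_gfp = numeric())),
               "undefined")
  # section-mean mode weights sections, not cells
  m2 <- data.frame(normalized_gfp = c(0.1, 0.3, 0.8), center_z = c(1, 1, 2))
  expect_equal(gfpTotalThreshold(m2, mode = "section_mean"),
               mean(c(0.2, 0.8)))
})

test_that("high/low classification partitions with ties going low", {
  m <- data.frame(normalized_gfp = c(0.2, 0.4, 0.6, 0.8))
  cls <- classifyHighLow(m, 0.5)
  expect_identical(as.character(cls$gfp_class), c("low", "low", "high",
                                                  "high"))
  tie <- classifyHighLow(data.frame(normalized_gfp = rep(0.5, 4)), 0.5)
  expect_true(all(tie$gfp_class == "low"))
  expect_false(anyNA(cls$gfp_class))
  expect_error(classifyHighLow(m, NA_real_), "finite")
})

test_that("well-separated mixtures classify >= 95% of cells correctly", {
  st <- demoStage(n = 400, wHigh = 0.5)
  sim <- simulateIsletStack(st, seed = 13, render = FALSE)
  tr <- sim$truth
  cls <- classifyHighLow(tr, gfpTotalThreshold(tr))
  expect_gte(mean(as.character(cls$gfp_class) == tr$gfp_class_true), 0.95)
})

test_that("marker positivity separates bimodal means and honours fixed cuts", {
  m <- data.frame(mean_EDU = c(rep(5, 10), rep(200, 10)))
  pos <- markerPositive(m, "EDU", method = "otsu")
  expect_identical(as.logical(pos), rep(c(FALSE, TRUE), each = 10))
  m2 <- data.frame(mean_EDU = c(50, 150))
  expect_identical(as.logical(markerPositive(m2, "EDU", "fixed",
                                             value = 100)),
                   c(FALSE, TRUE))
  expect_error(markerPositive(data.frame(mean_EDU = rep(7, 5)), "EDU",
                              "otsu"),
               "fixed")
  expect_error(markerPositive(m, "PCNA"), "PCNA")
})

test_that("planted EdU truth is perfectly recovered on noise-free stacks", {
  sim <- cachedIsletSim("noisefree", function()
    simulateIsletStack(demoStage(n = 30), seed = 5, applyNoise = FALSE))
  m <- measureCells(sim$stack, sim$labels)
  pos <- markerPositive(m, "EDU", "fixed", value = 60)
  tr <- sim$truth[match(m$cell_id, sim$truth$cell_id), ]
  expect_identical(as.logical(pos), tr$edu_true)
})

test_that("the FUCCI percentage counts green-only cells over all cells", {
  none <- data.frame(fucci_green = rep(FALSE, 100),
                     fucci_red = rep(TRUE, 100))
  expect_equal(fucciProliferationPercentage(none), 0)
  two <- data.frame(fucci_green = c(rep(TRUE, 2), rep(FALSE, 198)),
                    fucci_red = c(rep(FALSE, 2), rep(TRUE, 198)))
  expect_equal(fucciProliferationPercentage(two), 1)
  # 10 cells: one green+red double positive, one green-only -> 10%
  ten <- data.frame(fucci_green = c(TRUE, TRUE, rep(FALSE, 8)),
                    fucci_red = c(TRUE, FALSE, rep(TRUE, 8)))
  expect_equal(fucciProliferationPercentage(ten), 10)
  expect_error(fucciProliferationPercentage(ten[0, ]), "undefined")
  # adding a double-positive cell never raises the numerator
  set.seed(4)
  for (r in 1:20) {
    n <- sample(5:50, 1)
    cells <- data.frame(fucci_green = runif(n) < 0.3,
                        fucci_red = runif(n) < 0.5)
    before <- fucciProliferationPercentage(cells)
    after <- fucciProliferationPercentage(
      rbind(cells, data.frame(fucci_green = TRUE, fucci_red = TRUE)))
    expect_lte(after, before)
  }
})

test_that("mosaic percentages match brute-force counts and flag empties", {
  cells <- data.frame(
    cfp_pos = rep(c(TRUE, FALSE), each = 50),
    fucci_green = c(rep(FALSE, 50), rep(TRUE, 5), rep(FALSE, 45)),
    fucci_red = c(rep(TRUE, 50), rep(FALSE, 5), rep(TRUE, 45)))
  mp <- mosaicProliferationPercentages(cells)
  expect_equal(mp$pct_cfp_pos, 0)
  expect_equal(mp$pct_cfp_neg, 10)
  expect_length(mp$undefined, 0)
  noPos <- mosaicProliferationPercentages(cells[!cells$cfp_pos, ])
  expect_true(is.na(noPos$pct_cfp_pos))
  expect_identical(noPos$undefined, "cfp_pos")
  set.seed(9)
  for (r in 1:20) {
    n <- sample(10:80, 1)
    cc <- data.frame(cfp_pos = runif(n) < 0.5,
                     fucci_green = runif(n) < 0.2,
                     fucci_red = runif(n) < 0.5)
    mp <- mosaicProliferationPercentages(cc)
    gOnly <- cc$fucci_green & !cc$fucci_red
    if (any(cc$cfp_pos))
      expect_equal(mp$pct_cfp_pos,
                   100 * sum(gOnly & cc$cfp_pos) / sum(cc$cfp_pos))
    if (any(!cc$cfp_pos))
      expect_equal(mp$pct_cfp_neg,
                   100 * sum(gOnly & !cc$cfp_pos) / sum(!cc$cfp_pos))
  }
})

test_that("paired class comparison handles degenerate islet sets", {
  same <- data.frame(pct_marker_pos_high = c(1, 2, 3),
                     pct_marker_pos_low = c(1, 2, 3))
  res <- classMarkerComparison(same)
  expect_equal(res$p_value, 1)
  expect_equal(res$mean_difference, 0)
  expect_identical(res$flag, "identical")
  shifted <- data.frame(pct_marker_pos_high = (1:10) + 5,
                        pct_marker_pos_low = 1:10)
  res2 <- classMarkerComparison(shifted)
  expect_identical(res2$flag, "zero_variance")
  expect_true(is.na(res2$p_value))
  expect_equal(res2$mean_difference, 5)
  one <- data.frame(pct_marker_pos_high = 1, pct_marker_pos_low = 2)
  expect_error(classMarkerComparison(one), "2 islets")
  withNA <- data.frame(pct_marker_pos_high = c(4, 6, NA, 3),
                       pct_marker_pos_low = c(1, 2, 5, 2))
  res3 <- classMarkerComparison(withNA)
  expect_identical(res3$n_islets_excluded, 1L)
  expect_identical(res3$n_islets_used, 3L)
  expect_equal(res3$p_value,
               t.test(c(4, 6, 3), c(1, 2, 2), paired = TRUE)$p.value)
})

test_that("one-way ANOVA matches the hand-computed table and t^2 identity", {
  # hand-computed example, sums of squares evaluated independently below
  pct <- c(6, 8, 4, 5, 3, 4, 6, 2, 2, 6, 8, 7, 10, 8, 4)
  grp <- rep(c("a", "b", "c"), each = 5)
  res <- stageComparisonAnova(pct, grp)
  gm <- mean(pct)
  ssb <- 5 * sum((tapply(pct, grp, mean) - gm)^2)
  ssw <- sum((pct - ave(pct, grp))^2)
  Fhand <- (ssb / 2) / (ssw / 12)
  expect_equal(res$F, Fhand)
  expect_equal(res$p_value, pf(Fhand, 2, 12, lower.tail = FALSE))
  # two groups: F equals the squared equal-variance t statistic
  x <- c(3.1, 4.2, 2.8, 5.0)
  y <- c(6.3, 5.9, 7.4)
  res2 <- stageComparisonAnova(c(x, y), rep(c("x", "y"), c(4, 3)))
  tstat <- t.test(x, y, var.equal = TRUE)$statistic
  expect_equal(res2$F, unname(tstat)^2)
  # constant data: documented F = 0, p = 1 convention
  resC <- stageComparisonAnova(rep(2, 6), rep(c("a", "b"), 3))
  expect_identical(resC$flag, "constant")
  expect_equal(resC$F, 0)
  expect_equal(resC$p_value, 1)
  expect_error(stageComparisonAnova(1:5, rep("a", 5)), "2 stages")
})

test_that("islet scoring assembles a consistent summary", {
  set.seed(3)
  cells <- data.frame(normalized_gfp = c(runif(40, 0, 0.2),
                                         runif(10, 0.5, 1)),
                      fucci_green = rep(c(TRUE, FALSE), c(5, 45)),
                      fucci_red = rep(c(FALSE, TRUE), c(5, 45)),
                      marker_pos = runif(50) < 0.2)
  s <- scoreIslet(cells, "i1", "3mpf")
  expect_identical(s$n_cells, 50L)
  expect_equal(s$n_gfp_high + s$n_gfp_low, 50)
  expect_equal(s$pct_proliferating, 10)
  expect_equal(s$gfp_total, mean(cells$normalized_gfp))
  hi <- cells$normalized_gfp > s$gfp_total
  expect_equal(s$pct_marker_pos_high, 100 * mean(cells$marker_pos[hi]))
  expect_equal(s$pct_marker_pos_low, 100 * mean(cells$marker_pos[!hi]))
})
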