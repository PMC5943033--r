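test_that("housekeeping filtering drops exactly the failing cells", {
  ct <- matrix(c(20, 20, 20, 25,   # cell ok
                 20, 40, 20, 25,   # fails ef1a
                 20, 20, 20, 40),  # candidate undetected: kept
               nrow = 4,
               dimnames = list(c("bact1", "ef1a", "rpl13a", "tnfa"),
                               c("c1", "c2", "c3")))
  x <- CtExperiment(ct, stage = rep("3mpf", 3))
  expect_message(f <- housekeepingFilter(x), "1 of 3")
  expect_identical(colnames(f), c("c1", "c3"))
  expect_identical(S4Vectors::metadata(f)$housekeeping_removed, 1L)
  clean <- CtExperiment(ct[, 1, drop = FALSE], stage = "3mpf")
  expect_identical(dim(suppressMessages(housekeepingFilter(clean))),
                   dim(clean))
  expect_error(housekeepingFilter(x, c("bact1", "gapdh")), "gapdh")
  # random censoring pattern vs a brute-force row scan
  x2 <- simulateCtTable(hkStage(), c("bact1", "ef1a", "rpl13a", "tnfa"),
                        nCells = 150, seed = 6)
  keepOracle <- logical(150)
  ctm <- ctValues(x2)
  for (j in seq_len(150)) {
    ok <- TRUE
    for (g in c("bact1", "ef1a", "rpl13a")) if (ctm[g, j] == 40) ok <- FALSE
    keepOracle[j] <- ok
  }
  f2 <- suppressMessages(housekeepingFilter(x2))
  expect_identical(colnames(f2), colnames(x2)[keepOracle])
})

test_that("detection uses strict Ct < 40 with the sentinel excluded", {
  ct <- matrix(c(38, 40, 40, 35), nrow = 1,
               dimnames = list("tnfa", paste0("c", 1:4)))
  x <- CtExperiment(ct, stage = rep("3mpf", 4))
  d <- detectionFraction(x, "tnfa", "3mpf")
  expect_equal(d$pct_detected, 50)
  expect_identical(d$n_detected, 2L)
  allc <- CtExperiment(matrix(40, 1, 3, dimnames = list("g", NULL)),
                       stage = rep("s", 3))
  expect_equal(detectionFraction(allc, "g", "s")$pct_detected, 0)
  boundary <- CtExperiment(matrix(39.999, 1, 1,
                                  dimnames = list("g", NULL)),
                           stage = "s")
  expect_equal(detectionFraction(boundary, "g", "s")$pct_detected, 100)
  expect_error(detectionFraction(allc, "g", "missing"), "missing")
  expect_error(detectionFraction(allc, "nope", "s"), "nope")
})

test_that("chi-square equals the hand 2x2 formula and is symmetric", {
  mkSummary <- function(det, n, stage)
    data.frame(gene = "g", stage = stage, n_cells = n, n_detected = det,
               pct_detected = 100 * det / n)
  a <- mkSummary(30, 100, "3mpf")
  b <- mkSummary(60, 100, "1ypf")
  res <- chiSquareDetection(a, b)
  # independent hand evaluation of the 2x2 Pearson formula
  hand <- 200 * (30 * 40 - 70 * 60)^2 / (100 * 100 * 90 * 110)
  expect_equal(res$chi2, hand)
  expect_equal(hand, 18.18, tolerance = 1e-3)
  expect_identical(res$df, 1L)
  flip <- chiSquareDetection(b, a)
  expect_equal(flip$chi2, res$chi2)
  expect_equal(flip$p_value, res$p_value)
  same <- chiSquareDetection(mkSummary(25, 50, "a"), mkSummary(25, 50, "b"))
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)
  expect_error(chiSquareDetection(mkSummary(50, 50, "a"),
                                  mkSummary(50, 50, "b")),
               "expected")
  bad <- mkSummary(10, 20, "a"); bad$gene <- "other"
  expect_error(chiSquareDetection(a, bad), "different genes")
})

test_that("the -log10 representation maps the sentinel to about -1.6", {
  expect_equal(negLog10Ct(40), -log10(40))
  expect_equal(round(negLog10Ct(40), 1), -1.6)
  expect_equal(negLog10Ct(10), -1)
  expect_equal(negLog10Ct(1), 0)
  expect_error(negLog10Ct(c(10, 0)), "> 0")
  expect_error(negLog10Ct(41), "sentinel")
  v <- sort(runif(50, 0.5, 40))
  expect_true(all(diff(negLog10Ct(v)) < 0))  # strictly decreasing
})

test_that("fold changes follow the 2^-ddCt identities and plate invariance", {
  bulk <- simulateBulkQpcr(c(ref = 1, g = 2), "ref", nReplicates = 4,
                           seed = 2, noiseSd = 0)
  res <- deltaCtFoldChange(bulk, "g", "ref")
  expect_equal(res$fold_change, 2)
  expect_equal(res$per_replicate_ddct, rep(-1, 4))
  # identical groups: fold 1, all ddCt zero, flagged identical
  bulkSame <- bulk
  bulkSame$ct[bulkSame$gene == "g"] <- 25
  resSame <- deltaCtFoldChange(bulkSame, "g", "ref")
  expect_equal(resSame$fold_change, 1)
  expect_identical(resSame$flag, "identical")
  expect_equal(resSame$p_value, 1)
  # plate shift: adding a constant to one replicate's Cts changes nothing
  bulkN <- simulateBulkQpcr(c(ref = 1, g = 2.5), "ref", nReplicates = 5,
                            seed = 3, noiseSd = 0.2)
  shifted <- bulkN
  shifted$ct[shifted$replicate == 2] <- shifted$ct[shifted$replicate == 2] + 3.3
  expect_equal(deltaCtFoldChange(shifted, "g", "ref")$fold_change,
               deltaCtFoldChange(bulkN, "g", "ref")$fold_change)
  # missing pairing errors
  broken <- bulkN[!(bulkN$gene == "g" & bulkN$replicate == 1 &
                      bulkN$group == "low"), ]
  expect_error(deltaCtFoldChange(broken, "g", "ref"), "pairing")
})

test_that("R^2 matches a hand covariance formula and its limits", {
  x <- 1:10
  exact <- data.frame(f = x, ct = 10^(-(0.1 * x - 1.5)))
  expect_equal(intensityExpressionR2(exact$f, exact$ct), 1)
  set.seed(8)
  f <- runif(20, 100, 1000)
  ct <- runif(20, 15, 35)
  # independent oracle: raw-sum Pearson formula
  n <- 20
  e <- -log10(ct)
  rHand <- (n * sum(f * e) - sum(f) * sum(e)) /
    sqrt((n * sum(f^2) - sum(f)^2) * (n * sum(e^2) - sum(e)^2))
  expect_equal(intensityExpressionR2(f, ct), rHand^2)
  # censored cells are dropped before correlating
  fc <- c(f, 5000); ctc <- c(ct, 40)
  expect_equal(intensityExpressionR2(fc, ctc), rHand^2)
  expect_equal(intensityExpressionR2(fc, ctc, dropCensored = FALSE),
               cor(fc, -log10(ctc))^2)
  expect_error(intensityExpressionR2(c(1, 2), c(20, 30)), "3")
  expect_error(intensityExpressionR2(rep(1, 5), runif(5, 10, 30)),
               "variance")
})

test_that("detection fractions recover planted probabilities within CI", {
  x <- simulateCtTable(hkStage(), c("bact1", "ef1a", "rpl13a", "tnfa"),
                       nCells = 400, seed = 12)
  d <- detectionFraction(x, "tnfa", "hk")
  expect_gte(d$n_detected, qbinom(0.0005, 400, 0.3))
  expect_lte(d$n_detected, qbinom(0.9995, 400, 0.3))
})
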