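test_that("zero-probability plants force the outcome with no exceptions", {
  st <- demoStage(pProlif = 0)
  sim <- simulateIsletStack(st, seed = 1, render = FALSE)
  expect_false(any(sim$truth$proliferating_true))
  expect_true(all(sim$truth$fucci_red_true))
  stM <- stageParams("m", cells_min = 80, cells_max = 80, p_cfp = 0,
                     p_prolif_given_cfp = 0.5, p_prolif_given_nocfp = 0.5)
  simM <- simulateMosaicIslet(stM, seed = 1, render = FALSE)
  expect_false(any(simM$truth$cfp_true))
  stH <- demoStage(wHigh = 1)
  simH <- simulateIsletStack(stH, seed = 1, render = FALSE)
  expect_true(all(simH$truth$gfp_class_true == "high"))
})

test_that("identical (stage, seed) gives voxel-identical stacks and truth", {
  st <- demoStage(n = 40)
  a <- simulateIsletStack(st, seed = 9)
  b <- simulateIsletStack(st, seed = 9)
  expect_identical(a$stack@data, b$stack@data)
  expect_identical(labelData(a$labels), labelData(b$labels))
  expect_identical(a$truth, b$truth)
  c <- simulateIsletStack(st, seed = 10)
  expect_false(identical(a$truth, c$truth))
})

test_that("planted mixture weight is recovered within the exact binomial band", {
  st <- stageParams("w", cells_min = 400, cells_max = 400,
                    p_proliferating = 0,
                    gfp_mixture = list(w_high = 0.5, mu_low = 1.6,
                                       sigma_low = 0.4, mu_high = 4.1,
                                       sigma_high = 0.4))
  sim <- simulateIsletStack(st, seed = 3, render = FALSE)
  nHigh <- sum(sim$truth$gfp_class_true == "high")
  # central 99.9% binomial interval for n = 400, p = 0.5
  expect_gte(nHigh, qbinom(0.0005, 400, 0.5))
  expect_lte(nHigh, qbinom(0.9995, 400, 0.5))
})

test_that("labels conserve cells: one label per cell, non-overlapping spheres", {
  sim <- cachedIsletSim()
  lab <- labelData(sim$labels)
  ids <- sort(setdiff(unique(as.integer(lab)), 0L))
  expect_identical(ids, sim$truth$cell_id)
  expect_identical(nCells(sim$labels), nrow(sim$truth))
  # every sphere fully voxelized: per-cell voxel counts near the analytic
  # sphere volume (4/3 pi 6^3 ~ 905), and packed centers never closer than
  # one diameter, so no voxel is claimed twice
  counts <- tabulate(lab[lab > 0L])
  expect_true(all(counts > 850 & counts < 990))
  ctrs <- as.matrix(sim$truth[, c("centroid_z", "centroid_y",
                                  "centroid_x")])
  expect_gte(min(dist(ctrs)), 2 * sim$truth$radius_vox[1] - 1e-9)
  # ground truth consistent with pre-noise channels: centroid voxel carries
  # the cell's own label
  ctr <- round(as.matrix(sim$truth[, c("centroid_z", "centroid_y",
                                       "centroid_x")]))
  expect_identical(as.integer(lab[ctr]), sim$truth$cell_id)
})

test_that("over-dense packing fails with an explicit density error", {
  expect_error(
    isletAging:::.packSpheres(200, 6, maxAttempts = 500L,
                              packingFraction = 0.9),
    "packing")
})

test_that("cohorts preserve stage structure and are seed-deterministic", {
  sc <- IsletScenario(stages = list(a = demoStage("a", n = 30),
                                    b = demoStage("b", n = 30),
                                    c = demoStage("c", n = 30)))
  coh <- simulateCohort(sc, seed = 4, render = FALSE)
  expect_length(coh, 6L)  # 3 stages x 2 islets
  expect_identical(vapply(coh, `[[`, character(1), "stage"),
                   rep(c("a", "b", "c"), each = 2))
  coh2 <- simulateCohort(sc, seed = 4, render = FALSE)
  expect_identical(cohortTruth(coh), cohortTruth(coh2))
})

test_that("pooled cohort proliferation recovers the plant within binomial CI", {
  st <- stageParams("p", n_islets = 6L, cells_min = 500, cells_max = 500,
                    p_proliferating = 0.05)
  sc <- IsletScenario(stages = list(p = st))
  tr <- cohortTruth(simulateCohort(sc, seed = 8, render = FALSE))
  k <- sum(tr$proliferating_true)
  n <- nrow(tr)
  expect_gte(k, qbinom(0.0005, n, 0.05))
  expect_lte(k, qbinom(0.9995, n, 0.05))
})

test_that("mosaic class plants are recovered and the null plant is null", {
  stM <- stageParams("m", n_islets = 9L, cells_min = 200, cells_max = 200,
                     p_cfp = 0.3, p_prolif_given_cfp = 0.011,
                     p_prolif_given_nocfp = 0.084)
  # Monte-Carlo over replicate cohorts: class-wise pooled rates converge on
  # the plants
  reps <- 60
  pos <- neg <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulateMosaicIslet(stM, seed = deriveSeed(11, r),
                               render = FALSE)
    tr <- sim$truth
    pos[r] <- mean(tr$proliferating_true[tr$cfp_true])
    neg[r] <- mean(tr$proliferating_true[!tr$cfp_true])
  }
  # 4-sigma binomial bands around the plants
  nPos <- reps * 200 * 0.3
  nNeg <- reps * 200 * 0.7
  expect_lt(abs(mean(pos) - 0.011), 4 * sqrt(0.011 * 0.989 / nPos))
  expect_lt(abs(mean(neg) - 0.084), 4 * sqrt(0.084 * 0.916 / nNeg))
  # equal conditional plants: planted class difference is zero in the mean
  stNull <- stageParams("n", cells_min = 400, cells_max = 400, p_cfp = 0.5,
                        p_prolif_given_cfp = 0.05,
                        p_prolif_given_nocfp = 0.05)
  diffs <- vapply(seq_len(40), function(r) {
    tr <- simulateMosaicIslet(stNull, seed = deriveSeed(5, r),
                              render = FALSE)$truth
    mean(tr$proliferating_true[tr$cfp_true]) -
      mean(tr$proliferating_true[!tr$cfp_true])
  }, numeric(1))
  se <- sqrt(2 * 0.05 * 0.95 / 200) / sqrt(40)
  expect_lt(abs(mean(diffs)), 4 * se)
})

test_that("rendered channels reflect ground truth before noise", {
  st <- demoStage(n = 30)
  sim <- simulateIsletStack(st, seed = 6, applyNoise = FALSE)
  lab <- labelData(sim$labels)
  tr <- sim$truth
  edu <- getChannel(sim$stack, "EDU")
  fg <- getChannel(sim$stack, "FUCCI_G")
  for (i in tr$cell_id) {
    vox <- lab == i
    expect_equal(unique(edu[vox]), if (tr$edu_true[i]) 120 else 0)
    expect_equal(unique(fg[vox]), if (tr$proliferating_true[i]) 80 else 0)
  }
  expect_true(all(getChannel(sim$stack, "DAPI")[lab > 0] == 100))
  expect_true(all(getChannel(sim$stack, "DAPI")[lab == 0] == 0))
})
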