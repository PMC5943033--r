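#' @importFrom data.table data.table rbindlist setDF :=
NULL

# Nominal pre-noise channel intensities (fluorescence a.u.). The NF-kB GFP
# channel is per-cell (log-normal mixture); all others are on/off levels.
.defaultChannelLevels <- c(DAPI = 100, INS = 60, EDU = 120, FUCCI_R = 80,
                           FUCCI_G = 80, CFP = 90)

.isletChannels <- c("DAPI", "INS", "NFKB_GFP", "EDU", "FUCCI_R", "FUCCI_G",
                    "CFP")

# Draw the per-cell ground-truth states for one islet. `mosaic` switches the
# proliferation model from the marginal p_proliferating to the
# CFP-conditional probabilities.
.drawCellStates <- function(stage, n, mosaic = FALSE) {
  mix <- stage$gfp_mixture
  if (!is.null(mix)) {
    high <- runif(n) < mix$w_high
    gfp <- ifelse(high,
                  exp(rnorm(n, mix$mu_high, mix$sigma_high)),
                  exp(rnorm(n, mix$mu_low, mix$sigma_low)))
  } else {
    high <- rep(FALSE, n)
    gfp <- rep(0, n)
  }
  if (mosaic) {
    if (is.null(stage$p_cfp) || is.null(stage$p_prolif_given_cfp) ||
        is.null(stage$p_prolif_given_nocfp))
      stop("mosaic simulation requires p_cfp, p_prolif_given_cfp and ",
           "p_prolif_given_nocfp for stage '", stage$name, "'")
    cfp <- runif(n) < stage$p_cfp
    pProl <- ifelse(cfp, stage$p_prolif_given_cfp,
                    stage$p_prolif_given_nocfp)
    prolif <- runif(n) < pProl
  } else {
    cfp <- rep(FALSE, n)
    p <- if (is.null(stage$p_proliferating)) 0 else stage$p_proliferating
    prolif <- runif(n) < p
  }
  pEdu <- rep(0, n)
  if (!is.null(stage$p_edu_given_gfp_high))
    pEdu[high] <- stage$p_edu_given_gfp_high
  if (!is.null(stage$p_edu_given_gfp_low))
    pEdu[!high] <- stage$p_edu_given_gfp_low
  edu <- runif(n) < pEdu
  data.table::data.table(
    cell_id = seq_len(n),
    gfp_class_true = ifelse(high, "high", "low"),
    gfp_intensity_true = gfp,
    proliferating_true = prolif,
    edu_true = edu,
    cfp_true = cfp,
    fucci_green_true = prolif,
    fucci_red_true = !prolif
  )
}

# Non-overlapping sphere packing inside an axis-aligned ellipsoid by
# rejection sampling; hard cap of `maxAttempts` draws per cell. Centers are
# kept at least one radius inside the ellipsoid surface. Returns voxel
# coordinates (z, y, x) and the chosen volume dimensions.
.packSpheres <- function(n, radiusVox, maxAttempts = 10000L,
                         packingFraction = 0.25, zFlatten = 0.7) {
  sphereVol <- 4 / 3 * pi * radiusVox^3
  ellVol <- n * sphereVol / packingFraction
  # semi-axes a_z = zFlatten * a, a_y = a_x = a
  a <- (ellVol * 3 / (4 * pi * zFlatten))^(1 / 3)
  semi <- c(z = zFlatten * a, y = a, x = a)
  inner <- pmax(semi - radiusVox, radiusVox / 2)
  # centers stay in the inner ellipsoid, so spheres reach at most `semi`
  dims <- as.integer(ceiling(2 * (semi + 2)))
  ctr <- (dims + 1) / 2
  centers <- matrix(NA_real_, nrow = n, ncol = 3)
  minD2 <- (2 * radiusVox)^2
  for (i in seq_len(n)) {
    attempts <- 0L
    placed <- FALSE
    while (!placed) {
      batch <- min(64L, maxAttempts - attempts)
      if (batch <= 0L)
        stop("sphere packing failed after ", maxAttempts,
             " attempts for cell ", i, " of ", n,
             ": requested density exceeds the packing limit ",
             "(packing fraction ", packingFraction, ")")
      cand <- cbind(runif(batch, -1, 1), runif(batch, -1, 1),
                    runif(batch, -1, 1))
      # cand lives in the unit-ball coordinates of the *inner* ellipsoid;
      # the affine map below preserves uniformity
      cand <- cand[rowSums(cand^2) <= 1, , drop = FALSE]
      attempts <- attempts + batch
      if (nrow(cand) == 0L) next
      pts <- sweep(sweep(cand, 2, inner, "*"), 2, ctr, "+")
      if (i > 1L) {
        acc <- centers[seq_len(i - 1L), , drop = FALSE]
        d2 <- outer(pts[, 1], acc[, 1], "-")^2 +
              outer(pts[, 2], acc[, 2], "-")^2 +
              outer(pts[, 3], acc[, 3], "-")^2
        ok <- which(rowSums(d2 < minD2) == 0L)
      } else ok <- 1L
      if (length(ok)) {
        centers[i, ] <- pts[ok[1L], ]
        placed <- TRUE
      }
    }
  }
  list(centers = centers, dims = dims)
}

# Voxelize spheres into a label volume: voxel value = cell_id, 0 background.
# Distances are taken from the exact (sub-voxel) centers, so spheres packed
# at >= 2r separation can never claim the same voxel (up to the measure-zero
# equidistant boundary, where the first cell wins).
.voxelizeLabels <- function(centers, radiusVox, dims) {
  lab <- array(0L, dim = dims)
  r <- ceiling(radiusVox)
  off <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
  for (i in seq_len(nrow(centers))) {
    base <- round(centers[i, ])
    frac <- centers[i, ] - base
    keep <- (off[, 1] - frac[1])^2 + (off[, 2] - frac[2])^2 +
      (off[, 3] - frac[3])^2 <= radiusVox^2 + 1e-9
    vox <- sweep(off[keep, , drop = FALSE], 2, base, "+")
    ok <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
          vox[, 2] >= 1 & vox[, 2] <= dims[2] &
          vox[, 3] >= 1 & vox[, 3] <= dims[3]
    v <- vox[ok, , drop = FALSE]
    tgt <- cbind(v[, 1], v[, 2], v[, 3])
    free <- lab[tgt] == 0L
    lab[tgt[free, , drop = FALSE]] <- i
  }
  lab
}

# Forward noise model: Gaussian blur (sigma in um), constant background,
# Poisson shot noise of scaled intensities.
.applyNoise <- function(vol, noise, voxelSizeUm) {
  if (noise$blur_sigma_um > 0)
    vol <- blur3d(vol, noise$blur_sigma_um / voxelSizeUm)
  lam <- noise$photon_scale * (vol + noise$background)
  out <- rpois(length(lam), lam) / noise$photon_scale
  dim(out) <- dim(vol)
  out
}

.renderIslet <- function(truth, lab, noise, voxelSizeUm,
                         channelLevels = .defaultChannelLevels,
                         applyNoise = TRUE, channels = .isletChannels) {
  dims <- dim(lab)
  channels <- intersect(.isletChannels, channels)
  nCh <- length(channels)
  stack <- array(0, dim = c(nCh, dims))
  perCell <- function(values) c(0, values)[lab + 1L]
  chan <- list(
    DAPI = perCell(rep(channelLevels[["DAPI"]], nrow(truth))),
    INS = perCell(rep(channelLevels[["INS"]], nrow(truth))),
    NFKB_GFP = perCell(truth$gfp_intensity_true),
    EDU = perCell(ifelse(truth$edu_true, channelLevels[["EDU"]], 0)),
    FUCCI_R = perCell(ifelse(truth$fucci_red_true,
                             channelLevels[["FUCCI_R"]], 0)),
    FUCCI_G = perCell(ifelse(truth$fucci_green_true,
                             channelLevels[["FUCCI_G"]], 0)),
    CFP = perCell(ifelse(truth$cfp_true, channelLevels[["CFP"]], 0))
  )
  for (i in seq_len(nCh)) {
    v <- chan[[channels[i]]]
    dim(v) <- dims
    if (applyNoise) v <- .applyNoise(v, noise, voxelSizeUm)
    stack[i, , , ] <- v
  }
  IsletStack(stack, channels, voxelSizeUm)
}

#' Simulate one synthetic islet image stack with ground truth
#'
#' Packs non-overlapping spherical nuclei into an axis-aligned ellipsoid,
#' draws per-cell ground-truth states (NF-kB GFP intensity from a
#' two-component log-normal mixture, FUCCI cell-cycle state, EdU
#' incorporation, mosaic CFP), renders a 7-channel image (DAPI, INS,
#' NFKB_GFP, EDU, FUCCI_R, FUCCI_G, CFP), and applies the forward noise
#' model (Gaussian blur, constant background, Poisson shot noise). The
#' companion label volume stores the pre-noise cell identities, so ground
#' truth is exact.
#'
#' @param stage a stage parameter list from [stageParams()].
#' @param noise noise model list (`photon_scale`, `background`,
#'   `blur_sigma_um`); defaults to the standard forward model.
#' @param seed integer seed; identical (stage, seed) pairs give
#'   voxel-identical output.
#' @param voxelSizeUm,nucleusRadiusUm imaging geometry (micrometres).
#' @param mosaic logical; draw proliferation conditionally on mosaic CFP
#'   labelling instead of the marginal rate.
#' @param render logical; if `FALSE`, skip sphere packing and rendering
#'   and return ground truth only (fast path for count-based scoring).
#' @param applyNoise logical; `FALSE` renders noise-free channels
#'   (used for validation against planted intensities).
#' @param channels channels to render (default: all seven); restricting
#'   to the channels an experiment uses cuts rendering cost without
#'   changing ground truth.
#' @return a list with elements `stack` ([IsletStack-class] or `NULL`),
#'   `labels` ([LabelVolume-class] or `NULL`) and `truth` (data.frame of
#'   per-cell ground truth: `cell_id`, `centroid_z/y/x` (1-based voxel
#'   coordinates), `radius_vox`, `gfp_class_true`, `gfp_intensity_true`,
#'   `proliferating_true`, `edu_true`, `cfp_true`, FUCCI flags).
#' @examples
#' st <- stageParams("demo", cells_min = 40, cells_max = 40,
#'                   p_proliferating = 0.1)
#' sim <- simulateIsletStack(st, seed = 7)
#' sim$stack
#' @export
simulateIsletStack <- function(stage,
                               noise = list(photon_scale = 2, background = 2,
                                            blur_sigma_um = 0.5),
                               seed = 1L, voxelSizeUm = 0.5,
                               nucleusRadiusUm = 3, mosaic = FALSE,
                               render = TRUE, applyNoise = TRUE,
                               channels = .isletChannels) {
  err <- .checkStageParams(stage)
  if (!is.null(err)) stop(paste(err, collapse = "; "))
  withSeed(seed, function() {
    n <- if (stage$cells_max > stage$cells_min)
      sample(stage$cells_min:stage$cells_max, 1L) else stage$cells_min
    truth <- .drawCellStates(stage, n, mosaic = mosaic)
    if (!render) {
      truth$normalized_gfp <- truth$gfp_intensity_true /
        .defaultChannelLevels[["DAPI"]]
      return(list(stack = NULL, labels = NULL, truth = data.table::setDF(truth)))
    }
    radiusVox <- nucleusRadiusUm / voxelSizeUm
    pk <- .packSpheres(n, radiusVox)
    lab <- .voxelizeLabels(pk$centers, radiusVox, pk$dims)
    truth$centroid_z <- pk$centers[, 1]
    truth$centroid_y <- pk$centers[, 2]
    truth$centroid_x <- pk$centers[, 3]
    truth$radius_vox <- radiusVox
    stack <- .renderIslet(truth, lab, noise, voxelSizeUm,
                          applyNoise = applyNoise, channels = channels)
    list(stack = stack, labels = LabelVolume(lab),
         truth = data.table::setDF(truth))
  })
}

#' Simulate a mosaic-transgenesis islet
#'
#' As [simulateIsletStack()], but beta-cells carry the CFP-marked mosaic
#' transgene with probability `p_cfp` and proliferate with
#' class-conditional probabilities `p_prolif_given_cfp` /
#' `p_prolif_given_nocfp`. This emulates stochastic genomic integration of
#' an insulin-promoter construct (e.g. socs2-T2A-CFP) injected at the
#' one-cell stage.
#'
#' @inheritParams simulateIsletStack
#' @return see [simulateIsletStack()].
#' @export
simulateMosaicIslet <- function(stage,
                                noise = list(photon_scale = 2,
                                             background = 2,
                                             blur_sigma_um = 0.5),
                                seed = 1L, voxelSizeUm = 0.5,
                                nucleusRadiusUm = 3, render = TRUE,
                                applyNoise = TRUE) {
  simulateIsletStack(stage, noise = noise, seed = seed,
                     voxelSizeUm = voxelSizeUm,
                     nucleusRadiusUm = nucleusRadiusUm, mosaic = TRUE,
                     render = render, applyNoise = applyNoise)
}

#' Simulate a multi-stage cohort of islets
#'
#' Generates `n_islets` islets for every requested stage of a scenario.
#' Per-islet seeds are derived deterministically from
#' `deriveSeed(seed, stage_index, islet_index)`, so any islet can be
#' regenerated in isolation.
#'
#' @param scenario an [IsletScenario-class].
#' @param seed integer root seed.
#' @param stageNames stages to simulate (default: all).
#' @param render logical; `FALSE` generates ground-truth tables only.
#' @param mosaicStages character vector of stage names to simulate with
#'   the CFP-conditional mosaic model (default: stages that define
#'   `p_cfp`).
#' @param channels channels to render (see [simulateIsletStack()]).
#' @return a list of per-islet results; each element is the
#'   [simulateIsletStack()] output plus `stage`, `islet_id` and the
#'   derived `seed`.
#' @seealso [cohortTruth()]
#' @export
simulateCohort <- function(scenario, seed = scenario@seed,
                           stageNames = stages(scenario), render = TRUE,
                           mosaicStages = NULL,
                           channels = .isletChannels) {
  stopifnot(is(scenario, "IsletScenario"))
  if (is.null(mosaicStages))
    mosaicStages <- names(Filter(function(s) !is.null(s$p_cfp),
                                 scenario@stages))
  out <- list()
  for (si in seq_along(stageNames)) {
    nm <- stageNames[si]
    stage <- stageParamsOf(scenario, nm)
    stageIdx <- match(nm, stages(scenario))
    for (ii in seq_len(stage$n_islets)) {
      isletSeed <- deriveSeed(seed, stageIdx, ii)
      sim <- simulateIsletStack(stage, noise = scenario@noiseModel,
                                seed = isletSeed,
                                voxelSizeUm = scenario@voxelSizeUm,
                                nucleusRadiusUm = scenario@nucleusRadiusUm,
                                mosaic = nm %in% mosaicStages,
                                render = render, channels = channels)
      sim$stage <- nm
      sim$islet_id <- paste0(nm, "_islet", ii)
      sim$seed <- isletSeed
      out[[length(out) + 1L]] <- sim
    }
  }
  out
}

#' Pooled ground-truth table of a cohort
#'
#' @param cohort result of [simulateCohort()].
#' @return data.frame of all per-cell ground-truth rows with `stage` and
#'   `islet_id` columns prepended.
#' @export
cohortTruth <- function(cohort) {
  dt <- data.table::rbindlist(lapply(cohort, function(el) {
    tr <- data.table::as.data.table(el$truth)
    tr[, `:=`(stage = el$stage, islet_id = el$islet_id)]
    tr
  }), fill = TRUE)
  data.table::setDF(dt)
}
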