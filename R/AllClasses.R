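#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Multi-channel 3D islet image stack
#'
#' Container for a 4D fluorescence intensity array with axis order
#' (channel, z, y, x), named channels and an isotropic voxel size.
#' Intensities are arbitrary fluorescence units; they must be finite and
#' non-negative.
#'
#' @slot data 4D numeric array, dimensions (channel, z, y, x).
#' @slot channelNames character vector naming the channel axis, e.g.
#'   `"DAPI"`, `"INS"`, `"NFKB_GFP"`, `"EDU"`, `"FUCCI_R"`, `"FUCCI_G"`,
#'   `"CFP"`.
#' @slot voxelSizeUm single positive numeric, isotropic voxel edge in
#'   micrometres.
#'
#' @seealso [IsletStack()], [getChannel()], [simulateIsletStack()]
#' @export
setClass("IsletStack",
  representation(
    data = "array",
    channelNames = "character",
    voxelSizeUm = "numeric"
  )
)

setValidity("IsletStack", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4D array (channel, z, y, x)")
  else if (dim(object@data)[1L] != length(object@channelNames))
    msg <- c(msg, "length(channelNames) must equal the channel axis length")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  if (length(object@voxelSizeUm) != 1L || !is.finite(object@voxelSizeUm) ||
      object@voxelSizeUm <= 0)
    msg <- c(msg, "voxelSizeUm must be a single positive number")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "intensities must be finite")
  else if (any(object@data < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Construct an IsletStack
#'
#' @param data 4D numeric array with axis order (channel, z, y, x).
#' @param channelNames character vector of channel names.
#' @param voxelSizeUm isotropic voxel size in micrometres.
#' @return An [IsletStack-class] object.
#' @examples
#' a <- array(runif(2 * 4 * 5 * 5), dim = c(2, 4, 5, 5))
#' IsletStack(a, c("DAPI", "NFKB_GFP"), voxelSizeUm = 0.5)
#' @export
IsletStack <- function(data, channelNames, voxelSizeUm) {
  new("IsletStack", data = data, channelNames = as.character(channelNames),
      voxelSizeUm = as.numeric(voxelSizeUm))
}

#' Per-voxel cell identity volume
#'
#' Integer labels over a (z, y, x) volume; 0 is background, values >= 1
#' identify cells. Companion to an [IsletStack-class] of matching spatial
#' dimensions.
#'
#' @slot labels 3D integer array (z, y, x), values >= 0.
#' @seealso [LabelVolume()], [segmentNuclei()], [measureCells()]
#' @export
setClass("LabelVolume", representation(labels = "array"))

setValidity("LabelVolume", function(object) {
  msg <- NULL
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array (z, y, x)")
  if (!is.integer(object@labels))
    msg <- c(msg, "labels must be integer")
  else if (anyNA(object@labels) || any(object@labels < 0L))
    msg <- c(msg, "labels must be >= 0 with no NA")
  if (is.null(msg)) TRUE else msg
})

#' Construct a LabelVolume
#'
#' @param labels 3D integer (or coercible) array, 0 = background.
#' @return A [LabelVolume-class] object.
#' @export
LabelVolume <- function(labels) {
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels)
}

#' Censored single-cell qPCR cycle-threshold experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay
#' `"ct"` of cycle-threshold values (genes x cells). Values lie in
#' (0, 40]; the sentinel Ct = 40 means "not detected" (the assay runs 40
#' amplification cycles, so a transcript whose signal never crosses
#' threshold is censored at 40). Column data must carry a non-empty
#' `stage` label per cell.
#'
#' @seealso [CtExperiment()], [housekeepingFilter()], [detectionFraction()]
#' @export
setClass("CtExperiment", contains = "SummarizedExperiment")

setValidity("CtExperiment", function(object) {
  msg <- NULL
  if (!"ct" %in% SummarizedExperiment::assayNames(object))
    return("assay 'ct' is required")
  ct <- SummarizedExperiment::assay(object, "ct")
  if (anyNA(ct) || any(ct <= 0) || any(ct > 40))
    msg <- c(msg, "all Ct values must lie in (0, 40]")
  cd <- SummarizedExperiment::colData(object)
  if (!"stage" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'stage' column")
  else if (any(is.na(cd$stage)) || any(!nzchar(as.character(cd$stage))))
    msg <- c(msg, "stage label must be non-empty for every cell")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CtExperiment
#'
#' @param ct numeric matrix of Ct values, genes in rows, cells in columns;
#'   values in (0, 40], with 40 the "not detected" sentinel.
#' @param stage character/factor of per-cell stage labels, length
#'   `ncol(ct)`.
#' @param colData optional extra per-cell annotation (`DataFrame` or
#'   data.frame); a `stage` column in it is overridden by `stage`.
#' @return A [CtExperiment-class].
#' @examples
#' ct <- matrix(c(25, 40, 30, 40), nrow = 2,
#'              dimnames = list(c("ins", "tnfa"), c("c1", "c2")))
#' CtExperiment(ct, stage = c("3mpf", "1ypf"))
#' @export
CtExperiment <- function(ct, stage, colData = NULL) {
  ct <- as.matrix(ct)
  if (is.null(colData)) {
    colData <- S4Vectors::DataFrame(stage = as.character(stage),
                                    row.names = colnames(ct))
  } else {
    colData <- S4Vectors::DataFrame(colData)
    colData$stage <- as.character(stage)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ct = ct), colData = colData)
  new("CtExperiment", se)
}

#' Synthetic-cohort scenario
#'
#' Describes the study conditions a synthetic cohort is generated under:
#' a list of per-stage parameter sets (see [stageParams()]), the imaging
#' geometry (isotropic voxel size, nuclear radius) and the noise forward
#' model (Gaussian blur then Poisson shot noise over a constant
#' background).
#'
#' @slot stages named list of stage parameter lists (see [stageParams()]).
#' @slot voxelSizeUm isotropic voxel size, micrometres.
#' @slot nucleusRadiusUm nuclear radius, micrometres.
#' @slot noiseModel list with `photon_scale` (> 0), `background` (>= 0)
#'   and `blur_sigma_um` (>= 0).
#' @slot extras list of auxiliary plant parameters that are not per-islet
#'   stages (bulk qPCR fold changes, indexed-sort correlation,
#'   intra-islet leukocyte scenario, ...).
#' @slot seed integer root seed recorded with the scenario.
#' @seealso [IsletScenario()], [paperCalibratedScenario()],
#'   [simulateCohort()]
#' @export
setClass("IsletScenario",
  representation(
    stages = "list",
    voxelSizeUm = "numeric",
    nucleusRadiusUm = "numeric",
    noiseModel = "list",
    extras = "list",
    seed = "integer"
  )
)

setValidity("IsletScenario", function(object) {
  msg <- NULL
  nm <- names(object@stages)
  if (length(object@stages) == 0L)
    msg <- c(msg, "at least one stage is required")
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    msg <- c(msg, "stage names must be unique and non-empty")
  for (s in object@stages) {
    err <- .checkStageParams(s)
    if (!is.null(err)) msg <- c(msg, err)
  }
  if (length(object@voxelSizeUm) != 1L || object@voxelSizeUm <= 0)
    msg <- c(msg, "voxel_size_um must be > 0")
  if (length(object@nucleusRadiusUm) != 1L || object@nucleusRadiusUm <= 0)
    msg <- c(msg, "nucleus_radius_um must be > 0")
  nmod <- object@noiseModel
  if (is.null(nmod$photon_scale) || nmod$photon_scale <= 0)
    msg <- c(msg, "noise photon_scale must be > 0")
  if (is.null(nmod$background) || nmod$background < 0)
    msg <- c(msg, "noise background must be >= 0")
  if (is.null(nmod$blur_sigma_um) || nmod$blur_sigma_um < 0)
    msg <- c(msg, "noise blur_sigma_um must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct an IsletScenario
#'
#' @param stages named list of stage parameter lists built with
#'   [stageParams()].
#' @param voxelSizeUm isotropic voxel size in micrometres (default 0.5).
#' @param nucleusRadiusUm nuclear radius in micrometres (default 3).
#' @param noiseModel list with `photon_scale`, `background`,
#'   `blur_sigma_um`.
#' @param extras list of auxiliary plant parameters (may be empty).
#' @param seed integer root seed.
#' @return An [IsletScenario-class].
#' @export
IsletScenario <- function(stages, voxelSizeUm = 0.5, nucleusRadiusUm = 3,
                          noiseModel = list(photon_scale = 2, background = 2,
                                            blur_sigma_um = 0.5),
                          extras = list(), seed = 1L) {
  if (is.null(names(stages)))
    names(stages) <- vapply(stages, function(s) s$name, character(1))
  new("IsletScenario", stages = stages, voxelSizeUm = voxelSizeUm,
      nucleusRadiusUm = nucleusRadiusUm, noiseModel = noiseModel,
      extras = extras, seed = as.integer(seed))
}

setMethod("show", "IsletStack", function(object) {
  d <- dim(object@data)
  cat("IsletStack:", d[1L], "channels,",
      paste(d[2:4], collapse = " x "), "(z y x) voxels\n")
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
  cat("  voxel size:", object@voxelSizeUm, "um (isotropic)\n")
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  cat("LabelVolume:", paste(d, collapse = " x "), "(z y x),",
      nCells(object), "labelled cells\n")
})

setMethod("show", "IsletScenario", function(object) {
  cat("IsletScenario:", length(object@stages), "stage(s):",
      paste(names(object@stages), collapse = ", "), "\n")
  cat("  voxel", object@voxelSizeUm, "um, nucleus radius",
      object@nucleusRadiusUm, "um, seed", object@seed, "\n")
})
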