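#' Channel names of an image stack
#' @param x an [IsletStack-class].
#' @return character vector of channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "IsletStack", function(x) x@channelNames)

#' Voxel size in micrometres
#' @param x an [IsletStack-class].
#' @return single numeric, isotropic voxel edge in micrometres.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "IsletStack", function(x) x@voxelSizeUm)

#' Extract one channel as a 3D array
#' @param x an [IsletStack-class].
#' @param channel channel name.
#' @return 3D numeric array (z, y, x).
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' @rdname getChannel
#' @export
setMethod("getChannel", "IsletStack", function(x, channel) {
  i <- match(channel, x@channelNames)
  if (is.na(i))
    stop("channel '", channel, "' not found; available: ",
         paste(x@channelNames, collapse = ", "))
  ch <- x@data[i, , , , drop = FALSE]
  dim(ch) <- dim(x@data)[2:4]
  ch
})

#' Label array of a LabelVolume
#' @param x a [LabelVolume-class].
#' @return 3D integer array (z, y, x), 0 = background.
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))

#' @rdname labelData
#' @export
setMethod("labelData", "LabelVolume", function(x) x@labels)

#' Number of labelled cells
#' @param x a [LabelVolume-class].
#' @return integer count of distinct non-zero labels.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname nCells
#' @export
setMethod("nCells", "LabelVolume", function(x) {
  length(setdiff(unique(as.integer(x@labels)), 0L))
})

#' Cycle-threshold assay matrix
#' @param x a [CtExperiment-class].
#' @return numeric matrix of Ct values (genes x cells).
#' @export
setGeneric("ctValues", function(x) standardGeneric("ctValues"))

#' @rdname ctValues
#' @export
setMethod("ctValues", "CtExperiment", function(x)
  SummarizedExperiment::assay(x, "ct"))

#' Stage labels of an experiment
#' @param x a [CtExperiment-class] or [IsletScenario-class].
#' @return character vector of stage labels.
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))

#' @rdname stages
#' @export
setMethod("stages", "CtExperiment", function(x)
  as.character(SummarizedExperiment::colData(x)$stage))

#' @rdname stages
#' @export
setMethod("stages", "IsletScenario", function(x) names(x@stages))

#' Stage parameter list of a scenario
#' @param x an [IsletScenario-class].
#' @param name stage name.
#' @return the stage parameter list (see [stageParams()]).
#' @export
setGeneric("stageParamsOf", function(x, name) standardGeneric("stageParamsOf"))

#' @rdname stageParamsOf
#' @export
setMethod("stageParamsOf", "IsletScenario", function(x, name) {
  if (!name %in% names(x@stages))
    stop("stage '", name, "' not in scenario; available: ",
         paste(names(x@stages), collapse = ", "))
  x@stages[[name]]
})
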