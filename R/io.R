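# File interchange: image stacks and label volumes as multi-page 16-bit
# TIFF with a JSON sidecar (channel names, axis order CZYX, voxel size);
# tables as plain CSV.

#' Write an IsletStack to a multi-page TIFF
#'
#' Pages are ordered channel-major then z (axis order CZYX), 16-bit
#' unsigned; intensities are rounded to integer counts (values above
#' 65535 are clipped). A JSON sidecar `<path>.json` records channel
#' names, axis order, dimensions and voxel size.
#'
#' @param stack an [IsletStack-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @seealso [readIsletStack()]
#' @export
writeIsletStack <- function(stack, path) {
  stopifnot(is(stack, "IsletStack"))
  d <- dim(stack@data)
  pages <- vector("list", d[1L] * d[2L])
  k <- 1L
  for (ci in seq_len(d[1L])) for (zi in seq_len(d[2L])) {
    m <- stack@data[ci, zi, , ]
    dim(m) <- d[3:4]
    pages[[k]] <- pmin(round(m), 65535) / 65535
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(axis_order = "CZYX", channel_names = stack@channelNames,
         shape = d, voxel_size_um = stack@voxelSizeUm),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an IsletStack written by [writeIsletStack()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must exist).
#' @return an [IsletStack-class].
#' @export
readIsletStack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$shape)
  a <- array(0, dim = d)
  k <- 1L
  for (ci in seq_len(d[1L])) for (zi in seq_len(d[2L])) {
    a[ci, zi, , ] <- round(pages[[k]] * 65535)
    k <- k + 1L
  }
  IsletStack(a, meta$channel_names, meta$voxel_size_um)
}

#' Write a LabelVolume to a multi-page TIFF
#'
#' One 16-bit page per z plane; voxel value = cell id, 0 = background.
#' A JSON sidecar records the dimensions.
#'
#' @param labels a [LabelVolume-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeLabelVolume <- function(labels, path) {
  stopifnot(is(labels, "LabelVolume"))
  lab <- labelData(labels)
  if (max(lab) > 65535) stop("label ids exceed the 16-bit TIFF range")
  d <- dim(lab)
  pages <- lapply(seq_len(d[1L]), function(zi) {
    m <- lab[zi, , ]
    dim(m) <- d[2:3]
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(axis_order = "ZYX", shape = d),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a LabelVolume written by [writeLabelVolume()]
#'
#' @param path TIFF path.
#' @return a [LabelVolume-class].
#' @export
readLabelVolume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$shape)
  lab <- array(0L, dim = d)
  for (zi in seq_len(d[1L]))
    lab[zi, , ] <- as.integer(round(pages[[zi]] * 65535))
  LabelVolume(lab)
}

#' Write a Ct experiment to CSV
#'
#' The Ct matrix goes to `path` (genes in rows, cells in columns) and the
#' per-cell annotation (cell id, stage) to `metaPath`.
#'
#' @param x a [CtExperiment-class].
#' @param path CSV path for the Ct matrix.
#' @param metaPath CSV path for the cell metadata (default:
#'   `<path>` with a `_cells.csv` suffix).
#' @return `path`, invisibly.
#' @export
writeCtTable <- function(x, path,
                         metaPath = sub("\\.csv$", "_cells.csv", path)) {
  stopifnot(is(x, "CtExperiment"))
  write.csv(data.frame(gene = rownames(x), ctValues(x),
                       check.names = FALSE),
            path, row.names = FALSE)
  write.csv(data.frame(cell = colnames(x), stage = stages(x)),
            metaPath, row.names = FALSE)
  invisible(path)
}

#' Read a Ct experiment written by [writeCtTable()]
#'
#' @param path CSV path of the Ct matrix.
#' @param metaPath CSV path of the cell metadata.
#' @return a [CtExperiment-class].
#' @export
readCtTable <- function(path,
                        metaPath = sub("\\.csv$", "_cells.csv", path)) {
  tab <- read.csv(path, check.names = FALSE)
  meta <- read.csv(metaPath)
  ct <- as.matrix(tab[, -1, drop = FALSE])
  rownames(ct) <- tab$gene
  CtExperiment(ct, stage = meta$stage[match(colnames(ct), meta$cell)])
}
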