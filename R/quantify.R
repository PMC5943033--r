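#' Center optical plane of a labelled cell
#'
#' The cell's center plane is the z index whose in-plane voxel count for
#' that label is largest (the optical section containing the largest area
#' of the nucleus); ties are broken towards the smallest z. Indices are
#' 1-based.
#'
#' @param labels a [LabelVolume-class].
#' @param cellId integer cell label.
#' @return integer z index (1-based).
#' @examples
#' lab <- array(0L, c(5, 4, 4)); lab[2:4, 2:3, 2:3] <- 1L
#' findCenterPlane(LabelVolume(lab), 1)
#' @export
findCenterPlane <- function(labels, cellId) {
  stopifnot(is(labels, "LabelVolume"))
  lab <- labelData(labels)
  idx <- which(lab == as.integer(cellId))
  if (!length(idx))
    stop("cell id ", cellId, " not present in the label volume")
  z <- ((idx - 1L) %% dim(lab)[1L]) + 1L
  counts <- tabulate(z, nbins = dim(lab)[1L])
  which.max(counts)  # which.max returns the first (smallest z) maximum
}

# per-cell voxel index table of a label volume
.labelTable <- function(lab) {
  idx <- which(lab != 0L)
  data.table::data.table(
    cell = lab[idx],
    z = ((idx - 1L) %% dim(lab)[1L]) + 1L,
    idx = idx)
}

#' Measure per-cell channel intensities at the center plane
#'
#' For every requested cell, the measurement region of interest (ROI) is
#' the cell's labelled voxels on its center plane (see
#' [findCenterPlane()]); the mean intensity of each requested channel is
#' the arithmetic mean over those pixels. When both the GFP and DAPI
#' channels are measured, the DAPI-normalized GFP intensity
#' `normalized_gfp = mean(GFP) / mean(DAPI)` is added — the per-cell
#' readout of NF-kB reporter activity. An optional in-plane dilation of
#' the nuclear mask is available (`dilatePx`, default 0 = mask-exact).
#'
#' @param stack an [IsletStack-class].
#' @param labels the companion [LabelVolume-class].
#' @param cellIds integer labels to measure (default: all).
#' @param channels channels to measure (default: all in the stack).
#' @param gfpChannel,dapiChannel channel names used for the normalized
#'   GFP ratio; normalization is skipped unless both are measured.
#' @param dilatePx non-negative integer; in-plane disc dilation radius of
#'   the ROI in pixels.
#' @return data.frame with one row per cell: `cell_id`, `center_z`
#'   (1-based), `roi_area_px`, one `mean_<channel>` column per channel,
#'   and `normalized_gfp` when applicable.
#' @seealso [measureCell()], [gfpTotalThreshold()]
#' @export
measureCells <- function(stack, labels, cellIds = NULL,
                         channels = channelNames(stack),
                         gfpChannel = "NFKB_GFP", dapiChannel = "DAPI",
                         dilatePx = 0L) {
  stopifnot(is(stack, "IsletStack"), is(labels, "LabelVolume"))
  bad <- setdiff(channels, channelNames(stack))
  if (length(bad))
    stop("channel(s) not in stack: ", paste(bad, collapse = ", "))
  lab <- labelData(labels)
  if (!identical(dim(lab), dim(stack@data)[2:4]))
    stop("label volume dimensions do not match the stack")
  dt <- .labelTable(lab)
  if (!is.null(cellIds)) {
    missing <- setdiff(as.integer(cellIds), unique(dt$cell))
    if (length(missing))
      stop("cell id(s) not present: ", paste(missing, collapse = ", "))
    dt <- dt[dt$cell %in% as.integer(cellIds), ]
  }
  N <- cell <- z <- val <- NULL  # data.table NSE bindings
  counts <- dt[, list(N = .N), by = list(cell, z)]
  data.table::setorder(counts, cell, -N, z)
  centers <- counts[, list(center_z = z[1L]), by = cell]
  roi <- merge(dt, centers, by.x = c("cell", "z"),
               by.y = c("cell", "center_z"))
  if (dilatePx > 0L) roi <- .dilateRois(roi, lab, dilatePx)
  data.table::setorder(roi, cell)
  out <- roi[, list(center_z = z[1L], roi_area_px = .N), by = cell]
  for (ch in channels) {
    chv <- getChannel(stack, ch)
    roi[, val := chv[idx]]
    m <- roi[, list(m = mean(val)), by = cell]
    out[[paste0("mean_", ch)]] <- m$m[match(out$cell, m$cell)]
  }
  if (all(c(gfpChannel, dapiChannel) %in% channels)) {
    dap <- out[[paste0("mean_", dapiChannel)]]
    if (any(dap == 0))
      stop("mean DAPI intensity is zero for cell(s) ",
           paste(out$cell[dap == 0], collapse = ", "),
           "; normalized GFP is undefined")
    out$normalized_gfp <- out[[paste0("mean_", gfpChannel)]] / dap
  }
  data.table::setnames(out, "cell", "cell_id")
  data.table::setDF(out)
}

# grow each cell's center-plane ROI by an in-plane disc of radius r,
# excluding pixels claimed by other cells on that plane
.dilateRois <- function(roi, lab, r) {
  d <- dim(lab)
  off <- as.matrix(expand.grid(dy = -r:r, dx = -r:r))
  off <- off[rowSums(off^2) <= r^2 + 1e-9, , drop = FALSE]
  pieces <- lapply(split(roi, roi$cell), function(rr) {
    z0 <- rr$z[1L]
    rest <- (rr$idx - 1L) %/% d[1L]
    y <- (rest %% d[2L]) + 1L
    x <- (rest %/% d[2L]) + 1L
    yy <- rep(y, each = nrow(off)) + off[, 1L]
    xx <- rep(x, each = nrow(off)) + off[, 2L]
    ok <- yy >= 1L & yy <= d[2L] & xx >= 1L & xx <= d[3L]
    idx <- z0 + (yy[ok] - 1L) * d[1L] + (xx[ok] - 1L) * d[1L] * d[2L]
    idx <- unique(idx)
    idx <- idx[lab[idx] %in% c(0L, rr$cell[1L])]
    data.table::data.table(cell = rr$cell[1L], z = z0, idx = idx)
  })
  data.table::rbindlist(pieces)
}

#' Measure a single cell
#'
#' Convenience wrapper around [measureCells()] for one cell id.
#'
#' @inheritParams measureCells
#' @param cellId single integer label.
#' @return one-row data.frame (see [measureCells()]).
#' @export
measureCell <- function(stack, labels, cellId,
                        channels = channelNames(stack),
                        gfpChannel = "NFKB_GFP", dapiChannel = "DAPI",
                        dilatePx = 0L) {
  measureCells(stack, labels, cellIds = cellId, channels = channels,
               gfpChannel = gfpChannel, dapiChannel = dapiChannel,
               dilatePx = dilatePx)
}

# 3D distance-to-background estimate: minimum of per-plane 2D Euclidean
# distance maps taken over the three axis orientations (upper bound on the
# true 3D distance, exact for in-plane directions; sufficient for seed
# detection in near-spherical nuclei)
.distance3d <- function(mask) {
  a <- array(as.numeric(mask), dim(mask))
  d1 <- EBImage::distmap(a)
  d2 <- aperm(EBImage::distmap(aperm(a, c(1, 3, 2))), c(1, 3, 2))
  d3 <- aperm(EBImage::distmap(aperm(a, c(2, 3, 1))), c(3, 1, 2))
  pmin(d1, d2, d3)
}

# separable running maximum over a cubic window of half-width h
.boxMax3d <- function(a, h) {
  d <- dim(a)
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1L])
    out <- m
    n <- dp[1L]
    for (off in seq_len(h)) {
      out[seq_len(n - off), ] <- pmax(out[seq_len(n - off), , drop = FALSE],
                                      m[seq_len(n - off) + off, ,
                                        drop = FALSE])
      out[seq_len(n - off) + off, ] <- pmax(out[seq_len(n - off) + off, ,
                                                drop = FALSE],
                                            m[seq_len(n - off), ,
                                              drop = FALSE])
    }
    dim(out) <- dp
    a <- aperm(out, order(perm))
  }
  a
}

#' Fallback nuclei segmentation from the DAPI channel
#'
#' Used when no ground-truth label volume accompanies a stack: global
#' Otsu thresholding of the DAPI volume, then splitting of touching
#' nuclei by a distance-transform watershed in seeded form — local maxima
#' of the 3D distance-to-background map (at least a nuclear radius apart)
#' seed the nuclei, and every foreground voxel is assigned to its nearest
#' seed. Objects smaller than a minimum volume are dropped and labels are
#' renumbered consecutively from 1. When ground-truth labels exist
#' (synthetic data) they should be used directly; segmentation quality is
#' benchmarked, not assumed.
#'
#' @param dapi 3D numeric array (z, y, x) of DAPI intensities.
#' @param voxelSizeUm isotropic voxel size in micrometres.
#' @param minVolumeUm3 minimum object volume kept, cubic micrometres
#'   (default 40, about a third of a 3-um-radius nucleus).
#' @param nucleusRadiusUm expected nuclear radius, micrometres; sets the
#'   seed exclusion distance and the minimum seed depth.
#' @return a [LabelVolume-class]; an all-background input yields zero
#'   labels with a warning.
#' @export
segmentNuclei <- function(dapi, voxelSizeUm, minVolumeUm3 = 40,
                          nucleusRadiusUm = 3) {
  stopifnot(length(dim(dapi)) == 3L)
  empty <- function(msg) {
    warning(msg)
    LabelVolume(array(0L, dim(dapi)))
  }
  if (diff(range(dapi)) == 0)
    return(empty("constant DAPI volume: no foreground found, returning empty labelling"))
  th <- otsuThreshold(as.numeric(dapi))
  mask <- dapi > th
  if (!any(mask))
    return(empty("no foreground above the Otsu threshold, returning empty labelling"))
  rVox <- nucleusRadiusUm / voxelSizeUm
  dm <- .distance3d(mask)
  h <- max(1L, as.integer(round(0.7 * rVox)))
  isPeak <- mask & dm >= pmax(2, 0.4 * rVox) & dm == .boxMax3d(dm, h)
  peakIdx <- which(isPeak)
  if (!length(peakIdx))
    return(empty("no distance-map seeds found, returning empty labelling"))
  d <- dim(dapi)
  pz <- ((peakIdx - 1L) %% d[1L]) + 1L
  rest <- (peakIdx - 1L) %/% d[1L]
  py <- (rest %% d[2L]) + 1L
  px <- (rest %/% d[2L]) + 1L
  ord <- order(dm[peakIdx], decreasing = TRUE)
  seeds <- matrix(numeric(0), ncol = 3)
  minSep2 <- rVox^2
  for (k in ord) {
    p <- c(pz[k], py[k], px[k])
    if (nrow(seeds)) {
      d2 <- (seeds[, 1] - p[1])^2 + (seeds[, 2] - p[2])^2 +
        (seeds[, 3] - p[3])^2
      if (min(d2) < minSep2) next
    }
    seeds <- rbind(seeds, p)
  }
  fg <- which(mask)
  fz <- ((fg - 1L) %% d[1L]) + 1L
  rest <- (fg - 1L) %/% d[1L]
  fy <- (rest %% d[2L]) + 1L
  fx <- (rest %/% d[2L]) + 1L
  assign <- integer(length(fg))
  best <- rep(Inf, length(fg))
  for (s in seq_len(nrow(seeds))) {
    d2 <- (fz - seeds[s, 1])^2 + (fy - seeds[s, 2])^2 +
      (fx - seeds[s, 3])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    assign[upd] <- s
  }
  lab <- array(0L, d)
  lab[fg] <- assign
  minVox <- max(1L, as.integer(round(minVolumeUm3 / voxelSizeUm^3)))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minVox)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  LabelVolume(lab)
}

#' Volume-normalized GFP density of an islet region
#'
#' Reports the mean GFP intensity within a mask divided by the mask
#' volume in cubic micrometres — the volume-normalized readout used for
#' secondary islets, where individual nuclei are not resolved.
#'
#' @param stack an [IsletStack-class].
#' @param mask 3D logical array matching the stack's spatial dimensions.
#' @param channel GFP channel name.
#' @return list with `density` (mean intensity per um^3),
#'   `mean_intensity` and `volume_um3`.
#' @export
isletGfpDensity <- function(stack, mask, channel = "NFKB_GFP") {
  stopifnot(is(stack, "IsletStack"))
  if (!identical(dim(mask), dim(stack@data)[2:4]))
    stop("mask dimensions do not match the stack")
  nVox <- sum(mask)
  if (nVox == 0) stop("empty mask: GFP density is undefined")
  mi <- mean(getChannel(stack, channel)[mask])
  vol <- nVox * voxelSize(stack)^3
  list(density = mi / vol, mean_intensity = mi, volume_um3 = vol)
}

#' Match two label volumes by intersection-over-union
#'
#' Greedy 1:1 matching of reference labels (e.g. planted ground truth) to
#' test labels (e.g. a segmentation), by decreasing IoU. Used to
#' benchmark [segmentNuclei()] against synthetic ground truth.
#'
#' @param reference,test [LabelVolume-class] objects of equal dimensions.
#' @return data.frame with one row per reference label: `ref`, `test`
#'   (matched test label or `NA`) and `iou`.
#' @export
labelMatchIoU <- function(reference, test) {
  a <- labelData(reference); b <- labelData(test)
  stopifnot(identical(dim(a), dim(b)))
  idx <- which(a != 0L | b != 0L)
  dt <- data.table::data.table(a = a[idx], b = b[idx])
  na <- dt[dt$a != 0L, list(na = .N), by = "a"]
  nb <- dt[dt$b != 0L, list(nb = .N), by = "b"]
  inter <- dt[dt$a != 0L & dt$b != 0L, list(n = .N), by = c("a", "b")]
  inter <- merge(inter, na, by = "a")
  inter <- merge(inter, nb, by = "b")
  inter$iou <- inter$n / (inter$na + inter$nb - inter$n)
  data.table::setorder(inter, -iou)
  usedB <- integer(0)
  out <- data.frame(ref = na$a, test = NA_integer_, iou = 0)
  for (k in seq_len(nrow(inter))) {
    i <- match(inter$a[k], out$ref)
    if (!is.na(out$test[i]) || inter$b[k] %in% usedB) next
    out$test[i] <- inter$b[k]
    out$iou[i] <- inter$iou[k]
    usedB <- c(usedB, inter$b[k])
  }
  out[order(out$ref), ]
}
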