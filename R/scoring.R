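#' Per-islet GFP classification threshold (GFP-total)
#'
#' The GFP-total threshold of an islet is the average DAPI-normalized GFP
#' intensity of all its measured cells. By default cells are pooled
#' across all optical sections of the islet (the cell-pooled mean is
#' independent of how cells distribute over sections); `mode =
#' "section_mean"` instead averages per-section means, for workflows that
#' weight sections equally.
#'
#' @param measurements data.frame of per-cell measurements with a
#'   `normalized_gfp` column (and `center_z` for `"section_mean"`).
#' @param mode `"pooled"` (default) or `"section_mean"`.
#' @return single numeric threshold.
#' @seealso [classifyHighLow()]
#' @export
gfpTotalThreshold <- function(measurements, mode = c("pooled",
                                                     "section_mean")) {
  mode <- match.arg(mode)
  v <- measurements$normalized_gfp
  if (is.null(v) || !length(v))
    stop("no cells with normalized_gfp: GFP-total is undefined")
  if (mode == "pooled") return(mean(v))
  secs <- split(v, measurements$center_z)
  mean(vapply(secs, mean, numeric(1)))
}

#' Classify cells into GFP-high and GFP-low
#'
#' Cells with normalized GFP strictly above the threshold are `"high"`,
#' all others `"low"` (ties go to low, so the two classes always
#' partition the islet).
#'
#' @param measurements data.frame with a `normalized_gfp` column.
#' @param threshold finite numeric threshold (typically
#'   [gfpTotalThreshold()]).
#' @return `measurements` with a `gfp_class` factor column
#'   (levels `low`, `high`) appended.
#' @export
classifyHighLow <- function(measurements, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  measurements$gfp_class <- factor(
    ifelse(measurements$normalized_gfp > threshold, "high", "low"),
    levels = c("low", "high"))
  measurements
}

#' Proliferation-marker positivity per cell
#'
#' Thresholds the per-cell mean intensity of a proliferation marker
#' channel (EdU or PCNA). `method = "otsu"` derives the threshold from
#' the distribution of per-cell means; `method = "fixed"` uses the given
#' value. A cell is positive iff its mean is strictly greater than the
#' threshold.
#'
#' @param measurements data.frame of per-cell measurements.
#' @param markerChannel channel name, e.g. `"EDU"`; the column
#'   `mean_<markerChannel>` must exist.
#' @param method `"otsu"` or `"fixed"`.
#' @param value fixed threshold (required for `method = "fixed"`).
#' @return logical vector of per-cell positivity, with the threshold used
#'   in attribute `"threshold"`.
#' @export
markerPositive <- function(measurements, markerChannel,
                           method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  col <- paste0("mean_", markerChannel)
  if (!col %in% colnames(measurements))
    stop("marker channel '", markerChannel, "' was not measured (missing ",
         col, ")")
  v <- measurements[[col]]
  if (anyNA(v)) stop("marker means contain NA")
  th <- if (method == "fixed") {
    if (is.null(value)) stop("method = 'fixed' requires a threshold value")
    value
  } else {
    otsuThreshold(v)
  }
  structure(v > th, threshold = th)
}

#' FUCCI proliferation percentage
#'
#' Percentage of proliferating beta-cells under the FUCCI reporter pair:
#' cells positive for the S/G2/M (green) reporter and negative for the
#' G0/G1 (red) reporter, over all beta-cells, times 100. Cells positive
#' for both reporters are not counted as proliferating.
#'
#' @param cells data.frame with logical columns `fucci_green` and
#'   `fucci_red`.
#' @return percentage in \[0, 100\].
#' @examples
#' cells <- data.frame(fucci_green = c(TRUE, TRUE, FALSE),
#'                     fucci_red = c(FALSE, TRUE, TRUE))
#' fucciProliferationPercentage(cells)  # 1 of 3 green-only
#' @export
fucciProliferationPercentage <- function(cells) {
  if (!nrow(cells)) stop("no cells: proliferation percentage is undefined")
  stopifnot(all(c("fucci_green", "fucci_red") %in% colnames(cells)))
  if (anyNA(cells$fucci_green) || anyNA(cells$fucci_red))
    stop("FUCCI flags must be defined for every cell")
  100 * sum(cells$fucci_green & !cells$fucci_red) / nrow(cells)
}

#' Mosaic proliferation percentages by CFP class
#'
#' Proliferation percentage (FUCCI green-only over class total) computed
#' separately for CFP-positive and CFP-negative beta-cells of a mosaic
#' islet. An empty class yields `NA` for its percentage together with an
#' explicit `undefined` flag (never silently 0).
#'
#' @param cells data.frame with logical columns `cfp_pos`, `fucci_green`,
#'   `fucci_red`.
#' @return list with `pct_cfp_pos`, `pct_cfp_neg`, `n_cfp_pos`,
#'   `n_cfp_neg`, `undefined` (character vector naming any empty class).
#' @export
mosaicProliferationPercentages <- function(cells) {
  stopifnot(all(c("cfp_pos", "fucci_green", "fucci_red") %in%
                  colnames(cells)))
  prolif <- cells$fucci_green & !cells$fucci_red
  pos <- cells$cfp_pos
  undefined <- character(0)
  pctPos <- if (any(pos)) 100 * sum(prolif[pos]) / sum(pos) else {
    undefined <- c(undefined, "cfp_pos"); NA_real_
  }
  pctNeg <- if (any(!pos)) 100 * sum(prolif[!pos]) / sum(!pos) else {
    undefined <- c(undefined, "cfp_neg"); NA_real_
  }
  list(pct_cfp_pos = pctPos, pct_cfp_neg = pctNeg,
       n_cfp_pos = sum(pos), n_cfp_neg = sum(!pos), undefined = undefined)
}

#' Paired comparison of marker positivity between GFP classes
#'
#' Two-tailed paired t-test across islets, each islet contributing one
#' GFP-high and one GFP-low marker-positive percentage. Islets with a
#' missing class percentage (`NA`) are excluded and counted. Degenerate
#' cases are flagged instead of silently returning `NaN`: if every
#' within-islet difference is zero the comparison is reported with
#' `p = 1`; if the differences are constant but non-zero the t statistic
#' is undefined and `p = NA` with flag `"zero_variance"`.
#'
#' @param perIslet data.frame with numeric columns `pct_marker_pos_high`
#'   and `pct_marker_pos_low`, one row per islet.
#' @return list with `mean_high`, `mean_low`, `mean_difference`,
#'   `p_value`, `n_islets_used`, `n_islets_excluded`, `flag`.
#' @export
classMarkerComparison <- function(perIslet) {
  stopifnot(all(c("pct_marker_pos_high", "pct_marker_pos_low") %in%
                  colnames(perIslet)))
  ok <- stats::complete.cases(perIslet[, c("pct_marker_pos_high",
                                           "pct_marker_pos_low")])
  excluded <- sum(!ok)
  hi <- perIslet$pct_marker_pos_high[ok]
  lo <- perIslet$pct_marker_pos_low[ok]
  if (length(hi) < 2L)
    stop("paired comparison needs at least 2 islets with both classes ",
         "defined (got ", length(hi), ")")
  d <- hi - lo
  flag <- "ok"
  if (sd(d) == 0) {
    if (all(d == 0)) {
      p <- 1; flag <- "identical"
    } else {
      p <- NA_real_; flag <- "zero_variance"
    }
  } else {
    p <- t.test(hi, lo, paired = TRUE)$p.value
  }
  list(mean_high = mean(hi), mean_low = mean(lo),
       mean_difference = mean(d), p_value = p,
       n_islets_used = length(hi), n_islets_excluded = excluded,
       flag = flag)
}

#' One-way ANOVA of per-islet percentages across stages
#'
#' One-way analysis of variance of per-islet proliferation (or
#' positivity) percentages grouped by stage. If every value is identical
#' the F statistic is undefined; by convention the result is reported as
#' `F = 0`, `p = 1` with flag `"constant"`.
#'
#' @param pct numeric vector of per-islet percentages.
#' @param stage grouping factor/character of the same length.
#' @return list with `F`, `p_value`, `df_between`, `df_within`, `flag`.
#' @export
stageComparisonAnova <- function(pct, stage) {
  stage <- factor(stage)
  if (nlevels(stage) < 2L)
    stop("ANOVA needs at least 2 stages (got ", nlevels(stage), ")")
  if (length(pct) - nlevels(stage) < 1L)
    stop("ANOVA needs at least one stage with >= 2 islets")
  if (sd(pct) == 0)
    return(list(F = 0, p_value = 1, df_between = nlevels(stage) - 1L,
                df_within = length(pct) - nlevels(stage),
                flag = "constant"))
  fit <- aov(pct ~ stage)
  s <- summary(fit)[[1L]]
  list(F = s[["F value"]][1L], p_value = s[["Pr(>F)"]][1L],
       df_between = s[["Df"]][1L], df_within = s[["Df"]][2L], flag = "ok")
}

#' Score one islet's cell records into an islet summary
#'
#' Computes the islet-level summary used throughout the pipeline: the
#' GFP-total threshold and high/low split, the FUCCI proliferation
#' percentage, the marker-positive percentage within each GFP class, and
#' (for mosaic islets) the CFP class percentages.
#'
#' @param cells data.frame of per-cell records; must have
#'   `normalized_gfp` plus logical `fucci_green`/`fucci_red` and
#'   optionally `marker_pos` and `cfp_pos` columns.
#' @param isletId,stage identifiers copied into the summary.
#' @return one-row data.frame (`islet_id`, `stage`, `n_cells`,
#'   `gfp_total`, `n_gfp_high`, `n_gfp_low`, `pct_proliferating`,
#'   `pct_marker_pos_high`, `pct_marker_pos_low`,
#'   `pct_cfp_pos_proliferating`, `pct_cfp_neg_proliferating`).
#' @export
scoreIslet <- function(cells, isletId = "islet", stage = NA_character_) {
  if (!nrow(cells)) stop("no cells to score for islet ", isletId)
  hasGfp <- "normalized_gfp" %in% colnames(cells) &&
    !anyNA(cells$normalized_gfp)
  gfpTotal <- NA_real_; nHigh <- NA_integer_; nLow <- NA_integer_
  pctHi <- NA_real_; pctLo <- NA_real_
  if (hasGfp) {
    gfpTotal <- gfpTotalThreshold(cells)
    cells <- classifyHighLow(cells, gfpTotal)
    nHigh <- sum(cells$gfp_class == "high")
    nLow <- sum(cells$gfp_class == "low")
    if ("marker_pos" %in% colnames(cells)) {
      pctHi <- if (nHigh > 0)
        100 * sum(cells$marker_pos[cells$gfp_class == "high"]) / nHigh
        else NA_real_
      pctLo <- if (nLow > 0)
        100 * sum(cells$marker_pos[cells$gfp_class == "low"]) / nLow
        else NA_real_
    }
  }
  pctProlif <- if (all(c("fucci_green", "fucci_red") %in% colnames(cells)))
    fucciProliferationPercentage(cells) else NA_real_
  cfpPos <- cfpNeg <- NA_real_
  if ("cfp_pos" %in% colnames(cells)) {
    mp <- mosaicProliferationPercentages(cells)
    cfpPos <- mp$pct_cfp_pos; cfpNeg <- mp$pct_cfp_neg
  }
  data.frame(islet_id = isletId, stage = stage, n_cells = nrow(cells),
             gfp_total = gfpTotal, n_gfp_high = nHigh, n_gfp_low = nLow,
             pct_proliferating = pctProlif,
             pct_marker_pos_high = pctHi, pct_marker_pos_low = pctLo,
             pct_cfp_pos_proliferating = cfpPos,
             pct_cfp_neg_proliferating = cfpNeg)
}
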