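#' Remove cells failing housekeeping-gene detection
#'
#' Pre-analysis cleanup of a single-cell Ct table: every cell with an
#' undetected value (Ct = 40) for any of the housekeeping genes is
#' removed; the removal count is reported as a message and in the
#' `housekeeping_removed` metadata entry.
#'
#' @param x a [CtExperiment-class].
#' @param housekeeping character vector of housekeeping gene names
#'   (default: b-actin1, ef1a and rpl13a as `c("bact1", "ef1a",
#'   "rpl13a")`).
#' @return the filtered [CtExperiment-class].
#' @export
housekeepingFilter <- function(x, housekeeping = c("bact1", "ef1a",
                                                   "rpl13a")) {
  stopifnot(is(x, "CtExperiment"))
  missing <- setdiff(housekeeping, rownames(x))
  if (length(missing))
    stop("housekeeping gene(s) absent from the Ct matrix: ",
         paste(missing, collapse = ", "))
  ct <- ctValues(x)
  fail <- colSums(ct[housekeeping, , drop = FALSE] == 40) > 0
  message(sum(fail), " of ", ncol(x),
          " cells removed by the housekeeping filter")
  out <- x[, !fail]
  S4Vectors::metadata(out)$housekeeping_removed <- sum(fail)
  out
}

#' Detection fraction of a gene within a stage
#'
#' A gene is "detected" in a cell iff its Ct is strictly below the
#' 40-cycle censoring sentinel. The percentage of cells in the given
#' stage with detectable expression is `100 * n_detected / n_cells`.
#'
#' @param x a [CtExperiment-class].
#' @param gene gene name.
#' @param stage stage label to restrict to.
#' @return one-row data.frame: `gene`, `stage`, `n_cells`, `n_detected`,
#'   `pct_detected`.
#' @export
detectionFraction <- function(x, gene, stage) {
  stopifnot(is(x, "CtExperiment"))
  if (!gene %in% rownames(x)) stop("gene '", gene, "' not in the Ct matrix")
  sel <- stages(x) == stage
  if (!any(sel)) stop("no cells with stage '", stage, "'")
  ct <- ctValues(x)[gene, sel]
  nDet <- sum(ct < 40)
  data.frame(gene = gene, stage = stage, n_cells = length(ct),
             n_detected = nDet, pct_detected = 100 * nDet / length(ct))
}

#' Pearson chi-square comparison of two detection fractions
#'
#' Pearson's chi-square test (no continuity correction, 1 df) on the 2x2
#' table of detected / not-detected counts for the same gene in two
#' stages.
#'
#' @param summaryA,summaryB one-row data.frames from
#'   [detectionFraction()] for the same gene.
#' @return list with `chi2`, `p_value`, `df`.
#' @export
chiSquareDetection <- function(summaryA, summaryB) {
  if (summaryA$gene != summaryB$gene)
    stop("detection summaries are for different genes: ", summaryA$gene,
         " vs ", summaryB$gene)
  if (summaryA$n_cells == 0 || summaryB$n_cells == 0)
    stop("both stages need at least one cell")
  tab <- rbind(c(summaryA$n_detected, summaryA$n_cells -
                   summaryA$n_detected),
               c(summaryB$n_detected, summaryB$n_cells -
                   summaryB$n_detected))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("chi-square test undefined: an expected count is zero ",
         "(all cells detected, or none, in both stages)")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' -log10 representation of Ct values
#'
#' Maps each Ct value v to -log10(v), the representation scale on which
#' violin plots of single-cell expression are drawn: lower Ct (more
#' transcript) maps higher, and the Ct = 40 censoring sentinel maps to
#' -log10(40) = -1.602, the "undetectable" floor (about -1.6).
#'
#' @param ct numeric vector of Ct values in (0, 40].
#' @return numeric vector of -log10(Ct) values.
#' @examples
#' negLog10Ct(c(10, 40))  # -1, -1.602
#' @export
negLog10Ct <- function(ct) {
  if (any(ct <= 0)) stop("Ct values must be > 0")
  if (any(ct > 40)) stop("Ct values above the 40-cycle sentinel are invalid")
  -log10(ct)
}

#' Delta-delta-Ct fold change between two groups
#'
#' Standard 2^(-ddCt) relative quantification: per replicate, the gene's
#' Ct is normalized to the reference (housekeeping) gene within each
#' group (dCt = Ct_gene - Ct_ref), the group difference ddCt = dCt_A -
#' dCt_B is formed, and the fold change of group A relative to group B is
#' `2^(-mean(ddCt))`. A two-tailed paired t-test of the per-replicate
#' ddCt values against 0 gives the p-value. Because each replicate's
#' reference measurement absorbs plate-wide shifts, the estimator is
#' invariant to adding a constant to all Ct values of a replicate.
#'
#' @param bulk data.frame with columns `replicate`, `group`, `gene`,
#'   `ct` (as produced by [simulateBulkQpcr()]).
#' @param gene gene of interest.
#' @param referenceGene housekeeping reference gene.
#' @param groupA,groupB group labels; the fold change is A relative to B.
#' @return list with `gene`, `fold_change`, `per_replicate_ddct`,
#'   `p_value`, `flag`.
#' @export
deltaCtFoldChange <- function(bulk, gene, referenceGene, groupA = "high",
                              groupB = "low") {
  need <- c("replicate", "group", "gene", "ct")
  stopifnot(all(need %in% colnames(bulk)))
  getCt <- function(g, grp) {
    sub <- bulk[bulk$gene == g & bulk$group == grp, ]
    sub$ct[match(reps, sub$replicate)]
  }
  reps <- sort(unique(bulk$replicate))
  ctA <- getCt(gene, groupA); ctRefA <- getCt(referenceGene, groupA)
  ctB <- getCt(gene, groupB); ctRefB <- getCt(referenceGene, groupB)
  if (anyNA(c(ctA, ctRefA, ctB, ctRefB)))
    stop("missing replicate pairing: gene '", gene, "' and reference '",
         referenceGene, "' must be measured in both groups for every ",
         "replicate")
  ddct <- (ctA - ctRefA) - (ctB - ctRefB)
  flag <- "ok"
  p <- if (sd(ddct) == 0) {
    if (all(ddct == 0)) { flag <- "identical"; 1 }
    else { flag <- "zero_variance"; NA_real_ }
  } else t.test(ddct, mu = 0)$p.value
  list(gene = gene, fold_change = 2^(-mean(ddct)),
       per_replicate_ddct = ddct, p_value = p, flag = flag)
}

#' Squared correlation of fluorescence with expression level
#'
#' Squared Pearson correlation between per-cell fluorescence intensity
#' and transcript expression, with expression taken on the -log10(Ct)
#' representation scale by default; cells censored at Ct = 40 are
#' excluded by default (set `dropCensored = FALSE` to keep them at the
#' -1.6 floor).
#'
#' @param fluorescence numeric vector of per-cell intensities.
#' @param ct numeric vector of matching Ct values in (0, 40].
#' @param scale `"neglog10"` (default) or `"ct"` (raw Ct).
#' @param dropCensored drop cells with Ct = 40 before correlating.
#' @return squared Pearson correlation in \[0, 1\].
#' @export
intensityExpressionR2 <- function(fluorescence, ct,
                                  scale = c("neglog10", "ct"),
                                  dropCensored = TRUE) {
  scale <- match.arg(scale)
  stopifnot(length(fluorescence) == length(ct))
  if (dropCensored) {
    keep <- ct < 40
    fluorescence <- fluorescence[keep]
    ct <- ct[keep]
  }
  if (length(ct) < 3L)
    stop("at least 3 uncensored pairs are required")
  expr <- if (scale == "neglog10") negLog10Ct(ct) else ct
  if (sd(fluorescence) == 0 || sd(expr) == 0)
    stop("zero variance: correlation is undefined")
  cor(fluorescence, expr)^2
}
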