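#' Simulate a censored single-cell RT-qPCR Ct table
#'
#' For each (gene, cell) pair the transcript is detected with the stage's
#' planted `detection_prob[gene]`; detected measurements draw
#' Ct ~ Normal(`ct_mean`, `ct_sd`) truncated to (0, 40), undetected ones
#' are censored at exactly Ct = 40 (the assay's 40-cycle sentinel).
#'
#' @param stage stage parameter list with a `detection_prob` entry for
#'   every requested gene.
#' @param genes character vector of genes to simulate.
#' @param nCells number of cells.
#' @param seed integer seed.
#' @return a [CtExperiment-class] with the stage label on every cell and a
#'   logical `detected` ground-truth matrix in
#'   `S4Vectors::metadata(x)$detected_true`.
#' @examples
#' st <- stageParams("3mpf", detection_prob = list(ins = 0.9, tnfa = 0.2))
#' simulateCtTable(st, c("ins", "tnfa"), nCells = 50, seed = 1)
#' @export
simulateCtTable <- function(stage, genes, nCells, seed = 1L) {
  dp <- unlist(stage$detection_prob)
  missing <- setdiff(genes, names(dp))
  if (length(missing))
    stop("no detection_prob for gene(s): ", paste(missing, collapse = ", "))
  withSeed(seed, function() {
    ct <- matrix(40, nrow = length(genes), ncol = nCells,
                 dimnames = list(genes, paste0(stage$name, "_cell",
                                               seq_len(nCells))))
    det <- matrix(FALSE, nrow = length(genes), ncol = nCells,
                  dimnames = dimnames(ct))
    for (g in genes) {
      hit <- runif(nCells) < dp[[g]]
      det[g, ] <- hit
      if (any(hit))
        ct[g, hit] <- rtruncnorm(sum(hit), stage$ct_mean, stage$ct_sd,
                                 lo = .Machine$double.eps, hi = 40 - 1e-9)
    }
    x <- CtExperiment(ct, stage = rep(stage$name, nCells))
    S4Vectors::metadata(x)$detected_true <- det
    x
  })
}

#' Simulate bulk RT-qPCR replicates for two sorted populations
#'
#' Generates paired replicate Ct values for groups `"high"` and `"low"`
#' (e.g. NF-kB reporter GFP-high vs GFP-low sorted beta-cells) such that
#' the expected delta-delta-Ct of every gene equals
#' `-log2(fold_changes[gene])`, i.e. the planted fold change is recovered
#' in expectation by the 2^(-ddCt) estimator. Per-measurement Gaussian
#' noise of `noiseSd` cycles is added, plus a shared per-replicate plate
#' shift (absorbed by the reference gene).
#'
#' @param foldChanges named numeric vector/list of planted fold changes
#'   (group high relative to group low); the reference gene must be 1.
#' @param referenceGene housekeeping reference gene name.
#' @param nReplicates number of paired biological replicates.
#' @param seed integer seed.
#' @param noiseSd per-measurement Ct noise, cycles (0 = noise-free).
#' @param baseCt nominal Ct of every gene in the reference group.
#' @param groups length-2 character: the enriched group first, then the
#'   reference group (defaults to sorted populations `"high"`, `"low"`;
#'   use stage labels to compare stages instead).
#' @return data.frame with columns `replicate`, `group`, `gene`, `ct`.
#' @examples
#' simulateBulkQpcr(c(bact2 = 1, socs2 = 2.5), "bact2", nReplicates = 4,
#'                  seed = 1)
#' @export
simulateBulkQpcr <- function(foldChanges, referenceGene, nReplicates = 4L,
                             seed = 1L, noiseSd = 0.2, baseCt = 22,
                             groups = c("high", "low")) {
  fc <- unlist(foldChanges)
  if (any(fc <= 0)) stop("fold changes must be positive")
  if (!referenceGene %in% names(fc) || fc[[referenceGene]] != 1)
    stop("reference gene '", referenceGene,
         "' must be present with fold change 1")
  withSeed(seed, function() {
    genes <- names(fc)
    stopifnot(length(groups) == 2L)
    rows <- expand.grid(replicate = seq_len(nReplicates),
                        group = groups, gene = genes,
                        stringsAsFactors = FALSE)
    plateShift <- rnorm(nReplicates, 0, noiseSd)  # shared per replicate
    dCt <- ifelse(rows$group == groups[1L], -log2(fc[rows$gene]), 0)
    rows$ct <- baseCt + dCt + plateShift[rows$replicate] +
      rnorm(nrow(rows), 0, noiseSd)
    rows[order(rows$gene, rows$group, rows$replicate), ]
  })
}

#' Simulate index-sorted cells pairing fluorescence with transcript Ct
#'
#' Emulates index sorting, where the cytometer records each sorted cell's
#' GFP fluorescence and the same cell is then profiled by single-cell
#' RT-qPCR for the GFP transcript. A latent linear relation on the
#' -log10(Ct) expression scale is noised so that the population squared
#' Pearson correlation equals `targetR2` exactly in expectation
#' (`targetR2 = 1` gives zero noise, hence sample R^2 of exactly 1;
#' `targetR2 = 0` gives expression independent of fluorescence).
#'
#' @param nCells number of cells.
#' @param targetR2 planted population R^2 in \[0, 1\].
#' @param seed integer seed.
#' @return data.frame with columns `gfp_fluorescence` (a.u.) and `gfp_ct`
#'   (cycles, uncensored).
#' @examples
#' head(simulateIndexedCells(100, targetR2 = 0.28, seed = 1))
#' @export
simulateIndexedCells <- function(nCells, targetR2, seed = 1L) {
  if (targetR2 < 0 || targetR2 > 1) stop("targetR2 must lie in [0, 1]")
  withSeed(seed, function() {
    z <- rnorm(nCells)
    expr <- sqrt(targetR2) * z + sqrt(1 - targetR2) * rnorm(nCells)
    # fluorescence linear in the latent; expression mapped to Ct through the
    # -log10 representation scale, kept well inside (0, 40)
    fluor <- 1000 + 150 * z
    negLog10 <- -1.38 + 0.03 * expr
    data.frame(gfp_fluorescence = fluor, gfp_ct = 10^(-negLog10))
  })
}
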