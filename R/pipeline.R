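#' @importFrom utils packageVersion write.csv read.csv
NULL

.presets <- c("aging_decline", "nfkb_edu", "nfkb_pcna", "mosaic_socs2",
              "tnfrsf1b_injection", "tnfa_macrophage", "qpcr_detection",
              "bulk_foldchange", "gfp_transcript", "facs_split",
              "indexed_correlation")

.configDefaults <- function() {
  list(preset = NULL, seed = 1L, scenario = NULL, render = FALSE,
       n_qpcr_cells = 60L, n_facs_events = 10000L,
       thresholds = list(marker_method = "fixed", marker_value = 30,
                         fucci_value = 30,
                         gfp_positive_value = NULL,
                         facs_method = "valley", facs_value = NULL),
       out_dir = NULL, log_level = "info")
}

#' Validate and normalize a run configuration
#'
#' Accepts a YAML file path or a list; checks it against the known keys,
#' fills defaults, loads the scenario (the packaged paper-calibrated
#' scenario when none is given), and rejects unknown keys by name.
#'
#' @param config path to a YAML config file, or a named list.
#' @return validated config list of class `isletRunConfig` (with the
#'   [IsletScenario-class] attached under `$scenario_obj`).
#' @seealso [runExperiment()]
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  def <- .configDefaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(config$thresholds)) {
    unknownTh <- setdiff(names(config$thresholds), names(def$thresholds))
    if (length(unknownTh))
      stop("unknown thresholds key(s): ", paste(unknownTh, collapse = ", "))
    def$thresholds[names(config$thresholds)] <- config$thresholds
    config$thresholds <- NULL
  }
  def[names(config)] <- config
  cfg <- def
  if (is.null(cfg$preset) || !cfg$preset %in% .presets)
    stop("preset must be one of: ", paste(.presets, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$seed)) stop("seed must be an integer")
  cfg$scenario_obj <- if (is.null(cfg$scenario)) paperCalibratedScenario()
                      else readScenario(cfg$scenario)
  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  class(cfg) <- "isletRunConfig"
  cfg
}

# Per-cell records for scoring, from either route: measured image stacks
# (quantify + threshold the FUCCI / marker / CFP channels) or the
# generator's ground-truth tables (fast path when no stack was rendered).
.cellsFromIslet <- function(sim, thresholds) {
  if (!is.null(sim$stack)) {
    m <- measureCells(sim$stack, sim$labels)
    fv <- thresholds$fucci_value
    if ("mean_FUCCI_G" %in% colnames(m)) m$fucci_green <- m$mean_FUCCI_G > fv
    if ("mean_FUCCI_R" %in% colnames(m)) m$fucci_red <- m$mean_FUCCI_R > fv
    if ("mean_CFP" %in% colnames(m)) m$cfp_pos <- m$mean_CFP > fv
    if ("mean_EDU" %in% colnames(m)) {
      m$marker_pos <- if (identical(thresholds$marker_method, "otsu"))
        as.logical(markerPositive(m, "EDU", method = "otsu"))
        else as.logical(markerPositive(m, "EDU", method = "fixed",
                                       value = thresholds$marker_value))
    }
    m
  } else {
    tr <- sim$truth
    data.frame(cell_id = tr$cell_id, normalized_gfp = tr$normalized_gfp,
               fucci_green = tr$fucci_green_true,
               fucci_red = tr$fucci_red_true, cfp_pos = tr$cfp_true,
               marker_pos = tr$edu_true)
  }
}

.scoreCohort <- function(cohort, thresholds) {
  do.call(rbind, lapply(cohort, function(sim) {
    cells <- .cellsFromIslet(sim, thresholds)
    scoreIslet(cells, isletId = sim$islet_id, stage = sim$stage)
  }))
}

#' Run a packaged experiment preset end to end
#'
#' Executes simulate -> quantify -> score -> statistics for one of the
#' packaged experiment presets, each reproducing one figure-level
#' analysis of the study on synthetic cohorts:
#' `aging_decline` (FUCCI proliferation across 35 dpf / 3 mpf / 1 ypf,
#' one-way ANOVA), `nfkb_edu` / `nfkb_pcna` (marker positivity in
#' GFP-high vs GFP-low cells, paired t-test), `mosaic_socs2` (CFP+
#' vs CFP- proliferation, paired t-test), `tnfrsf1b_injection`
#' (reporter-positive fraction, injected vs control larvae),
#' `tnfa_macrophage` (tnfa-reporter-positive intra-islet leukocytes),
#' `qpcr_detection` (censored detection fractions with chi-square
#' stage comparisons), `bulk_foldchange` and `gfp_transcript`
#' (delta-delta-Ct fold changes), `facs_split` (KDE-valley population
#' split) and `indexed_correlation` (fluorescence-expression R^2).
#'
#' @param config an `isletRunConfig` from [validateConfig()], a config
#'   list/path, or `NULL` to build one from `preset` and `seed`.
#' @param preset,seed convenience shortcuts used when `config` is `NULL`.
#' @return a `RunReport` list: `preset`, `seed`, `summaries` (per-islet
#'   or per-unit data.frame), `stats` (test results), `provenance`
#'   (config hash, package version, R version). Written to
#'   `config$out_dir` as CSV + JSON when set.
#' @examples
#' rep <- runExperiment(preset = "indexed_correlation", seed = 1)
#' rep$stats$r2
#' @export
runExperiment <- function(config = NULL, preset = NULL, seed = 1L) {
  if (is.null(config)) config <- list(preset = preset, seed = seed)
  if (!inherits(config, "isletRunConfig")) config <- validateConfig(config)
  sc <- config$scenario_obj
  th <- config$thresholds
  seed <- config$seed
  for (st in sc@stages)
    if (st$n_islets < 1L)
      stop("stage '", st$name, "' has n_islets = ", st$n_islets,
           ": nothing to simulate")
  summaries <- NULL
  stats <- list()
  run <- config$preset
  if (run == "aging_decline") {
    cohort <- simulateCohort(sc, seed = seed,
                             stageNames = c("35dpf", "3mpf", "1ypf"),
                             render = config$render)
    summaries <- .scoreCohort(cohort, th)
    stats$anova <- stageComparisonAnova(summaries$pct_proliferating,
                                        summaries$stage)
    stats$stage_means <- tapply(summaries$pct_proliferating,
                                summaries$stage, mean)
  } else if (run %in% c("nfkb_edu", "nfkb_pcna")) {
    stage <- stageParamsOf(sc, "3mpf")
    if (run == "nfkb_pcna") stage$n_islets <- 13L  # PCNA snapshot cohort
    sc2 <- sc; sc2@stages <- list(`3mpf` = stage)
    cohort <- simulateCohort(sc2, seed = seed, stageNames = "3mpf",
                             render = config$render)
    summaries <- .scoreCohort(cohort, th)
    stats$paired <- classMarkerComparison(summaries)
  } else if (run == "mosaic_socs2") {
    cohort <- simulateCohort(sc, seed = seed, stageNames = "mosaic_23dpf",
                             render = config$render)
    summaries <- .scoreCohort(cohort, th)
    stats$paired <- classMarkerComparison(data.frame(
      pct_marker_pos_high = summaries$pct_cfp_pos_proliferating,
      pct_marker_pos_low = summaries$pct_cfp_neg_proliferating))
    stats$mean_cfp_pos <- mean(summaries$pct_cfp_pos_proliferating,
                               na.rm = TRUE)
    stats$mean_cfp_neg <- mean(summaries$pct_cfp_neg_proliferating,
                               na.rm = TRUE)
  } else if (run == "tnfrsf1b_injection") {
    res <- lapply(c(injected = "larva_injected", control = "larva_control"),
                  function(nm) {
      cohort <- simulateCohort(sc, seed = seed, stageNames = nm,
                               render = config$render)
      vapply(cohort, function(sim) {
        cells <- .cellsFromIslet(sim, th)
        cut <- if (!is.null(th$gfp_positive_value)) th$gfp_positive_value
               else .gfpPositiveCut(stageParamsOf(sc, nm))
        100 * mean(cells$normalized_gfp > cut)
      }, numeric(1))
    })
    summaries <- data.frame(
      condition = rep(names(res), lengths(res)),
      animal = unlist(lapply(res, seq_along)),
      pct_gfp_positive = unlist(res), row.names = NULL)
    stats$mean_injected <- mean(res$injected)
    stats$mean_control <- mean(res$control)
    stats$t_test <- t.test(res$injected, res$control)$p.value
  } else if (run == "tnfa_macrophage") {
    mp <- sc@extras$macrophage
    if (is.null(mp)) stop("scenario has no macrophage extras")
    tabs <- lapply(seq_along(mp), function(i) {
      tab <- simulateMacrophageCounts(mp[[i]], seed = deriveSeed(seed, i))
      tab$stage <- names(mp)[i]
      tab
    })
    summaries <- do.call(rbind, tabs)
    stats$stage_means <- tapply(summaries$pct_tnfa_pos, summaries$stage,
                                mean)
    if (length(mp) >= 2L)
      stats$t_test <- t.test(tabs[[1L]]$pct_tnfa_pos,
                             tabs[[2L]]$pct_tnfa_pos)$p.value
  } else if (run == "qpcr_detection") {
    genes <- names(stageParamsOf(sc, "3mpf")$detection_prob)
    hk <- intersect(c("bact1", "ef1a", "rpl13a"), genes)
    tabs <- lapply(c("3mpf", "1ypf"), function(nm) {
      simulateCtTable(stageParamsOf(sc, nm), genes, config$n_qpcr_cells,
                      seed = deriveSeed(seed, match(nm, stages(sc))))
    })
    x <- CtExperiment(do.call(cbind, lapply(tabs, ctValues)),
                      stage = unlist(lapply(tabs, stages)))
    x <- housekeepingFilter(x, hk)
    candidates <- setdiff(genes, hk)
    summaries <- do.call(rbind, lapply(candidates, function(g) {
      rbind(detectionFraction(x, g, "3mpf"), detectionFraction(x, g, "1ypf"))
    }))
    stats$chi_square <- lapply(setNames(nm = candidates), function(g) {
      chiSquareDetection(detectionFraction(x, g, "3mpf"),
                         detectionFraction(x, g, "1ypf"))
    })
  } else if (run %in% c("bulk_foldchange", "gfp_transcript")) {
    ex <- if (run == "bulk_foldchange") sc@extras$bulk_qpcr
          else sc@extras$gfp_transcript
    if (is.null(ex)) stop("scenario is missing the ", run, " extras")
    groups <- if (run == "bulk_foldchange") c("high", "low")
              else c("1ypf", "3mpf")
    bulk <- simulateBulkQpcr(unlist(ex$fold_changes), ex$reference_gene,
                             nReplicates = ex$n_replicates, seed = seed,
                             noiseSd = ex$noise_sd, groups = groups)
    genes <- setdiff(names(ex$fold_changes), ex$reference_gene)
    stats$fold_changes <- lapply(setNames(nm = genes), function(g)
      deltaCtFoldChange(bulk, g, ex$reference_gene, groupA = groups[1L],
                        groupB = groups[2L]))
    summaries <- data.frame(
      gene = genes,
      fold_change = vapply(stats$fold_changes, `[[`, numeric(1),
                           "fold_change"),
      p_value = vapply(stats$fold_changes, `[[`, numeric(1), "p_value"),
      row.names = NULL)
  } else if (run == "facs_split") {
    res <- lapply(c("3mpf", "1ypf"), function(nm) {
      ev <- simulateFacsEvents(stageParamsOf(sc, nm), config$n_facs_events,
                               seed = deriveSeed(seed, match(nm, stages(sc))))
      cut <- if (identical(th$facs_method, "fixed"))
        splitThreshold(ev, "fixed", value = th$facs_value)
        else splitThreshold(ev, "valley")
      c(list(stage = nm, threshold = cut), populationProportions(ev, cut))
    })
    summaries <- do.call(rbind, lapply(res, as.data.frame))
    stats$thresholds <- setNames(vapply(res, `[[`, numeric(1), "threshold"),
                                 vapply(res, `[[`, character(1), "stage"))
  } else if (run == "indexed_correlation") {
    ex <- sc@extras$indexed
    if (is.null(ex)) stop("scenario is missing the indexed extras")
    pairs <- simulateIndexedCells(ex$n_cells, ex$target_r2, seed = seed)
    stats$r2 <- intensityExpressionR2(pairs$gfp_fluorescence, pairs$gfp_ct)
    summaries <- data.frame(n_cells = nrow(pairs), r2 = stats$r2)
  }
  report <- list(
    preset = run, seed = seed, summaries = summaries, stats = stats,
    provenance = list(
      config_hash = rlang::hash(config[setdiff(names(config),
                                               "scenario_obj")]),
      package_version = as.character(packageVersion("isletAging")),
      r_version = R.version.string))
  class(report) <- "isletRunReport"
  if (!is.null(config$out_dir)) writeRunReport(report, config$out_dir)
  report
}

# midpoint (on the log scale) between the two planted mixture components,
# mapped to the normalized-GFP scale: the reporter-positivity cut used when
# no explicit gate is configured
.gfpPositiveCut <- function(stage) {
  mix <- stage$gfp_mixture
  if (is.null(mix)) stop("stage '", stage$name, "' has no gfp_mixture")
  exp((mix$mu_low + mix$mu_high) / 2) / .defaultChannelLevels[["DAPI"]]
}

#' Write a run report to disk
#'
#' Saves the per-islet summaries as CSV and the full report (statistics
#' and provenance) as JSON.
#'
#' @param report an `isletRunReport` from [runExperiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeRunReport <- function(report, dir) {
  stopifnot(inherits(report, "isletRunReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(report$summaries))
    write.csv(report$summaries,
              file.path(dir, paste0(report$preset, "_summaries.csv")),
              row.names = FALSE)
  out <- report
  class(out) <- NULL
  jsonlite::write_json(out, file.path(dir, paste0(report$preset,
                                                  "_report.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
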