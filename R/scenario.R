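#' Build a per-stage parameter set
#'
#' A stage parameter set collects the planted ground truth that synthetic
#' islets, qPCR tables and FACS events for one developmental stage (or
#' experimental condition) are generated under. All probability fields are
#' optional: a stage used only for FUCCI scoring needs only
#' `p_proliferating`; a mosaic stage needs the CFP fields; a qPCR stage
#' needs `detection_prob`; and so on. Validity is checked on construction
#' and again when the stage enters an [IsletScenario-class].
#'
#' @param name stage label, e.g. `"35dpf"`, `"3mpf"`, `"1ypf"`.
#' @param n_islets number of islets (or animals) simulated at this stage.
#' @param cells_min,cells_max inclusive range of beta-cells per islet.
#' @param p_proliferating probability that a beta-cell is in S/G2/M
#'   (FUCCI green-only).
#' @param gfp_mixture two-component log-normal mixture of per-cell NF-kB
#'   reporter intensity: list with `w_high` (weight of the high component)
#'   and `mu_low`, `sigma_low`, `mu_high`, `sigma_high` on the natural-log
#'   intensity scale; `mu_high > mu_low` required.
#' @param p_edu_given_gfp_high,p_edu_given_gfp_low probability of
#'   proliferation-marker (EdU/PCNA) positivity conditional on the true
#'   GFP class.
#' @param p_cfp probability that a beta-cell carries the mosaic CFP
#'   transgene.
#' @param p_prolif_given_cfp,p_prolif_given_nocfp proliferation
#'   probability conditional on CFP status (mosaic stages).
#' @param detection_prob named list/vector, per-gene probability that a
#'   transcript is detected (Ct < 40) in a single cell.
#' @param facs two-component log-normal mixture of FACS GFP intensity,
#'   same fields as `gfp_mixture`.
#' @param ct_mean,ct_sd location and spread of detected single-cell Ct
#'   draws (truncated to (0, 40)).
#' @return a validated stage parameter list.
#' @examples
#' stageParams("35dpf", n_islets = 5, cells_min = 300, cells_max = 600,
#'             p_proliferating = 0.0153)
#' @export
stageParams <- function(name, n_islets = 1L, cells_min = 100L,
                        cells_max = 200L, p_proliferating = NULL,
                        gfp_mixture = NULL, p_edu_given_gfp_high = NULL,
                        p_edu_given_gfp_low = NULL, p_cfp = NULL,
                        p_prolif_given_cfp = NULL,
                        p_prolif_given_nocfp = NULL, detection_prob = NULL,
                        facs = NULL, ct_mean = 25, ct_sd = 2) {
  s <- list(name = name, n_islets = as.integer(n_islets),
            cells_min = as.integer(cells_min),
            cells_max = as.integer(cells_max),
            p_proliferating = p_proliferating, gfp_mixture = gfp_mixture,
            p_edu_given_gfp_high = p_edu_given_gfp_high,
            p_edu_given_gfp_low = p_edu_given_gfp_low, p_cfp = p_cfp,
            p_prolif_given_cfp = p_prolif_given_cfp,
            p_prolif_given_nocfp = p_prolif_given_nocfp,
            detection_prob = detection_prob, facs = facs,
            ct_mean = ct_mean, ct_sd = ct_sd)
  err <- .checkStageParams(s)
  if (!is.null(err)) stop(paste(err, collapse = "; "))
  s
}

# shared validity for stage parameter lists (also called from the
# IsletScenario validity method)
.checkStageParams <- function(s) {
  msg <- NULL
  who <- if (!is.null(s$name)) s$name else "<unnamed>"
  if (is.null(s$name) || !nzchar(s$name))
    msg <- c(msg, "stage name must be non-empty")
  if (!is.null(s$cells_min) && !is.null(s$cells_max) &&
      (s$cells_min < 1L || s$cells_max < s$cells_min))
    msg <- c(msg, sprintf("stage %s: invalid cells_per_islet range", who))
  probs <- c(p_proliferating = s$p_proliferating,
             p_edu_given_gfp_high = s$p_edu_given_gfp_high,
             p_edu_given_gfp_low = s$p_edu_given_gfp_low,
             p_cfp = s$p_cfp, p_prolif_given_cfp = s$p_prolif_given_cfp,
             p_prolif_given_nocfp = s$p_prolif_given_nocfp,
             unlist(s$detection_prob))
  if (length(probs) && (any(probs < 0) || any(probs > 1)))
    msg <- c(msg, sprintf("stage %s: probabilities must lie in [0, 1]", who))
  for (mixName in c("gfp_mixture", "facs")) {
    mix <- s[[mixName]]
    if (is.null(mix)) next
    need <- c("w_high", "mu_low", "sigma_low", "mu_high", "sigma_high")
    if (!all(need %in% names(mix))) {
      msg <- c(msg, sprintf("stage %s: %s must have fields %s", who, mixName,
                            paste(need, collapse = ", ")))
      next
    }
    if (mix$w_high < 0 || mix$w_high > 1)
      msg <- c(msg, sprintf("stage %s: %s w_high must be in [0, 1]", who,
                            mixName))
    if (mix$mu_high <= mix$mu_low)
      msg <- c(msg, sprintf("stage %s: %s requires mu_high > mu_low", who,
                            mixName))
    if (mix$sigma_low <= 0 || mix$sigma_high <= 0)
      msg <- c(msg, sprintf("stage %s: %s sigmas must be > 0", who, mixName))
  }
  msg
}

#' Read a scenario from YAML
#'
#' The YAML layout mirrors the [IsletScenario()] constructor: top-level
#' keys `stages` (a named map of stage parameter maps), `voxel_size_um`,
#' `nucleus_radius_um`, `noise_model`, optional `extras` and `seed`.
#'
#' @param path path to a YAML scenario file.
#' @return an [IsletScenario-class].
#' @seealso [writeScenario()], [paperCalibratedScenario()]
#' @export
readScenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  y <- yaml::read_yaml(path)
  stages <- lapply(names(y$stages), function(nm) {
    do.call(stageParams, c(list(name = nm), y$stages[[nm]]))
  })
  names(stages) <- names(y$stages)
  IsletScenario(
    stages = stages,
    voxelSizeUm = if (is.null(y$voxel_size_um)) 0.5 else y$voxel_size_um,
    nucleusRadiusUm = if (is.null(y$nucleus_radius_um)) 3
                      else y$nucleus_radius_um,
    noiseModel = if (is.null(y$noise_model))
      list(photon_scale = 2, background = 2, blur_sigma_um = 0.5)
      else y$noise_model,
    extras = if (is.null(y$extras)) list() else y$extras,
    seed = if (is.null(y$seed)) 1L else y$seed)
}

#' Write a scenario to YAML
#'
#' @param scenario an [IsletScenario-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScenario <- function(scenario, path) {
  stopifnot(is(scenario, "IsletScenario"))
  stages <- lapply(scenario@stages, function(s) {
    s$name <- NULL
    s[!vapply(s, is.null, logical(1))]
  })
  y <- list(stages = stages,
            voxel_size_um = scenario@voxelSizeUm,
            nucleus_radius_um = scenario@nucleusRadiusUm,
            noise_model = scenario@noiseModel,
            extras = scenario@extras,
            seed = scenario@seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' The packaged paper-calibrated scenario
#'
#' Loads the scenario shipped with the package
#' (`extdata/paper_calibrated.yaml`), whose planted stage means are the
#' group means reported for the zebrafish islet aging study: FUCCI
#' green-only fractions of 1.53% (35 dpf), 0.15% (3 mpf) and 0.06%
#' (1 ypf); mosaic socs2 proliferation of 8.44% (CFP-) vs 1.08% (CFP+);
#' NF-kB reporter positivity of 32.2% (tnfrsf1b-injected larvae) vs 2.4%
#' (controls); 25% tnfa-reporter-positive intra-islet leukocytes at
#' 3 mpf; a 2.5-fold socs2 enrichment in GFP-high sorted cells; a 1.5-fold
#' GFP transcript increase between 3 mpf and 1 ypf; and an indexed-sort
#' fluorescence-expression R^2 of 0.28.
#'
#' @return an [IsletScenario-class].
#' @examples
#' sc <- paperCalibratedScenario()
#' stages(sc)
#' @export
paperCalibratedScenario <- function() {
  path <- system.file("extdata", "paper_calibrated.yaml",
                      package = "isletAging", mustWork = TRUE)
  readScenario(path)
}
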