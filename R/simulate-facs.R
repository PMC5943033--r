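#' Simulate FACS GFP-intensity events for one stage
#'
#' Draws per-event log-intensities from the stage's two-component normal
#' mixture (`facs` field of [stageParams()]) and exponentiates to the
#' intensity scale; the true mixture component of every event is
#' recorded, enabling classification benchmarking.
#'
#' @param stage stage parameter list with a `facs` mixture.
#' @param nEvents number of events (0 gives an empty table).
#' @param seed integer seed.
#' @return data.frame with columns `stage`, `intensity` (> 0) and
#'   `true_component` (`"low"`/`"high"`).
#' @examples
#' st <- stageParams("3mpf",
#'   facs = list(w_high = 0.35, mu_low = 3.4, sigma_low = 0.5,
#'               mu_high = 5.7, sigma_high = 0.5))
#' head(simulateFacsEvents(st, 1000, seed = 1))
#' @export
simulateFacsEvents <- function(stage, nEvents, seed = 1L) {
  mix <- stage$facs
  if (is.null(mix)) stop("stage '", stage$name, "' has no facs mixture")
  withSeed(seed, function() {
    if (nEvents == 0L)
      return(data.frame(stage = character(), intensity = numeric(),
                        true_component = character()))
    high <- runif(nEvents) < mix$w_high
    logi <- ifelse(high, rnorm(nEvents, mix$mu_high, mix$sigma_high),
                   rnorm(nEvents, mix$mu_low, mix$sigma_low))
    data.frame(stage = stage$name, intensity = exp(logi),
               true_component = ifelse(high, "high", "low"))
  })
}

#' Simulate intra-islet leukocyte counts with a tnfa-reporter plant
#'
#' Emulates counting tnfa:GFP-positive cells among L-plastin-positive
#' (pan-leukocyte) cells inside the islet: per animal, the leukocyte count
#' is drawn uniformly from a planted range and each leukocyte is
#' reporter-positive with probability `p_tnfa`.
#'
#' @param params list with `n_animals`, `leuko_min`, `leuko_max`,
#'   `p_tnfa` (see the `macrophage` extras of the packaged scenario).
#' @param seed integer seed.
#' @return data.frame with one row per animal: `animal`, `n_leukocytes`,
#'   `n_tnfa_pos`, `pct_tnfa_pos`.
#' @export
simulateMacrophageCounts <- function(params, seed = 1L) {
  stopifnot(all(c("n_animals", "leuko_min", "leuko_max", "p_tnfa") %in%
                  names(params)))
  if (params$p_tnfa < 0 || params$p_tnfa > 1)
    stop("p_tnfa must lie in [0, 1]")
  withSeed(seed, function() {
    n <- params$n_animals
    nl <- if (params$leuko_max > params$leuko_min)
      sample(params$leuko_min:params$leuko_max, n, replace = TRUE)
      else rep(params$leuko_min, n)
    pos <- rbinom(n, nl, params$p_tnfa)
    data.frame(animal = seq_len(n), n_leukocytes = nl, n_tnfa_pos = pos,
               pct_tnfa_pos = 100 * pos / nl)
  })
}
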