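# Shared fixtures: small stages and one cached rendered islet so the
# image-based tests pay the rendering cost once.

demoStage <- function(name = "demo", n = 50, pProlif = 0.1,
                      wHigh = 0.4, ...) {
  stageParams(name, n_islets = 2L, cells_min = n, cells_max = n,
              p_proliferating = pProlif,
              gfp_mixture = list(w_high = wHigh, mu_low = 1.6,
                                 sigma_low = 0.4, mu_high = 4.1,
                                 sigma_high = 0.4),
              p_edu_given_gfp_high = 0.05, p_edu_given_gfp_low = 0.2, ...)
}

.fixtureCache <- new.env(parent = emptyenv())

cachedIsletSim <- function(key = "default", builder = NULL) {
  if (is.null(.fixtureCache[[key]])) {
    .fixtureCache[[key]] <- if (is.null(builder)) {
      simulateIsletStack(demoStage(), seed = 42)
    } else builder()
  }
  .fixtureCache[[key]]
}

hkStage <- function() {
  stageParams("hk", detection_prob = list(bact1 = 0.8, ef1a = 0.8,
                                          rpl13a = 0.8, tnfa = 0.3))
}

# a tiny hand-built stack: 2 channels, one 3-plane cell
tinyStackFixture <- function(gfp = 50, dapi = 100) {
  lab <- array(0L, c(5, 6, 6))
  lab[2, 2:3, 2:3] <- 1L
  lab[3, 2:4, 2:4] <- 1L
  lab[4, 2:3, 2:3] <- 1L
  a <- array(0, c(2, 5, 6, 6))
  a[1, , , ] <- dapi
  a[2, , , ] <- gfp
  list(stack = IsletStack(a, c("DAPI", "NFKB_GFP"), 0.5),
       labels = LabelVolume(lab))
}
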