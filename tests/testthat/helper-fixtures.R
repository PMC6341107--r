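# Shared fixtures built in code at test time.

# compact locus for fast simulation tests: 100-kb chromosomes, same
# structural layout as the default model (scaled)
smallLocusConfig <- function(nEnhancers = 2) {
  locusConfig(chromLengths = c(chr4s = 1e5, chr9s = 1e5),
              nEnhancers = nEnhancers, nCtcfSites = 4,
              enhancerWidth = 2000, clusterSpan = c(30000, 64000),
              acceptorTss = 50000, acceptorCtcfOffset = 13500,
              positionJitter = 100)
}

# synthetic per-case cohort tables whose group tallies reproduce the
# published break-apart FISH and IHC aggregates (24 positive of 28
# evaluable tumor cases with one non-evaluable; 0 of 75 in other
# entities; 28 of 29 positive by IHC)
fishCohortTable <- function() {
  data.frame(
    case_id = c(sprintf("acicc_%02d", 1:29), sprintf("other_%02d", 1:75)),
    group = rep(c("AciCC", "other"), c(29, 75)),
    status = c(rep(TRUE, 24), rep(FALSE, 4), NA, rep(FALSE, 75)),
    stringsAsFactors = FALSE)
}

ihcCohortTable <- function() {
  data.frame(
    case_id = sprintf("acicc_%02d", 1:29),
    group = "AciCC",
    status = c(rep(TRUE, 28), FALSE),
    stringsAsFactors = FALSE)
}

# simple deterministic toy PWM fixtures
toyPfm <- function(L = 4, seed = 7) {
  set.seed(seed)
  m <- matrix(sample(0:20, 4 * L, replace = TRUE), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m
}
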