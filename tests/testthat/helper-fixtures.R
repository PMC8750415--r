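## Small designs used across the test files. Sizes are kept small so the
## whole suite runs quickly; statistical checks that need power use their own
## larger, seeded configurations.

authenticDesign <- function(nSamples = 20L, nReplicates = 5L, seed = 1L) {
    SampleDesign(nCowSmp = as.integer(nSamples), nBuffaloMix = 0L,
                 adulterants = character(), nSpikedSmps = 0L,
                 blendingModes = "dry", nReplicates = as.integer(nReplicates),
                 seed = as.integer(seed))
}

smallStudyDesign <- function(seed = 1L) {
    SampleDesign(nCowSmp = 12L, nBuffaloMix = 1L,
                 adulterants = c("ammonium_sulfate", "cornstarch"),
                 fraudLevels = c(0.5, 5, 10), nSpikedSmps = 4L,
                 blendingModes = c("dry", "wet"), nReplicates = 3L,
                 seed = as.integer(seed))
}

flatSpectraSet <- function(n = 10L, K = 64L, level = 1) {
    SpectraSet(matrix(level, n, K), seq(900, 1700, length.out = K),
               data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                          replicate_idx = 1L))
}
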