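# Shared synthetic dataset, built once per test run (seeded, so every
# run sees identical data).

.syn_cache <- new.env()

getSyntheticRun <- function() {
  if (is.null(.syn_cache$run)) {
    .syn_cache$run <- runSyntheticPipeline(
      n_true = 10L, n_decoy = 10L, genome_length = 50000L,
      knockdown_factor = 0.25, depth_per_locus = 200L, rng_seed = 101L
    )
  }
  .syn_cache$run
}

# a small perfect stem-loop: complementary stem, A/C loop
makeStemLoop <- function(stem_len = 12L, loop_len = 6L) {
  stem <- sample(c("A", "C", "G", "T"), stem_len, replace = TRUE)
  loop <- sample(c("A", "C"), loop_len, replace = TRUE)
  paste(c(stem, loop, rev(chartr("ACGT", "TGCA", stem))), collapse = "")
}

# hand-built ArmExpression (counts/rpm keyed by library id)
makeArmExpression <- function(candidate_id, arm, counts, rpm = NULL) {
  structure(list(candidate_id = candidate_id, arm = arm,
                 counts = counts, rpm = rpm),
            class = "ArmExpression")
}
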