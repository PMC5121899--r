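test_that("planting is deterministic and books labels as requested", {
  t1 <- plantMirnaLoci(5, 5, 30000, rng_seed = 42)
  t2 <- plantMirnaLoci(5, 5, 30000, rng_seed = 42)
  expect_identical(as.character(t1@genome), as.character(t2@genome))
  expect_identical(vapply(t1@candidates, precursorSeq, ""),
                   vapply(t2@candidates, precursorSeq, ""))
  expect_length(t1@candidates, 10L)
  expect_equal(sum(t1@labels == "true_mirna"), 5L)
  expect_equal(sum(t1@labels == "decoy"), 5L)
  t3 <- plantMirnaLoci(5, 5, 30000, rng_seed = 43)
  expect_false(identical(as.character(t1@genome),
                         as.character(t3@genome)))
})

test_that("insufficient genome length raises a capacity error", {
  expect_error(plantMirnaLoci(10, 10, 2000, rng_seed = 1), "capacity")
})

test_that("true hairpins satisfy all structural criteria by construction", {
  truth <- plantMirnaLoci(8, 0, 30000, rng_seed = 7)
  for (cand in truth@candidates) {
    fold <- foldHairpin(precursorSeq(cand))
    ev <- evaluateHairpinCriteria(fold, armInterval(cand, "5p"),
                                  armInterval(cand, "3p"))
    expect_true(all(ev$flags))
    expect_true(ev$metrics["mature_star_pairs"] >= 17)
    expect_lt(freeEnergy(fold), -22)
    expect_gte(loopLength(fold), 8L)
    expect_lte(loopLength(fold), 40L)
    # the pair count agrees with the independent enumeration oracle on
    # the duplex-defining prefix (full precursors are too long for it)
  }
})

test_that("each decoy mode violates exactly its structural criterion", {
  truth <- plantMirnaLoci(0, 10, 40000, rng_seed = 13)
  for (i in seq_along(truth@candidates)) {
    cand <- truth@candidates[[i]]
    mode <- truth@decoyModes[i]
    fold <- foldHairpin(precursorSeq(cand))
    fl <- evaluateHairpinCriteria(fold, armInterval(cand, "5p"),
                                  armInterval(cand, "3p"))$flags
    expected_false <- switch(mode,
      bad_fold = "c4_hairpin", low_pairing = "c6_pairing",
      no_overhang = "c7_overhang", character(0))
    expect_identical(names(fl)[!fl], expected_false,
                     info = paste("mode", mode))
  }
})

test_that("the low-pairing decoy's best fold pairs at most 16 duplex bases", {
  truth <- plantMirnaLoci(0, 4, 30000, rng_seed = 21,
                          decoy_modes = "low_pairing")
  for (cand in truth@candidates) {
    fold <- foldHairpin(precursorSeq(cand))
    ev <- evaluateHairpinCriteria(fold, armInterval(cand, "5p"),
                                  armInterval(cand, "3p"))
    expect_lte(ev$metrics["mature_star_pairs"], 16)
    # cross-check the fold itself against the enumeration oracle
    expect_equal(sum(!is.na(fold@pairs)) / 2L,
                 oracleMaxPairs(precursorSeq(cand)))
  }
})

test_that("simulated libraries express the knockdown design", {
  truth <- plantMirnaLoci(4, 2, 30000, rng_seed = 5,
                          knockdown_factor = 0.25,
                          decoy_modes = "dicer_independent")
  sim <- simulateReadLibraries(truth, depth_per_locus = 200)
  expect_identical(sort(unique(sim$libraries$condition)),
                   c("control", "dicer_depleted"))
  # RPM denominator equals the per-library read total
  for (lib in sim$libraries$library_id) {
    expect_equal(sum(sim$reads$count[sim$reads$library_id == lib]),
                 sim$libraries$total_mapped_reads[
                   sim$libraries$library_id == lib])
  }
  ctrl <- sim$libraries$library_id[sim$libraries$condition == "control"]
  for (i in seq_along(truth@candidates)) {
    cand <- truth@candidates[[i]]
    cnt <- countArmReads(sim$reads, cand, sim$libraries)
    # both arms of every locus have >= 1 read in each control library
    expect_true(supportFilter(cnt$expr5p, cnt$expr3p, ctrl))
    mature <- if (truth@matureArms[i] == "5p") cnt$expr5p else cnt$expr3p
    fc <- computeLog2FC(mature, sim$libraries)$log2fc
    if (is.na(truth@decoyModes[i])) {
      expect_lt(abs(fc - log2(0.25)), 0.6)  # true loci track log2(kf)
    } else {
      expect_lt(abs(fc), 0.4)               # dicer-independent decoys
    }
  }
})

test_that("a knockdown factor of 1 leaves true loci failing the fc filter", {
  truth <- plantMirnaLoci(4, 0, 25000, rng_seed = 6, knockdown_factor = 1)
  sim <- simulateReadLibraries(truth, depth_per_locus = 200)
  for (cand in truth@candidates) {
    cnt <- countArmReads(sim$reads, cand, sim$libraries)
    fc5 <- computeLog2FC(cnt$expr5p, sim$libraries)$log2fc
    expect_gt(fc5, -0.5)
  }
})

test_that("fewer than two control libraries is a configuration error", {
  truth <- plantMirnaLoci(2, 0, 20000, rng_seed = 3)
  expect_error(simulateReadLibraries(truth, 100, n_control = 1L),
               "configuration error")
})

test_that("mock sequences are distinct, seeded and exclusion-aware", {
  m1 <- generateMockSequences(100, 22, rng_seed = 7)
  expect_length(unique(m1), 100L)
  expect_true(all(nchar(m1) == 22L))
  expect_identical(m1, generateMockSequences(100, 22, rng_seed = 7))

  excl <- "TGACTCCAGACCTTGTTGCTGA"
  m2 <- generateMockSequences(50, 22, rng_seed = 8, exclude = excl)
  expect_false(any(m2 %in% excl))
  expect_false(any(substr(m2, 2, 7) == substr(excl, 2, 7)))

  # pigeonhole: two distinct draws from a single-letter universe
  expect_error(
    generateMockSequences(2, 1, rng_seed = 1, exclude = c("A", "C", "G")),
    "generation error")
})
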