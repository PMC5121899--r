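test_that("conserved assignment implements the >18-column, <=1-mismatch rule", {
  ref22 <- "TGGAATGTAAAGAAGTATGGAG"
  refs <- c(`Mir-1` = ref22)

  expect_identical(unname(assignConserved(ref22, refs)), "Mir-1")

  # 19 columns with exactly one mismatch: conserved
  cand19_1mm <- paste0("A", substr(ref22, 2, 19))
  expect_identical(unname(assignConserved(cand19_1mm, refs)), "Mir-1")
  # 19 columns with two mismatches: not conserved
  cand19_2mm <- paste0("AA", substr(ref22, 3, 19))
  expect_true(is.na(assignConserved(cand19_2mm, refs)))
  # 18 perfect columns: not conserved ("longer than 18")
  expect_true(is.na(assignConserved(substr(ref22, 1, 18), refs)))
  # 19 perfect columns: conserved
  expect_identical(unname(assignConserved(substr(ref22, 1, 19), refs)),
                   "Mir-1")
})

test_that("conserved assignment is symmetric and tie-broken by name", {
  a <- "TGAGGTAGTAGGTTGTATAGTT"
  b <- paste0("TGAGGTAGTAGGTTGTATAGA", "A")  # 2 trailing mismatches
  fwd <- assignConserved(a, c(ref = b))
  rev <- assignConserved(b, c(ref = a))
  expect_identical(is.na(fwd), is.na(rev))

  refs <- c(`Mir-B` = a, `Mir-A` = a)
  expect_identical(unname(assignConserved(a, refs)), "Mir-A")
})

test_that("seed extraction matches the published family-defining hexamers", {
  expect_identical(extractSeed("ATGAAATGGACGATTGGCTGTG"), "TGAAAT")
  expect_identical(extractSeed("TACATAACCGCAATCACCGATT"), "ACATAA")
  expect_identical(extractSeed("TGTGATGTGCATGTGGGCTTTCC"), "GTGATG")
  expect_identical(extractSeed("GATTACA", c(1L, 1L)), "G")
  expect_error(extractSeed("ACG"), "contract error")
})

test_that("family grouping partitions genes by exact seed identity", {
  cat13 <- bgeNovelMatures()
  fams <- groupFamilies(cat13)
  expect_equal(nrow(fams), 13L)                      # partition: all genes
  expect_equal(anyDuplicated(fams$name), 0L)
  sizes <- sort(as.integer(table(fams$family)))
  expect_equal(sizes, c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 3L))
  expect_equal(length(unique(fams$family)), 9L)

  # the two identical bg5 matures share one family
  bg5 <- fams$family[fams$seed == "GTGATG"]
  expect_equal(length(unique(bg5)), 1L)
  expect_equal(length(bg5), 2L)

  single <- groupFamilies(data.frame(name = "g1",
                                     mature = "TGAGGTAGTAGGTTGTATAGTT"))
  expect_equal(nrow(single), 1L)

  # expression ordering names the most abundant novel family first
  genes <- data.frame(name = c("gA", "gB"),
                      mature = c("TAAAAAACCCCCCCCGGGGGGG",
                                 "TCCCCCCAAAAAAAAGGGGGGG"))
  named <- groupFamilies(genes, species_code = "xx",
                         expression = c(gA = 10, gB = 500))
  expect_equal(named$family[named$name == "gB"], "MIR-xx1")
})

test_that("arm designation uses the <2 co-maturity ratio strictly", {
  libs <- c("c1", "c2")
  mk <- function(t5, t3) list(
    makeArmExpression("x", "5p", counts = c(c1 = t5, c2 = 0)),
    makeArmExpression("x", "3p", counts = c(c1 = t3, c2 = 0)))
  e <- mk(100, 60)   # ratio 1.67 < 2
  expect_identical(designateArms(e[[1]], e[[2]], libs), "co-mature")
  e <- mk(100, 40)   # ratio 2.5
  expect_identical(designateArms(e[[1]], e[[2]], libs), "5p")
  e <- mk(50, 50)    # ratio 1
  expect_identical(designateArms(e[[1]], e[[2]], libs), "co-mature")
  e <- mk(100, 50)   # ratio exactly 2 is NOT co-mature
  expect_identical(designateArms(e[[1]], e[[2]], libs), "5p")
  e <- mk(0, 30)     # min floored at one read
  expect_identical(designateArms(e[[1]], e[[2]], libs), "3p")
  e <- mk(0, 0)
  expect_error(designateArms(e[[1]], e[[2]], libs), "contract error")
})

test_that("5' homogeneity is the modal-offset fraction", {
  all_same <- fivePrimeHomogeneity(c(0, 0), c(40, 10))
  expect_equal(all_same$fraction, 1)
  expect_true(all_same$pass)

  half <- fivePrimeHomogeneity(c(0, 1), c(50, 50))
  expect_equal(half$fraction, 0.5)
  expect_false(half$pass)

  mixed <- fivePrimeHomogeneity(c(0, 1, -1), c(70, 20, 10))
  expect_equal(mixed$fraction, 0.7)
  expect_true(mixed$pass)

  expect_error(fivePrimeHomogeneity(integer(), integer()), "no reads")
})

test_that("assembly artifacts need identical precursors AND context", {
  set.seed(41)
  prec <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  ctx <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  other <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  filler <- strrep("A", 200)
  # identical precursor + identical 50 nt context at two loci
  gseq1 <- paste0(ctx, prec, ctx, filler, ctx, prec, ctx, filler)
  genome1 <- Biostrings::DNAStringSet(c(ctg = gseq1))
  at <- function(id, start) newMiRNACandidate(
    id, "ctg", start, start + 80, "+", prec, c(2, 24), c(56, 78),
    genome = genome1)
  cands <- list(at("a", 60), at("b", 60 + 80 + 60 + 200 + 60))
  arts <- detectAssemblyArtifacts(cands, genome1)
  expect_identical(as.character(arts), "b")     # lowest coordinate kept
  expect_identical(attr(arts, "pairs")$kept, "a")

  # same precursor, context differing -> paralogues, both kept
  gseq2 <- paste0(ctx, prec, ctx, filler, other, prec, other, filler)
  genome2 <- Biostrings::DNAStringSet(c(ctg = gseq2))
  at2 <- function(id, start) newMiRNACandidate(
    id, "ctg", start, start + 80, "+", prec, c(2, 24), c(56, 78),
    genome = genome2)
  cands2 <- list(at2("a", 60), at2("b", 60 + 80 + 60 + 200 + 60))
  expect_length(detectAssemblyArtifacts(cands2, genome2), 0L)

  # single-copy precursor: nothing flagged
  expect_length(detectAssemblyArtifacts(cands2[1], genome2), 0L)

  # identical loci flush against the contig end: flagged with truncation
  gseq3 <- paste0(prec, filler, prec)
  genome3 <- Biostrings::DNAStringSet(c(ctg = gseq3))
  cands3 <- list(
    newMiRNACandidate("a", "ctg", 0, 80, "+", prec, c(2, 24), c(56, 78),
                      genome = genome3),
    newMiRNACandidate("b", "ctg", 280, 360, "+", prec, c(2, 24),
                      c(56, 78), genome = genome3))
  arts3 <- detectAssemblyArtifacts(cands3, genome3)
  expect_length(arts3, 1L)
  expect_true(attr(arts3, "pairs")$truncated[1L])
})

test_that("criterion flags hold their strict inequalities at the boundary", {
  struct_ok <- c(c4_hairpin = TRUE, c5_energy = TRUE, c6_pairing = TRUE,
                 c7_overhang = TRUE)
  at_threshold <- criterionFlags(-0.5, 0.9, struct_ok)
  expect_false(at_threshold["c2_dicer_fc"])       # -0.5 exactly fails
  expect_true(criterionFlags(-0.51, 0.9, struct_ok)["c2_dicer_fc"])
  expect_true(criterionFlags(-0.5, 0.66, struct_ok)["c3_5prime_homogeneity"])
  expect_false(criterionFlags(-0.5, 0.659, struct_ok)["c3_5prime_homogeneity"])
})

test_that("the bona-fide verdict separates truth from decoys", {
  run <- getSyntheticRun()
  v <- run$verdicts
  truth <- run$truth
  is_true <- truth@labels == "true_mirna"
  expect_true(all(v$status[is_true] == "novel_bona_fide"))
  expect_true(all(v$status[!is_true] == "rejected"))
  # flag invariant: bona fide implies every flag true
  flag_cols <- grep("^c[1-7]_|^support_|^not_", names(v), value = TRUE)
  bona <- v$status == "novel_bona_fide"
  expect_true(all(as.matrix(v[bona, flag_cols])))
})

test_that("conserved candidates bypass the structural criteria", {
  run <- getSyntheticRun()
  truth <- run$truth
  sim <- run$sim
  # use a decoy's designated-mature sequence as the reference catalogue
  decoy_idx <- which(truth@decoyModes %in%
                       c("no_overhang", "low_pairing"))[1L]
  cand <- truth@candidates[[decoy_idx]]
  ref <- setNames(armSeq(cand, truth@matureArms[decoy_idx]), "Mir-ref")
  v <- curateMiRNAs(truth@candidates, sim$reads, sim$libraries,
                    genome = truth@genome, reference = ref)
  expect_identical(v$status[decoy_idx], "conserved")
  expect_identical(v$conserved_match[decoy_idx], "Mir-ref")
})

test_that("missing upstream inputs raise dependency errors", {
  run <- getSyntheticRun()
  cand <- run$truth@candidates[[1L]]
  cnt <- attr(run$verdicts, "counts")[[1L]]
  fold <- attr(run$verdicts, "folds")[[1L]]
  libs <- run$sim$libraries
  expect_error(applyBonaFideFilter(cand, list(), libs, fold),
               "dependency error")
  expect_error(applyBonaFideFilter(cand, cnt, libs, NULL),
               "dependency error")
})

test_that("relaxing thresholds never shrinks the accepted set", {
  run <- getSyntheticRun()
  truth <- run$truth
  sim <- run$sim
  strict <- run$verdicts
  relaxed_th <- mirThresholds(fc = -0.2, energy = -15, min_pairs = 12,
                              homogeneity = 0.4, overhang_tol = 2L)
  relaxed <- curateMiRNAs(truth@candidates, sim$reads, sim$libraries,
                          genome = truth@genome, thresholds = relaxed_th)
  acc_strict <- strict$candidate_id[strict$status == "novel_bona_fide"]
  acc_relaxed <- relaxed$candidate_id[relaxed$status == "novel_bona_fide"]
  expect_true(all(acc_strict %in% acc_relaxed))
})
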