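libs2x2 <- data.frame(
  library_id = c("c1", "c2", "d1", "d2"),
  condition = c("control", "control", "dicer_depleted", "dicer_depleted"),
  total_mapped_reads = rep(1e6, 4),
  stringsAsFactors = FALSE
)

test_that("arm read assignment respects the 5' tolerance boundary", {
  set.seed(2)
  cand <- plantMirnaLoci(1, 0, 15000, rng_seed = 2)@candidates[[1L]]
  iv <- armInterval(cand, "5p")
  exact <- substr(precursorSeq(cand), iv[1L] + 1L, iv[2L])
  reads <- data.frame(sequence = exact, count = 12L, library_id = "c1",
                      stringsAsFactors = FALSE)
  cnt <- countArmReads(reads, cand, libs2x2, tolerance = 2L)
  expect_equal(unname(cnt$expr5p$counts["c1"]), 12)
  expect_equal(sum(cnt$expr3p$counts), 0)

  # a read starting tolerance+1 nt downstream is unassigned
  off3 <- substr(precursorSeq(cand), iv[1L] + 4L, iv[2L] + 3L)
  cnt3 <- countArmReads(
    data.frame(sequence = off3, count = 5L, library_id = "c1"),
    cand, libs2x2, tolerance = 2L)
  expect_equal(sum(cnt3$expr5p$counts) + sum(cnt3$expr3p$counts), 0)
  # while tolerance nt downstream is still assigned
  off2 <- substr(precursorSeq(cand), iv[1L] + 3L, iv[2L] + 2L)
  cnt2 <- countArmReads(
    data.frame(sequence = off2, count = 5L, library_id = "c1"),
    cand, libs2x2, tolerance = 2L)
  expect_equal(unname(cnt2$expr5p$counts["c1"]), 5)
})

test_that("log2 fold change follows the mean-RPM-with-pseudocount contract", {
  e <- makeArmExpression("x", "5p",
    counts = c(c1 = 10, c2 = 20, d1 = 5, d2 = 5),
    rpm = c(c1 = 10, c2 = 20, d1 = 5, d2 = 5))
  fc <- computeLog2FC(e, libs2x2, pseudocount = 0)
  expect_equal(fc$log2fc, log2(5 / 15), tolerance = 1e-12)  # -1.585

  eq <- makeArmExpression("x", "5p",
    counts = c(c1 = 7, c2 = 7, d1 = 7, d2 = 7),
    rpm = c(c1 = 7, c2 = 7, d1 = 7, d2 = 7))
  expect_equal(computeLog2FC(eq, libs2x2, 0)$log2fc, 0)

  only_ctrl <- libs2x2[libs2x2$condition == "control", ]
  expect_error(computeLog2FC(e, only_ctrl), "configuration error")
})

test_that("the control-support filter needs one read per arm per control", {
  e5 <- makeArmExpression("x", "5p", counts = c(c1 = 3, c2 = 1))
  e3 <- makeArmExpression("x", "3p", counts = c(c1 = 1, c2 = 1))
  expect_true(supportFilter(e5, e3, c("c1", "c2")))
  e3b <- makeArmExpression("x", "3p", counts = c(c1 = 0, c2 = 5))
  expect_false(supportFilter(e5, e3b, c("c1", "c2")))
  expect_error(supportFilter(e5, e3, character(0)), "configuration error")
})

test_that("Welch's t-test matches the hand formula and is symmetric", {
  res <- welchTTest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$statistic, oracleWelchT(c(1, 2, 3), c(2, 3, 4)),
               tolerance = 1e-12)
  expect_equal(res$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4, tolerance = 1e-9)

  same <- welchTTest(c(1, 2, 3), c(3, 1, 2))  # same group, shuffled
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  expect_error(welchTTest(c(1, 1, 1), c(1, 2, 3)), "groupA")
  expect_error(welchTTest(c(1, 2, 3), c(2, 2)), "groupB")
})

test_that("negative-control regions obey coverage, length and exclusion", {
  set.seed(31)
  gseq <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(ctg = gseq))
  tile <- function(from, to, mult) {
    st <- seq(from, to - 21L, by = 4L)
    data.frame(sequence = substr(rep(gseq, length(st)), st, st + 21L),
               count = mult, stringsAsFactors = FALSE)
  }
  mk_lib <- function(lib) {
    rd <- rbind(tile(501, 800, 4L),    # 300 nt region at ~12-24x
                tile(1501, 2200, 4L))  # 700 nt region: too long
    rd$library_id <- lib
    rd
  }
  reads <- rbind(mk_lib("c1"), mk_lib("c2"), mk_lib("d1"), mk_lib("d2"))
  libs <- libs2x2
  libs$total_mapped_reads <- as.numeric(
    tapply(reads$count, reads$library_id, sum)[libs$library_id])

  sel <- selectNegativeControls(genome, reads, libs, max_len = 500,
                                min_cov = 10)
  expect_true(length(sel) >= 1L)
  in300 <- IRanges::overlapsAny(
    sel, GenomicRanges::GRanges("ctg", IRanges::IRanges(501, 800)))
  expect_true(any(in300))
  # the 700 nt fully covered run is rejected by length
  expect_false(any(IRanges::width(sel) >= 500))
  expect_false(any(IRanges::overlapsAny(
    sel, GenomicRanges::GRanges("ctg", IRanges::IRanges(1550, 2100)))))

  # a region overlapping an excluded locus by one base is rejected
  hit <- sel[in300][1L]
  excl <- GenomicRanges::GRanges("ctg",
    IRanges::IRanges(GenomicRanges::end(hit), GenomicRanges::end(hit)))
  sel2 <- selectNegativeControls(genome, reads, libs, excluded = excl,
                                 max_len = 500, min_cov = 10)
  expect_false(any(sel2 == hit))
})

test_that("relaxing the coverage rule never strands a selected region", {
  run <- getSyntheticRun()
  sim <- run$sim
  genome <- run$truth@genome
  aln <- mapReadsToGenome(sim$reads, genome)
  strict <- selectNegativeControls(genome, sim$reads, sim$libraries,
                                   max_len = 10000L, min_cov = 15L,
                                   alignments = aln)
  relaxed <- selectNegativeControls(genome, sim$reads, sim$libraries,
                                    max_len = 10000L, min_cov = 10L,
                                    alignments = aln)
  # with the length filter inert, every strict region is contained in
  # a relaxed one, and raising max_len alone never removes regions
  expect_true(all(IRanges::overlapsAny(strict, relaxed, type = "within")))
  longer <- selectNegativeControls(genome, sim$reads, sim$libraries,
                                   max_len = 20000L, min_cov = 15L,
                                   alignments = aln)
  expect_true(all(as.character(strict) %in% as.character(longer)))
})

test_that("RPM mass is conserved on the synthetic dataset", {
  run <- getSyntheticRun()
  sim <- run$sim
  for (lib in sim$libraries$library_id) {
    tot <- sim$libraries$total_mapped_reads[
      sim$libraries$library_id == lib]
    counted <- 0
    for (cand in run$truth@candidates) {
      cnt <- countArmReads(sim$reads, cand, sim$libraries)
      counted <- counted + cnt$expr5p$counts[lib] + cnt$expr3p$counts[lib]
    }
    expect_lte(counted, tot)
    expect_lte(counted * 1e6 / tot, 1e6)
  }
})
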