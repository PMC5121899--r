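tree7 <- insectSpeciesTree()
endo <- c("Ame", "Tca", "Bmo", "Dme")
endo_label <- paste(sort(endo), collapse = ",")

dolloFor <- function(present, root_present = character()) {
  fams <- list()
  per_species <- lapply(tree7$tip.label, function(sp)
    if (sp %in% present) "fam" else character(0))
  names(per_species) <- tree7$tip.label
  dolloGainLoss(buildPresenceMatrix(per_species), tree7, root_present)
}

test_that("the presence matrix fills absent cells explicitly", {
  m <- buildPresenceMatrix(list(A = "f1", B = c("f1", "f2")))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["A", "f2"], 0L)
  expect_equal(m["B", "f2"], 1L)
  m2 <- buildPresenceMatrix(list(A = character(0), B = c("f1")),
                            genomic_only = list(A = "f1"))
  expect_equal(m2["A", "f1"], 2L)   # genomic-only counts as present
  expect_error(buildPresenceMatrix(list(A = "f1")), "two species")
})

test_that("Dollo places single gains on the subtending edge", {
  # present in the four endopterygotes: gain on their stem, no loss
  d <- dolloFor(endo)
  expect_equal(d$events$type, "gain")
  expect_equal(d$events$edge, endo_label)

  # present everywhere: gain at the root, no losses
  d_all <- dolloFor(tree7$tip.label)
  expect_equal(d_all$events$type, "gain")
  expect_equal(d_all$events$edge, "root")

  # present in Ame and Dme only: endopterygote gain, two terminal losses
  d2 <- dolloFor(c("Ame", "Dme"))
  expect_equal(sum(d2$events$type == "gain"), 1L)
  expect_equal(d2$events$edge[d2$events$type == "gain"], endo_label)
  expect_setequal(d2$events$edge[d2$events$type == "loss"],
                  c("Tca", "Bmo"))
})

test_that("a hemimetabolan family is lost once on the endopterygote stem", {
  d <- dolloFor(c("Bge", "Lmi", "Api"))
  gain <- d$events[d$events$type == "gain", ]
  loss <- d$events[d$events$type == "loss", ]
  expect_equal(gain$edge, "root")
  expect_equal(loss$edge, endo_label)  # one loss beats two gains
})

test_that("zero-presence families warn and place no gain", {
  m <- matrix(0L, 7L, 1L, dimnames = list(tree7$tip.label, "fam"))
  expect_warning(d <- dolloGainLoss(m, tree7), "no species")
  expect_equal(nrow(d$events), 0L)
})

test_that("gain/loss totals equal the exhaustive Dollo minima", {
  set.seed(3)
  picks <- c(list(character(0), tree7$tip.label),
             lapply(1:25, function(i)
               sample(tree7$tip.label, sample(1:6, 1L))))
  for (present in picks) {
    if (!length(present)) next
    d <- dolloFor(present)
    expect_equal(nrow(d$events), oracleDollo(present, tree7),
                 info = paste(present, collapse = "+"))
    # root-constrained: losses only
    dr <- dolloFor(present, root_present = "fam")
    expect_equal(sum(dr$events$type == "gain"), 0L)
    expect_equal(nrow(dr$events),
                 oracleDollo(present, tree7, root_constrained = TRUE),
                 info = paste("constrained", paste(present, collapse = "+")))
  }
})

test_that("per-edge gains sum to the number of gained families", {
  pats <- endopterygotePresencePatterns()
  per_species <- lapply(tree7$tip.label, function(sp)
    names(pats)[vapply(pats, function(p) sp %in% p, TRUE)])
  names(per_species) <- tree7$tip.label
  d <- dolloGainLoss(buildPresenceMatrix(per_species), tree7)
  expect_equal(sum(d$edge_totals$gains), length(pats))
})

test_that("cluster chaining follows the max-gap rule", {
  # the Mir-71/Mir-2 shape: gaps 0.5, 1, 12.5, 0.8, 1.2 kb
  w <- 100L
  starts <- cumsum(c(1000L, w + 500L, w + 1000L, w + 12500L, w + 800L,
                     w + 1200L))
  loci <- GenomicRanges::GRanges("ctg",
    IRanges::IRanges(starts, width = w),
    names = sprintf("mir%d", 1:6))
  names(loci) <- sprintf("mir%d", 1:6)

  one <- detectClusters(loci, max_gap = 20000L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_members, 6L)

  two <- detectClusters(loci, max_gap = 10000L)
  expect_equal(nrow(two), 2L)
  expect_equal(two$n_members, c(3L, 3L))

  # single locus: no cluster
  expect_equal(nrow(detectClusters(loci[1], max_gap = 20000L)), 0L)

  # input order invariance
  shuf <- detectClusters(loci[c(4, 1, 6, 2, 5, 3)], max_gap = 20000L)
  expect_identical(shuf$members, one$members)

  # monotone in max_gap: clusters only merge as the gap grows
  for (cl in strsplit(two$members, ",")) {
    inside <- vapply(strsplit(one$members, ","), function(big)
      all(cl %in% big), TRUE)
    expect_true(any(inside))
  }
})

test_that("the cluster-length regression reports OLS and r-squared", {
  perfect <- clusterSizeRegression(
    data.frame(g = c(1, 2, 3), l = c(2, 4, 6)))
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$slope, 2)

  near <- clusterSizeRegression(
    data.frame(g = c(1, 2, 3), l = c(2, 3, 5)))
  expect_equal(near$r_squared, 27 / 28, tolerance = 1e-9)  # 0.964

  expect_error(clusterSizeRegression(
    data.frame(g = c(1, 1, 1), l = c(2, 3, 5))), "zero variance")
  expect_error(clusterSizeRegression(
    data.frame(g = c(1, 2), l = c(2, 3))), "3 points")
})

test_that("noisier cluster lengths weaken the fit in expectation", {
  set.seed(8)
  x <- c(0.12, 0.2, 0.3, 0.46, 0.72, 2.0)
  base <- 2 + 5 * x
  mean_r2 <- function(sigma) {
    mean(vapply(1:40, function(i) {
      clusterSizeRegression(
        data.frame(g = x, l = base + rnorm(6, 0, sigma)))$r_squared
    }, 0))
  }
  expect_gt(mean_r2(0.5), mean_r2(4))
})
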