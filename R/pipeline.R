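## End-to-end curation: counting, folding, homology, artifact detection
## and the bona-fide verdict for a set of candidates.

#' Curate a set of miRNA candidates
#'
#' Runs the full decision pipeline over all candidates: per-arm read
#' counting, precursor folding, assembly-artifact detection (when a
#' genome is supplied), conserved assignment against a reference
#' catalogue (when supplied), and the bona-fide filter.
#'
#' @param candidates list of [MiRNACandidate-class].
#' @param reads read data.frame (`sequence`, `count`, `library_id`).
#' @param libraries library data.frame (`library_id`, `condition`,
#'   `total_mapped_reads`).
#' @param genome optional named `DNAStringSet` (enables artifact
#'   detection).
#' @param reference optional named character vector of reference mature
#'   sequences (enables conserved assignment).
#' @param thresholds a [mirThresholds()].
#' @param backend folding backend, `"internal"` or `"external"`.
#' @return data.frame with one verdict row per candidate (see
#'   [applyBonaFideFilter()]); the per-candidate [HairpinFold-class]
#'   objects and count structures are attached as attributes `"folds"`
#'   and `"counts"`.
#' @examples
#' truth <- plantMirnaLoci(2, 1, 15000, rng_seed = 5)
#' sim <- simulateReadLibraries(truth, depth_per_locus = 100)
#' v <- curateMiRNAs(truth@candidates, sim$reads, sim$libraries)
#' v[, c("candidate_id", "status")]
#' @export
curateMiRNAs <- function(candidates, reads, libraries, genome = NULL,
                         reference = NULL,
                         thresholds = mirThresholds(),
                         backend = "internal") {
  validateLibraries(libraries)
  folds <- lapply(candidates, function(x)
    foldHairpin(precursorSeq(x), backend = backend))
  counts <- lapply(candidates, function(x)
    countArmReads(reads, x, libraries,
                  tolerance = thresholds$arm_tolerance))
  artifacts <- if (!is.null(genome))
    detectAssemblyArtifacts(candidates, genome,
                            thresholds$precursor_flank)
  else character(0)

  ctrl <- libraries$library_id[libraries$condition == "control"]
  conserved <- rep(NA_character_, length(candidates))
  if (!is.null(reference)) {
    matures <- vapply(seq_along(candidates), function(i) {
      e5 <- counts[[i]]$expr5p
      e3 <- counts[[i]]$expr3p
      if (sum(e5$counts[ctrl]) + sum(e3$counts[ctrl]) == 0)
        return(NA_character_)
      arm <- if (sum(e5$counts[ctrl]) >= sum(e3$counts[ctrl])) "5p"
             else "3p"
      armSeq(candidates[[i]], arm)
    }, "")
    ok <- !is.na(matures)
    if (any(ok))
      conserved[ok] <- assignConserved(matures[ok], reference,
                                       thresholds$align_min_cols,
                                       thresholds$align_max_mismatch)
  }

  rows <- lapply(seq_along(candidates), function(i)
    applyBonaFideFilter(
      candidates[[i]], counts[[i]], libraries, folds[[i]], thresholds,
      conserved_match = conserved[i],
      is_artifact = candidateId(candidates[[i]]) %in% artifacts
    ))
  verdicts <- do.call(rbind, rows)
  attr(verdicts, "folds") <- folds
  attr(verdicts, "counts") <- counts
  verdicts
}

#' Run the synthetic parameter-recovery experiment
#'
#' Plants loci, simulates libraries, curates, and scores recovery
#' against the known truth. Also selects negative-control regions and
#' reports their log2FC distribution.
#'
#' @param n_true,n_decoy,genome_length,knockdown_factor,rng_seed passed
#'   to [plantMirnaLoci()].
#' @param depth_per_locus passed to [simulateReadLibraries()].
#' @param thresholds a [mirThresholds()].
#' @return list with `truth`, `sim`, `verdicts`, `recovery` (fraction
#'   of true loci called `novel_bona_fide`), `decoy_rejected` (fraction
#'   of decoys not called `novel_bona_fide`), `decoy_flags` (data.frame
#'   of decoy mode vs per-criterion flags), `negctrl_log2fc` (numeric
#'   vector over negative-control regions).
#' @export
runSyntheticPipeline <- function(n_true = 10L, n_decoy = 10L,
                                 genome_length = 50000L,
                                 knockdown_factor = 0.25,
                                 depth_per_locus = 200L,
                                 rng_seed = 1L,
                                 thresholds = mirThresholds()) {
  truth <- plantMirnaLoci(n_true, n_decoy, genome_length, rng_seed,
                          knockdown_factor)
  sim <- simulateReadLibraries(truth, depth_per_locus,
                               rng_seed = rng_seed + 1L)
  verdicts <- curateMiRNAs(truth@candidates, sim$reads, sim$libraries,
                           genome = truth@genome,
                           thresholds = thresholds)
  is_true <- truth@labels == "true_mirna"
  recovery <- mean(verdicts$status[is_true] == "novel_bona_fide")
  decoy_rejected <- if (any(!is_true))
    mean(verdicts$status[!is_true] != "novel_bona_fide") else NA_real_

  flag_cols <- c("c1_both_arms", "c2_dicer_fc", "c3_5prime_homogeneity",
                 "c4_hairpin", "c5_energy", "c6_pairing", "c7_overhang")
  decoy_flags <- cbind(
    data.frame(candidate_id = verdicts$candidate_id[!is_true],
               decoy_mode = truth@decoyModes[!is_true],
               stringsAsFactors = FALSE),
    verdicts[!is_true, flag_cols, drop = FALSE]
  )

  aln <- mapReadsToGenome(sim$reads, truth@genome)
  excluded <- do.call(c, lapply(truth@candidates, precursorLocus))
  regions <- selectNegativeControls(truth@genome, sim$reads,
                                    sim$libraries, excluded,
                                    thresholds$neg_max_len,
                                    thresholds$neg_min_cov,
                                    alignments = aln)
  neg_fc <- regionLog2FC(regions, aln, sim$libraries,
                         thresholds$pseudocount)
  list(truth = truth, sim = sim, verdicts = verdicts,
       recovery = recovery, decoy_rejected = decoy_rejected,
       decoy_flags = decoy_flags, negctrl_regions = regions,
       negctrl_log2fc = neg_fc)
}
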