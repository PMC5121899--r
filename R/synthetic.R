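## Seeded synthetic data: a toy genome with planted true-miRNA hairpins
## and per-criterion decoy loci, plus simulated control / Dicer-1-depleted
## read libraries with a known knockdown effect.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.DECOY_MODES <- c("no_star_reads", "bad_fold", "low_pairing",
                  "no_overhang", "dicer_independent")

.revcompChars <- function(ch) rev(chartr("ACGT", "TGCA", ch))

#' SyntheticTruth: planted loci with known labels
#'
#' The ground truth of one synthetic dataset: the toy genome, the
#' planted candidate loci, per-locus labels (`true_mirna` or `decoy`),
#' the decoy mode each decoy violates, the designated mature arm used
#' by the read simulator, and the knockdown factor applied to
#' Dicer-1-dependent loci in depleted libraries.
#'
#' @slot genome a one-sequence [Biostrings::DNAStringSet].
#' @slot candidates list of [MiRNACandidate-class].
#' @slot labels `"true_mirna"` or `"decoy"` per candidate.
#' @slot decoyModes decoy mode per candidate (`NA` for true loci).
#' @slot matureArms `"5p"`/`"3p"` per candidate.
#' @slot knockdownFactor depleted/control expression ratio in (0, 1].
#' @slot rngSeed the seed the dataset is a deterministic function of.
#' @seealso [plantMirnaLoci()], [simulateReadLibraries()]
#' @export
setClass("SyntheticTruth",
  representation(
    genome = "DNAStringSet",
    candidates = "list",
    labels = "character",
    decoyModes = "character",
    matureArms = "character",
    knockdownFactor = "numeric",
    rngSeed = "integer"
  )
)

setValidity("SyntheticTruth", function(object) {
  n <- length(object@candidates)
  msg <- character()
  if (length(object@labels) != n || length(object@decoyModes) != n ||
      length(object@matureArms) != n)
    msg <- c(msg, "per-candidate annotation lengths must match")
  if (!all(object@labels %in% c("true_mirna", "decoy")))
    msg <- c(msg, "labels must be 'true_mirna' or 'decoy'")
  if (object@knockdownFactor <= 0 || object@knockdownFactor > 1)
    msg <- c(msg, "knockdownFactor must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth: ", sum(object@labels == "true_mirna"), " true + ",
      sum(object@labels == "decoy"), " decoy loci on a ",
      nchar(object@genome[[1L]]), " nt genome (knockdown factor ",
      object@knockdownFactor, ", seed ", object@rngSeed, ")\n", sep = "")
})

# One synthetic hairpin in transcript coordinates. The duplex stem is a
# perfect reverse complement (pair i <-> L-1-i); the loop and all
# deliberately unpaired letters are drawn from {A, C}, a mutually
# non-pairing alphabet (no Watson-Crick, no GU), so the max-pairing fold
# is the designed structure.
.makeHairpin <- function(mode, alen, lp) {
  stem <- sample(c("A", "C", "G", "T"), alen + 2L, replace = TRUE)
  inert <- function(k) sample(c("A", "C"), k, replace = TRUE)
  if (mode == "bad_fold") {
    # two side-branch hairpins inside the main loop -> two terminal loops
    branch <- function() {
      b <- sample(c("A", "C", "G", "T"), 6L, replace = TRUE)
      c(b, inert(4L), .revcompChars(b))
    }
    loop <- c(inert(3L), branch(), inert(3L), branch(), inert(3L))
  } else {
    loop <- inert(lp)
  }
  chars <- c(stem, loop, .revcompChars(stem))
  L <- length(chars)
  arm5p <- c(2L, 2L + alen)
  arm3p <- if (mode == "no_overhang") c(L - alen - 2L, L - 2L)
           else c(L - alen, L)
  if (mode == "low_pairing") {
    # reduce the mature/star duplex to exactly 16 paired bases via one
    # symmetric internal loop: the 5p side becomes A, its partner C
    # (A and C pair with nothing else present in the construction).
    # An intact duplex pairs alen - 2 bases (each arm's 2-nt 3'
    # overhang pairs outside the other arm), hence alen - 18 mismatches.
    n_mm <- alen - 18L
    mm <- 5L + seq_len(n_mm)        # contiguous interior block, 0-based
    chars[mm + 1L] <- "A"
    chars[L - mm] <- "C"            # partner of position mm is L-1-mm
  }
  list(seq = paste(chars, collapse = ""), arm5p = arm5p, arm3p = arm3p,
       length = L)
}

.expectedStructFlags <- function(mode) {
  switch(mode,
    bad_fold = c(c4_hairpin = FALSE, c5_energy = TRUE, c6_pairing = TRUE,
                 c7_overhang = TRUE),
    low_pairing = c(c4_hairpin = TRUE, c5_energy = TRUE, c6_pairing = FALSE,
                    c7_overhang = TRUE),
    no_overhang = c(c4_hairpin = TRUE, c5_energy = TRUE, c6_pairing = TRUE,
                    c7_overhang = FALSE),
    c(c4_hairpin = TRUE, c5_energy = TRUE, c6_pairing = TRUE,
      c7_overhang = TRUE)  # true_mirna, no_star_reads, dicer_independent
  )
}

#' Plant miRNA hairpins and decoy loci in a toy genome
#'
#' Generates a random genome and plants `n_true` structurally valid
#' miRNA hairpins (>= 17 mature/star paired bases, a 2-nt 3' overhang on
#' each arm, terminal loop well inside 8-40 nt, free energy far below
#' -22 kcal/mol) and `n_decoy` decoys, each violating exactly one named
#' criterion. Every drawn hairpin is folded and checked against its
#' expected criterion pattern before acceptance, so the construction is
#' valid for any seed. Loci are spaced by at least 100 nt and the whole
#' dataset is a deterministic function of `rng_seed`.
#'
#' Decoy modes: `no_star_reads` and `dicer_independent` are structurally
#' perfect (they fail at the expression stage); `bad_fold` carries two
#' side-branch hairpins (not a single-stem hairpin); `low_pairing` has a
#' mature/star duplex of exactly 16 paired bases; `no_overhang` has a
#' blunt-ended duplex.
#'
#' @param n_true,n_decoy numbers of true and decoy loci.
#' @param genome_length toy genome length, nt.
#' @param rng_seed integer seed.
#' @param knockdown_factor depleted/control ratio in (0, 1] applied to
#'   Dicer-1-dependent loci by [simulateReadLibraries()].
#' @param decoy_modes decoy modes to cycle through (defaults to all
#'   five).
#' @return a [SyntheticTruth-class].
#' @examples
#' truth <- plantMirnaLoci(3, 2, 20000, rng_seed = 1)
#' truth
#' @export
plantMirnaLoci <- function(n_true, n_decoy, genome_length, rng_seed,
                           knockdown_factor = 0.25,
                           decoy_modes = .DECOY_MODES) {
  stopifnot(n_true >= 0, n_decoy >= 0, n_true + n_decoy > 0)
  if (!all(decoy_modes %in% .DECOY_MODES))
    stop("unknown decoy mode(s): ",
         paste(setdiff(decoy_modes, .DECOY_MODES), collapse = ", "))
  .withSeed(rng_seed, {
    modes <- c(rep("true_mirna", n_true),
               rep(decoy_modes, length.out = n_decoy))
    modes <- sample(modes)  # interleave true and decoy loci
    n <- length(modes)
    hairpins <- vector("list", n)
    mature_arms <- character(n)
    for (i in seq_len(n)) {
      mode <- if (modes[i] == "true_mirna") "true_mirna" else modes[i]
      hp_mode <- if (mode %in% c("true_mirna", "no_star_reads",
                                 "dicer_independent")) "plain" else mode
      expected <- .expectedStructFlags(mode)
      ok <- FALSE
      for (attempt in seq_len(200L)) {
        alen <- sample(20:25, 1L, prob = c(.10, .20, .35, .20, .10, .05))
        lp <- sample(10:20, 1L, prob = c(1, 2, 3, 4, 6, 6, 4, 3, 2, 1, 1))
        hp <- .makeHairpin(hp_mode, alen, lp)
        fold <- foldHairpin(hp$seq)
        ev <- evaluateHairpinCriteria(fold, hp$arm5p, hp$arm3p)
        if (identical(unname(ev$flags), unname(expected))) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not construct a hairpin for mode '", mode,
             "' within 200 attempts")
      hairpins[[i]] <- hp
      mature_arms[i] <- sample(c("5p", "3p"), 1L, prob = c(0.4, 0.6))
    }
    # placement with >= 100 nt spacing (and 100 nt margins)
    gaps <- 100L + sample.int(51L, n, replace = TRUE) - 1L
    lens <- vapply(hairpins, `[[`, 0L, "length")
    starts <- 100L + cumsum(gaps) - gaps[1L] + cumsum(c(0L, lens[-n]))
    if (starts[n] + lens[n] + 100L > genome_length)
      stop("capacity error: ", n, " loci do not fit in a ",
           genome_length, " nt genome with 100 nt spacing")
    g <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)
    cands <- vector("list", n)
    for (i in seq_len(n)) {
      hp <- hairpins[[i]]
      idx <- (starts[i] + 1L):(starts[i] + hp$length)
      g[idx] <- strsplit(hp$seq, "")[[1L]]
      cands[[i]] <- newMiRNACandidate(
        sprintf("synth-%02d", i), "toy_contig", starts[i],
        starts[i] + hp$length, "+", hp$seq, hp$arm5p, hp$arm3p,
        sourceTags = "synthetic"
      )
    }
    genome <- DNAStringSet(setNames(paste(g, collapse = ""), "toy_contig"))
    new("SyntheticTruth",
        genome = genome, candidates = cands,
        labels = ifelse(modes == "true_mirna", "true_mirna", "decoy"),
        decoyModes = ifelse(modes == "true_mirna", NA_character_, modes),
        matureArms = mature_arms,
        knockdownFactor = knockdown_factor,
        rngSeed = as.integer(rng_seed))
  })
}

.sampleArmReads <- function(candidate, arm, lambda, floor_one) {
  # read variants around the arm 5' end: modal start with +-1 nt isomiR
  # wobble (modal fraction 0.8) and small length variation
  iv <- armInterval(candidate, arm)
  L <- nchar(precursorSeq(candidate))
  alen <- iv[2L] - iv[1L]
  offs <- c(0L, -1L, 1L)
  p_off <- c(0.80, 0.10, 0.10)
  dls <- c(0L, -1L, 1L)
  p_dl <- c(0.70, 0.15, 0.15)
  probs <- as.vector(outer(p_off, p_dl))
  combos <- expand.grid(off = offs, dl = dls)
  n_total <- rpois(1L, lambda)
  if (floor_one) n_total <- max(1L, n_total)
  if (n_total == 0L) return(NULL)
  counts <- as.vector(stats::rmultinom(1L, n_total, probs))
  keep <- counts > 0L
  if (!any(keep)) return(NULL)
  combos <- combos[keep, , drop = FALSE]
  counts <- counts[keep]
  start <- pmax(iv[1L] + combos$off, 0L)
  len <- pmin(alen + combos$dl, L - start)
  # guarantee the modal variant for floored arms
  data.frame(
    sequence = substr(rep(precursorSeq(candidate), length(counts)),
                      start + 1L, start + len),
    count = counts,
    stringsAsFactors = FALSE
  )
}

#' Simulate control and Dicer-1-depleted read libraries
#'
#' True-miRNA arms receive on average `depth_per_locus` reads on the
#' mature arm (and 35% of that on the star arm) in every control
#' library, and `knockdownFactor(truth) * depth` in depleted libraries;
#' `dicer_independent` decoys keep full depth in both conditions and
#' `no_star_reads` decoys never emit star-arm reads. Both arms of every
#' true locus are guaranteed at least one read in every control library.
#' A Dicer-independent background is layered on top: densely tiled
#' windows (negative-control material: several regions shorter than
#' 500 nt covered at least 10-fold in each control library) plus a
#' scattered low-complexity background, all placed at least 50 nt away
#' from planted loci. Background dominates the library so that planted
#' miRNAs are a realistic minority of mapped reads.
#'
#' @param truth a [SyntheticTruth-class].
#' @param depth_per_locus expected mature-arm reads per control library
#'   (>= 10).
#' @param n_control,n_depleted library counts (`n_control >= 2`: the
#'   control-support filter needs two control libraries).
#' @param rng_seed integer seed.
#' @param n_windows,window_cov tiled negative-control windows and the
#'   expected per-read multiplicity in them.
#' @param n_scatter,scatter_mult scattered background positions and
#'   their expected multiplicity.
#' @return list with `libraries` (data.frame: `library_id`, `condition`,
#'   `total_mapped_reads`) and `reads` (data.frame: `sequence`, `count`,
#'   `library_id`); the tiled window loci are attached as the
#'   `"background_windows"` attribute (a [GenomicRanges::GRanges]).
#' @export
simulateReadLibraries <- function(truth, depth_per_locus,
                                  n_control = 2L, n_depleted = 2L,
                                  rng_seed = truth@rngSeed + 1L,
                                  n_windows = 5L, window_cov = 25,
                                  n_scatter = 3000L, scatter_mult = 20) {
  if (n_control < 2L)
    stop("configuration error: need at least two control libraries")
  if (depth_per_locus < 10) stop("depth_per_locus must be >= 10")
  .withSeed(rng_seed, {
    libs <- data.frame(
      library_id = c(sprintf("ctrl_%d", seq_len(n_control)),
                     sprintf("dd_%d", seq_len(n_depleted))),
      condition = c(rep("control", n_control),
                    rep("dicer_depleted", n_depleted)),
      stringsAsFactors = FALSE
    )
    kf <- truth@knockdownFactor
    gseq <- as.character(truth@genome[[1L]])
    glen <- nchar(gseq)

    # free space (>= 50 nt away from planted loci) for background
    occ <- rep(FALSE, glen)
    for (cand in truth@candidates) {
      lo <- max(1L, cand@precursorStart + 1L - 50L)
      hi <- min(glen, cand@precursorEnd + 50L)
      occ[lo:hi] <- TRUE
    }
    free_runs <- IRanges(Rle(!occ))
    free_runs <- free_runs[width(free_runs) >= 400L]
    # candidate window slots: tile the free runs in 400 nt steps
    slots <- unlist(lapply(seq_along(free_runs), function(i) {
      seq(start(free_runs)[i] + 30L, end(free_runs)[i] - 330L, by = 400L)
    }))
    if (length(slots) < n_windows)
      stop("genome too crowded for ", n_windows, " background windows")
    win_start <- sort(sample(slots, n_windows))  # 1-based genome coords
    win_w <- sample(220:300, n_windows, replace = TRUE)
    windows <- GRanges("toy_contig",
                       IRanges(win_start, width = win_w))
    # scatter positions avoid planted loci as well
    free_pos <- which(!occ)
    free_pos <- free_pos[free_pos + 24L <= glen]
    scatter_pos <- sample(free_pos, min(n_scatter, length(free_pos)))
    scatter_len <- sample(20:24, length(scatter_pos), replace = TRUE)

    all_reads <- vector("list", nrow(libs))
    for (li in seq_len(nrow(libs))) {
      is_ctrl <- libs$condition[li] == "control"
      parts <- list()
      for (ci in seq_along(truth@candidates)) {
        cand <- truth@candidates[[ci]]
        mode <- truth@decoyModes[ci]
        dicer_dep <- is.na(mode) || mode != "dicer_independent"
        fac <- if (is_ctrl || !dicer_dep) 1 else kf
        mature <- truth@matureArms[ci]
        star <- if (mature == "5p") "3p" else "5p"
        floor_one <- is_ctrl
        parts[[length(parts) + 1L]] <-
          .sampleArmReads(cand, mature, depth_per_locus * fac, floor_one)
        if (is.na(mode) || mode != "no_star_reads")
          parts[[length(parts) + 1L]] <-
            .sampleArmReads(cand, star, 0.35 * depth_per_locus * fac,
                            floor_one)
      }
      # tiled background windows (Dicer-independent by construction)
      for (wi in seq_along(windows)) {
        st <- seq(start(windows)[wi], end(windows)[wi] - 22L, by = 5L)
        cnt <- rpois(length(st), window_cov)
        keep <- cnt > 0L
        parts[[length(parts) + 1L]] <- data.frame(
          sequence = substr(rep(gseq, sum(keep)), st[keep],
                            st[keep] + 21L),
          count = cnt[keep], stringsAsFactors = FALSE
        )
      }
      cnt <- rpois(length(scatter_pos), scatter_mult)
      keep <- cnt > 0L
      parts[[length(parts) + 1L]] <- data.frame(
        sequence = substr(rep(gseq, sum(keep)), scatter_pos[keep],
                          scatter_pos[keep] + scatter_len[keep] - 1L),
        count = cnt[keep], stringsAsFactors = FALSE
      )
      rd <- do.call(rbind, parts)
      rd <- stats::aggregate(count ~ sequence, rd, sum)
      rd$library_id <- libs$library_id[li]
      all_reads[[li]] <- rd
    }
    reads <- do.call(rbind, all_reads)
    rownames(reads) <- NULL
    totals <- tapply(reads$count, reads$library_id, sum)
    libs$total_mapped_reads <- as.integer(totals[libs$library_id])
    structure(list(libraries = libs, reads = reads),
              background_windows = windows)
  })
}

#' Generate mock miRNA sequences
#'
#' Draws `n` distinct uniform-random sequences that neither appear in
#' `exclude` nor share a seed (positions 2-7) with any excluded
#' sequence. Used as the null baseline for target-count comparisons.
#'
#' @param n number of sequences.
#' @param length sequence length, nt (the published baseline used 100
#'   mock miRNAs; both the 20-nt and 22-nt variants are supported).
#' @param rng_seed integer seed.
#' @param exclude character vector of sequences to avoid.
#' @return character vector of `n` sequences.
#' @examples
#' generateMockSequences(5, 22, rng_seed = 7)
#' @export
generateMockSequences <- function(n, length, rng_seed,
                                  exclude = character()) {
  stopifnot(n >= 1, length >= 1)
  exclude <- toupper(chartr("Uu", "Tt", exclude))
  excl_seeds <- if (length >= 7L)
    unique(substr(exclude[nchar(exclude) >= 7L], 2L, 7L)) else character()
  .withSeed(rng_seed, {
    out <- character(0)
    attempts <- 0L
    max_attempts <- max(1000L, 50L * n)
    while (length(out) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
      if (s %in% out || s %in% exclude) next
      if (length >= 7L && substr(s, 2L, 7L) %in% excl_seeds) next
      out <- c(out, s)
    }
    if (length(out) < n)
      stop("generation error: could not draw ", n,
           " admissible sequences (exclusion too restrictive)")
    out
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes the genome FASTA, a truth GFF3 (with `label` and `decoy_mode`
#' attributes), one collapsed FASTA per library, and the libraries TSV.
#'
#' @param truth a [SyntheticTruth-class].
#' @param sim result of [simulateReadLibraries()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticData <- function(truth, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(truth@genome, file.path(dir, "genome.fa"))
  writeCandidateGff(truth@candidates, file.path(dir, "truth.gff3"),
                    labels = truth@labels, decoy_modes = truth@decoyModes)
  for (lib in sim$libraries$library_id) {
    rd <- sim$reads[sim$reads$library_id == lib, ]
    writeCollapsedFasta(rd, file.path(dir, paste0(lib, ".fa")))
  }
  writeLibrariesTsv(sim$libraries, file.path(dir, "libraries.tsv"))
  invisible(dir)
}
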