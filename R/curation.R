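## The decision core: conserved assignment by homology, assembly-artifact
## detection, arm designation, seed/family grouping, and the bona-fide
## verdict combining the expression and structure criteria.

# longest run with at most max_mm mismatches (two-pointer)
.longestRun <- function(mismatch, max_mm) {
  best_len <- 0L
  best_mm <- 0L
  lo <- 1L
  mm <- 0L
  for (hi in seq_along(mismatch)) {
    if (mismatch[hi]) mm <- mm + 1L
    while (mm > max_mm) {
      if (mismatch[lo]) mm <- mm - 1L
      lo <- lo + 1L
    }
    len <- hi - lo + 1L
    if (len > best_len || (len == best_len && mm < best_mm)) {
      best_len <- len
      best_mm <- mm
    }
  }
  c(len = best_len, mm = best_mm)
}

# best ungapped local alignment between two sequences over all shifts
.bestUngapped <- function(a, b, max_mm) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  na <- length(ca)
  nb <- length(cb)
  best <- c(len = 0L, mm = 0L)
  for (s in (-(na - 1L)):(nb - 1L)) {
    ia <- max(1L, 1L - s):min(na, nb - s)
    if (!length(ia)) next
    mism <- ca[ia] != cb[ia + s]
    r <- .longestRun(mism, max_mm)
    if (r["len"] > best["len"] ||
        (r["len"] == best["len"] && r["mm"] < best["mm"]))
      best <- r
  }
  best
}

#' Assign candidates to conserved miRNAs by homology
#'
#' A candidate mature is conserved when some ungapped local alignment
#' to a reference mature spans at least `min_cols` columns ("longer
#' than 18 nucleotides") with at most `max_mismatch` mismatches. The
#' best match is the longest alignment; ties break by fewer mismatches,
#' then by lexicographic reference name.
#'
#' @param candidate_matures character vector (optionally named) of
#'   candidate mature sequences.
#' @param reference_matures named character vector: reference name ->
#'   mature sequence.
#' @param min_cols,max_mismatch the homology rule (defaults 19 / 1).
#' @return character vector parallel to `candidate_matures`: the best
#'   reference name, or `NA` when not conserved.
#' @examples
#' ref <- c(`Mir-1` = "TGGAATGTAAAGAAGTATGGAG")
#' assignConserved("TGGAATGTAAAGAAGTATGGAG", ref)
#' @export
assignConserved <- function(candidate_matures, reference_matures,
                            min_cols = 19L, max_mismatch = 1L) {
  if (!length(reference_matures)) stop("empty reference catalogue")
  refn <- sort(names(reference_matures))
  cand <- toupper(chartr("Uu", "Tt", candidate_matures))
  refs <- toupper(chartr("Uu", "Tt", reference_matures[refn]))
  out <- rep(NA_character_, length(cand))
  for (i in seq_along(cand)) {
    best <- c(len = 0L, mm = 0L)
    best_ref <- NA_character_
    for (r in seq_along(refs)) {
      sc <- .bestUngapped(cand[i], refs[r], max_mismatch)
      if (sc["len"] > best["len"] ||
          (sc["len"] == best["len"] && sc["mm"] < best["mm"])) {
        best <- sc
        best_ref <- refn[r]
      }
    }
    if (best["len"] >= min_cols) out[i] <- best_ref
  }
  names(out) <- names(candidate_matures)
  out
}

#' Detect genome-assembly artifacts among candidates
#'
#' Candidates sharing an identical precursor sequence are suspects:
#' for each such pair the precursor plus `flank` nucleotides of genomic
#' context is compared, and perfect identity of the extended precursors
#' marks an assembly artifact. The lowest-coordinate copy is retained;
#' the other is flagged. When a locus sits closer than `flank` to a
#' contig end, both extensions are truncated symmetrically and the
#' truncation recorded.
#'
#' @param candidates list of [MiRNACandidate-class].
#' @param genome named `DNAStringSet`.
#' @param flank flanking nucleotides (default 50).
#' @return character vector of artifact candidate ids; the compared
#'   pairs are attached as the `"pairs"` attribute (data.frame with
#'   `kept`, `artifact`, `truncated`).
#' @export
detectAssemblyArtifacts <- function(candidates, genome, flank = 50L) {
  ids <- vapply(candidates, candidateId, "")
  precs <- vapply(candidates, precursorSeq, "")
  arts <- character(0)
  pairs <- data.frame(kept = character(), artifact = character(),
                      truncated = logical(), stringsAsFactors = FALSE)
  for (seqv in unique(precs[duplicated(precs)])) {
    grp <- which(precs == seqv)
    # order by genomic coordinate: lowest kept
    ord <- grp[order(vapply(candidates[grp], function(x) x@seqId, ""),
                     vapply(candidates[grp], function(x) x@precursorStart,
                            0L))]
    ext <- function(i) {
      x <- candidates[[i]]
      glen <- nchar(as.character(genome[[x@seqId]]))
      f <- min(flank, x@precursorStart, glen - x@precursorEnd)
      s <- substr(as.character(genome[[x@seqId]]),
                  x@precursorStart - f + 1L, x@precursorEnd + f)
      if (x@strand == "-")
        s <- as.character(reverseComplement(DNAString(s)))
      list(seq = s, f = f)
    }
    for (a in seq_along(ord)[-1L]) {
      for (b in seq_len(a - 1L)) {
        ea <- ext(ord[a])
        eb <- ext(ord[b])
        f <- min(ea$f, eb$f)
        trim <- function(e) substr(e$seq, e$f - f + 1L,
                                   nchar(e$seq) - (e$f - f))
        if (identical(trim(ea), trim(eb))) {
          arts <- union(arts, ids[ord[a]])
          pairs <- rbind(pairs, data.frame(
            kept = ids[ord[b]], artifact = ids[ord[a]],
            truncated = f < flank, stringsAsFactors = FALSE))
        }
      }
    }
  }
  structure(arts, pairs = pairs)
}

#' Designate the mature arm (or co-maturity)
#'
#' Arm totals are summed over control libraries; the ratio of the more
#' to the less abundant arm (floored at one read) decides: ratio below
#' `ratio_threshold` (default 2) means both arms are co-mature,
#' otherwise the higher-count arm is the mature one.
#'
#' @param expr5p,expr3p `ArmExpression` objects.
#' @param control_libs character vector of control library ids.
#' @param ratio_threshold co-maturity threshold.
#' @return `"5p"`, `"3p"`, or `"co-mature"`.
#' @export
designateArms <- function(expr5p, expr3p, control_libs,
                          ratio_threshold = 2) {
  t5 <- sum(expr5p$counts[control_libs])
  t3 <- sum(expr3p$counts[control_libs])
  if (t5 == 0 && t3 == 0)
    stop("contract error: no control reads on either arm")
  ratio <- max(t5, t3) / max(1, min(t5, t3))
  if (ratio < ratio_threshold) "co-mature"
  else if (t5 >= t3) "5p" else "3p"
}

#' 5' homogeneity of arm reads
#'
#' Fraction of arm reads whose 5' end sits at the modal offset;
#' criterion 3 requires this fraction to reach a configurable
#' threshold (default 0.66; the published rule is qualitative).
#'
#' @param offsets integer vector of per-read 5' offsets from the arm
#'   start (parallel to `counts`), or a data.frame with `offset` and
#'   `count`.
#' @param counts collapsed multiplicities.
#' @param threshold minimum modal fraction.
#' @return list with `fraction` and logical `pass`.
#' @export
fivePrimeHomogeneity <- function(offsets, counts = NULL,
                                 threshold = 0.66) {
  if (is.data.frame(offsets)) {
    counts <- offsets$count
    offsets <- offsets$offset
  }
  if (!length(offsets) || sum(counts) == 0)
    stop("no reads on arm")
  per_off <- tapply(counts, offsets, sum)
  fraction <- max(per_off) / sum(per_off)
  list(fraction = unname(fraction), pass = fraction >= threshold)
}

#' Extract the seed from a mature sequence
#'
#' @param mature mature sequence.
#' @param positions 1-based inclusive positions, default 2-7 (the
#'   hexamer that defines family identity).
#' @return the seed string.
#' @examples
#' extractSeed("ATGAAATGGACGATTGGCTGTG")  # "TGAAAT"
#' @export
extractSeed <- function(mature, positions = c(2L, 7L)) {
  if (any(nchar(mature) < positions[2L]))
    stop("contract error: mature shorter than the seed window")
  substr(mature, positions[1L], positions[2L])
}

#' Group miRNA genes into seed families
#'
#' Genes are partitioned by exact seed identity. Conserved genes keep
#' their reference family name; novel families are named
#' `MIR-<species_code><k>` with `k` assigned by decreasing expression
#' of the family's most abundant member (the most abundantly expressed
#' novel gene founds family 1), falling back to input order when no
#' expression is supplied.
#'
#' @param genes data.frame with columns `name` and `mature`; an
#'   optional `family` column carries reference family names for
#'   conserved genes (`NA` for novel ones).
#' @param seed_positions 1-based inclusive seed window.
#' @param species_code code used in novel family names (default
#'   `"bg"`).
#' @param expression optional named numeric vector (gene name -> total
#'   expression) used to order novel families.
#' @return data.frame with `name`, `mature`, `seed`, `family`; one row
#'   per gene, each gene in exactly one family.
#' @export
groupFamilies <- function(genes, seed_positions = c(2L, 7L),
                          species_code = "bg", expression = NULL) {
  stopifnot(all(c("name", "mature") %in% names(genes)))
  seeds <- extractSeed(genes$mature, seed_positions)
  fam_ref <- if ("family" %in% names(genes)) genes$family
             else rep(NA_character_, nrow(genes))
  useed <- unique(seeds)
  fam_name <- setNames(rep(NA_character_, length(useed)), useed)
  # conserved seeds inherit the (first) reference family name
  for (s in useed) {
    known <- fam_ref[seeds == s]
    known <- known[!is.na(known)]
    if (length(known)) fam_name[s] <- known[1L]
  }
  novel <- useed[is.na(fam_name[useed])]
  if (length(novel)) {
    score <- if (is.null(expression)) {
      # input order: earlier first member -> smaller number
      -vapply(novel, function(s) min(which(seeds == s)), 0L)
    } else {
      vapply(novel, function(s)
        max(expression[genes$name[seeds == s]], na.rm = TRUE), 0)
    }
    ord <- novel[order(score, decreasing = TRUE)]
    fam_name[ord] <- sprintf("MIR-%s%d", species_code,
                             seq_along(ord))
  }
  data.frame(name = genes$name, mature = genes$mature, seed = seeds,
             family = unname(fam_name[seeds]), stringsAsFactors = FALSE)
}

#' Assemble the per-criterion flags of the bona-fide filter
#'
#' The numeric-to-flag step shared by [applyBonaFideFilter()]:
#' criterion 2 passes when the mature-arm log2FC is strictly below the
#' threshold (-0.5), criterion 3 when the modal-5'-offset fraction
#' reaches the homogeneity threshold; the structural flags c4-c7 come
#' from [evaluateHairpinCriteria()].
#'
#' @param log2fc mature-arm log2 fold change.
#' @param homogeneity_fraction modal 5'-offset fraction.
#' @param structural named logical vector with `c4_hairpin`,
#'   `c5_energy`, `c6_pairing`, `c7_overhang`.
#' @param thresholds a [mirThresholds()].
#' @return named logical vector `c2_dicer_fc`, `c3_5prime_homogeneity`,
#'   `c4_hairpin`, `c5_energy`, `c6_pairing`, `c7_overhang`.
#' @export
criterionFlags <- function(log2fc, homogeneity_fraction, structural,
                           thresholds = mirThresholds()) {
  c(c2_dicer_fc = !is.na(log2fc) && log2fc < thresholds$fc,
    c3_5prime_homogeneity = !is.na(homogeneity_fraction) &&
      homogeneity_fraction >= thresholds$homogeneity,
    structural[c("c4_hairpin", "c5_energy", "c6_pairing", "c7_overhang")])
}

#' Apply the bona-fide filter to one candidate
#'
#' Combines all criteria into a verdict: c1 (expression on both arms in
#' any library), c2 (log2FC under Dicer-1 depletion strictly below
#' -0.5 on the mature arm), c3 (5' read homogeneity), c4-c7 (hairpin
#' structure), the control-support filter, and the assembly-artifact
#' flag. Candidates matching a conserved reference bypass c2-c7 (they
#' are validated by homology) and are reported as `conserved`;
#' otherwise the status is `novel_bona_fide` iff every flag is true,
#' `artifact` when flagged as one, and `rejected` otherwise.
#'
#' @param candidate a [MiRNACandidate-class].
#' @param counts result of [countArmReads()] for this candidate
#'   (counted with `libraries` so that RPM is available).
#' @param libraries library data.frame.
#' @param fold [HairpinFold-class] of the precursor.
#' @param thresholds a [mirThresholds()].
#' @param conserved_match reference name when the candidate is
#'   conserved, `NA` otherwise.
#' @param is_artifact logical from [detectAssemblyArtifacts()].
#' @return one-row data.frame: `candidate_id`, the nine flags,
#'   `mature_arm`, `log2fc`, `conserved_match`, `status`.
#' @export
applyBonaFideFilter <- function(candidate, counts, libraries, fold,
                                thresholds = mirThresholds(),
                                conserved_match = NA_character_,
                                is_artifact = FALSE) {
  if (is.null(counts$expr5p) || is.null(counts$expr3p))
    stop("dependency error: arm counts missing (run countArmReads)")
  if (is.null(fold))
    stop("dependency error: precursor fold missing (run foldHairpin)")
  ctrl <- libraries$library_id[libraries$condition == "control"]
  e5 <- counts$expr5p
  e3 <- counts$expr3p
  c1 <- sum(e5$counts) > 0 && sum(e3$counts) > 0
  support <- supportFilter(e5, e3, ctrl)

  mature_arm <- NA_character_
  log2fc <- NA_real_
  hom_frac <- NA_real_
  if (sum(e5$counts[ctrl]) + sum(e3$counts[ctrl]) > 0) {
    des <- designateArms(e5, e3, ctrl, thresholds$co_mature_ratio)
    mature_arm <- des
    # for co-mature duplexes the more abundant arm carries the fc test
    fc_arm <- if (des == "co-mature") {
      if (sum(e5$counts[ctrl]) >= sum(e3$counts[ctrl])) "5p" else "3p"
    } else des
    expr_m <- if (fc_arm == "5p") e5 else e3
    log2fc <- computeLog2FC(expr_m, libraries,
                            thresholds$pseudocount)$log2fc
    offs <- counts$assignments[counts$assignments$arm == fc_arm, ,
                               drop = FALSE]
    if (nrow(offs))
      hom_frac <- fivePrimeHomogeneity(offs$offset, offs$count,
                                       thresholds$homogeneity)$fraction
  } else {
    fc_arm <- NA_character_
  }

  mat_iv <- if (!is.na(fc_arm) && fc_arm == "3p")
    armInterval(candidate, "3p") else armInterval(candidate, "5p")
  star_iv <- if (!is.na(fc_arm) && fc_arm == "3p")
    armInterval(candidate, "5p") else armInterval(candidate, "3p")
  ev <- evaluateHairpinCriteria(fold, mat_iv, star_iv, thresholds)
  flags <- c(
    c1_both_arms = c1,
    criterionFlags(log2fc, hom_frac, ev$flags, thresholds),
    support_controls = support,
    not_artifact = !is_artifact
  )
  status <- if (is_artifact) "artifact"
    else if (!is.na(conserved_match)) "conserved"
    else if (all(flags)) "novel_bona_fide"
    else "rejected"
  out <- data.frame(candidate_id = candidateId(candidate),
                    as.data.frame(t(flags)),
                    mature_arm = mature_arm, log2fc = log2fc,
                    conserved_match = conserved_match, status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[2:10] <- names(flags)
  out
}
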