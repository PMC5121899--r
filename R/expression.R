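## Per-arm read counting, RPM normalisation, the Dicer-1 knockdown
## log2 fold change, the control-support filter, and negative-control
## baseline regions.

#' Count reads on the two arms of a candidate
#'
#' A read is assigned to an arm when its 5' end lies within `tolerance`
#' nt of the arm's 5' end (isomiR wobble) and the read is fully
#' contained in the precursor. Assignment is by exact sequence identity
#' against the precursor; collapsed multiplicities are summed. Each
#' distinct read sequence is assigned at most once per candidate (the
#' smallest 5' offset wins, 5p before 3p on ties).
#'
#' @param reads data.frame with `sequence`, `count`, `library_id`.
#' @param candidate a [MiRNACandidate-class].
#' @param libraries optional library data.frame (adds RPM).
#' @param tolerance allowed 5'-end offset, nt.
#' @param read_length admissible read lengths.
#' @return list with `expr5p` and `expr3p` (each a list holding
#'   `candidate_id`, `arm`, per-library `counts` and, when `libraries`
#'   is given, `rpm`) and `assignments` (per-read detail:
#'   `sequence`, `arm`, `offset`, `library_id`, `count`).
#' @export
countArmReads <- function(reads, candidate, libraries = NULL,
                          tolerance = 2L, read_length = c(16L, 30L)) {
  if (any(is.na(armInterval(candidate, "5p"))))
    stop("contract error: candidate arms undefined")
  prec <- precursorSeq(candidate)
  L <- nchar(prec)
  lib_ids <- if (is.null(libraries)) unique(reads$library_id)
             else libraries$library_id

  # enumerate admissible arm-anchored substrings, nearest offsets first
  combos <- expand.grid(
    off = order_offsets <- c(0L, as.vector(rbind(-seq_len(tolerance),
                                                 seq_len(tolerance)))),
    arm = c("5p", "3p"), stringsAsFactors = FALSE
  )
  assigned <- list()
  seen <- character(0)
  for (k in seq_len(nrow(combos))) {
    arm <- combos$arm[k]
    iv <- armInterval(candidate, arm)
    p <- iv[1L] + combos$off[k]
    if (p < 0L) next
    lens <- read_length[1L]:read_length[2L]
    lens <- lens[p + lens <= L]
    if (!length(lens)) next
    keys <- substr(rep(prec, length(lens)), p + 1L, p + lens)
    keys <- setdiff(unique(keys), seen)
    if (!length(keys)) next
    hit <- reads[reads$sequence %in% keys, , drop = FALSE]
    if (nrow(hit)) {
      hit$arm <- arm
      hit$offset <- combos$off[k]
      assigned[[length(assigned) + 1L]] <- hit
    }
    seen <- c(seen, keys)
  }
  assignments <- if (length(assigned)) do.call(rbind, assigned)
    else data.frame(sequence = character(), count = integer(),
                    library_id = character(), arm = character(),
                    offset = integer(), stringsAsFactors = FALSE)
  rownames(assignments) <- NULL

  mk <- function(arm) {
    sub <- assignments[assignments$arm == arm, , drop = FALSE]
    counts <- setNames(rep(0, length(lib_ids)), lib_ids)
    if (nrow(sub)) {
      agg <- tapply(sub$count, sub$library_id, sum)
      counts[names(agg)] <- agg
    }
    out <- list(candidate_id = candidateId(candidate), arm = arm,
                counts = counts)
    if (!is.null(libraries)) {
      tot <- setNames(libraries$total_mapped_reads, libraries$library_id)
      out$rpm <- counts * 1e6 / tot[names(counts)]
    }
    structure(out, class = "ArmExpression")
  }
  list(expr5p = mk("5p"), expr3p = mk("3p"), assignments = assignments)
}

#' @export
print.ArmExpression <- function(x, ...) {
  cat("ArmExpression ", x$candidate_id, " [", x$arm, "]: ",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Log2 fold change between depleted and control libraries
#'
#' Replicates are averaged on the RPM scale per condition, then
#' `log2fc = log2((mean depleted RPM + pseudocount) /
#' (mean control RPM + pseudocount))`. Negative values mean reduction
#' under Dicer-1 depletion; a default pseudocount of 0.25 RPM keeps
#' zero-count arms finite.
#'
#' @param expr an `ArmExpression` from [countArmReads()] (must carry
#'   RPM, i.e. be counted with `libraries`).
#' @param libraries library data.frame.
#' @param pseudocount RPM pseudocount.
#' @return list with `candidate_id`, `arm`, `log2fc`.
#' @export
computeLog2FC <- function(expr, libraries, pseudocount = 0.25) {
  ctrl <- libraries$library_id[libraries$condition == "control"]
  depl <- libraries$library_id[libraries$condition == "dicer_depleted"]
  if (!length(ctrl) || !length(depl))
    stop("configuration error: need at least one library per condition")
  if (is.null(expr$rpm))
    stop("expression lacks RPM; count with 'libraries' supplied")
  m_ctrl <- mean(expr$rpm[ctrl])
  m_depl <- mean(expr$rpm[depl])
  list(candidate_id = expr$candidate_id, arm = expr$arm,
       log2fc = log2((m_depl + pseudocount) / (m_ctrl + pseudocount)))
}

#' Control-support filter
#'
#' Passes only candidates with at least one read in every control
#' library on both arms.
#'
#' @param expr5p,expr3p `ArmExpression` objects for the two arms.
#' @param control_libs character vector of control library ids.
#' @return logical.
#' @export
supportFilter <- function(expr5p, expr3p, control_libs) {
  if (!length(control_libs))
    stop("configuration error: empty control library set")
  all(expr5p$counts[control_libs] >= 1) &&
    all(expr3p$counts[control_libs] >= 1)
}

#' Map collapsed reads to a genome by exact matching
#'
#' Unique read sequences are grouped by width and matched exactly
#' against the genome with [Biostrings::matchPDict]; multi-hit reads
#' are reported at every position.
#'
#' @param reads data.frame with `sequence`, `count`, `library_id`.
#' @param genome named `DNAStringSet`.
#' @return a `GRanges` of alignments with `sequence`, `count`,
#'   `library_id` metadata.
#' @export
mapReadsToGenome <- function(reads, genome) {
  uniq <- unique(reads$sequence)
  hits <- vector("list", 0L)
  for (w in sort(unique(nchar(uniq)))) {
    seqs <- uniq[nchar(uniq) == w]
    pd <- PDict(DNAStringSet(seqs))
    for (sq in names(genome)) {
      m <- matchPDict(pd, genome[[sq]])
      n_per <- lengths(m)
      if (!sum(n_per)) next
      ir <- unlist(m)
      hits[[length(hits) + 1L]] <- GRanges(
        sq, IRanges(start(ir), end(ir)),
        sequence = rep(seqs, n_per)
      )
    }
  }
  if (!length(hits))
    return(GRanges(sequence = character(), count = integer(),
                   library_id = character()))
  aln <- do.call(c, hits)
  # expand per library occurrence of each sequence
  hit_of_seq <- split(seq_along(aln), aln$sequence)
  n_hits <- lengths(hit_of_seq[reads$sequence])
  n_hits[is.na(n_hits)] <- 0L
  rows <- rep(seq_len(nrow(reads)), n_hits)
  aln_idx <- unlist(hit_of_seq[reads$sequence], use.names = FALSE)
  out <- aln[aln_idx]
  out$count <- reads$count[rows]
  out$library_id <- reads$library_id[rows]
  GenomeInfoDb::seqlengths(out) <-
    setNames(nchar(as.character(genome)), names(genome))[
      GenomeInfoDb::seqlevels(out)]
  out
}

#' Select negative-control regions
#'
#' Returns maximal genomic regions shorter than `max_len` whose every
#' base is covered by at least `min_cov` reads in each control library
#' and which do not overlap any excluded locus (known miRNAs, coding
#' regions). These regions should not respond to Dicer-1 depletion and
#' anchor the log2FC baseline.
#'
#' @param genome named `DNAStringSet`.
#' @param reads read data.frame (all libraries; only control libraries
#'   contribute to the coverage requirement).
#' @param libraries library data.frame.
#' @param excluded `GRanges` of loci that must not overlap a selected
#'   region.
#' @param max_len,min_cov region rule (defaults 500 nt / 10x).
#' @param alignments optional precomputed [mapReadsToGenome()] result.
#' @return a `GRanges` of selected regions.
#' @export
selectNegativeControls <- function(genome, reads, libraries,
                                   excluded = GRanges(),
                                   max_len = 500L, min_cov = 10L,
                                   alignments = NULL) {
  if (is.null(alignments)) alignments <- mapReadsToGenome(reads, genome)
  ctrl <- libraries$library_id[libraries$condition == "control"]
  cov_min <- NULL
  for (lib in ctrl) {
    a <- alignments[alignments$library_id == lib]
    cv <- coverage(a, weight = a$count)
    cov_min <- if (is.null(cov_min)) cv else pmin(cov_min, cv)
  }
  if (is.null(cov_min)) return(GRanges())
  runs <- slice(cov_min, lower = min_cov, rangesOnly = TRUE)
  gr <- GRanges(runs)
  gr <- gr[width(gr) < max_len]
  if (length(excluded))
    gr <- gr[!IRanges::overlapsAny(gr, excluded, ignore.strand = TRUE)]
  sort(gr)
}

#' Per-region log2 fold change
#'
#' Counts reads overlapping each region per library, normalises to RPM
#' and computes the depleted/control log2 ratio, exactly as for miRNA
#' arms. The median over negative-control regions is the pipeline's
#' normalisation baseline (close to 0 when depletion is specific).
#'
#' @param regions `GRanges` of regions (e.g. from
#'   [selectNegativeControls()]).
#' @param alignments [mapReadsToGenome()] result.
#' @param libraries library data.frame.
#' @param pseudocount RPM pseudocount.
#' @return numeric vector of per-region log2FC values.
#' @export
regionLog2FC <- function(regions, alignments, libraries,
                         pseudocount = 0.25) {
  if (!length(regions)) return(numeric(0))
  tot <- setNames(libraries$total_mapped_reads, libraries$library_id)
  rpm <- matrix(0, length(regions), nrow(libraries),
                dimnames = list(NULL, libraries$library_id))
  for (lib in libraries$library_id) {
    a <- alignments[alignments$library_id == lib]
    ov <- findOverlaps(regions, a, ignore.strand = TRUE)
    cnt <- tapply(a$count[subjectHits(ov)], queryHits(ov), sum)
    rpm[as.integer(names(cnt)), lib] <- cnt * 1e6 / tot[lib]
  }
  ctrl <- libraries$condition == "control"
  m_ctrl <- rowMeans(rpm[, ctrl, drop = FALSE])
  m_depl <- rowMeans(rpm[, !ctrl, drop = FALSE])
  log2((m_depl + pseudocount) / (m_ctrl + pseudocount))
}

#' Welch's two-sample t-test
#'
#' Two-sided unequal-variance t-test (Welch-Satterthwaite degrees of
#' freedom), used to compare expression between miRNA groups. Each
#' group needs at least two values and the pair must not be
#' variance-degenerate.
#'
#' @param groupA,groupB numeric vectors.
#' @return list with `statistic`, `p.value`, `df`.
#' @export
welchTTest <- function(groupA, groupB) {
  if (length(groupA) < 2L) stop("groupA needs at least 2 values")
  if (length(groupB) < 2L) stop("groupB needs at least 2 values")
  if (stats::var(groupA) == 0) stop("degenerate variance in groupA")
  if (stats::var(groupB) == 0) stop("degenerate variance in groupB")
  tt <- t.test(groupA, groupB, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter))
}
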