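## Per-miRNA reports: read alignments against the extended precursor
## and a deterministic text/SVG rendering of structure, arms and
## per-library counts.

#' Align reads to an extended precursor for reporting
#'
#' Reads of length 18-26 nt are aligned ungapped at every admissible
#' offset; alignments overlapping the seed region must be mismatch-free
#' there ("perfect matches in the seed region") and at most one
#' mismatch is allowed elsewhere. Reads matching at several positions
#' are reported at all of them with a multi-hit flag.
#'
#' @param reads data.frame with `sequence`, `count`, `library_id`.
#' @param extended_precursor precursor plus flanking sequence.
#' @param seed_region `c(start, end)` 0-based half-open interval of the
#'   seed within the extended precursor.
#' @param read_length admissible read lengths (default 18-26).
#' @param max_mismatch mismatches tolerated outside the seed.
#' @return data.frame: `sequence`, `offset` (0-based), `length`,
#'   `multi_hit`, `library_id`, `count`.
#' @export
alignReadsForReport <- function(reads, extended_precursor, seed_region,
                                read_length = c(18L, 26L),
                                max_mismatch = 1L) {
  prec <- strsplit(toupper(chartr("Uu", "Tt", extended_precursor)),
                   "")[[1L]]
  n <- length(prec)
  len <- nchar(reads$sequence)
  reads <- reads[len >= read_length[1L] & len <= read_length[2L], ,
                 drop = FALSE]
  uniq <- unique(reads$sequence)
  out <- list()
  for (s in uniq) {
    rc <- strsplit(s, "")[[1L]]
    m <- length(rc)
    offs <- integer(0)
    for (p in 0:(n - m)) {
      idx <- (p + 1L):(p + m)
      mism <- prec[idx] != rc
      in_seed <- idx > seed_region[1L] & idx <= seed_region[2L]
      if (any(mism & in_seed)) next
      if (sum(mism) > max_mismatch) next
      offs <- c(offs, p)
    }
    if (!length(offs)) next
    rows <- reads[reads$sequence == s, , drop = FALSE]
    for (p in offs) {
      out[[length(out) + 1L]] <- data.frame(
        sequence = s, offset = p, length = m,
        multi_hit = length(offs) > 1L,
        library_id = rows$library_id, count = rows$count,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sequence = character(), offset = integer(),
                      length = integer(), multi_hit = logical(),
                      library_id = character(), count = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$offset, res$sequence, res$library_id), , drop = FALSE]
}

#' Build a per-miRNA report
#'
#' Collects everything a per-miRNA report shows: the precursor extended
#' by `flank` genomic nucleotides, its fold, the arm intervals, the
#' aligned reads with per-library counts, and the per-arm count table
#' from [countArmReads()] (so that report counts equal pipeline
#' counts).
#'
#' @param candidate a [MiRNACandidate-class].
#' @param genome named `DNAStringSet`.
#' @param reads read data.frame.
#' @param libraries library data.frame.
#' @param mature_arm `"5p"` or `"3p"`; its positions 2-7 define the
#'   seed region used to constrain report alignments.
#' @param flank flanking nucleotides (default 30).
#' @param fold optional precomputed [HairpinFold-class].
#' @param homologues optional data.frame with `name` and `mature`
#'   columns (mature sequences of homologous miRNAs in other species).
#' @param thresholds a [mirThresholds()].
#' @return list of class `"MiRNAReport"`.
#' @export
buildMiRNAReport <- function(candidate, genome, reads, libraries,
                             mature_arm = "5p", flank = 30L,
                             fold = NULL, homologues = NULL,
                             thresholds = mirThresholds()) {
  gseq <- as.character(genome[[candidate@seqId]])
  f_lo <- min(flank, candidate@precursorStart)
  f_hi <- min(flank, nchar(gseq) - candidate@precursorEnd)
  ext <- substr(gseq, candidate@precursorStart - f_lo + 1L,
                candidate@precursorEnd + f_hi)
  if (candidate@strand == "-") {
    ext <- as.character(reverseComplement(DNAString(ext)))
    tmp <- f_lo
    f_lo <- f_hi
    f_hi <- tmp
  }
  if (is.null(fold)) fold <- foldHairpin(precursorSeq(candidate))
  mat_iv <- armInterval(candidate, mature_arm)
  seed_region <- c(f_lo + mat_iv[1L] + 1L, f_lo + mat_iv[1L] + 7L)
  aligned <- alignReadsForReport(reads, ext, seed_region,
                                 thresholds$read_length)
  counts <- countArmReads(reads, candidate, libraries,
                          tolerance = thresholds$arm_tolerance)
  structure(list(
    candidate_id = candidateId(candidate),
    extended_precursor = ext,
    flank = c(f_lo, f_hi),
    dot_bracket = dotBracket(fold),
    free_energy = freeEnergy(fold),
    arm5p = armInterval(candidate, "5p") + f_lo,
    arm3p = armInterval(candidate, "3p") + f_lo,
    mature_arm = mature_arm,
    aligned_reads = aligned,
    arm_counts = counts,
    libraries = libraries,
    homologues = homologues
  ), class = "MiRNAReport")
}

.reportLines <- function(report) {
  n <- nchar(report$extended_precursor)
  pad <- function(off, s) paste0(strrep(" ", off), s)
  arm_line <- rep(".", n)
  arm_line[(report$arm5p[1L] + 1L):report$arm5p[2L]] <- "5"
  arm_line[(report$arm3p[1L] + 1L):report$arm3p[2L]] <- "3"
  lines <- c(
    paste0("miRNA report: ", report$candidate_id),
    paste0("mature arm: ", report$mature_arm,
           " | fold dG = ", format(report$free_energy, digits = 4),
           " kcal/mol"),
    "",
    report$extended_precursor,
    pad(report$flank[1L], report$dot_bracket),
    paste(arm_line, collapse = "")
  )
  ar <- report$aligned_reads
  if (nrow(ar)) {
    key <- paste(ar$sequence, ar$offset)
    for (k in unique(key)) {
      sub <- ar[key == k, , drop = FALSE]
      cnts <- tapply(sub$count, sub$library_id, sum)
      lines <- c(lines, paste0(
        pad(sub$offset[1L], sub$sequence[1L]), "  ",
        paste(names(cnts), cnts, sep = ":", collapse = " "),
        if (sub$multi_hit[1L]) " [multi]" else ""))
    }
  }
  lines <- c(lines, "", "arm counts (collapsed reads):")
  for (arm in c("5p", "3p")) {
    e <- if (arm == "5p") report$arm_counts$expr5p
         else report$arm_counts$expr3p
    lines <- c(lines, paste0("  ", arm, ": ",
      paste(names(e$counts), e$counts, sep = "=", collapse = " ")))
  }
  if (!is.null(report$homologues)) {
    lines <- c(lines, "", "homologues:")
    for (i in seq_len(nrow(report$homologues)))
      lines <- c(lines, paste0("  ", report$homologues$name[i], "  ",
                               report$homologues$mature[i]))
  }
  lines
}

#' Render a per-miRNA report
#'
#' Deterministic rendering: identical reports produce byte-identical
#' documents. The text format stacks the extended precursor, its
#' dot-bracket, an arm annotation track (5/3), the aligned reads with
#' per-library counts, and the per-arm count table; the SVG format
#' wraps the same monospace lines in an SVG document.
#'
#' @param report a `MiRNAReport` from [buildMiRNAReport()].
#' @param format `"text"` or `"svg"`.
#' @return a single character scalar (the document).
#' @export
renderReport <- function(report, format = c("text", "svg")) {
  format <- match.arg(format)
  lines <- .reportLines(report)
  if (format == "text") return(paste(lines, collapse = "\n"))
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  h <- 14L * (length(lines) + 2L)
  w <- 8L * max(nchar(lines), 40L)
  body <- sprintf(
    '<text x="10" y="%d" xml:space="preserve">%s</text>',
    14L * seq_along(lines) + 6L, esc(lines))
  paste(c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" font-family="monospace" font-size="12">',
    w, h), body, "</svg>"), collapse = "\n")
}
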