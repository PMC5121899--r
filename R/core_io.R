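## Readers and writers for the external formats the pipeline touches.
## Internal conventions: DNA alphabet (U -> T on input), 0-based half-open
## coordinates, minus-strand precursors stored in transcript orientation.

#' Read sequences from FASTA/FASTQ/collapsed-FASTA
#'
#' `format = "fasta"` and `"fastq"` return a [Biostrings::DNAStringSet]
#' (genome or transcript sequences). `format = "collapsed_fasta"` reads
#' adapter-trimmed, collapsed small-RNA reads whose headers carry the
#' collapsed multiplicity as a `_x<count>` token (e.g. `>r1_x12`), and
#' returns a read table. U is converted to T internally; sequences are
#' uppercased.
#'
#' @param path input file path.
#' @param format one of `"fasta"`, `"fastq"`, `"collapsed_fasta"`.
#' @param library_id library identifier attached to collapsed reads.
#' @param length_range reads outside this length range are dropped on
#'   collapsed input (collapse filtering keeps 16-30 nt by default).
#' @return a `DNAStringSet`, or for `collapsed_fasta` a `data.frame`
#'   with columns `sequence`, `count`, `library_id`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGT"), fa)
#' readSequences(fa)
#' @export
readSequences <- function(path, format = c("fasta", "fastq",
                                           "collapsed_fasta"),
                          library_id = NA_character_,
                          length_range = c(16L, 30L)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  # read as raw strings first so RNA (U) and lowercase input survive,
  # then normalise to the internal DNA alphabet
  seqs <- tryCatch(
    if (format == "fastq") Biostrings::readBStringSet(path, format = "fastq")
    else Biostrings::readBStringSet(path),
    error = function(e) stop("parse error in ", basename(path), ": ",
                             conditionMessage(e), call. = FALSE)
  )
  norm <- toupper(chartr("Uu", "Tt", as.character(seqs)))
  bad <- grep("[^ACGTN]", norm)
  if (length(bad))
    stop("parse error in ", basename(path), ": record ", bad[1L], " ('",
         names(seqs)[bad[1L]], "') has characters outside {A,C,G,T,U,N}")
  if (format != "collapsed_fasta") {
    if (length(seqs) == 0L) stop("no records in ", basename(path))
    out <- DNAStringSet(norm)
    names(out) <- sub("\\s.*$", "", names(seqs))
    return(out)
  }
  hdr <- names(seqs)
  m <- regmatches(hdr, regexpr("_x([0-9]+)\\b", hdr))
  bad <- which(lengths(regmatches(hdr, gregexpr("_x[0-9]+\\b", hdr))) == 0L)
  if (length(bad))
    stop("format error in ", basename(path), ": header '", hdr[bad[1L]],
         "' (record ", bad[1L], ") lacks a _x<count> token")
  counts <- as.integer(sub("_x", "", m))
  reads <- data.frame(
    sequence = unname(norm),
    count = counts,
    library_id = library_id,
    stringsAsFactors = FALSE
  )
  rownames(reads) <- NULL
  len <- nchar(reads$sequence)
  reads[len >= length_range[1L] & len <= length_range[2L], , drop = FALSE]
}

#' Write collapsed small-RNA reads as `>id_x<count>` FASTA
#'
#' @param reads data.frame with columns `sequence` and `count`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCollapsedFasta <- function(reads, path) {
  stopifnot(all(c("sequence", "count") %in% names(reads)))
  lines <- as.vector(rbind(
    sprintf(">r%d_x%d", seq_len(nrow(reads)), reads$count),
    reads$sequence
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Read a rooted species tree from newick
#'
#' Parses a newick file (or literal string via `text`) and checks that
#' the tree is rooted and its leaf labels are unique, as required by
#' the Dollo reconstruction.
#'
#' @param path path to a newick file (ignored when `text` is given).
#' @param text optional literal newick string.
#' @return an [ape::read.tree] `phylo` object.
#' @examples
#' tr <- readSpeciesTree(text = "((Bge,Lmi),(Api,(Ame,(Tca,(Bmo,Dme)))));")
#' length(tr$tip.label)  # 7
#' @export
readSpeciesTree <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    suppressWarnings(
      if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
    ),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("structural error: input is not valid newick")
  if (anyDuplicated(tr$tip.label))
    stop("structural error: duplicate leaf labels in tree")
  if (!ape::is.rooted(tr))
    stop("structural error: tree must be rooted")
  tr
}

#' Check loci against their genome sequences
#'
#' Rejects any locus that refers to a missing sequence or extends beyond
#' its end. Used at load time so downstream arithmetic can assume
#' in-bounds coordinates.
#'
#' @param loci a [GenomicRanges::GRanges] (1-based, as returned by
#'   [precursorLocus()] or `rtracklayer::import`).
#' @param genome named `DNAStringSet`.
#' @return `loci`, invisibly, or an error naming the first offender.
#' @export
checkLociWithinGenome <- function(loci, genome) {
  sq <- as.character(seqnames(loci))
  missing <- !(sq %in% names(genome))
  if (any(missing))
    stop("locus refers to unknown sequence '", sq[which(missing)[1L]], "'")
  lens <- nchar(as.character(genome))[sq]
  bad <- which(start(loci) < 1L | end(loci) > lens)
  if (length(bad))
    stop("locus ", bad[1L], " (", sq[bad[1L]], ":", start(loci)[bad[1L]],
         "-", end(loci)[bad[1L]], ") outside its sequence")
  invisible(loci)
}

#' Write candidate loci (with arms and synthetic labels) as GFF3
#'
#' One `pre_miRNA` feature per candidate; the arm intervals (transcript
#' coordinates) and any synthetic-truth attributes travel as GFF3
#' attributes so a round-trip reconstructs the candidates exactly.
#'
#' @param candidates list of [MiRNACandidate-class].
#' @param path output path.
#' @param labels,decoy_modes optional per-candidate character vectors
#'   (synthetic truth annotations).
#' @return `path`, invisibly.
#' @export
writeCandidateGff <- function(candidates, path, labels = NULL,
                              decoy_modes = NULL) {
  gr <- GRanges(
    vapply(candidates, function(x) x@seqId, ""),
    IRanges(
      vapply(candidates, function(x) x@precursorStart + 1L, 1L),
      vapply(candidates, function(x) x@precursorEnd, 1L)
    ),
    strand = vapply(candidates, function(x) x@strand, "")
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = "pre_miRNA",
    ID = vapply(candidates, candidateId, ""),
    arm5p = vapply(candidates, function(x) paste(x@arm5p, collapse = "-"), ""),
    arm3p = vapply(candidates, function(x) paste(x@arm3p, collapse = "-"), "")
  )
  if (!is.null(labels)) gr$label <- labels
  if (!is.null(decoy_modes)) gr$decoy_mode <- decoy_modes
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read candidate loci from GFF3
#'
#' Inverse of [writeCandidateGff()]; precursor sequences are extracted
#' from `genome` (reverse-complemented for minus-strand loci).
#'
#' @param path GFF3 path.
#' @param genome named `DNAStringSet`.
#' @return list of [MiRNACandidate-class]; synthetic `label` /
#'   `decoy_mode` attributes, when present, are attached as the
#'   `"label"` and `"decoy_mode"` attributes of the list.
#' @export
readCandidateGff <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  checkLociWithinGenome(gr, genome)
  parse_iv <- function(s) as.integer(strsplit(s, "-")[[1L]])
  cands <- lapply(seq_along(gr), function(i) {
    sq <- as.character(seqnames(gr))[i]
    st <- start(gr)[i] - 1L
    en <- end(gr)[i]
    strand_i <- as.character(strand(gr))[i]
    seq <- substr(as.character(genome[[sq]]), st + 1L, en)
    if (strand_i == "-")
      seq <- as.character(reverseComplement(DNAString(seq)))
    newMiRNACandidate(gr$ID[i], sq, st, en, strand_i, seq,
                      parse_iv(gr$arm5p[i]), parse_iv(gr$arm3p[i]))
  })
  if (!is.null(gr$label)) attr(cands, "label") <- gr$label
  if (!is.null(gr$decoy_mode)) attr(cands, "decoy_mode") <- gr$decoy_mode
  cands
}

#' Read/write the library description table
#'
#' TSV with columns `library_id`, `condition` (`control` or
#' `dicer_depleted`) and `total_mapped_reads` (the RPM denominator).
#'
#' @param path TSV path.
#' @return data.frame with the three columns above.
#' @export
readLibrariesTsv <- function(path) {
  libs <- read.delim(path, stringsAsFactors = FALSE)
  validateLibraries(libs)
  libs
}

#' @rdname readLibrariesTsv
#' @param libraries library data.frame.
#' @export
writeLibrariesTsv <- function(libraries, path) {
  validateLibraries(libraries)
  write.table(libraries, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validateLibraries <- function(libraries) {
  req <- c("library_id", "condition", "total_mapped_reads")
  if (!all(req %in% names(libraries)))
    stop("library table needs columns: ", paste(req, collapse = ", "))
  if (!all(libraries$condition %in% c("control", "dicer_depleted")))
    stop("condition must be 'control' or 'dicer_depleted'")
  if (any(libraries$total_mapped_reads < 0))
    stop("total_mapped_reads must be >= 0")
  invisible(libraries)
}
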