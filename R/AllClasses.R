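#' MiRNACandidate: a candidate precursor locus with annotated arms
#'
#' Holds one miRNA candidate: its genomic precursor locus, the precursor
#' sequence in transcript orientation (minus-strand loci are stored
#' reverse-complemented), and the 5p/3p arm intervals in transcript
#' coordinates. All coordinates are 0-based, half-open.
#'
#' @slot id candidate identifier.
#' @slot seqId identifier of the genome sequence the locus lies on.
#' @slot strand `"+"` or `"-"`.
#' @slot precursorStart,precursorEnd genomic interval, 0-based half-open.
#' @slot precursorSeq precursor sequence (DNA alphabet, transcript
#'   orientation).
#' @slot arm5p,arm3p integer length-2 vectors `c(start, end)` giving the
#'   arm intervals as 0-based half-open offsets into `precursorSeq`.
#' @slot sourceTags character vector of free-form provenance tags
#'   (e.g. which upstream predictor emitted the candidate).
#'
#' @seealso [newMiRNACandidate()], [armSeq()], [precursorLocus()]
#' @export
setClass("MiRNACandidate",
  representation(
    id = "character",
    seqId = "character",
    strand = "character",
    precursorStart = "integer",
    precursorEnd = "integer",
    precursorSeq = "character",
    arm5p = "integer",
    arm3p = "integer",
    sourceTags = "character"
  )
)

setValidity("MiRNACandidate", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  n <- nchar(object@precursorSeq)
  if (n < 1L) msg <- c(msg, "precursorSeq must be non-empty")
  if (grepl("[^ACGTN]", object@precursorSeq))
    msg <- c(msg, "precursorSeq must be over {A,C,G,T,N}")
  if (object@precursorEnd - object@precursorStart != n)
    msg <- c(msg, "genomic interval length must equal nchar(precursorSeq)")
  if (object@precursorStart < 0L || object@precursorStart >= object@precursorEnd)
    msg <- c(msg, "precursor locus must satisfy 0 <= start < end")
  for (arm in list(`5p` = object@arm5p, `3p` = object@arm3p)) {
    if (length(arm) != 2L || any(is.na(arm)) || arm[1L] < 0L ||
        arm[1L] >= arm[2L] || arm[2L] > n)
      msg <- c(msg, "arm intervals must be within the precursor and non-empty")
  }
  if (length(msg) == 0L && object@arm5p[2L] > object@arm3p[1L])
    msg <- c(msg, "5p arm must precede and not overlap the 3p arm")
  if (length(msg)) msg else TRUE
})

#' Construct a MiRNACandidate
#'
#' @param id candidate identifier.
#' @param seqId genome sequence identifier.
#' @param start,end genomic precursor interval, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param precursorSeq precursor sequence in transcript orientation.
#' @param arm5p,arm3p `c(start, end)` 0-based half-open intervals of the
#'   arms in transcript coordinates.
#' @param sourceTags optional character vector of provenance tags.
#' @param genome optional named [Biostrings::DNAStringSet] (or named
#'   character vector); when supplied, the precursor sequence is checked
#'   against the genome at the stated locus (strand-aware) and the locus
#'   is checked to lie within the sequence.
#' @return a validated [MiRNACandidate-class] object.
#' @examples
#' cand <- newMiRNACandidate("bg1", "contig1", 100, 180, "+",
#'   precursorSeq = paste(rep("ACGT", 20), collapse = ""),
#'   arm5p = c(2, 24), arm3p = c(56, 78))
#' armSeq(cand, "5p")
#' @export
newMiRNACandidate <- function(id, seqId, start, end, strand, precursorSeq,
                              arm5p, arm3p, sourceTags = character(),
                              genome = NULL) {
  obj <- new("MiRNACandidate",
    id = as.character(id), seqId = as.character(seqId),
    strand = strand,
    precursorStart = as.integer(start), precursorEnd = as.integer(end),
    precursorSeq = toupper(chartr("Uu", "Tt", as.character(precursorSeq))),
    arm5p = as.integer(arm5p), arm3p = as.integer(arm3p),
    sourceTags = as.character(sourceTags)
  )
  if (!is.null(genome)) {
    gseq <- as.character(genome[[seqId]])
    if (is.na(gseq) || end > nchar(gseq))
      stop("locus of candidate '", id, "' extends beyond sequence '",
           seqId, "'")
    genomic <- substr(gseq, start + 1L, end)
    if (strand == "-")
      genomic <- as.character(reverseComplement(DNAString(genomic)))
    if (!identical(genomic, obj@precursorSeq))
      stop("precursorSeq of candidate '", id,
           "' does not match the genome at its locus")
  }
  obj
}

#' @describeIn MiRNACandidate-class candidate identifier
#' @param x a `MiRNACandidate`.
#' @export
candidateId <- function(x) x@id

#' @describeIn MiRNACandidate-class precursor sequence (transcript
#'   orientation, DNA alphabet)
#' @export
precursorSeq <- function(x) x@precursorSeq

#' @describeIn MiRNACandidate-class arm interval `c(start, end)` in
#'   transcript coordinates (0-based half-open)
#' @param arm `"5p"` or `"3p"`.
#' @export
armInterval <- function(x, arm = c("5p", "3p")) {
  arm <- match.arg(arm)
  if (arm == "5p") x@arm5p else x@arm3p
}

#' @describeIn MiRNACandidate-class arm sequence
#' @export
armSeq <- function(x, arm = c("5p", "3p")) {
  iv <- armInterval(x, arm)
  substr(x@precursorSeq, iv[1L] + 1L, iv[2L])
}

#' @describeIn MiRNACandidate-class genomic precursor locus as a
#'   1-based [GenomicRanges::GRanges]
#' @export
precursorLocus <- function(x) {
  GRanges(x@seqId,
          IRanges(x@precursorStart + 1L, x@precursorEnd),
          strand = x@strand, candidate_id = x@id)
}

setMethod("show", "MiRNACandidate", function(object) {
  cat("MiRNACandidate '", object@id, "' (", object@seqId, ":",
      object@precursorStart, "-", object@precursorEnd, object@strand,
      ", ", nchar(object@precursorSeq), " nt)\n", sep = "")
  cat("  5p arm [", object@arm5p[1L], ",", object@arm5p[2L], "): ",
      armSeq(object, "5p"), "\n", sep = "")
  cat("  3p arm [", object@arm3p[1L], ",", object@arm3p[2L], "): ",
      armSeq(object, "3p"), "\n", sep = "")
})

#' HairpinFold: a predicted precursor secondary structure
#'
#' The result of folding one precursor: dot-bracket structure, a folding
#' free energy in kcal/mol under the package's nearest-neighbour stack
#' model (or the external backend's energy), the pairing partner table,
#' and hairpin-loop summaries used by the structural criteria.
#'
#' @slot dotBracket dot-bracket string, same length as the precursor.
#' @slot freeEnergy folding free energy, kcal/mol (more negative =
#'   more stable).
#' @slot pairs integer vector: `pairs[i]` is the 1-based partner of
#'   base `i`, or `NA` if unpaired.
#' @slot loopLength size of the (smallest) terminal hairpin loop, 0 when
#'   the structure has no pair.
#' @slot nTerminalLoops number of terminal hairpin loops; a canonical
#'   pre-miRNA hairpin has exactly one.
#' @seealso [foldHairpin()], [evaluateHairpinCriteria()]
#' @export
setClass("HairpinFold",
  representation(
    dotBracket = "character",
    freeEnergy = "numeric",
    pairs = "integer",
    loopLength = "integer",
    nTerminalLoops = "integer"
  )
)

setValidity("HairpinFold", function(object) {
  db <- object@dotBracket
  msg <- character()
  if (length(db) != 1L) msg <- c(msg, "dotBracket must be a single string")
  ch <- strsplit(db, "")[[1L]]
  if (sum(ch == "(") != sum(ch == ")"))
    msg <- c(msg, "dotBracket must be balanced")
  if (length(object@pairs) != nchar(db))
    msg <- c(msg, "pairs table length must match dotBracket")
  if (length(msg)) msg else TRUE
})

#' @describeIn HairpinFold-class dot-bracket string
#' @param x a `HairpinFold`.
#' @export
dotBracket <- function(x) x@dotBracket

#' @describeIn HairpinFold-class folding free energy (kcal/mol)
#' @export
freeEnergy <- function(x) x@freeEnergy

#' @describeIn HairpinFold-class terminal-loop length
#' @export
loopLength <- function(x) x@loopLength

setMethod("show", "HairpinFold", function(object) {
  cat("HairpinFold (", nchar(object@dotBracket), " nt, ",
      sum(!is.na(object@pairs)) / 2L, " pairs, dG = ",
      format(object@freeEnergy, digits = 4), " kcal/mol, ",
      object@nTerminalLoops, " terminal loop(s))\n", sep = "")
  cat(" ", object@dotBracket, "\n")
})
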