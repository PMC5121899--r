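## Hairpin folding and the structural half of the bona-fide criteria.
##
## The internal backend computes the maximum-pairing pseudoknot-free
## structure (dynamic programming, minimum hairpin loop of 3) and scores
## it with an embedded nearest-neighbour stack table plus a constant
## per-enclosed-unpaired-base loop penalty. This Turner-style model is
## NOT mfold-equivalent; the external backend (ViennaRNA's RNAfold) is
## the fidelity path when available.

# Stack free energies, kcal/mol: rows = outer pair (i, j), columns =
# inner pair (i+1, j-1); Watson-Crick plus GU wobble, DNA letters with
# T standing for U.
.PAIR_TYPES <- c("AT", "TA", "GC", "CG", "GT", "TG")
.STACK_DG <- matrix(c(
  # AT    TA    GC    CG    GT    TG     (inner)
  -0.9, -1.1, -2.1, -2.2, -0.6, -1.4,  # outer AT
  -1.3, -0.9, -2.1, -2.4, -1.0, -1.3,  # outer TA
  -2.4, -2.2, -3.3, -3.4, -1.5, -2.5,  # outer GC
  -2.1, -2.1, -2.4, -3.3, -1.4, -2.1,  # outer CG
  -1.3, -1.4, -2.1, -2.5, -0.5,  1.3,  # outer GT
  -1.0, -0.6, -1.4, -1.5,  0.3, -0.5   # outer TG
), nrow = 6, byrow = TRUE, dimnames = list(.PAIR_TYPES, .PAIR_TYPES))

.LOOP_DG_PER_BASE <- 0.3  # penalty per unpaired base enclosed by a pair

.normalizeSeq <- function(x) {
  s <- toupper(chartr("Uu", "Tt", as.character(x)))
  if (grepl("[^ACGTN]", s))
    stop("input error: sequence contains characters outside {A,C,G,T,U,N}")
  s
}

#' Stack-model free energy of a fixed structure
#'
#' Sums nearest-neighbour stack energies over adjacent pairs and adds a
#' constant penalty of 0.3 kcal/mol per unpaired base enclosed by at
#' least one pair. Unstructured exterior bases are free, so a fully
#' unpaired sequence has energy 0.
#'
#' @param seq sequence (DNA or RNA letters).
#' @param pairs 1-based partner table (`NA` = unpaired).
#' @return free energy in kcal/mol.
#' @export
stackEnergy <- function(seq, pairs) {
  s <- strsplit(.normalizeSeq(seq), "")[[1L]]
  n <- length(s)
  stopifnot(length(pairs) == n)
  e <- 0
  enclosed <- logical(n)
  for (i in seq_len(n)) {
    j <- pairs[i]
    if (is.na(j) || j < i) next
    if (j - i > 1L) enclosed[(i + 1L):(j - 1L)] <- enclosed[(i + 1L):(j - 1L)] | TRUE
    # stack with the immediately nested pair, if present
    if (i + 1L <= n && !is.na(pairs[i + 1L]) && pairs[i + 1L] == j - 1L) {
      outer <- paste0(s[i], s[j])
      inner <- paste0(s[i + 1L], s[j - 1L])
      if (outer %in% .PAIR_TYPES && inner %in% .PAIR_TYPES)
        e <- e + .STACK_DG[outer, inner]
    }
  }
  e + .LOOP_DG_PER_BASE * sum(enclosed & is.na(pairs))
}

.pairsToDotBracket <- function(pairs) {
  ch <- rep(".", length(pairs))
  i <- which(!is.na(pairs) & pairs > seq_along(pairs))
  ch[i] <- "("
  ch[pairs[i]] <- ")"
  paste(ch, collapse = "")
}

#' Parse a dot-bracket string into a partner table
#'
#' @param dot_bracket dot-bracket string (`(`, `)`, `.`).
#' @return integer vector of 1-based partners (`NA` = unpaired).
#' @export
pairsFromDotBracket <- function(dot_bracket) {
  ch <- strsplit(dot_bracket, "")[[1L]]
  pairs <- rep(NA_integer_, length(ch))
  stack <- integer()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket")
  pairs
}

.loopSummaries <- function(pairs) {
  # terminal (hairpin) loops: pairs enclosing only unpaired bases
  n <- length(pairs)
  loops <- integer()
  for (i in seq_len(n)) {
    j <- pairs[i]
    if (is.na(j) || j <= i) next
    inside <- if (j - i > 1L) pairs[(i + 1L):(j - 1L)] else integer()
    if (all(is.na(inside))) loops <- c(loops, j - i - 1L)
  }
  list(n_terminal = length(loops),
       loop_length = if (length(loops)) min(loops) else 0L)
}

#' Construct a HairpinFold from an explicit structure
#'
#' @param dot_bracket dot-bracket string.
#' @param free_energy energy in kcal/mol; when `NULL` it is computed
#'   with [stackEnergy()] (requires `seq`).
#' @param seq the folded sequence (needed only to compute the energy).
#' @return a [HairpinFold-class].
#' @export
newHairpinFold <- function(dot_bracket, free_energy = NULL, seq = NULL) {
  pairs <- pairsFromDotBracket(dot_bracket)
  if (is.null(free_energy)) {
    if (is.null(seq)) stop("need 'seq' to compute the energy")
    free_energy <- stackEnergy(seq, pairs)
  }
  lo <- .loopSummaries(pairs)
  new("HairpinFold", dotBracket = dot_bracket,
      freeEnergy = free_energy, pairs = pairs,
      loopLength = lo$loop_length, nTerminalLoops = lo$n_terminal)
}

#' Maximum-pairing structure of an arbitrary sequence
#'
#' The folding primitive behind the internal backend, without the
#' precursor length contract: useful for validating the dynamic
#' programme against exhaustive enumeration on short sequences.
#'
#' @param seq sequence (DNA or RNA letters).
#' @return a [HairpinFold-class].
#' @examples
#' dotBracket(maxPairingStructure("GGGGAAAACCCC"))  # "((((....))))"
#' @export
maxPairingStructure <- function(seq) {
  s <- .normalizeSeq(seq)
  pairs <- .nussinovPairs(s, .STACK_DG)
  newHairpinFold(.pairsToDotBracket(pairs), stackEnergy(s, pairs))
}

#' Fold a candidate precursor
#'
#' The internal backend computes the maximum-pairing pseudoknot-free
#' structure (minimum hairpin loop 3) with a deterministic traceback and
#' scores it with the embedded stack table. The external backend shells
#' out to ViennaRNA's `RNAfold` and parses its dot-bracket and minimum
#' free energy; if `RNAfold` is not on the PATH an explicit error is
#' raised (never a silent fallback).
#'
#' @param precursor precursor sequence, 40-400 nt.
#' @param backend `"internal"` or `"external"`.
#' @return a [HairpinFold-class].
#' @examples
#' fold <- foldHairpin(strrep("ACGT", 15))
#' dotBracket(fold)
#' @export
foldHairpin <- function(precursor, backend = c("internal", "external")) {
  backend <- match.arg(backend)
  s <- .normalizeSeq(precursor)
  n <- nchar(s)
  if (n < 40L || n > 400L)
    stop("precursor length must be in [40, 400], got ", n)
  if (backend == "internal") return(maxPairingStructure(s))
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe))
    stop("backend error: external folding backend 'RNAfold' not found")
  out <- system2(exe, args = c("--noPS"),
                 input = chartr("T", "U", s), stdout = TRUE)
  line <- out[length(out)]
  db <- sub("^([.()]+).*$", "\\1", line)
  mfe <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
  if (nchar(db) != n || is.na(mfe))
    stop("backend error: could not parse RNAfold output")
  newHairpinFold(db, mfe)
}

#' Evaluate the structural bona-fide criteria on a fold
#'
#' Criteria on the hairpin (numbering follows the bona-fide filter):
#' c4 -- single-stem hairpin: exactly one terminal loop, with a loop
#' length inside a configurable sanity range; c5 -- free energy
#' strictly below -22 kcal/mol; c6 -- more than 16 (i.e. >= 17)
#' nucleotides paired between mature and star; c7 -- a 2-nt 3' overhang
#' on each arm of the duplex (the Drosha/Dicer-1 signature).
#'
#' @param fold a [HairpinFold-class].
#' @param mature_iv,star_iv arm intervals `c(start, end)`, 0-based
#'   half-open, in precursor coordinates; they must not overlap.
#' @param thresholds a [mirThresholds()] configuration.
#' @return list with logical `flags` (`c4_hairpin`, `c5_energy`,
#'   `c6_pairing`, `c7_overhang`) and numeric `metrics`
#'   (`mature_star_pairs`, `overhang_mature`, `overhang_star`,
#'   `loop_length`, `free_energy`).
#' @export
evaluateHairpinCriteria <- function(fold, mature_iv, star_iv,
                                    thresholds = mirThresholds()) {
  n <- length(fold@pairs)
  for (iv in list(mature_iv, star_iv))
    if (iv[1L] < 0L || iv[1L] >= iv[2L] || iv[2L] > n)
      stop("arm interval outside the precursor")
  if (max(mature_iv[1L], star_iv[1L]) < min(mature_iv[2L], star_iv[2L]))
    stop("mature and star intervals overlap")

  in_iv <- function(pos, iv) pos > iv[1L] & pos <= iv[2L]  # pos 1-based
  pairs <- fold@pairs
  pos <- seq_len(n)
  msp <- sum(in_iv(pos, mature_iv) & !is.na(pairs) & in_iv(pairs, star_iv))

  overhang3p <- function(iv, other_iv) {
    # trailing arm bases (3' end) not paired into the other arm
    k <- 0L
    for (p in seq(iv[2L], iv[1L] + 1L)) {  # 1-based positions, 3'->5'
      partner <- pairs[p]
      if (!is.na(partner) && in_iv(partner, other_iv)) break
      k <- k + 1L
    }
    k
  }
  ov_m <- overhang3p(mature_iv, star_iv)
  ov_s <- overhang3p(star_iv, mature_iv)

  th <- thresholds
  flags <- c(
    c4_hairpin = fold@nTerminalLoops == 1L &&
      fold@loopLength >= th$loop_range[1L] &&
      fold@loopLength <= th$loop_range[2L],
    c5_energy = fold@freeEnergy < th$energy,
    c6_pairing = msp >= th$min_pairs,
    c7_overhang = abs(ov_m - th$overhang) <= th$overhang_tol &&
      abs(ov_s - th$overhang) <= th$overhang_tol
  )
  list(flags = flags,
       metrics = c(mature_star_pairs = msp, overhang_mature = ov_m,
                   overhang_star = ov_s, loop_length = fold@loopLength,
                   free_energy = fold@freeEnergy))
}

#' Histogram of precursor terminal-loop lengths
#'
#' @param folds non-empty list of [HairpinFold-class] objects.
#' @return a `table` of loop lengths (exact integer histogram).
#' @export
loopLengthStats <- function(folds) {
  if (!length(folds)) stop("empty fold list")
  table(vapply(folds, loopLength, 0L))
}
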