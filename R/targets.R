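## Seed-match + duplex-energy target prediction, intersection of
## per-algorithm prediction sets, and per-group target-count summaries
## against a mock-miRNA baseline.
##
## The internal predictor is ONE algorithm (seed complementarity plus a
## nearest-neighbour duplex energy); externally computed prediction
## sets are ingested as pair tables and intersected.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.duplexPair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G") |
    (a == "G" & b == "T") | (a == "T" & b == "G")
}

#' Predict targets of one miRNA on a transcript set
#'
#' A candidate site requires perfect Watson-Crick complementarity of
#' the miRNA seed (positions 2-7) to the transcript. The duplex is then
#' extended ungapped in both directions while bases keep pairing
#' (Watson-Crick or GU), and scored with the nearest-neighbour stack
#' table; a site is reported when its energy is at or below
#' `energy_threshold` (default -12 kcal/mol). One pair per unique
#' (miRNA, transcript) is emitted, keeping the best-energy site.
#'
#' @param mirna mature miRNA sequence.
#' @param transcripts named character vector or `DNAStringSet`.
#' @param energy_threshold duplex energy cutoff, kcal/mol.
#' @param mirna_id identifier used in the output.
#' @param seed_positions 1-based inclusive seed window.
#' @return data.frame: `mirna_id`, `transcript_id`, `site_position`
#'   (1-based start of the seed match on the transcript),
#'   `duplex_energy`, `algorithm`.
#' @export
predictTargets <- function(mirna, transcripts, energy_threshold = -12,
                           mirna_id = "mirna",
                           seed_positions = c(2L, 7L)) {
  if (!length(transcripts)) stop("transcripts must be non-empty")
  tx <- toupper(chartr("Uu", "Tt", as.character(transcripts)))
  names(tx) <- if (is.null(names(transcripts)))
    sprintf("tx%d", seq_along(tx)) else names(transcripts)
  m <- strsplit(toupper(chartr("Uu", "Tt", mirna)), "")[[1L]]
  nm <- length(m)
  seed <- m[seed_positions[1L]:seed_positions[2L]]
  seed_rc <- paste(rev(.COMPLEMENT[seed]), collapse = "")

  out <- list()
  for (ti in seq_along(tx)) {
    tchars <- strsplit(tx[[ti]], "")[[1L]]
    nt <- length(tchars)
    hits <- gregexpr(seed_rc, tx[[ti]], fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    best <- Inf
    best_pos <- NA_integer_
    for (p in as.integer(hits)) {
      # miRNA base i pairs transcript base q - i (antiparallel duplex)
      q <- p + seed_positions[2L]
      lo <- seed_positions[1L]
      while (lo > 1L && q - (lo - 1L) <= nt &&
             .duplexPair(m[lo - 1L], tchars[q - (lo - 1L)]))
        lo <- lo - 1L
      hi <- seed_positions[2L]
      while (hi < nm && q - (hi + 1L) >= 1L &&
             .duplexPair(m[hi + 1L], tchars[q - (hi + 1L)]))
        hi <- hi + 1L
      e <- 0
      for (i in lo:(hi - 1L)) {
        outer <- paste0(m[i], tchars[q - i])
        inner <- paste0(m[i + 1L], tchars[q - i - 1L])
        if (outer %in% .PAIR_TYPES && inner %in% .PAIR_TYPES)
          e <- e + .STACK_DG[outer, inner]
      }
      if (e < best) {
        best <- e
        best_pos <- p
      }
    }
    if (best <= energy_threshold)
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = mirna_id, transcript_id = names(tx)[ti],
        site_position = best_pos, duplex_energy = best,
        algorithm = "mircurate", stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      site_position = integer(), duplex_energy = numeric(),
                      algorithm = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Ingest an externally computed target-pair table
#'
#' Reads a per-algorithm pair list (TSV with `mirna_id`,
#' `transcript_id`, `duplex_energy` and optionally `algorithm`) and
#' applies the free-energy threshold on ingest, so that all algorithms
#' feeding the intersection obey the same cutoff.
#'
#' @param path TSV path.
#' @param energy_threshold cutoff, kcal/mol (default -12; pairs above
#'   it are dropped).
#' @return data.frame of surviving pairs.
#' @export
readTargetPairsTsv <- function(path, energy_threshold = -12) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("mirna_id", "transcript_id", "duplex_energy")
  if (!all(req %in% names(tab)))
    stop("pair table needs columns: ", paste(req, collapse = ", "))
  tab[tab$duplex_energy <= energy_threshold, , drop = FALSE]
}

#' Intersect per-algorithm target predictions
#'
#' Keeps the (miRNA, transcript) pairs present in every input set; the
#' published analysis accepted only pairs predicted by all three
#' algorithms at the -12 kcal/mol threshold.
#'
#' @param sets list (length >= 2) of pair data.frames with `mirna_id`
#'   and `transcript_id` columns.
#' @return data.frame with `mirna_id`, `transcript_id` of the common
#'   pairs.
#' @export
intersectPredictions <- function(sets) {
  if (length(sets) < 2L) stop("need at least two prediction sets")
  keys <- lapply(sets, function(s)
    unique(paste(s$mirna_id, s$transcript_id, sep = "\r")))
  common <- Reduce(intersect, keys)
  if (!length(common))
    return(data.frame(mirna_id = character(),
                      transcript_id = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(common, "\r", fixed = TRUE)
  data.frame(mirna_id = vapply(parts, `[`, "", 1L),
             transcript_id = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Mean predicted targets per miRNA group
#'
#' Per-miRNA target counts (miRNAs with no surviving pair count as 0),
#' group means, and pairwise Welch t-tests between groups; groups with
#' fewer than two miRNAs are skipped with a warning. The published
#' pattern is mock < specific < conserved mean target counts.
#'
#' @param pairs intersected pair data.frame (`mirna_id`,
#'   `transcript_id`).
#' @param groups named character vector: miRNA id -> group label (every
#'   predicted miRNA must be assigned to exactly one group).
#' @return list with `counts` (named per-miRNA), `means` (named
#'   per-group), and `tests` (data.frame `groupA`, `groupB`,
#'   `statistic`, `p.value`).
#' @export
meanTargetsPerGroup <- function(pairs, groups) {
  if (any(!pairs$mirna_id %in% names(groups)))
    stop("every miRNA in 'pairs' must be assigned to a group")
  counts <- setNames(rep(0L, length(groups)), names(groups))
  if (nrow(pairs)) {
    tab <- table(pairs$mirna_id)
    counts[names(tab)] <- as.integer(tab)
  }
  glev <- unique(unname(groups))
  means <- vapply(glev, function(g) mean(counts[groups == g]), 0)
  tests <- list()
  if (length(glev) >= 2L) {
    for (a in seq_len(length(glev) - 1L)) {
      for (b in (a + 1L):length(glev)) {
        ga <- counts[groups == glev[a]]
        gb <- counts[groups == glev[b]]
        if (length(ga) < 2L || length(gb) < 2L) {
          warning("group comparison ", glev[a], " vs ", glev[b],
                  " skipped (fewer than 2 miRNAs)")
          next
        }
        tt <- tryCatch(welchTTest(ga, gb), error = function(e) NULL)
        if (is.null(tt)) {
          warning("group comparison ", glev[a], " vs ", glev[b],
                  " skipped (degenerate variance)")
          next
        }
        tests[[length(tests) + 1L]] <- data.frame(
          groupA = glev[a], groupB = glev[b],
          statistic = tt$statistic, p.value = tt$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(counts = counts, means = means,
       tests = if (length(tests)) do.call(rbind, tests)
               else data.frame(groupA = character(),
                               groupB = character(),
                               statistic = numeric(),
                               p.value = numeric()))
}
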