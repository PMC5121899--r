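# Independent reference implementations used to validate the package's
# dynamic programmes. They deliberately use different recurrences and
# run in plain R.

# Maximum number of non-crossing base pairs (min hairpin loop 3),
# top-down recursion splitting on the FIRST base (the C++ engine splits
# on the last base, bottom-up).
oracleMaxPairs <- function(seq) {
  s <- strsplit(toupper(chartr("Uu", "Tt", seq)), "")[[1L]]
  n <- length(s)
  can_pair <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (j - i < 4L) return(0L)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- rec(i + 1L, j)  # i unpaired
    for (k in (i + 4L):j) {
      if (!can_pair(s[i], s[k])) next
      best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    memo[[key]] <- best
    best
  }
  if (n < 5L) return(0L)
  rec(1L, n)
}

# Minimum gains + losses for one presence pattern under Dollo parsimony
# (at most one 0->1 transition), by exhaustive enumeration of internal
# node states. `root_constrained` fixes the root present and does not
# charge its gain.
oracleDollo <- function(present_tips, tree, root_constrained = FALSE) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  internal <- (n_tip + 1L):n_node
  root <- n_tip + 1L
  tip_state <- as.integer(tree$tip.label %in% present_tips)
  best <- Inf
  for (mask in 0:(2^length(internal) - 1L)) {
    st <- integer(n_node)
    st[seq_len(n_tip)] <- tip_state
    st[internal] <- bitwAnd(bitwShiftR(mask, seq_along(internal) - 1L), 1L)
    if (root_constrained && st[root] == 0L) next
    gains <- sum(st[tree$edge[, 1L]] == 0L & st[tree$edge[, 2L]] == 1L)
    if (!root_constrained && st[root] == 1L) gains <- gains + 1L
    if (gains > 1L) next
    if (root_constrained && gains > 0L) next
    losses <- sum(st[tree$edge[, 1L]] == 1L & st[tree$edge[, 2L]] == 0L)
    best <- min(best, gains + losses)
  }
  best
}

# Welch t statistic from first principles
oracleWelchT <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}
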