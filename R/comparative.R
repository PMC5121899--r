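## Comparative layer: species x family presence matrix, Dollo parsimony
## gain/loss reconstruction on a fixed rooted tree, genomic cluster
## detection, and the cluster-length / genome-size regression.

#' Build a species x family presence matrix
#'
#' @param per_species_families named list: species -> character vector
#'   of family names present in that species.
#' @param genomic_only optional named list: species -> families found
#'   in the genome but without expression data (state 2; counts as
#'   present for parsimony).
#' @return integer matrix, rows = species, columns = families
#'   (0 absent, 1 present, 2 present without expression).
#' @examples
#' buildPresenceMatrix(list(A = c("f1"), B = c("f1", "f2")))
#' @export
buildPresenceMatrix <- function(per_species_families,
                                genomic_only = list()) {
  if (length(per_species_families) < 2L)
    stop("need at least two species")
  species <- names(per_species_families)
  fams <- unique(c(unlist(per_species_families, use.names = FALSE),
                   unlist(genomic_only, use.names = FALSE)))
  m <- matrix(0L, length(species), length(fams),
              dimnames = list(species, fams))
  for (sp in species) {
    m[sp, per_species_families[[sp]]] <- 1L
    if (sp %in% names(genomic_only)) m[sp, genomic_only[[sp]]] <- 2L
  }
  m
}

# tips under each node of an ape phylo (index = node id)
.cladeTips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  tips <- vector("list", n_node)
  for (i in seq_len(n_tip)) tips[[i]] <- tree$tip.label[i]
  # resolve internal nodes bottom-up, robust to edge-matrix ordering
  repeat {
    todo <- which(vapply(tips, is.null, TRUE))
    if (!length(todo)) break
    for (nd in todo) {
      kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
      if (all(!vapply(tips[kids], is.null, TRUE)))
        tips[[nd]] <- unlist(tips[kids])
    }
  }
  tips
}

.edgeLabel <- function(tips) paste(sort(tips), collapse = ",")

#' Dollo parsimony gain/loss reconstruction
#'
#' Each family is gained exactly once: on the edge subtending the last
#' common ancestor of the species carrying it (reported as `"root"`
#' when that ancestor is the root), with the minimal set of loss edges
#' inside the gain clade explaining the absent species. Families listed
#' in `root_present` are constrained present at the root (ancient
#' families whose origin predates the tree) and contribute losses only.
#' A state of 2 in the matrix (genomic presence without expression)
#' counts as present.
#'
#' @param matrix presence matrix from [buildPresenceMatrix()].
#' @param tree rooted `phylo` whose tip labels equal the matrix rows.
#' @param root_present character vector of root-constrained families.
#' @return list of class `"DolloGainLoss"`: `events` (data.frame with
#'   `family`, `type` = gain/loss, `node`, `edge` = comma-joined sorted
#'   tips of the child clade, or `"root"`), and `edge_totals`
#'   (data.frame with `edge`, `gains`, `losses`).
#' @examples
#' tr <- readSpeciesTree(text = "((A,B),(C,D));")
#' m <- buildPresenceMatrix(list(A = "f1", B = character(),
#'                               C = "f1", D = "f1"))
#' dolloGainLoss(m, tr)
#' @export
dolloGainLoss <- function(matrix, tree, root_present = character()) {
  tips_by_node <- .cladeTips(tree)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  if (!setequal(rownames(matrix), tree$tip.label))
    stop("contract error: matrix species must equal tree leaves")
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]

  events <- list()
  for (fam in colnames(matrix)) {
    present <- rownames(matrix)[matrix[, fam] >= 1L]
    constrained <- fam %in% root_present
    if (!length(present) && !constrained) {
      warning("family '", fam, "' present in no species; no gain placed")
      next
    }
    all_absent <- vapply(seq_along(tips_by_node), function(nd)
      !any(tips_by_node[[nd]] %in% present), TRUE)

    gain_node <- if (constrained) root
      else if (length(present) == 1L) match(present, tree$tip.label)
      else ape::getMRCA(tree, present)
    if (!constrained) {
      events[[length(events) + 1L]] <- data.frame(
        family = fam, type = "gain", node = gain_node,
        edge = if (gain_node == root) "root"
               else .edgeLabel(tips_by_node[[gain_node]]),
        stringsAsFactors = FALSE)
    }
    # losses: maximal all-absent subtrees within the gain clade
    if (length(present) || constrained) {
      in_clade <- vapply(seq_along(tips_by_node), function(nd)
        all(tips_by_node[[nd]] %in% tips_by_node[[gain_node]]), TRUE)
      for (nd in which(all_absent & in_clade)) {
        if (nd == gain_node) next
        p <- parent[nd]
        if (p == 0L || all_absent[p]) next  # not maximal
        events[[length(events) + 1L]] <- data.frame(
          family = fam, type = "loss", node = nd,
          edge = .edgeLabel(tips_by_node[[nd]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events)
    else data.frame(family = character(), type = character(),
                    node = integer(), edge = character(),
                    stringsAsFactors = FALSE)
  edges <- unique(events$edge)
  edge_totals <- data.frame(
    edge = edges,
    gains = vapply(edges, function(e)
      sum(events$type == "gain" & events$edge == e), 0L),
    losses = vapply(edges, function(e)
      sum(events$type == "loss" & events$edge == e), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(events = events, edge_totals = edge_totals),
            class = "DolloGainLoss")
}

#' @export
print.DolloGainLoss <- function(x, ...) {
  cat("Dollo gain/loss reconstruction:",
      sum(x$events$type == "gain"), "gains,",
      sum(x$events$type == "loss"), "losses\n")
  print(x$edge_totals)
  invisible(x)
}

#' Detect genomic miRNA clusters
#'
#' Single-linkage chaining: consecutive precursor loci on one contig
#' (strand-agnostic) whose gap is at most `max_gap` bp join one
#' cluster. Only clusters of at least `min_members` loci are emitted.
#'
#' @param loci a named `GRanges` of precursor loci (names become member
#'   identifiers).
#' @param max_gap maximum inter-locus gap, bp (default 20 kb).
#' @param min_members minimum cluster size (default 2; singletons are
#'   not clusters).
#' @return data.frame with one row per cluster: `cluster_id`,
#'   `seqnames`, `start`, `end`, `n_members`, `span_bp`, `members`
#'   (comma-joined, in genomic order).
#' @export
detectClusters <- function(loci, max_gap = 20000L, min_members = 2L) {
  if (!length(loci)) {
    return(data.frame(cluster_id = character(), seqnames = character(),
                      start = integer(), end = integer(),
                      n_members = integer(), span_bp = integer(),
                      members = character(), stringsAsFactors = FALSE))
  }
  if (is.null(names(loci)))
    names(loci) <- sprintf("locus%d", seq_along(loci))
  out <- list()
  for (sq in unique(as.character(seqnames(loci)))) {
    sub <- loci[as.character(seqnames(loci)) == sq]
    sub <- sub[order(start(sub), end(sub))]
    if (!length(sub)) next
    gap <- start(sub)[-1L] - head(cummax(end(sub)), -1L) - 1L
    grp <- cumsum(c(TRUE, gap > max_gap))
    for (g in unique(grp)) {
      mem <- sub[grp == g]
      if (length(mem) < min_members) next
      out[[length(out) + 1L]] <- data.frame(
        seqnames = sq, start = min(start(mem)), end = max(end(mem)),
        n_members = length(mem),
        span_bp = max(end(mem)) - min(start(mem)),
        members = paste(names(mem), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(cluster_id = character(), seqnames = character(),
                      start = integer(), end = integer(),
                      n_members = integer(), span_bp = integer(),
                      members = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$seqnames, res$start), , drop = FALSE]
  cbind(data.frame(cluster_id = sprintf("cluster%d", seq_len(nrow(res))),
                   stringsAsFactors = FALSE), res)
}

#' Regression of mean cluster length on genome size
#'
#' Ordinary least squares of per-species mean cluster length (kb) on
#' genome size (Gbp); the fit quality is the squared Pearson
#' correlation.
#'
#' @param points data.frame (or matrix) whose first column is genome
#'   size and second is mean cluster length.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @examples
#' clusterSizeRegression(data.frame(g = c(1, 2, 3), l = c(2, 4, 6)))
#' @export
clusterSizeRegression <- function(points) {
  x <- points[[1L]]
  y <- points[[2L]]
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("zero variance in genome size")
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r_squared = stats::cor(x, y)^2)
}
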