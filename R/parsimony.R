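## Small parsimony over scaffold labels 1 (split) / 2 (not split) with the
## wildcard label 3 (can't tell).  An "event" is an edge whose endpoints
## carry different labels: the branch on which a rearrangement disrupting
## the scaffold must have occurred.  The DP minimises the number of event
## edges over all {1,2}-completions of the internal vertices and of the
## wildcard leaves.

.BIG <- 1e9

## Up-pass cost matrices.  L: npat x N integer matrix of leaf labels in
## {1,2,3}, columns ordered by tip number.  Returns per-vertex cost of the
## subtree when the vertex is labelled 1 (c1) or 2 (c2).
.dp_up <- function(phy, L) {
  N <- length(phy$tip.label)
  nv <- N + phy$Nnode
  np <- nrow(L)
  c1 <- matrix(0, np, nv)
  c2 <- matrix(0, np, nv)
  c1[, seq_len(N)] <- ifelse(L == 2L, .BIG, 0)
  c2[, seq_len(N)] <- ifelse(L == 1L, .BIG, 0)
  e <- phy$edge
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1L]
    ch <- e[i, 2L]
    c1[, p] <- c1[, p] + pmin(c1[, ch], c2[, ch] + 1)
    c2[, p] <- c2[, p] + pmin(c2[, ch], c1[, ch] + 1)
  }
  list(c1 = c1, c2 = c2, root = N + 1L)
}

.min_events_mat <- function(phy, L) {
  phy <- .postorder_tree(phy)
  d <- .dp_up(phy, L)
  as.integer(pmin(d$c1[, d$root], d$c2[, d$root]))
}

## Map a named label vector onto tip-number order.
.leaf_label_row <- function(tree, leaf_labels) {
  labs <- tree$tip.label
  if (is.null(names(leaf_labels))) {
    if (length(leaf_labels) != length(labs))
      stop("unnamed labels must have one entry per leaf")
    names(leaf_labels) <- labs
  }
  miss <- setdiff(labs, names(leaf_labels))
  if (length(miss))
    stop("missing label for leaf: ", paste(miss, collapse = ", "))
  v <- as.integer(leaf_labels[labs])
  if (anyNA(v) || any(!v %in% 1:3))
    stop("labels must be 1 (split), 2 (not split) or 3 (can't tell)")
  matrix(v, nrow = 1L)
}

#' Minimal number of event branches for one scaffold
#'
#' Given a tree whose leaves are labelled 1 (the scaffold is split in that
#' genome), 2 (not split) or 3 (can't tell), returns the minimum, over all
#' assignments of 1/2 to the internal vertices and to the wildcard leaves,
#' of the number of edges whose endpoints differ.  Computed by a
#' two-state unit-cost dynamic programme with label 3 as a free state; the
#' optimum does not depend on where the unrooted tree is rooted.
#'
#' @param tree a `"phylo"` tree (binary or multifurcating).
#' @param leaf_labels integer vector in `{1,2,3}`, named by tip label (or
#'   unnamed, in tip order).
#' @return Non-negative integer event count.
#' @examples
#' tr <- read_newick("(1,2,(3,4));")
#' min_events(tr, c(`1` = 1, `2` = 2, `3` = 2, `4` = 2))
#' @export
min_events <- function(tree, leaf_labels) {
  .min_events_mat(tree, .leaf_label_row(tree, leaf_labels))
}

## Name every edge by its leaf-set bipartition, written with the side
## containing the smallest leaf label first, e.g. "1,2,5|3,4".
.edge_names <- function(phy) {
  N <- length(phy$tip.label)
  nv <- N + phy$Nnode
  labs <- phy$tip.label
  sorted <- .sort_labels(labs)
  tl <- vector("list", nv)
  tl[seq_len(N)] <- as.list(seq_len(N))
  e <- phy$edge
  for (i in seq_len(nrow(e)))
    tl[[e[i, 1L]]] <- c(tl[[e[i, 1L]]], tl[[e[i, 2L]]])
  vapply(seq_len(nrow(e)), function(i) {
    A <- labs[tl[[e[i, 2L]]]]
    B <- setdiff(labs, A)
    A <- intersect(sorted, A)   # sorted order
    B <- intersect(sorted, B)
    if (sorted[1L] %in% A) {
      paste0(paste(A, collapse = ","), "|", paste(B, collapse = ","))
    } else {
      paste0(paste(B, collapse = ","), "|", paste(A, collapse = ","))
    }
  }, "")
}

## Enumerate every optimal {1,2}-labelling of all vertices (wildcard
## leaves included) by backtracking over the DP choice points.
.optimal_labelings <- function(phy, L1) {
  phy <- .postorder_tree(phy)
  N <- length(phy$tip.label)
  nv <- N + phy$Nnode
  d <- .dp_up(phy, L1)
  c1 <- d$c1[1L, ]
  c2 <- d$c2[1L, ]
  best <- min(c1[d$root], c2[d$root])
  root_states <- which(c(c1[d$root], c2[d$root]) == best)
  ass <- lapply(root_states, function(s) {
    a <- integer(nv)
    a[d$root] <- s
    a
  })
  e <- phy$edge
  ## reverse postorder: parents are labelled before their children
  for (i in rev(seq_len(nrow(e)))) {
    p <- e[i, 1L]
    ch <- e[i, 2L]
    nxt <- vector("list", 2L * length(ass))
    cnt <- 0L
    for (a in ass) {
      s <- a[p]
      cost1 <- c1[ch] + (s != 1L)
      cost2 <- c2[ch] + (s != 2L)
      mn <- min(cost1, cost2)
      if (cost1 == mn) {
        b <- a
        b[ch] <- 1L
        cnt <- cnt + 1L
        nxt[[cnt]] <- b
      }
      if (cost2 == mn) {
        b <- a
        b[ch] <- 2L
        cnt <- cnt + 1L
        nxt[[cnt]] <- b
      }
    }
    ass <- nxt[seq_len(cnt)]
  }
  list(phy = phy, labelings = do.call(rbind, ass),
       event_number = as.integer(best))
}

#' All optimal placements of a scaffold's events on a tree
#'
#' Runs the parsimony DP and enumerates, by traceback over its choice
#' points, every optimal full labelling (every wildcard leaf and internal
#' vertex resolved to 1 or 2).  The candidate event branches are the edges
#' that separate a 1 from a 2 in at least one optimal labelling; when the
#' optimum is ambiguous, the unit score of each event is split into
#' fractions over the alternative branches.
#'
#' @inheritParams min_events
#' @param scaffold optional scaffold identifier carried into the result.
#' @return An object of class `"event_assignment"` with components
#'   `scaffold`, `event_number`, `candidate_edges` (bipartition strings),
#'   `optimal_labeling_count`, `edge_event_counts`, `edge_fractions`
#'   (summing to `event_number`), and the enumerated `labelings` matrix.
#' @export
optimal_assignments <- function(tree, leaf_labels, scaffold = NA) {
  L1 <- .leaf_label_row(tree, leaf_labels)
  opt <- .optimal_labelings(tree, L1)
  phy <- opt$phy
  e <- phy$edge
  en <- .edge_names(phy)
  A <- opt$labelings
  is_event <- A[, e[, 1L], drop = FALSE] != A[, e[, 2L], drop = FALSE]
  counts <- colSums(is_event)
  names(counts) <- en
  nlab <- nrow(A)
  keep <- counts > 0
  structure(list(
    scaffold = scaffold,
    event_number = opt$event_number,
    candidate_edges = en[keep],
    optimal_labeling_count = nlab,
    edge_event_counts = counts[keep],
    edge_fractions = counts[keep] / nlab,
    labelings = A,
    leaf_labels = setNames(as.integer(L1[1L, ]), phy$tip.label),
    tree = phy
  ), class = "event_assignment")
}

#' @export
print.event_assignment <- function(x, ...) {
  cat("<event_assignment>",
      if (!is.na(x$scaffold)) paste0(" scaffold ", x$scaffold), "\n",
      "  events: ", x$event_number,
      "  optimal labelings: ", x$optimal_labeling_count, "\n", sep = "")
  if (length(x$candidate_edges)) {
    for (i in seq_along(x$candidate_edges))
      cat(sprintf("  %s  (fraction %.3g)\n",
                  x$candidate_edges[i], x$edge_fractions[i]))
  }
  invisible(x)
}

#' Fractional event weight of each candidate branch
#'
#' The weight of an edge is the fraction of optimal labellings in which it
#' is an event; weights sum to the event number, distributing each unit
#' score over its alternative branches.
#'
#' @param a an `"event_assignment"`.
#' @return Named numeric vector over candidate edges.
#' @export
fractional_edge_weights <- function(a) {
  if (!inherits(a, "event_assignment"))
    stop("`a` must be an event_assignment")
  a$edge_event_counts / a$optimal_labeling_count
}

#' Detect conflicts in a scaffold's label pattern on a tree
#'
#' A conflict arises when two genomes that share a scaffold's adjacencies
#' (both leaves labelled 2) are reconstructed with a split (label 1)
#' vertex on the path between them, contradicting the principle that a
#' conserved adjacency forbids any disruption on the connecting path.
#' Conflicts are assessed over optimal labellings only.
#'
#' @inheritParams min_events
#' @return A list with `conflict` (`TRUE` if every optimal labelling has
#'   at least one offending leaf pair), `pairs` (two-column character
#'   matrix: the union of offending 2-2 leaf pairs over optimal
#'   labellings) and `optimal_labeling_count`.
#' @export
detect_conflict <- function(tree, leaf_labels) {
  L1 <- .leaf_label_row(tree, leaf_labels)
  opt <- .optimal_labelings(tree, L1)
  phy <- opt$phy
  N <- length(phy$tip.label)
  nv <- N + phy$Nnode
  leaves2 <- which(L1[1L, ] == 2L)
  A <- opt$labelings
  parent <- integer(nv)
  e <- phy$edge
  parent[e[, 2L]] <- e[, 1L]
  path_between <- function(u, v) {
    au <- u
    while (parent[au[length(au)]] != 0L)
      au <- c(au, parent[au[length(au)]])
    av <- v
    while (parent[av[length(av)]] != 0L)
      av <- c(av, parent[av[length(av)]])
    anc <- intersect(au, av)[1L]   # first common ancestor on u's path
    c(au[seq_len(match(anc, au))], av[seq_len(match(anc, av) - 1L)])
  }
  pairs <- if (length(leaves2) >= 2L) utils::combn(leaves2, 2L) else
    matrix(integer(0), 2L, 0L)
  offending <- matrix(FALSE, nrow(A), ncol(pairs))
  if (ncol(pairs)) {
    paths <- lapply(seq_len(ncol(pairs)), function(j)
      path_between(pairs[1L, j], pairs[2L, j]))
    for (r in seq_len(nrow(A)))
      offending[r, ] <- vapply(paths, function(p) any(A[r, p] == 1L), NA)
  }
  any_off <- ncol(pairs) > 0 && all(rowSums(offending) > 0)
  union_pairs <- which(colSums(offending) > 0)
  out_pairs <- if (length(union_pairs)) {
    cbind(phy$tip.label[pairs[1L, union_pairs]],
          phy$tip.label[pairs[2L, union_pairs]])
  } else {
    matrix(character(0), 0L, 2L)
  }
  colnames(out_pairs) <- c("leaf_a", "leaf_b")
  list(conflict = any_off, pairs = out_pairs,
       optimal_labeling_count = nrow(A))
}

## Reorder the columns of a label matrix to a tree's tip order.
.label_matrix_for_tree <- function(tree, M) {
  labs <- tree$tip.label
  if (is.null(colnames(M)) || !setequal(labs, colnames(M)))
    stop("tree leaves and label-matrix genomes do not match")
  M[, labs, drop = FALSE]
}

#' Score a tree against a scaffold label matrix
#'
#' The total event score of a tree is the sum over scaffolds of the
#' minimal event number for that scaffold's label pattern.  Restricted to
#' the classes seen with moderate rearrangement this is the weighted
#' total: number of 1-event scaffolds + 2 x number of 2-event scaffolds +
#' 3 x number of 3-event scaffolds (scaffolds needing more events
#' contribute their actual count).
#'
#' @param tree a `"phylo"` tree whose tips are the genome names.
#' @param M a `"label_matrix"` (rows scaffolds, columns genomes, entries
#'   in `{1,2,3}`).
#' @return An object of class `"tree_score"`: `total_events`,
#'   `scaffold_class_counts` (events 0 / 1 / 2 / 3+), `per_scaffold`
#'   event numbers, and the tree's `topology_key`.
#' @export
score_tree <- function(tree, M) {
  L <- .label_matrix_for_tree(tree, M)
  pat <- apply(L, 1L, paste0, collapse = "")
  uidx <- which(!duplicated(pat))
  ev_u <- .min_events_mat(tree, L[uidx, , drop = FALSE])
  ev <- ev_u[match(pat, pat[uidx])]
  classes <- c(`0` = sum(ev == 0L), `1` = sum(ev == 1L),
               `2` = sum(ev == 2L), `3+` = sum(ev >= 3L))
  structure(list(total_events = sum(ev),
                 scaffold_class_counts = classes,
                 per_scaffold = setNames(ev, rownames(M)),
                 tree_key = topology_key(tree)),
            class = "tree_score")
}

#' @export
print.tree_score <- function(x, ...) {
  cat("<tree_score> total events:", x$total_events, "\n")
  cat("  scaffolds by event number:",
      paste(names(x$scaffold_class_counts), x$scaffold_class_counts,
            sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Score and rank candidate tree topologies
#'
#' Scores every candidate tree by its total event count for the label
#' matrix and ranks them by competition rank: 1 plus the number of
#' strictly better-scoring trees, so ties share the best rank.
#'
#' @param M a `"label_matrix"`.
#' @param trees a `"multiPhylo"` list (or single tree) on the same leaf
#'   set as `M`'s genomes, e.g. from [enumerate_topologies()].
#' @param reference the tree whose rank is of interest (typically the
#'   data-generating tree); must be topologically identical to one of
#'   `trees`.
#' @return A data frame with one row per tree (`key`, `total_events`,
#'   `rank`), with the reference tree's rank in attribute
#'   `"reference_rank"`.
#' @export
rank_trees <- function(M, trees, reference) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  keys <- vapply(trees, topology_key, "")
  ref_key <- topology_key(reference)
  pos <- match(ref_key, keys)
  if (is.na(pos))
    stop("reference tree not found among the candidate trees")
  pat <- apply(M, 1L, paste0, collapse = "")
  uidx <- which(!duplicated(pat))
  cnt <- tabulate(match(pat, pat[uidx]), nbins = length(uidx))
  Mu <- M[uidx, , drop = FALSE]
  totals <- vapply(trees, function(t) {
    L <- .label_matrix_for_tree(t, Mu)
    sum(.min_events_mat(t, L) * cnt)
  }, 0)
  res <- data.frame(key = keys, total_events = totals,
                    rank = rank(totals, ties.method = "min"),
                    stringsAsFactors = FALSE)
  attr(res, "reference_rank") <- res$rank[pos]
  res
}

#' Event assignments for every scaffold of a label matrix
#'
#' @param tree a `"phylo"` tree on the label matrix's genomes.
#' @param M a `"label_matrix"`.
#' @return Named list of `"event_assignment"` objects, one per scaffold.
#' @export
assign_events <- function(tree, M) {
  L <- .label_matrix_for_tree(tree, M)
  out <- lapply(seq_len(nrow(L)), function(i)
    optimal_assignments(tree, setNames(L[i, ], colnames(L)),
                        scaffold = rownames(M)[i]))
  names(out) <- rownames(M)
  out
}
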