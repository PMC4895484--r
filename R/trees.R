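## Unrooted leaf-labelled binary trees.  Trees are ape "phylo" objects with
## tip labels "1".."N" (genome indices) or user names; the unrooted tree is
## stored rooted at an arbitrary internal vertex with a trifurcation, the
## standard ape representation.

## Convert a raw undirected edge list (leaves 1..N, internals N+1..2N-2,
## centre vertex N+1 guaranteed present) into a valid phylo object.
.edges_to_phylo <- function(edges, N) {
  nv <- N + N - 2L
  adj <- vector("list", nv)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1L]
    v <- edges[i, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  ## DFS from the centre vertex, renumbering internals in preorder so the
  ## root of the stored representation is N+1, as phylo requires
  new_id <- integer(nv)
  new_id[seq_len(N)] <- seq_len(N)
  new_id[N + 1L] <- N + 1L
  next_internal <- N + 2L
  edge_out <- matrix(0L, nrow(edges), 2L)
  k <- 0L
  visit_main <- function(v, parent) {
    for (w in adj[[v]]) {
      if (w != parent) {
        if (w > N && new_id[w] == 0L) {
          new_id[w] <<- next_internal
          next_internal <<- next_internal + 1L
        }
        k <<- k + 1L
        edge_out[k, ] <<- c(new_id[v], new_id[w])
        visit_main(w, v)
      }
    }
  }
  visit_main(N + 1L, 0L)
  phy <- list(edge = edge_out, Nnode = N - 2L,
              tip.label = as.character(seq_len(N)))
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

.base_star_edges <- function(N) {
  cbind(rep(N + 1L, 3L), 1:3)
}

#' Uniform random unrooted binary tree
#'
#' Generates a leaf-labelled unrooted binary tree on leaves `1..N` by
#' sequential leaf addition: starting from the 3-leaf star, each further
#' leaf is attached to a uniformly chosen existing edge.  This yields the
#' uniform distribution over the `(2N-5)!!` leaf-labelled topologies.
#' Uses the session RNG.
#'
#' @param N number of leaves, at least 3.
#' @return An unrooted `"phylo"` tree with tip labels `"1".."N"`; for
#'   binary trees on N leaves it has `2N - 3` edges (11 for N = 7: 7
#'   terminal and 4 internal branches).
#' @export
random_unrooted_tree <- function(N) {
  N <- as.integer(N)
  if (is.na(N) || N < 3L) stop("invalid size: need at least 3 leaves")
  edges <- .base_star_edges(N)
  next_internal <- N + 2L
  for (leaf in seq_len(N)[-(1:3)]) {
    i <- sample.int(nrow(edges), 1L)
    u <- edges[i, 1L]
    v <- edges[i, 2L]
    w <- next_internal
    next_internal <- next_internal + 1L
    edges <- rbind(edges[-i, , drop = FALSE], c(u, w), c(w, v), c(w, leaf))
  }
  .edges_to_phylo(edges, N)
}

#' Enumerate all unrooted binary topologies
#'
#' Produces every leaf-labelled unrooted binary topology on leaves `1..N`
#' exactly once, by recursively inserting each leaf into every edge of
#' every smaller tree.  The count is the double factorial `(2N-5)!!`
#' (3, 15, 105, 945 for N = 4..7).
#'
#' @param N number of leaves, between 3 and 9 (the practical bound:
#'   N = 10 already has 2,027,025 topologies).
#' @return A `"multiPhylo"` list of unrooted `"phylo"` trees.
#' @export
enumerate_topologies <- function(N) {
  N <- as.integer(N)
  if (is.na(N) || N < 3L || N > 9L)
    stop("invalid size: supported leaf counts are 3..9")
  acc <- vector("list", .n_topologies(N))
  cnt <- 0L
  recur <- function(edges, next_leaf, next_internal) {
    if (next_leaf > N) {
      cnt <<- cnt + 1L
      acc[[cnt]] <<- edges
      return(invisible(NULL))
    }
    for (i in seq_len(nrow(edges))) {
      u <- edges[i, 1L]
      v <- edges[i, 2L]
      w <- next_internal
      e2 <- rbind(edges[-i, , drop = FALSE],
                  c(u, w), c(w, v), c(w, next_leaf))
      recur(e2, next_leaf + 1L, next_internal + 1L)
    }
  }
  recur(.base_star_edges(N), 4L, N + 2L)
  trees <- lapply(acc, .edges_to_phylo, N = N)
  class(trees) <- "multiPhylo"
  trees
}

.n_topologies <- function(N) {
  if (N <= 3L) return(1L)
  prod(seq(3L, 2L * N - 5L, by = 2L))
}

.postorder_tree <- function(phy) {
  if (!identical(attr(phy, "order"), "postorder"))
    phy <- stats::reorder(phy, "postorder")
  phy
}

## Bitmask of tips (bit position = rank of tip label) below every vertex.
.tip_masks <- function(phy) {
  N <- length(phy$tip.label)
  nv <- N + phy$Nnode
  ord <- match(phy$tip.label, .sort_labels(phy$tip.label))
  mask <- numeric(nv)
  mask[seq_len(N)] <- 2^(ord - 1)
  e <- phy$edge
  for (i in seq_len(nrow(e)))
    mask[e[i, 1L]] <- mask[e[i, 1L]] + mask[e[i, 2L]]
  mask
}

.sort_labels <- function(labs) {
  num <- suppressWarnings(as.numeric(labs))
  if (!anyNA(num)) labs[order(num)] else sort(labs)
}

#' Canonical key of an unrooted leaf-labelled topology
#'
#' Encodes the tree as its sorted set of leaf-set bipartitions (splits),
#' each split written from the side not containing the smallest leaf
#' label.  Two trees receive the same key if and only if they are
#' isomorphic as leaf-labelled unrooted topologies, regardless of internal
#' vertex numbering, edge order or rooting of the stored representation.
#'
#' @param phy a `"phylo"` tree.
#' @return A character scalar.
#' @export
topology_key <- function(phy) {
  if (!inherits(phy, "phylo")) stop("`phy` must be a phylo tree")
  phy <- .postorder_tree(phy)
  N <- length(phy$tip.label)
  mask <- .tip_masks(phy)
  child <- phy$edge[, 2L]
  im <- mask[child[child > N]]
  im <- im[im < 2^N - 1]          # drop the root pseudo-split, if any
  im <- ifelse(im %% 2 >= 1, 2^N - 1 - im, im)
  paste0("n", N,
         "[", paste(sort(unique(im)), collapse = "|"), "]",
         "[", paste(.sort_labels(phy$tip.label), collapse = ","), "]")
}

#' Newick input and output for unrooted trees
#'
#' Thin wrappers around ape's Newick parser/writer that normalise the tree
#' to the unrooted representation used throughout the package (singles
#' collapsed, root unresolved) and reject trees with fewer than 3 leaves.
#' Reading then writing preserves the topology key.
#'
#' @param x a file path or a literal Newick string.
#' @return `read_newick()`: a `"phylo"` tree, or a `"multiPhylo"` list when
#'   the input holds several trees (e.g. one Newick per line).
#' @export
read_newick <- function(x) {
  phy <- if (length(x) == 1L && file.exists(x)) {
    ape::read.tree(x)
  } else {
    ape::read.tree(text = paste(x, collapse = "\n"))
  }
  if (is.null(phy)) stop("Newick parse error: could not read a tree")
  if (inherits(phy, "multiPhylo")) {
    out <- lapply(phy, .normalise_tree)
    class(out) <- "multiPhylo"
    return(out)
  }
  .normalise_tree(phy)
}

.normalise_tree <- function(phy) {
  if (length(phy$tip.label) < 3L)
    stop("Newick parse error: a tree needs at least 3 leaves")
  phy <- ape::collapse.singles(phy)
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  phy
}

#' @param phy a `"phylo"` tree (or `"multiPhylo"` list).
#' @param path optional file path; when `NULL` the Newick text is returned.
#' @rdname read_newick
#' @export
write_newick <- function(phy, path = NULL) {
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Check the anatomy of an unrooted binary tree
#'
#' @param phy a `"phylo"` tree.
#' @return `TRUE` if every leaf has degree 1, every internal vertex degree
#'   3, and the edge count is `2N - 3`.
#' @export
is_binary_unrooted <- function(phy) {
  N <- length(phy$tip.label)
  deg <- tabulate(phy$edge, nbins = N + phy$Nnode)
  all(deg[seq_len(N)] == 1L) &&
    all(deg[(N + 1L):(N + phy$Nnode)] == 3L) &&
    nrow(phy$edge) == 2L * N - 3L
}
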