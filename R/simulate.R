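## Simulation of inversion evolution along an unrooted tree, with one leaf
## genome fragmented into scaffolds to emulate a draft assembly.

## Undirected incidence structure: for each vertex, its neighbours and the
## tree$edge row of the connecting branch.
.incidence <- function(phy) {
  nv <- length(phy$tip.label) + phy$Nnode
  nb <- vector("list", nv)
  er <- vector("list", nv)
  e <- phy$edge
  for (i in seq_len(nrow(e))) {
    u <- e[i, 1L]
    v <- e[i, 2L]
    nb[[u]] <- c(nb[[u]], v)
    er[[u]] <- c(er[[u]], i)
    nb[[v]] <- c(nb[[v]], u)
    er[[v]] <- c(er[[v]], i)
  }
  list(nb = nb, er = er)
}

## Draw one inversion (two distinct boundaries, uniform over pairs), apply
## it to the gene vector, and record the adjacencies it destroys.
.random_inversion <- function(genes) {
  n <- length(genes)
  cuts <- sort(sample(0:n, 2L))
  cl <- cuts[1L]
  cr <- cuts[2L]
  broken <- character(0)
  if (cl > 0L) broken <- .adj_key(genes[cl], genes[cl + 1L])
  if (cr < n) broken <- c(broken, .adj_key(genes[cr], genes[cr + 1L]))
  idx <- (cl + 1L):cr
  genes[idx] <- -rev(genes[idx])
  created <- character(0)
  if (cl > 0L) created <- .adj_key(genes[cl], genes[cl + 1L])
  if (cr < n) created <- c(created, .adj_key(genes[cr], genes[cr + 1L]))
  list(genes = genes, cut_left = cl, cut_right = cr,
       broken = paste(broken, collapse = ";"),
       created = paste(created, collapse = ";"))
}

#' Evolve genomes along a tree by random inversions
#'
#' Places the identity genome `1..n_genes` at a root vertex (a uniformly
#' chosen internal vertex by default; the choice is immaterial because
#' inversions are symmetric) and walks outward, applying exactly
#' `k_per_branch` inversions on every branch.  Each inversion's two
#' endpoints are a uniformly drawn pair of distinct inter-gene boundaries.
#' Every event is logged with its branch, cut coordinates and the (1 or 2)
#' adjacencies it destroyed in the genome state at the time of
#' application.  Uses the session RNG.
#'
#' @param tree a `"phylo"` tree (binary or multifurcating).
#' @param n_genes number of genes in the ancestral chromosome.
#' @param k_per_branch inversions applied on each branch.
#' @param root_vertex optional internal vertex id to root the walk at.
#' @return A list with `leaf_genomes` (named list of `"genome"`),
#'   `events` (data frame: `branch` bipartition string, `cut_left`,
#'   `cut_right`, and the `;`-separated `broken_adjacencies` and
#'   `created_adjacencies`), and `root_vertex`.  The event log has
#'   `k_per_branch` rows per branch.
#' @export
evolve_genomes <- function(tree, n_genes, k_per_branch, root_vertex = NULL) {
  n_genes <- as.integer(n_genes)
  k_per_branch <- as.integer(k_per_branch)
  if (n_genes < 2L) stop("need at least 2 genes")
  if (k_per_branch < 0L) stop("k_per_branch must be non-negative")
  N <- length(tree$tip.label)
  nv <- N + tree$Nnode
  internal <- (N + 1L):nv
  if (is.null(root_vertex)) {
    root_vertex <- if (length(internal) == 1L) internal else
      sample(internal, 1L)
  }
  root_vertex <- as.integer(root_vertex)
  if (!root_vertex %in% internal) stop("root_vertex must be internal")
  inc <- .incidence(tree)
  enames <- .edge_names(.postorder_tree(tree))
  ## .edge_names is aligned with the postorder edge rows; realign to
  ## tree$edge rows via the unordered vertex pair
  pkey <- function(e) paste(pmin(e[, 1L], e[, 2L]),
                            pmax(e[, 1L], e[, 2L]))
  po <- .postorder_tree(tree)
  enames <- setNames(enames, pkey(po$edge))[pkey(tree$edge)]
  genomes_at <- vector("list", nv)
  genomes_at[[root_vertex]] <- seq_len(n_genes)
  events <- vector("list", k_per_branch * nrow(tree$edge))
  nev <- 0L
  queue <- root_vertex
  visited <- logical(nv)
  visited[root_vertex] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nbs <- inc$nb[[v]]
    for (j in seq_along(nbs)) {
      w <- nbs[j]
      if (visited[w]) next
      visited[w] <- TRUE
      g <- genomes_at[[v]]
      ename <- enames[[inc$er[[v]][j]]]
      if (k_per_branch > 0L) {
        for (kk in seq_len(k_per_branch)) {
          inv <- .random_inversion(g)
          g <- inv$genes
          nev <- nev + 1L
          events[[nev]] <- data.frame(
            branch = ename, cut_left = inv$cut_left,
            cut_right = inv$cut_right,
            broken_adjacencies = inv$broken,
            created_adjacencies = inv$created,
            stringsAsFactors = FALSE)
        }
      }
      genomes_at[[w]] <- g
      queue <- c(queue, w)
    }
  }
  leaf_genomes <- lapply(seq_len(N), function(t)
    genome(genomes_at[[t]], tree$tip.label[t]))
  names(leaf_genomes) <- tree$tip.label
  events <- if (nev) do.call(rbind, events[seq_len(nev)]) else
    data.frame(branch = character(0), cut_left = integer(0),
               cut_right = integer(0), broken_adjacencies = character(0),
               created_adjacencies = character(0),
               stringsAsFactors = FALSE)
  list(leaf_genomes = leaf_genomes, events = events,
       root_vertex = root_vertex)
}

#' Replay a simulation's event log
#'
#' Reconstructs every leaf genome by walking from the root to each leaf
#' and re-applying the logged inversions of the traversed branches in
#' their recorded order.  Used to verify event-log completeness.
#'
#' @param tree the `"phylo"` tree the log refers to.
#' @param events the event-log data frame from [evolve_genomes()].
#' @param root_vertex the internal vertex the simulation started from.
#' @param n_genes number of genes.
#' @return Named list of `"genome"` objects, one per leaf.
#' @export
replay_event_log <- function(tree, events, root_vertex, n_genes) {
  N <- length(tree$tip.label)
  inc <- .incidence(tree)
  pkey <- function(e) paste(pmin(e[, 1L], e[, 2L]),
                            pmax(e[, 1L], e[, 2L]))
  po <- .postorder_tree(tree)
  enames <- setNames(.edge_names(po), pkey(po$edge))[pkey(tree$edge)]
  out <- vector("list", N)
  walk <- function(v, parent, genes) {
    if (v <= N) {
      out[[v]] <<- genome(genes, tree$tip.label[v])
      return(invisible(NULL))
    }
    nbs <- inc$nb[[v]]
    for (j in seq_along(nbs)) {
      w <- nbs[j]
      if (w == parent) next
      ename <- enames[[inc$er[[v]][j]]]
      g <- genes
      rows <- which(events$branch == ename)
      for (r in rows) {
        idx <- (events$cut_left[r] + 1L):events$cut_right[r]
        g[idx] <- -rev(g[idx])
      }
      walk(w, v, g)
    }
  }
  walk(root_vertex, 0L, seq_len(n_genes))
  names(out) <- tree$tip.label
  out
}

#' Simulate a full fragmented-assembly dataset
#'
#' Composes the pieces of one simulation replicate: draw a uniform random
#' unrooted binary tree on `N` genomes, evolve a `n_genes`-gene identity
#' genome with `k_per_branch` inversions per branch, and fragment the
#' designated leaf genome into `m_scaffolds` scaffolds.  Fully
#' reproducible from `seed`.
#'
#' @param N number of genomes (leaves), at least 4.
#' @param n_genes genes per genome.
#' @param k_per_branch inversions per branch.
#' @param m_scaffolds number of scaffolds for the designated genome.
#' @param designated tip label of the genome to fragment.
#' @param seed optional integer seed (sets the session RNG).
#' @return An object of class `"rearrangement_sim"`: `tree`,
#'   `root_vertex`, `leaf_genomes`, `designated`, `fragmented`, `events`,
#'   `seed` and the parameter list.
#' @examples
#' sim <- simulate_dataset(N = 7, n_genes = 200, k_per_branch = 1,
#'                         m_scaffolds = 20, seed = 1)
#' sim
#' @export
simulate_dataset <- function(N = 7, n_genes = 1000, k_per_branch = 1,
                             m_scaffolds = 100, designated = "1",
                             seed = NULL) {
  if (N < 4L) stop("need at least 4 genomes")
  if (!is.null(seed)) set.seed(seed)
  tree <- random_unrooted_tree(N)
  ev <- evolve_genomes(tree, n_genes, k_per_branch)
  designated <- as.character(designated)
  if (!designated %in% tree$tip.label)
    stop("designated genome not among the leaves")
  fragmented <- fragment_genome(ev$leaf_genomes[[designated]], m_scaffolds)
  structure(list(tree = tree, root_vertex = ev$root_vertex,
                 leaf_genomes = ev$leaf_genomes, designated = designated,
                 fragmented = fragmented, events = ev$events,
                 seed = seed,
                 params = list(N = N, n_genes = n_genes,
                               k_per_branch = k_per_branch,
                               m_scaffolds = m_scaffolds)),
            class = "rearrangement_sim")
}

#' @export
print.rearrangement_sim <- function(x, ...) {
  p <- x$params
  cat("<rearrangement_sim> ", p$N, " genomes, ", p$n_genes, " genes, ",
      p$k_per_branch, " inversions/branch, ",
      p$m_scaffolds, " scaffolds (designated genome ", x$designated,
      ")\n", sep = "")
  cat("  true events:", nrow(x$events), "\n")
  invisible(x)
}

#' Write all artefacts of a simulation to a directory
#'
#' Writes the complete leaf genomes and the fragmented designated genome
#' as GRIMM text, the tree as Newick, and the event log as TSV.
#'
#' @param sim a `"rearrangement_sim"`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  complete <- sim$leaf_genomes[names(sim$leaf_genomes) != sim$designated]
  write_grimm(complete, file.path(dir, "complete_genomes.txt"))
  write_grimm(sim$fragmented, file.path(dir, "fragmented_genome.txt"))
  write_newick(sim$tree, file.path(dir, "tree.nwk"))
  write.table(sim$events, file.path(dir, "events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
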