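# Independent brute-force oracle for the event-parsimony optimum:
# enumerates every {1,2} completion of internal vertices and wildcard
# leaves and minimises the event-edge count directly, without the DP.

brute_force_events <- function(tree, leaf_labels) {
  labs <- tree$tip.label
  if (is.null(names(leaf_labels))) names(leaf_labels) <- labs
  N <- length(labs)
  nv <- N + tree$Nnode
  e <- tree$edge
  fixed <- integer(nv)
  fixed[seq_len(N)] <- as.integer(leaf_labels[labs])
  free <- c(which(fixed[seq_len(N)] == 3L), (N + 1L):nv)
  nfree <- length(free)
  best <- Inf
  solutions <- list()
  for (b in 0:(2^nfree - 1)) {
    a <- fixed
    a[free] <- as.integer(intToBits(b))[seq_len(nfree)] + 1L
    cost <- sum(a[e[, 1L]] != a[e[, 2L]])
    if (cost < best) {
      best <- cost
      solutions <- list(a)
    } else if (cost == best) {
      solutions[[length(solutions) + 1L]] <- a
    }
  }
  list(min = as.integer(best), solutions = solutions)
}

# Event-edge indicator per solution, rows aligned with tree$edge.
brute_force_edge_counts <- function(tree, leaf_labels) {
  bf <- brute_force_events(tree, leaf_labels)
  e <- tree$edge
  counts <- rep(0L, nrow(e))
  for (a in bf$solutions)
    counts <- counts + (a[e[, 1L]] != a[e[, 2L]])
  list(min = bf$min, counts = counts, n_solutions = length(bf$solutions))
}

# All 3^N leaf-label patterns for small N, one row per pattern.
all_label_patterns <- function(N) {
  as.matrix(expand.grid(rep(list(1:3), N)))
}
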