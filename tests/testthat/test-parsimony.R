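test_that("min_events handles the degenerate label patterns", {
  tr <- read_newick("((1,2),(3,4),((5,6),7));")
  all2 <- setNames(rep(2, 7), as.character(1:7))
  expect_identical(min_events(tr, all2), 0L)
  one1 <- replace(all2, "4", 1)
  expect_identical(min_events(tr, one1), 1L)
  all3 <- setNames(rep(3, 7), as.character(1:7))
  expect_identical(min_events(tr, all3), 0L)
  expect_error(min_events(tr, all2[-1]), "missing label")
  expect_error(min_events(tr, replace(all2, "1", 5)), "labels must be")
})

test_that("DP equals the brute-force optimum on a wildcard example", {
  tr <- read_newick("((1,2),(3,4),((5,6),7));")
  labs <- setNames(c(1, 1, 2, 2, 1, 2, 3), as.character(1:7))
  bf <- brute_force_events(tr, labs)
  expect_identical(min_events(tr, labs), bf$min)
})

test_that("DP equals brute force exhaustively on all 4- and 5-leaf trees", {
  for (N in 4:5) {
    trees <- enumerate_topologies(N)
    pats <- all_label_patterns(N)
    for (tr in trees) {
      L <- pats
      colnames(L) <- as.character(1:N)
      got <- vapply(seq_len(nrow(L)), function(i)
        min_events(tr, L[i, ]), 0L)
      want <- vapply(seq_len(nrow(L)), function(i)
        brute_force_events(tr, L[i, ])$min, 0L)
      expect_identical(got, want)
    }
  }
})

test_that("DP equals brute force on sampled 6- and 7-leaf cases", {
  set.seed(31)
  for (i in 1:60) {
    N <- sample(6:7, 1)
    tr <- random_unrooted_tree(N)
    labs <- setNames(sample(1:3, N, replace = TRUE), as.character(1:N))
    expect_identical(min_events(tr, labs),
                     brute_force_events(tr, labs)$min)
  }
})

test_that("wildcards never increase the optimum", {
  set.seed(32)
  for (i in 1:40) {
    N <- sample(5:7, 1)
    tr <- random_unrooted_tree(N)
    labs <- setNames(sample(1:3, N, replace = TRUE), as.character(1:N))
    before <- min_events(tr, labs)
    j <- sample(N, 1)
    labs[j] <- 3
    expect_lte(min_events(tr, labs), before)
  }
})

test_that("a connected block of split genomes needs exactly one event", {
  # the 1-leaves form the leaf set of a connected subtree; rest are 2
  tr <- read_newick("((1,2),(3,4),((5,6),7));")
  labs <- setNames(c(1, 1, 2, 2, 2, 2, 2), as.character(1:7))
  expect_identical(min_events(tr, labs), 1L)
  labs2 <- setNames(c(2, 2, 2, 2, 1, 1, 1), as.character(1:7))
  expect_identical(min_events(tr, labs2), 1L)
})

test_that("traceback enumerates exactly the optimal labelings", {
  set.seed(33)
  for (i in 1:30) {
    N <- sample(4:7, 1)
    tr <- random_unrooted_tree(N)
    labs <- setNames(sample(1:3, N, replace = TRUE), as.character(1:N))
    a <- optimal_assignments(tr, labs)
    bf <- brute_force_edge_counts(a$tree, labs)
    expect_identical(a$event_number, bf$min)
    expect_identical(a$optimal_labeling_count, bf$n_solutions)
    want <- setNames(bf$counts, fragphylo:::.edge_names(a$tree))
    want <- want[want > 0]
    expect_equal(a$edge_event_counts[names(want)], want,
                 ignore_attr = FALSE, tolerance = 0)
    # every optimal labeling has exactly event_number event edges
    e <- a$tree$edge
    per_lab <- rowSums(a$labelings[, e[, 1], drop = FALSE] !=
                       a$labelings[, e[, 2], drop = FALSE])
    expect_true(all(per_lab == a$event_number))
  }
})

test_that("candidate edges and fractions behave on canonical examples", {
  tr <- read_newick("((1,2),(3,4),((5,6),7));")
  one1 <- setNames(c(2, 2, 1, 2, 2, 2, 2), as.character(1:7))
  a <- optimal_assignments(tr, one1)
  expect_identical(a$event_number, 1L)
  expect_identical(a$optimal_labeling_count, 1L)
  expect_identical(a$candidate_edges, "1,2,4,5,6,7|3")
  expect_identical(unname(fractional_edge_weights(a)), 1)
  # a sister pair of split genomes pins the event on the cherry edge
  tr5 <- read_newick("((1,2),3,(4,5));")
  cherry <- setNames(c(1, 1, 2, 2, 2), as.character(1:5))
  a5 <- optimal_assignments(tr5, cherry)
  expect_identical(a5$event_number, 1L)
  expect_identical(a5$candidate_edges, "1,2|3,4,5")
})

test_that("ambiguous optima split the unit score into fractions", {
  # on a quartet with labels 1,2,3,2 the wildcard resolves either way,
  # moving the single event between two alternative branches
  tr <- read_newick("(1,2,(3,4));")
  labs <- setNames(c(1, 2, 3, 2), as.character(1:4))
  a <- optimal_assignments(tr, labs)
  bf <- brute_force_edge_counts(a$tree, labs)
  expect_identical(a$event_number, 1L)
  expect_identical(sum(a$edge_fractions), 1)
  expect_identical(a$optimal_labeling_count, bf$n_solutions)
})

test_that("edge fractions always sum to the event number", {
  set.seed(34)
  for (i in 1:30) {
    N <- sample(4:7, 1)
    tr <- random_unrooted_tree(N)
    labs <- setNames(sample(1:3, N, replace = TRUE), as.character(1:N))
    a <- optimal_assignments(tr, labs)
    expect_equal(sum(a$edge_fractions), a$event_number)
    expect_true(all(a$edge_fractions > 0))
  }
})

test_that("wildcard leaves resolve to the cheap state in the traceback", {
  # a can't-tell leaf next to genomes sharing the adjacency resolves to 2
  # with zero events; resolving it to 1 would cost one and is excluded
  tr <- read_newick("((1,2),(3,4),((5,6),7));")
  labs <- setNames(c(2, 2, 2, 2, 2, 2, 3), as.character(1:7))
  a <- optimal_assignments(tr, labs)
  expect_identical(a$event_number, 0L)
  expect_identical(a$optimal_labeling_count, 1L)
  expect_length(a$candidate_edges, 0)
})

test_that("conflicts are reported over optimal labelings", {
  tr <- read_newick("((1,2),(3,4),((5,6),7));")
  all2 <- setNames(rep(2, 7), as.character(1:7))
  expect_false(detect_conflict(tr, all2)$conflict)
  one1 <- replace(all2, "3", 1)
  expect_false(detect_conflict(tr, one1)$conflict)
  # alternating labels on a caterpillar: the unique optimum keeps every
  # internal vertex at 2, so no conserved pair is separated by a split
  # vertex (verified against the brute-force oracle)
  cat7 <- read_newick("(1,2,(3,(4,(5,(6,7)))));")
  alt <- setNames(c(2, 1, 2, 1, 2, 1, 2), as.character(1:7))
  expect_identical(min_events(cat7, alt), 3L)
  expect_identical(brute_force_events(cat7, alt)$min, 3L)
  expect_false(detect_conflict(cat7, alt)$conflict)
  # two distant conserved genomes with split evidence everywhere between
  # them force a 1-vertex onto their connecting path in every optimum
  far2 <- setNames(c(2, 1, 1, 1, 1, 1, 2), as.character(1:7))
  cc <- detect_conflict(cat7, far2)
  expect_true(cc$conflict)
  expect_true(nrow(cc$pairs) >= 1)
  expect_true(any(cc$pairs[, 1] == "1" & cc$pairs[, 2] == "7"))
})

test_that("tree scores are additive per-scaffold sums", {
  sim <- simulate_dataset(N = 7, n_genes = 300, k_per_branch = 2,
                          m_scaffolds = 30, seed = 40)
  M <- label_simulation(sim)
  sc <- score_tree(sim$tree, M)
  expect_identical(sc$total_events, sum(sc$per_scaffold))
  expect_identical(sum(sc$scaffold_class_counts), nrow(M))
  # additivity over row blocks
  M1 <- M[1:10, , drop = FALSE]
  M2 <- M[11:30, , drop = FALSE]
  class(M1) <- class(M2) <- class(M)
  attr(M1, "designated") <- attr(M2, "designated") <- attr(M, "designated")
  expect_identical(sc$total_events,
                   score_tree(sim$tree, M1)$total_events +
                   score_tree(sim$tree, M2)$total_events)
  # all-2 matrix scores zero
  M0 <- M
  M0[] <- 2L
  expect_identical(score_tree(sim$tree, M0)$total_events, 0L)
})

test_that("ranking uses competition rank with shared best rank on ties", {
  sim <- simulate_dataset(N = 6, n_genes = 200, k_per_branch = 1,
                          m_scaffolds = 20, seed = 41)
  M <- label_simulation(sim)
  trees <- enumerate_topologies(6)
  rk <- rank_trees(M, trees, sim$tree)
  expect_identical(nrow(rk), 105L)
  expect_identical(min(rk$rank), 1L)
  expect_true(all(rk$rank == vapply(rk$total_events, function(x)
    1L + sum(rk$total_events < x), 0L)))
  expect_identical(attr(rk, "reference_rank"),
                   rk$rank[rk$key == topology_key(sim$tree)])
  # single-tree list ranks 1; all-tie matrix ranks everyone 1
  rk1 <- rank_trees(M, list(sim$tree), sim$tree)
  expect_identical(attr(rk1, "reference_rank"), 1L)
  M0 <- M
  M0[] <- 2L
  rk0 <- rank_trees(M0, trees, sim$tree)
  expect_true(all(rk0$rank == 1L))
  other <- trees[[which(vapply(trees, topology_key, "") !=
                          topology_key(sim$tree))[1]]]
  expect_error(rank_trees(M, list(other), sim$tree), "not found")
})

test_that("a single inversion on a quartet ranks the true quartet first", {
  # one internal-branch inversion, whole genome as one scaffold: the
  # generating quartet explains the pattern with 1 event, the two wrong
  # quartets need at least as many
  inv <- apply_inversion(genome(1:40, "x"), 10, 30)
  genomes <- list(`1` = genome(1:40, "1"), `2` = genome(1:40, "2"),
                  `3` = genome(inv$genes, "3"), `4` = genome(inv$genes, "4"))
  M <- build_label_matrix(fragment_genome(genomes[["1"]], 1), genomes)
  trees <- enumerate_topologies(4)
  truth <- read_newick("((1,2),(3,4));")
  rk <- rank_trees(M, trees, truth)
  expect_identical(attr(rk, "reference_rank"), 1L)
  expect_identical(rk$total_events[rk$key == topology_key(truth)], 1)
})

test_that("assign_events maps every scaffold to an assignment", {
  sim <- simulate_dataset(N = 7, n_genes = 200, k_per_branch = 1,
                          m_scaffolds = 10, seed = 42)
  M <- label_simulation(sim)
  as <- assign_events(sim$tree, M)
  expect_identical(names(as), rownames(M))
  ev <- vapply(as, function(a) a$event_number, 0L)
  expect_identical(unname(ev), unname(score_tree(sim$tree, M)$per_scaffold))
})

test_that("candidate edges usually contain the true branch", {
  # with one inversion per branch and fine fragmentation, scaffolds hit
  # by exactly one event should point back at the branch it occurred on
  set.seed(43)
  rows <- list()
  for (i in 1:10) {
    sim <- simulate_dataset(N = 7, n_genes = 1000, k_per_branch = 1,
                            m_scaffolds = 100, seed = 4300 + i)
    rows[[i]] <- recover_true_events(sim)
  }
  df <- do.call(rbind, rows)
  expect_gt(nrow(df), 50)
  expect_gte(mean(df$located), 0.95)
})
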