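## Experiment runners.  Each replicate draws its own seed deterministically
## from the master seed (seed + a replicate offset), so reports are fully
## reproducible and matched across experimental arms.

.sim_replicate <- function(cfg, seed) {
  simulate_dataset(N = cfg$n_genomes, n_genes = cfg$n_genes,
                   k_per_branch = cfg$k_per_branch,
                   m_scaffolds = cfg$m_scaffolds, seed = seed)
}

## Ground truth: which true events left a trace inside which scaffold of
## the designated genome.  An event not on the designated lineage is
## visible there through the adjacencies it destroyed (still carried by
## the designated genome); an event on the designated lineage through the
## adjacencies it created.  Both are matched against each scaffold's
## internal adjacencies.
.true_events_per_scaffold <- function(sim) {
  scaff_adj <- lapply(sim$fragmented$scaffolds, adjacency_set)
  ev_adj <- Map(function(b, cr) {
    a <- c(strsplit(b, ";", fixed = TRUE)[[1L]],
           strsplit(cr, ";", fixed = TRUE)[[1L]])
    a[nzchar(a)]
  }, sim$events$broken_adjacencies, sim$events$created_adjacencies)
  hits <- lapply(ev_adj, function(aa) {
    which(vapply(scaff_adj, function(a) any(aa %in% a), NA))
  })
  per_scaffold <- tabulate(
    as.integer(unlist(lapply(hits, unique))), nbins = length(scaff_adj))
  list(per_scaffold = setNames(per_scaffold, names(scaff_adj)),
       event_scaffolds = hits)
}

.one_replicate_stats <- function(sim) {
  M <- label_simulation(sim)
  sc <- score_tree(sim$tree, M)
  truth <- .true_events_per_scaffold(sim)
  data.frame(
    true_events = nrow(sim$events),
    detected_events = sc$total_events,
    scaffolds_0 = unname(sc$scaffold_class_counts["0"]),
    scaffolds_1 = unname(sc$scaffold_class_counts["1"]),
    scaffolds_2 = unname(sc$scaffold_class_counts["2"]),
    scaffolds_3plus = unname(sc$scaffold_class_counts["3+"]),
    zero_breakpoint_scaffolds = sum(apply(M, 1L, function(r) all(r != 1L))),
    true_bp_multi_scaffolds = sum(truth$per_scaffold >= 2L),
    true_bp_zero_scaffolds = sum(truth$per_scaffold == 0L))
}

.new_report <- function(config, replicates, summary) {
  structure(list(config = config, replicates = replicates,
                 summary = summary), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cfg <- x$config
  cat("  config:", paste(names(cfg), unlist(lapply(cfg, paste,
      collapse = ",")), sep = "=", collapse = "  "), "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

.mean_summary <- function(df, by) {
  vars <- setdiff(names(df), c(by, "replicate"))
  out <- unique(df[, by, drop = FALSE])
  rownames(out) <- NULL
  for (v in vars)
    out[[paste0("mean_", v)]] <- vapply(seq_len(nrow(out)), function(i) {
      sel <- df[[by]] == out[[by]][i]
      mean(df[[v]][sel])
    }, 0)
  out
}

#' Detected events as a function of rearrangement rate
#'
#' For each per-branch inversion count `k`, simulates replicate datasets,
#' labels the scaffolds, and tallies the total detected events on the
#' true tree (the sum over scaffolds of minimal event numbers, i.e. the
#' weighted 1/2/3-event total), along with scaffold event-class counts,
#' scaffolds without any observed breakpoint, and ground-truth
#' breakpoints-per-scaffold collisions.
#'
#' @param k_values per-branch inversion counts to sweep.
#' @param m_scaffolds scaffolds for the designated genome.
#' @param n_genomes,n_genes,replicates,seed simulation configuration.
#' @return An `"experiment_report"`: per-replicate rows and per-`k` means.
#' @export
run_rate_experiment <- function(k_values = 1:5, m_scaffolds = 100,
                                n_genomes = 7, n_genes = 1000,
                                replicates = 100, seed = 1) {
  rows <- list()
  off <- 0L
  for (k in k_values) {
    cfg <- list(n_genomes = n_genomes, n_genes = n_genes,
                k_per_branch = k, m_scaffolds = m_scaffolds)
    for (r in seq_len(replicates)) {
      off <- off + 1L
      sim <- .sim_replicate(cfg, seed + off)
      st <- .one_replicate_stats(sim)
      rows[[off]] <- cbind(data.frame(k_per_branch = k, replicate = r),
                           st)
    }
  }
  df <- do.call(rbind, rows)
  .new_report(list(k_values = k_values, m_scaffolds = m_scaffolds,
                   n_genomes = n_genomes, n_genes = n_genes,
                   replicates = replicates, seed = seed),
              df, .mean_summary(df, "k_per_branch"))
}

#' Detected events as a function of fragmentation
#'
#' Sweeps the scaffold count `m` at a fixed rearrangement rate,
#' reporting how fragmentation trades multi-event scaffold collisions
#' against scaffolds that carry no breakpoint at all.
#'
#' @param m_values scaffold counts to sweep.
#' @param k_per_branch inversions per branch (default 5).
#' @inheritParams run_rate_experiment
#' @return An `"experiment_report"` with per-`m` means.
#' @export
run_fragmentation_experiment <- function(m_values = c(20, 40, 60, 100,
                                                      150, 250),
                                         k_per_branch = 5, n_genomes = 7,
                                         n_genes = 1000, replicates = 100,
                                         seed = 1) {
  rows <- list()
  off <- 0L
  for (m in m_values) {
    cfg <- list(n_genomes = n_genomes, n_genes = n_genes,
                k_per_branch = k_per_branch, m_scaffolds = m)
    for (r in seq_len(replicates)) {
      off <- off + 1L
      sim <- .sim_replicate(cfg, seed + off)
      st <- .one_replicate_stats(sim)
      rows[[off]] <- cbind(data.frame(m_scaffolds = m, replicate = r), st)
    }
  }
  df <- do.call(rbind, rows)
  .new_report(list(m_values = m_values, k_per_branch = k_per_branch,
                   n_genomes = n_genomes, n_genes = n_genes,
                   replicates = replicates, seed = seed),
              df, .mean_summary(df, "m_scaffolds"))
}

#' Rank of the data-generating tree among all topologies
#'
#' For each replicate, simulates a dataset, scores every candidate
#' topology (all `(2N-5)!!` unrooted binary trees by default; 945 for 7
#' genomes) by total inferred events, and records the competition rank of
#' the generating tree.  Optionally degrades the label matrix with
#' "can't tell" entries first.
#'
#' @param k_per_branch inversions per branch (default 3, a small rate).
#' @param m_scaffolds scaffolds (default 60).
#' @param cant_tell genomes per scaffold to mask with label 3 (default 0).
#' @param topologies optional pre-enumerated `"multiPhylo"` candidate set.
#' @inheritParams run_rate_experiment
#' @return An `"experiment_report"` whose summary holds the median and
#'   mean rank and the fraction of replicates with rank at most 12.
#' @export
run_tree_ranking_experiment <- function(k_per_branch = 3, m_scaffolds = 60,
                                        n_genomes = 7, n_genes = 1000,
                                        replicates = 30, cant_tell = 0,
                                        seed = 1, topologies = NULL) {
  if (is.null(topologies)) topologies <- enumerate_topologies(n_genomes)
  topologies <- lapply(topologies, .postorder_tree)
  cfg <- list(n_genomes = n_genomes, n_genes = n_genes,
              k_per_branch = k_per_branch, m_scaffolds = m_scaffolds)
  rows <- lapply(seq_len(replicates), function(r) {
    sim <- .sim_replicate(cfg, seed + r)
    M <- label_simulation(sim)
    if (cant_tell > 0L) M <- inject_cant_tell(M, cant_tell)
    rk <- rank_trees(M, topologies, sim$tree)
    data.frame(replicate = r,
               rank = attr(rk, "reference_rank"),
               true_tree_events = rk$total_events[
                 match(topology_key(sim$tree), rk$key)],
               best_events = min(rk$total_events),
               n_tied_best = sum(rk$rank == 1L))
  })
  df <- do.call(rbind, rows)
  summary <- data.frame(cant_tell = cant_tell,
                        median_rank = median(df$rank),
                        mean_rank = mean(df$rank),
                        prop_rank_le_12 = mean(df$rank <= 12))
  .new_report(c(cfg, list(replicates = replicates, cant_tell = cant_tell,
                          seed = seed)),
              df, summary)
}

#' Effect of "can't tell" degradation on phylogenetic accuracy
#'
#' Repeats the tree-ranking experiment for each level of "can't tell"
#' masking, with matched seeds across levels so each replicate reuses the
#' identical simulated dataset.
#'
#' @param cant_tell_values masking levels to sweep (genomes per scaffold).
#' @inheritParams run_tree_ranking_experiment
#' @return An `"experiment_report"` with per-level summaries.
#' @export
run_cant_tell_experiment <- function(cant_tell_values = c(0, 1, 2, 3),
                                     k_per_branch = 3, m_scaffolds = 60,
                                     n_genomes = 7, n_genes = 1000,
                                     replicates = 30, seed = 1,
                                     topologies = NULL) {
  if (is.null(topologies)) topologies <- enumerate_topologies(n_genomes)
  reports <- lapply(cant_tell_values, function(cc) {
    run_tree_ranking_experiment(
      k_per_branch = k_per_branch, m_scaffolds = m_scaffolds,
      n_genomes = n_genomes, n_genes = n_genes, replicates = replicates,
      cant_tell = cc, seed = seed, topologies = topologies)
  })
  df <- do.call(rbind, lapply(seq_along(reports), function(i)
    cbind(data.frame(cant_tell = cant_tell_values[i]),
          reports[[i]]$replicates)))
  summary <- do.call(rbind, lapply(reports, function(r) r$summary))
  .new_report(list(cant_tell_values = cant_tell_values,
                   k_per_branch = k_per_branch, m_scaffolds = m_scaffolds,
                   n_genomes = n_genomes, n_genes = n_genes,
                   replicates = replicates, seed = seed),
              df, summary)
}

#' Check which true events are located by the method
#'
#' A true event is attributed to the scaffolds that contain one of the
#' adjacencies it destroyed; for each scaffold attributed exactly one
#' event, the event counts as located when the scaffold's candidate edge
#' set on the true tree contains the branch the event occurred on.
#'
#' @param sim a `"rearrangement_sim"`.
#' @param M optional precomputed `"label_matrix"`.
#' @return Data frame with one row per (scaffold with exactly one
#'   attributed event): the scaffold, the event's branch, and `located`.
#' @export
recover_true_events <- function(sim, M = NULL) {
  if (is.null(M)) M <- label_simulation(sim)
  truth <- .true_events_per_scaffold(sim)
  scaffs <- names(truth$per_scaffold)[truth$per_scaffold == 1L]
  if (!length(scaffs))
    return(data.frame(scaffold = character(0), branch = character(0),
                      located = logical(0)))
  ## invert the event -> scaffolds map for the singly-hit scaffolds
  rows <- list()
  for (r in seq_along(truth$event_scaffolds)) {
    for (si in truth$event_scaffolds[[r]]) {
      s <- names(truth$per_scaffold)[si]
      if (s %in% scaffs)
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = s, branch = sim$events$branch[r],
          stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$located <- vapply(seq_len(nrow(df)), function(i) {
    a <- optimal_assignments(
      sim$tree, setNames(M[df$scaffold[i], ], colnames(M)),
      scaffold = df$scaffold[i])
    df$branch[i] %in% a$candidate_edges
  }, NA)
  df
}
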