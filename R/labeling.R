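## The 1/2/3 labels comparing each scaffold of the designated genome with
## every complete genome.  Because the other genomes are complete single
## chromosomes, "split" is operationalised as: at least one internal
## adjacency of the scaffold is a breakpoint (absent from the other
## genome).  A single-gene scaffold has no internal adjacency and is
## labelled 3 (can't tell).

#' Label one scaffold against one complete genome
#'
#' @param scaffold integer vector of signed genes (a contiguous run of the
#'   designated genome), or one element of a `"fragmented_genome"`.
#' @param g the complete `"genome"` to compare against.
#' @return `3L` if the scaffold has fewer than 2 genes (can't tell);
#'   `2L` (not split) if every internal adjacency of the scaffold is
#'   conserved in `g`; else `1L` (split).
#' @export
label_scaffold <- function(scaffold, g) {
  s <- .gene_vector(scaffold)
  gg <- .gene_vector(g)
  if (!all(abs(s) %in% abs(gg)))
    stop("gene content mismatch: scaffold genes missing from genome")
  if (length(s) < 2L) return(3L)
  if (all(adjacency_set(s) %in% adjacency_set(gg))) 2L else 1L
}

#' Build the scaffold-by-genome label matrix
#'
#' One row per scaffold of the fragmented (designated) genome, one column
#' per genome.  Each entry is the 1/2/3 label of [label_scaffold()]; the
#' designated genome's own column is fixed at 2, since a scaffold is
#' trivially unsplit in its own genome.
#'
#' @param f a `"fragmented_genome"`.
#' @param genomes named list of `"genome"` objects covering all leaves,
#'   including the designated genome (named as `f$source_name`).
#' @return An integer matrix of class `"label_matrix"` with the designated
#'   genome name in attribute `"designated"`.
#' @export
build_label_matrix <- function(f, genomes) {
  if (!inherits(f, "fragmented_genome"))
    stop("`f` must be a fragmented_genome")
  gnames <- names(genomes)
  if (is.null(gnames) || anyDuplicated(gnames))
    stop("`genomes` must be a uniquely named list")
  designated <- f$source_name
  if (!designated %in% gnames)
    stop("the designated genome (", designated,
         ") must appear among `genomes`")
  src_content <- sort(abs(unlist(f$scaffolds, use.names = FALSE)))
  scaff_adj <- lapply(f$scaffolds, adjacency_set)
  m <- length(f$scaffolds)
  M <- matrix(2L, m, length(genomes),
              dimnames = list(names(f$scaffolds), gnames))
  short <- lengths(f$scaffolds) < 2L
  for (j in seq_along(genomes)) {
    if (gnames[j] == designated) next
    gg <- .gene_vector(genomes[[j]])
    if (!identical(sort(abs(gg)), src_content))
      stop("gene content mismatch for genome ", gnames[j])
    aset <- adjacency_set(gg)
    lab <- vapply(scaff_adj, function(a) {
      if (all(a %in% aset)) 2L else 1L
    }, 0L)
    lab[short] <- 3L
    M[, j] <- lab
  }
  structure(M, designated = designated, class = c("label_matrix", "matrix"))
}

#' Degrade labels to "can't tell"
#'
#' For each scaffold independently, replaces the labels of exactly `c`
#' distinct non-designated genomes (drawn uniformly without replacement)
#' by 3, emulating breakpoints that cannot be identified in degraded real
#' data.  The designated genome's column is never touched.  Uses the
#' session RNG.
#'
#' @param M a `"label_matrix"`.
#' @param c number of genomes per scaffold to mask, between 0 and the
#'   number of non-designated genomes.
#' @return The degraded `"label_matrix"`.
#' @export
inject_cant_tell <- function(M, c) {
  if (!inherits(M, "label_matrix")) stop("`M` must be a label_matrix")
  c <- as.integer(c)
  nd <- setdiff(colnames(M), attr(M, "designated"))
  if (is.na(c) || c < 0L || c > length(nd))
    stop("invalid parameter: `c` must be between 0 and ", length(nd))
  if (c == 0L) return(M)
  for (i in seq_len(nrow(M)))
    M[i, sample(nd, c)] <- 3L
  M
}

#' Serialise a label matrix as TSV
#'
#' Rows are scaffolds, columns genome names (deterministic order as
#' built), cells in `{1,2,3}`.
#'
#' @param M a `"label_matrix"`.
#' @param path output file.
#' @export
write_label_matrix <- function(M, path) {
  df <- data.frame(scaffold = rownames(M), unclass(M)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Label matrix of a simulated dataset
#'
#' Convenience wrapper building the label matrix of a
#' [simulate_dataset()] result from its fragmented genome and leaf
#' genomes.
#'
#' @param sim a `"rearrangement_sim"`.
#' @return A `"label_matrix"`.
#' @export
label_simulation <- function(sim) {
  build_label_matrix(sim$fragmented, sim$leaf_genomes)
}
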