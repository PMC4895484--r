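#' Construct a signed gene-order genome
#'
#' A genome is a single linear chromosome holding every gene exactly once.
#' Genes are identified by the integers `1..n`; the sign encodes reading
#' orientation.  The model deliberately excludes gene loss, duplication and
#' multichromosomal structure, so the absolute gene values must be exactly
#' the set `{1, ..., n}`.
#'
#' @param genes ordered vector of nonzero signed integers.
#' @param name text identifier for the genome.
#' @return An object of class `"genome"` with components `genes` and `name`.
#' @examples
#' g <- genome(c(1, -3, 2), "toy")
#' adjacency_set(g)
#' @export
genome <- function(genes, name = "genome") {
  genes <- as.integer(genes)
  if (length(genes) == 0L)
    stop("a genome must contain at least one gene")
  if (anyNA(genes) || any(genes == 0L))
    stop("gene identifiers must be nonzero integers")
  if (!identical(sort(abs(genes)), seq_along(genes)))
    stop("genes must be a signed permutation of 1..n ",
         "(single-copy, equal gene content)")
  structure(list(genes = genes, name = as.character(name)[1L]),
            class = "genome")
}

#' Identity genome 1, 2, ..., n
#'
#' @param n number of genes.
#' @param name text identifier.
#' @return A `"genome"` whose gene order is the identity permutation, all
#'   genes in forward orientation.  Used as the ancestral (root) genome in
#'   simulations.
#' @export
identity_genome <- function(n, name = "root") {
  genome(seq_len(n), name)
}

#' @export
print.genome <- function(x, ...) {
  n <- length(x$genes)
  cat("<genome> ", x$name, ": ", n, " genes\n", sep = "")
  shown <- paste(x$genes[seq_len(min(n, 12L))], collapse = " ")
  cat("  ", shown, if (n > 12L) " ...", "\n", sep = "")
  invisible(x)
}

#' @export
length.genome <- function(x) length(x$genes)

.gene_vector <- function(g) {
  if (inherits(g, "genome")) g$genes else as.integer(g)
}

## Canonical key for an oriented adjacency: (a,b) and (-b,-a) are the same
## adjacency read from opposite strands, so both map to one string.
.adj_key <- function(a, b) {
  ra <- -b
  rb <- -a
  fwd <- (a < ra) | (a == ra & b <= rb)
  paste0(ifelse(fwd, a, ra), ",", ifelse(fwd, b, rb))
}

#' Canonical form of an oriented gene adjacency
#'
#' Two genes are adjacent when they are immediate neighbours on the
#' chromosome.  Reading the chromosome backwards turns the pair `(a, b)`
#' into `(-b, -a)`; both readings denote the same physical adjacency and
#' are mapped to an identical canonical key.  Order with signs matters:
#' `(a, b)` and `(b, a)` are distinct adjacencies.
#'
#' @param a,b nonzero signed gene identifiers with `|a| != |b|`.
#' @return A character scalar: the canonical adjacency key.
#' @examples
#' canonical_adjacency(1, 2) == canonical_adjacency(-2, -1)
#' @export
canonical_adjacency <- function(a, b) {
  a <- as.integer(a)[1L]
  b <- as.integer(b)[1L]
  if (is.na(a) || is.na(b) || a == 0L || b == 0L)
    stop("invalid adjacency: genes must be nonzero integers")
  if (abs(a) == abs(b))
    stop("invalid adjacency: a gene cannot neighbour itself")
  .adj_key(a, b)
}

#' Set of adjacencies of a gene order
#'
#' Returns one canonical adjacency per consecutive gene pair.  Chromosome
#' ends (telomeres) carry no adjacency, so a linear genome of `n` genes has
#' exactly `n - 1` adjacencies.
#'
#' @param g a `"genome"`, or a plain signed integer vector (e.g. a
#'   scaffold).
#' @return Character vector of canonical adjacency keys, in chromosome
#'   order.
#' @export
adjacency_set <- function(g) {
  genes <- .gene_vector(g)
  n <- length(genes)
  if (n < 2L) return(character(0))
  .adj_key(genes[-n], genes[-1L])
}

#' Breakpoints of one genome relative to another
#'
#' A breakpoint is an adjacency of `a` that is absent from `b`: the
#' observable trace of a rearrangement somewhere on the evolutionary path
#' between the two genomes.  The two directions always have equal
#' cardinality for genomes of equal gene content.
#'
#' @param a,b genomes over the same gene set.
#' @return Character vector of canonical adjacency keys present in `a` but
#'   not in `b`.
#' @export
breakpoint_set <- function(a, b) {
  ga <- .gene_vector(a)
  gb <- .gene_vector(b)
  if (!identical(sort(abs(ga)), sort(abs(gb))))
    stop("gene content mismatch: genomes must share the same gene set")
  setdiff(adjacency_set(ga), adjacency_set(gb))
}

#' Apply a chromosomal inversion
#'
#' Inversion endpoints are 0-based boundaries between gene positions:
#' boundary 0 lies before the first gene and boundary `n` after the last.
#' The gene segment strictly between the two cuts, i.e. positions
#' `cut_left + 1` to `cut_right`, is reversed in order with every sign
#' flipped.  An inversion with both cuts strictly internal disrupts exactly
#' two adjacencies; a cut at a chromosome end disrupts one.
#'
#' @param g a `"genome"`.
#' @param cut_left,cut_right boundaries with
#'   `0 <= cut_left < cut_right <= n`.
#' @return The rearranged `"genome"`.  Applying the same inversion twice
#'   restores the original genome.
#' @examples
#' apply_inversion(genome(1:5), 1, 4)  # 1 -4 -3 -2 5
#' @export
apply_inversion <- function(g, cut_left, cut_right) {
  if (!inherits(g, "genome")) stop("`g` must be a genome")
  n <- length(g$genes)
  cl <- as.integer(cut_left)
  cr <- as.integer(cut_right)
  if (is.na(cl) || is.na(cr) || cl < 0L || cr > n)
    stop("cut boundaries must lie in [0, n]")
  if (cl >= cr)
    stop("invalid segment: cut_left must be strictly less than cut_right")
  genes <- g$genes
  idx <- (cl + 1L):cr
  genes[idx] <- -rev(genes[idx])
  genome(genes, g$name)
}

#' Fragment a genome into scaffolds
#'
#' Splits the gene order into `m` contiguous scaffolds by drawing `m - 1`
#' distinct cut positions uniformly from the `n - 1` internal boundaries.
#' For `m` much smaller than `n` the resulting scaffold sizes are
#' approximately geometrically distributed, mimicking the fragment-length
#' profile of a draft assembly.  Uses the session RNG.
#'
#' @param g a `"genome"`.
#' @param m number of scaffolds, `1 <= m <= n`.
#' @return An object of class `"fragmented_genome"`: a named list of
#'   scaffolds (integer vectors, in source order) plus the source genome
#'   name.  Concatenating the scaffolds in order restores `g` exactly.
#' @export
fragment_genome <- function(g, m) {
  if (!inherits(g, "genome")) stop("`g` must be a genome")
  n <- length(g$genes)
  m <- as.integer(m)
  if (is.na(m) || m < 1L || m > n)
    stop("infeasible fragmentation: need 1 <= m <= number of genes")
  cuts <- if (m > 1L) sort(sample.int(n - 1L, m - 1L)) else integer(0)
  bounds <- c(0L, cuts, n)
  scaffolds <- lapply(seq_len(m), function(i) {
    g$genes[(bounds[i] + 1L):bounds[i + 1L]]
  })
  names(scaffolds) <- paste0("scaffold_", seq_len(m))
  structure(list(scaffolds = scaffolds, source_name = g$name),
            class = "fragmented_genome")
}

#' @export
print.fragmented_genome <- function(x, ...) {
  sizes <- lengths(x$scaffolds)
  cat("<fragmented_genome> source ", x$source_name, ": ",
      length(sizes), " scaffolds, ", sum(sizes), " genes ",
      "(sizes ", min(sizes), "-", max(sizes), ")\n", sep = "")
  invisible(x)
}

#' Read and write signed gene orders in GRIMM-style text
#'
#' The format is one record per genome: a header line `>name`, then
#' whitespace-separated signed integers (possibly over several lines)
#' terminated by `$`.  One chromosome per genome.  `write_grimm()` followed
#' by `read_grimm()` is bit-exact on the canonical single-line layout it
#' produces.
#'
#' @param path file path.
#' @return `read_grimm()`: a named list of `"genome"` objects.
#' @export
read_grimm <- function(path) {
  recs <- .read_grimm_records(path)
  out <- lapply(names(recs), function(nm) genome(recs[[nm]], nm))
  names(out) <- names(recs)
  out
}

.read_grimm_records <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  recs <- list()
  name <- NULL
  buf <- character(0)
  flush <- function() {
    if (is.null(name)) return()
    toks <- unlist(strsplit(paste(buf, collapse = " "), "[[:space:]]+"))
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L || toks[length(toks)] != "$")
      stop("malformed GRIMM record '", name, "': missing terminating $")
    toks <- toks[-length(toks)]
    if (any(toks == "$"))
      stop("multichromosomal record '", name, "' not supported")
    recs[[name]] <<- as.integer(toks)
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      name <- trimws(sub("^>", "", ln))
      buf <- character(0)
    } else {
      if (is.null(name)) stop("GRIMM parse error: data before first >name")
      buf <- c(buf, ln)
    }
  }
  flush()
  if (length(recs) == 0L) stop("no GRIMM records found in ", path)
  recs
}

#' @param x a list of `"genome"` objects, or a `"fragmented_genome"` (one
#'   record per scaffold).
#' @rdname read_grimm
#' @export
write_grimm <- function(x, path) {
  if (inherits(x, "fragmented_genome")) {
    nms <- names(x$scaffolds)
    vecs <- x$scaffolds
  } else {
    if (inherits(x, "genome")) x <- list(x)
    vecs <- lapply(x, .gene_vector)
    nms <- vapply(x, function(g) {
      if (inherits(g, "genome")) g$name else ""
    }, "")
    if (!is.null(names(x)) && any(!nzchar(nms))) nms <- names(x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(vecs)) {
    writeLines(paste0(">", nms[i]), con)
    writeLines(paste(c(vecs[[i]], "$"), collapse = " "), con)
  }
  invisible(path)
}

#' Read a fragmented genome from GRIMM scaffold records
#'
#' Each record is one scaffold in source order.  The concatenation of all
#' scaffolds must be a valid signed permutation (the source genome).
#'
#' @param path file path.
#' @param source_name name to give the reconstructed source genome.
#' @return A `"fragmented_genome"`.
#' @export
read_grimm_scaffolds <- function(path, source_name = "designated") {
  recs <- .read_grimm_records(path)
  full <- unlist(recs, use.names = FALSE)
  genome(full, source_name)  # validates the partition reassembles a genome
  structure(list(scaffolds = recs, source_name = source_name),
            class = "fragmented_genome")
}
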