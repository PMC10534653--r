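#' Pairwise sequence identity
#'
#' Fraction of identical bases in a banded global alignment of `a` and
#' `b`, divided by the length of the shorter sequence (the CD-HIT
#' denominator convention). The alignment band is the main diagonal,
#' widened by the length difference plus `band` nt of slack on each side;
#' with the default `band = 2` this is exact for the near-constant-length
#' pools (39--41 nt) this package analyses.
#'
#' @param a,b Non-empty A/C/G/T sequences.
#' @param band Band slack in nt.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity(strrep("A", 40), strrep("A", 40))  # 1
#' @export
pairwise_identity <- function(a, b, band = 2L) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (!is_acgt(a) || !is_acgt(b)) stop("sequences must contain only A/C/G/T")
  identity_matches_cpp(a, b, as.integer(band)) / min(nchar(a), nchar(b))
}

#' Greedy identity clustering of a sequence pool
#'
#' Reimplements the CD-HIT-style step used on SELEX pools: distinct
#' sequences are sorted by read count descending (ties lexicographic) and
#' scanned once; each sequence joins the first existing cluster, in
#' founding order, whose representative (seed) is within `threshold`
#' identity, otherwise it founds a new cluster with itself as
#' representative. Because candidates are visited in abundance order, the
#' representative of every cluster is its most abundant member.
#'
#' @param pool A non-empty [round_counts()].
#' @param threshold Identity threshold in `(0, 1]`; default 0.90.
#' @param band Alignment band slack, see [pairwise_identity()].
#' @return A data.frame of class `selex_clusters` with one row per cluster
#'   in founding order: `cluster_index`, `representative`,
#'   `representative_count`, `total_count`, `rpm` (reads per million of
#'   the round total), `n_unique_members`. The member map is attached as
#'   attribute `members` (list of named integer vectors); `round_label`,
#'   `total_reads` and `threshold` are attributes.
#' @export
greedy_cluster <- function(pool, threshold = 0.90, band = 2L) {
  stopifnot(inherits(pool, "round_counts"))
  if (length(pool$counts) == 0L) {
    return(empty_clusters(pool, threshold))
  }
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  # round_counts is already ordered by count desc, ties lexicographic
  assign <- greedy_assign_cpp(names(pool$counts), threshold, as.integer(band))
  build_clusters(pool, assign, threshold)
}

#' Brute-force clustering oracle
#'
#' Executes the same greedy rule as [greedy_cluster()] but from a
#' precomputed all-pairs identity matrix. Intended for validation on small
#' pools; refuses more than 500 distinct sequences.
#'
#' @inheritParams greedy_cluster
#' @return Same structure as [greedy_cluster()].
#' @export
brute_force_cluster <- function(pool, threshold = 0.90, band = 2L) {
  stopifnot(inherits(pool, "round_counts"))
  n <- length(pool$counts)
  if (n == 0L) return(empty_clusters(pool, threshold))
  if (n > 500L) stop("brute_force_cluster is a test oracle; limited to 500 unique sequences")
  seqs <- names(pool$counts)
  lens <- nchar(seqs)
  m <- identity_matrix_cpp(seqs, as.integer(band))
  assign <- integer(n)
  reps <- integer(0)  # indices of founding sequences, in founding order
  for (i in seq_len(n)) {
    hit <- 0L
    for (c in seq_along(reps)) {
      r <- reps[c]
      if (m[i, r] / min(lens[i], lens[r]) >= threshold - 1e-9) { hit <- c; break }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      assign[i] <- length(reps)
    } else {
      assign[i] <- hit
    }
  }
  build_clusters(pool, assign, threshold)
}

build_clusters <- function(pool, assign, threshold) {
  counts <- pool$counts
  k <- max(assign)
  fa <- factor(assign, levels = seq_len(k))  # keep numeric, not lexical, order
  total <- as.vector(tapply(counts, fa, sum))
  nmem <- as.vector(tapply(counts, fa, length))
  # first member of each cluster (in abundance order) is the representative
  first <- match(seq_len(k), assign)
  members <- split(counts, fa)
  names(members) <- NULL
  df <- data.frame(
    cluster_index = seq_len(k),
    representative = names(counts)[first],
    representative_count = unname(counts[first]),
    total_count = as.integer(total),
    rpm = total / pool$total_reads * 1e6,
    n_unique_members = as.integer(nmem),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("selex_clusters", "data.frame"),
            members = members, round_label = pool$round_label,
            total_reads = pool$total_reads, threshold = threshold)
}

empty_clusters <- function(pool, threshold) {
  df <- data.frame(cluster_index = integer(0), representative = character(0),
                   representative_count = integer(0), total_count = integer(0),
                   rpm = numeric(0), n_unique_members = integer(0),
                   stringsAsFactors = FALSE)
  structure(df, class = c("selex_clusters", "data.frame"),
            members = list(), round_label = pool$round_label,
            total_reads = pool$total_reads, threshold = threshold)
}

#' Cluster members
#'
#' @param clusters A `selex_clusters` object.
#' @param i Cluster index.
#' @return Named integer vector of member sequence counts.
#' @export
cluster_members <- function(clusters, i) attr(clusters, "members")[[i]]

#' Write a cluster table as TSV
#'
#' @param clusters A `selex_clusters` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  df <- as.data.frame(clusters)
  df <- cbind(round_label = attr(clusters, "round_label"), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
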