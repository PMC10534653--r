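#' Classify clusters as unique or enriched
#'
#' Clusters with `cutoff` (default 50) total reads or fewer are "unique";
#' larger clusters are "enriched". Fractions are read-count weighted: the
#' sum of read counts in each class over the total number of reads in the
#' round.
#'
#' @param clusters A `selex_clusters` object (one round).
#' @param cutoff Read-count boundary; a cluster of exactly `cutoff` reads
#'   is unique.
#' @return Named numeric vector `c(unique_fraction, enriched_fraction)`.
#' @export
classify_clusters <- function(clusters, cutoff = 50L) {
  if (nrow(clusters) == 0L) {
    warning("no clusters: unique and enriched fractions are both 0")
    return(c(unique_fraction = 0, enriched_fraction = 0))
  }
  total <- sum(clusters$total_count)
  uniq <- sum(clusters$total_count[clusters$total_count <= cutoff])
  c(unique_fraction = uniq / total, enriched_fraction = (total - uniq) / total)
}

# read-count bands printed on the round-summary figure
BIN_BREAKS <- c(0, 10, 100, 1000, 5000, 10000, Inf)
BIN_LABELS <- c("<=10", "11-100", "101-1000", "1001-5000", "5001-10000", ">10000")

#' Read-count bin fractions
#'
#' Assigns each cluster's total read count to one of six bands (<=10,
#' 11--100, 101--1000, 1001--5000, 5001--10,000, >10,000) and reports the
#' read-count-weighted fraction of each band.
#'
#' @param clusters A `selex_clusters` object.
#' @return Named numeric vector over the six bands, summing to 1 for a
#'   non-empty round.
#' @export
bin_clusters <- function(clusters) {
  out <- setNames(numeric(length(BIN_LABELS)), BIN_LABELS)
  if (nrow(clusters) == 0L) return(out)
  band <- cut(clusters$total_count, breaks = BIN_BREAKS, labels = BIN_LABELS)
  sums <- tapply(clusters$total_count, band, sum, default = 0)
  out[names(sums)] <- sums / sum(clusters$total_count)
  out
}

#' Positional nucleotide frequencies of a pool
#'
#' Read-count-weighted frequency of A, C, G, T and N at each of the
#' `var_len` variable-region positions. Sequences shorter than `var_len`
#' are right-padded with N; longer sequences are truncated to `var_len`,
#' so the matrix always has `var_len` rows that each sum to 1.
#'
#' @param pool A [round_counts()].
#' @param var_len Number of profile positions (default 40).
#' @return Numeric matrix `var_len` x 5 with columns A, C, G, T, N.
#' @export
nucleotide_profile <- function(pool, var_len = 40L) {
  stopifnot(inherits(pool, "round_counts"))
  bases <- c("A", "C", "G", "T", "N")
  prof <- matrix(0, nrow = var_len, ncol = 5L,
                 dimnames = list(seq_len(var_len), bases))
  if (length(pool$counts) == 0L) return(prof)
  seqs <- names(pool$counts)
  w <- as.numeric(pool$counts)
  padded <- formatC(substr(seqs, 1L, var_len), width = var_len, flag = "-")
  padded <- chartr(" ", "N", padded)
  chars <- matrix(unlist(strsplit(padded, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), byrow = TRUE)
  for (b in bases) prof[, b] <- colSums((chars == b) * w)
  prof / sum(w)
}

#' Abundance vector of a pool or cluster set
#'
#' Relative abundances over distinct observed sequences (default) or over
#' clusters, the input to the diversity indices.
#'
#' @param x A [round_counts()] or `selex_clusters` object.
#' @param level `"sequence"` (distinct sequences) or `"cluster"` (cluster
#'   total counts).
#' @return Numeric vector of abundances summing to 1.
#' @export
abundance_vector <- function(x, level = c("sequence", "cluster")) {
  level <- match.arg(level)
  counts <- if (inherits(x, "round_counts")) {
    if (level == "cluster") stop("cluster-level abundances need a selex_clusters object")
    x$counts
  } else if (inherits(x, "selex_clusters")) {
    if (level == "cluster") x$total_count
    else unlist(attr(x, "members"), use.names = FALSE)
  } else {
    stop("x must be a round_counts or selex_clusters object")
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("empty abundance vector")
  as.numeric(counts) / sum(counts)
}

#' Diversity indices of a sequence pool
#'
#' For relative abundances `p_1..p_R` over the `R` distinct sequences (or
#' clusters) observed in a round: richness is `R`; the Shannon index is
#' `H = -sum(p_i * log(p_i))` (natural logarithm); the inverse Simpson
#' index is `1 / sum(p_i^2)`.
#'
#' @param p Numeric vector of positive relative abundances summing to 1
#'   (see [abundance_vector()]).
#' @return `richness()` an integer; `shannon()` and `inverse_simpson()`
#'   numbers, with `0 <= H <= log(R)` and `1 <= 1/sum(p^2) <= R`.
#' @export
richness <- function(p) {
  check_abundances(p)
  length(p)
}

#' @rdname richness
#' @export
shannon <- function(p) {
  check_abundances(p)
  -sum(p * log(p))
}

#' @rdname richness
#' @export
inverse_simpson <- function(p) {
  check_abundances(p)
  1 / sum(p^2)
}

check_abundances <- function(p) {
  if (length(p) == 0L) stop("empty abundance vector")
  if (any(p <= 0)) stop("all abundances must be > 0")
  if (abs(sum(p) - 1) > 1e-6) stop("abundances must sum to 1")
  invisible(p)
}

#' Full per-round statistics
#'
#' Bundles the unique/enriched fractions, bin fractions, positional
#' nucleotide profile and diversity indices for one round.
#'
#' @param pool A [round_counts()].
#' @param clusters The round's `selex_clusters`.
#' @param var_len Profile length, see [nucleotide_profile()].
#' @param cutoff Unique/enriched boundary, see [classify_clusters()].
#' @param diversity_level Abundance level for the diversity indices
#'   (`"sequence"`, the default, or `"cluster"`).
#' @return A list of class `round_stats`.
#' @export
round_stats <- function(pool, clusters, var_len = 40L, cutoff = 50L,
                        diversity_level = "sequence") {
  cls <- classify_clusters(clusters, cutoff = cutoff)
  p <- abundance_vector(if (diversity_level == "cluster") clusters else pool,
                        level = diversity_level)
  structure(list(
    round_label = pool$round_label,
    total_reads = pool$total_reads,
    n_clusters = nrow(clusters),
    unique_fraction = unname(cls["unique_fraction"]),
    enriched_fraction = unname(cls["enriched_fraction"]),
    bin_fractions = bin_clusters(clusters),
    nt_profile = nucleotide_profile(pool, var_len = var_len),
    richness = richness(p),
    shannon = shannon(p),
    inverse_simpson = inverse_simpson(p)
  ), class = "round_stats")
}

#' @export
print.round_stats <- function(x, ...) {
  cat(sprintf("round_stats '%s': %d reads, %d clusters\n",
              x$round_label, x$total_reads, x$n_clusters))
  cat(sprintf("  unique %.3f / enriched %.3f of reads\n",
              x$unique_fraction, x$enriched_fraction))
  cat(sprintf("  richness %d, Shannon %.3f, inverse Simpson %.1f\n",
              x$richness, x$shannon, x$inverse_simpson))
  invisible(x)
}

#' Write round statistics
#'
#' `write_round_stats` emits the full stats as JSON; the nucleotide
#' profile can additionally be written as a TSV matrix.
#'
#' @param stats A `round_stats` object.
#' @param path Output JSON path.
#' @param profile_path Optional TSV path for the nucleotide profile.
#' @return `path`, invisibly.
#' @export
write_round_stats <- function(stats, path, profile_path = NULL) {
  out <- unclass(stats)
  out$bin_fractions <- as.list(out$bin_fractions)
  out$nt_profile <- as.data.frame(out$nt_profile)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(profile_path)) {
    write.table(cbind(position = seq_len(nrow(stats$nt_profile)), stats$nt_profile),
                profile_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
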