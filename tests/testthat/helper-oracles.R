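# Independent reference implementations and fixture builders used across the
# suite. These deliberately share no code with the package internals.

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# substitute the base at a fixed position (deterministic cyclic replacement)
mutate_seq_at <- function(s, pos) {
  chars <- strsplit(s, "")[[1]]
  bases <- c("A", "C", "G", "T")
  chars[pos] <- bases[(match(chars[pos], bases) %% 4L) + 1L]
  paste(chars, collapse = "")
}

# substitute k distinct positions of s with a different base
mutate_seq <- function(s, k) {
  stopifnot(k <= nchar(s))
  pos <- sample.int(nchar(s), k)
  chars <- strsplit(s, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# n sequences of length len that are mutually dissimilar (< 0.8 identity),
# so each founds its own cluster at the 0.9 threshold
dissimilar_seqs <- function(n, len = 40L) {
  out <- character(0)
  while (length(out) < n) {
    cand <- random_seq(len)
    if (all(vapply(out, function(s) pairwise_identity(cand, s) < 0.8, TRUE))) {
      out <- c(out, cand)
    }
  }
  out
}

# a small pool mixing dissimilar "parents" (with given counts) and mutated
# low-count variants, mimicking a sequenced SELEX round
random_pool <- function(n_parents, n_variants, len_range = 39:41,
                        parent_counts = NULL, round_label = "R1") {
  parents <- vapply(seq_len(n_parents), function(i) random_seq(sample(len_range, 1L)), "")
  if (is.null(parent_counts)) parent_counts <- sample(20:200, n_parents, replace = TRUE)
  counts <- setNames(parent_counts, parents)
  for (i in seq_len(n_variants)) {
    p <- sample(parents, 1L)
    v <- mutate_seq(p, sample(1:2, 1L))
    counts[v] <- if (is.na(counts[v])) 1L else counts[v] + 1L
  }
  round_counts(counts, round_label = round_label)
}

# full-matrix affine-gap global alignment (Gotoh), plain R
gotoh_r <- function(a, b, match = 1, mismatch = -1, open = 2, ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] - (open + ext), X[i - 1, j] - ext,
                     Y[i - 1, j] - (open + ext))
      Y[i, j] <- max(M[i, j - 1] - (open + ext), Y[i, j - 1] - ext,
                     X[i, j - 1] - (open + ext))
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# banded maximum-match global alignment, plain R (identity oracle)
banded_matches_r <- function(a, b, band = 2L) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  dmin <- min(0L, m - n) - band
  dmax <- max(0L, m - n) + band
  M <- matrix(NEG, n + 1, m + 1)
  for (j in 0:min(m, dmax)) M[1, j + 1] <- 0
  for (i in 1:n) {
    jlo <- max(0L, i + dmin); jhi <- min(m, i + dmax)
    if (jlo > jhi) return(0L)
    for (j in jlo:jhi) {
      best <- M[i, j + 1]
      if (j > 0) {
        if (M[i, j] > NEG) best <- max(best, M[i, j] + (A[i] == B[j]))
        best <- max(best, M[i + 1, j])
      }
      M[i + 1, j + 1] <- best
    }
  }
  max(0L, M[n + 1, m + 1])
}

# write a minimal Phred+33 FASTQ file; quals may be a single integer (applied
# to every base), a vector of per-read integers, or a list of per-base vectors
write_test_fastq <- function(path, seqs, quals = 35L) {
  n <- length(seqs)
  if (is.list(quals)) {
    qstr <- vapply(quals, function(q) intToUtf8(q + 33L), "")
  } else {
    if (length(quals) == 1L) quals <- rep(quals, n)
    qstr <- vapply(seq_len(n), function(i) {
      intToUtf8(rep(quals[i] + 33L, nchar(seqs[i])))
    }, "")
  }
  writeLines(paste0("@read", seq_len(n), "\n", seqs, "\n+\n", qstr), path)
  path
}

# clusters object from a set of mutually dissimilar sequences with set counts
clusters_with_counts <- function(counts, len = 40L) {
  seqs <- dissimilar_seqs(length(counts), len)
  greedy_cluster(round_counts(setNames(as.integer(counts), seqs)))
}
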