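#' Aptamer library geometry
#'
#' Describes the amplicon layout of a SELEX library: a 5' constant arm, a
#' randomized variable region, and a 3' constant arm. The default geometry
#' is a 40-nt variable region flanked by arms of 18 and 19 nt, i.e. a 77-nt
#' transcript-level amplicon (the corresponding DNA template view, with
#' primer extensions, is 94 bp and can be described by passing longer arms).
#'
#' The default arm sequences are fixed arbitrary sequences of the documented
#' lengths; real analyses should supply the experiment's own arms.
#'
#' @param arm5 5' constant-arm sequence (A/C/G/T).
#' @param arm3 3' constant-arm sequence (A/C/G/T).
#' @param var_len Length of the randomized variable region in nt.
#' @return An object of class `library_spec` with fields `arm5`, `arm3`,
#'   `var_len` and derived `amplicon_len`.
#' @examples
#' spec <- library_spec()
#' spec$amplicon_len  # 77
#' @export
library_spec <- function(arm5 = "GGGAGGACGAUGCGGACG",
                         arm3 = "CAGACGACUCGCUGAGGAU",
                         var_len = 40L) {
  arm5 <- rna_to_dna(arm5)
  arm3 <- rna_to_dna(arm3)
  stopifnot(is.character(arm5), length(arm5) == 1L, nzchar(arm5),
            is.character(arm3), length(arm3) == 1L, nzchar(arm3))
  if (!is_acgt(arm5) || !is_acgt(arm3)) {
    stop("constant arms must contain only A/C/G/T (U is converted to T)")
  }
  var_len <- as.integer(var_len)
  if (is.na(var_len) || var_len < 1L) stop("var_len must be >= 1")
  structure(
    list(arm5 = arm5, arm3 = arm3, var_len = var_len,
         amplicon_len = nchar(arm5) + var_len + nchar(arm3)),
    class = "library_spec"
  )
}

#' @export
print.library_spec <- function(x, ...) {
  cat("SELEX library geometry\n")
  cat("  5' arm : ", x$arm5, " (", nchar(x$arm5), " nt)\n", sep = "")
  cat("  variable region: ", x$var_len, " nt\n", sep = "")
  cat("  3' arm : ", x$arm3, " (", nchar(x$arm3), " nt)\n", sep = "")
  cat("  amplicon length: ", x$amplicon_len, " nt\n", sep = "")
  invisible(x)
}

# DNA alphabet check; the package works on the DNA view of sequences.
is_acgt <- function(x) !grepl("[^ACGT]", x)

rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Per-round counted sequence pool
#'
#' A `round_counts` object is the unit the analysis operates on: a named
#' integer vector mapping each distinct variable-region sequence to its
#' read count, plus the round label and total read count.
#'
#' @param counts Named integer vector (names = sequences, values = counts),
#'   or a named numeric vector coercible to integer.
#' @param round_label Label for the selection round (e.g. `"R1"`).
#' @return An object of class `round_counts`.
#' @export
round_counts <- function(counts, round_label = "R1") {
  if (length(counts) && is.null(names(counts))) {
    stop("counts must be a named vector (names are sequences)")
  }
  counts <- counts[counts > 0]
  storage.mode(counts) <- "integer"
  if (length(counts) == 0L) {
    counts <- setNames(integer(0), character(0))
    return(structure(list(round_label = as.character(round_label),
                          counts = counts, total_reads = 0L),
                     class = "round_counts"))
  }
  if (anyDuplicated(names(counts))) {
    counts <- tapply(counts, names(counts), sum)
    counts <- setNames(as.integer(counts), names(counts))
  }
  # deterministic order: abundance descending, ties lexicographic
  ord <- order(-counts, names(counts), method = "radix")
  counts <- counts[ord]
  structure(
    list(round_label = as.character(round_label),
         counts = counts,
         total_reads = sum(counts)),
    class = "round_counts"
  )
}

#' @export
print.round_counts <- function(x, ...) {
  cat(sprintf("round_counts '%s': %d reads over %d distinct sequences\n",
              x$round_label, x$total_reads, length(x$counts)))
  invisible(x)
}

#' Write / read a counted pool as TSV
#'
#' @param pool A [round_counts()] object.
#' @param path Output TSV path (columns `sequence`, `count`).
#' @return `write_pool` returns `path` invisibly; `read_pool` returns a
#'   [round_counts()] object.
#' @export
write_pool <- function(pool, path) {
  stopifnot(inherits(pool, "round_counts"))
  df <- data.frame(sequence = names(pool$counts), count = unname(pool$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool
#' @param round_label Round label to attach on reading.
#' @export
read_pool <- function(path, round_label = "R1") {
  df <- read.table(path, header = TRUE, sep = "\t", colClasses = c("character", "integer"))
  round_counts(setNames(df$count, df$sequence), round_label = round_label)
}
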