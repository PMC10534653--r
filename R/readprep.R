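#' Read-preparation parameters
#'
#' @param qual_threshold Minimum per-read mean Phred quality (reads with a
#'   lower arithmetic mean are discarded). Default 28.
#' @param max_arm_mismatch Maximum substitutions tolerated when locating
#'   each constant arm. Default 2.
#' @param arm_offset Positional slack (nt) scanned on each side of the
#'   nominal arm placement, absorbing single indels. Default 2.
#' @param len_lo,len_hi Accepted variable-region length window. Default
#'   39--41 nt.
#' @return A named list of class `prep_params`.
#' @export
prep_params <- function(qual_threshold = 28, max_arm_mismatch = 2L,
                        arm_offset = 2L, len_lo = 39L, len_hi = 41L) {
  structure(list(qual_threshold = qual_threshold,
                 max_arm_mismatch = as.integer(max_arm_mismatch),
                 arm_offset = as.integer(arm_offset),
                 len_lo = as.integer(len_lo), len_hi = as.integer(len_hi)),
            class = "prep_params")
}

#' Mean-quality filter for a single read
#'
#' A read passes when the arithmetic mean of its Phred scores is greater
#' than or equal to `threshold` (a mean of exactly 28 passes at the
#' default).
#'
#' @param quals Integer vector of Phred scores, one per base.
#' @param threshold Minimum mean quality.
#' @return Logical scalar.
#' @export
quality_filter <- function(quals, threshold = 28) {
  if (length(quals) == 0L) stop("empty read: no quality values")
  mean(quals) >= threshold
}

#' Length/alphabet filter for a variable region
#'
#' Accepts sequences whose length lies in `[lo, hi]` and that contain only
#' A/C/G/T. Reads with ambiguous bases (N) in the variable region are
#' rejected so that downstream clustering and alignment see a clean
#' alphabet; their prevalence is still reported by [load_round()].
#'
#' @param v Variable-region sequence(s).
#' @param lo,hi Accepted length window (defaults 39 and 41).
#' @return Logical vector.
#' @export
length_filter <- function(v, lo = 39L, hi = 41L) {
  nchar(v) >= lo & nchar(v) <= hi & is_acgt(v)
}

#' Trim the constant arms from one read
#'
#' Locates the 5' arm at the read start and the 3' arm at the read end,
#' each as the best ungapped placement scanned over `arm_offset` nt of
#' positional slack, and returns the enclosed variable region. A placement
#' needing more than `max_arm_mismatch` substitutions is a rejection, not
#' an error.
#'
#' @param bases Read sequence.
#' @param spec A [library_spec()].
#' @param max_arm_mismatch Maximum substitutions per arm.
#' @param arm_offset Placement slack in nt.
#' @return The variable-region string, or `NA_character_` with attribute
#'   `reason` (`"arm5_not_found"` / `"arm3_not_found"`) on rejection.
#' @export
trim_constant_regions <- function(bases, spec, max_arm_mismatch = 2L,
                                  arm_offset = 2L) {
  stopifnot(inherits(spec, "library_spec"), nzchar(spec$arm5), nzchar(spec$arm3))
  res <- prep_reads_cpp(bases, strrep("I", nchar(bases)), spec$arm5, spec$arm3,
                        as.integer(max_arm_mismatch), as.integer(arm_offset),
                        0, 0L, .Machine$integer.max)
  v <- res$var[1L]
  if (res$reason[1L] %in% c(2L, 3L)) {
    v <- NA_character_
    attr(v, "reason") <- c("arm5_not_found", "arm3_not_found")[res$reason[1L] - 1L]
  }
  v
}

REJECTION_REASONS <- c("quality", "arm5_not_found", "arm3_not_found",
                       "length_out_of_range", "non_acgt")

#' Load and prepare one round's FASTQ file
#'
#' Applies, in order: the mean-quality filter, constant-arm trimming, and
#' the variable-region length/alphabet filter, then counts the surviving
#' variable regions.
#'
#' @param fastq_path Path to a (Phred+33) FASTQ file.
#' @param spec A [library_spec()].
#' @param params A [prep_params()].
#' @param round_label Label for the resulting pool.
#' @return A list of class `prep_result` with elements `pool` (a
#'   [round_counts()]) and `report` (list: `round_label`, `input_reads`,
#'   `survivors`, `rejections` named by reason, `n_read_fraction` = share
#'   of raw reads containing at least one N). Read accounting satisfies
#'   `input_reads == survivors + sum(rejections)`.
#' @export
load_round <- function(fastq_path, spec = library_spec(), params = prep_params(),
                       round_label = "R1") {
  if (!file.exists(fastq_path)) stop("FASTQ file not found: ", fastq_path)
  fq <- tryCatch(
    # suppressed warning: Biostrings drops its own metadata columns here
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(fastq_path, quality.scoring = "phred")
    ),
    error = function(e) stop("malformed FASTQ in ", fastq_path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  bases <- as.character(fq)
  quals <- as.character(Biostrings::quality(fq))
  res <- prep_reads_cpp(bases, quals, spec$arm5, spec$arm3,
                        params$max_arm_mismatch, params$arm_offset,
                        params$qual_threshold, params$len_lo, params$len_hi)
  surv <- res$reason == 0L
  rejections <- setNames(tabulate(res$reason, nbins = 5L), REJECTION_REASONS)
  counts <- if (any(surv)) table(res$var[surv]) else integer(0)
  pool <- round_counts(setNames(as.integer(counts), names(counts)),
                       round_label = round_label)
  report <- list(round_label = round_label,
                 input_reads = length(bases),
                 survivors = sum(surv),
                 rejections = as.list(rejections),
                 n_read_fraction = if (length(bases)) mean(res$has_n) else 0)
  structure(list(pool = pool, report = report), class = "prep_result")
}

#' @export
print.prep_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("prep '%s': %d reads in, %d survivors (%.1f%%)\n",
              r$round_label, r$input_reads, r$survivors,
              if (r$input_reads) 100 * r$survivors / r$input_reads else 0))
  rej <- unlist(r$rejections)
  for (nm in names(rej)) if (rej[[nm]] > 0) cat(sprintf("  rejected %-20s %d\n", nm, rej[[nm]]))
  invisible(x)
}

#' Write a prep report as JSON
#'
#' @param prep A `prep_result` from [load_round()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_prep_report <- function(prep, path) {
  jsonlite::write_json(prep$report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
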