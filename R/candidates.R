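#' Rank tracked clusters at the final round
#'
#' Clusters present at `final_round` sorted by RPM descending; ties are
#' broken by total count, then by lexicographic representative.
#'
#' @param tracked A `selex_tracking` object.
#' @param final_round Round label to rank at (default: last tracked round).
#' @return A data.frame with the trajectory columns of the final round in
#'   rank order, plus `rank`.
#' @export
rank_clusters <- function(tracked, final_round = NULL) {
  stopifnot(inherits(tracked, "selex_tracking"))
  if (is.null(final_round)) final_round <- tracked$rounds[length(tracked$rounds)]
  if (!final_round %in% tracked$rounds) stop("unknown round: ", final_round)
  df <- tracked$trajectory[tracked$trajectory$round == final_round, , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("no clusters at round ", final_round)
    df$rank <- integer(0)
    return(df)
  }
  ord <- order(-df$rpm, -df$total_count, df$representative, method = "radix")
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Seed-sequence dominance of a cluster
#'
#' Fraction of a cluster's reads carried by its representative (seed)
#' sequence; a value of 0.83 means the seed represents 83% of the cluster
#' population. Invariant under uniform scaling of member counts.
#'
#' @param cluster One row of a `selex_clusters` / ranked data.frame, or
#'   any list with `representative_count` and `total_count`.
#' @return Fraction in `(0, 1]`.
#' @export
seed_fraction <- function(cluster) {
  if (is.null(cluster$total_count) || length(cluster$total_count) == 0L) {
    stop("cluster must carry representative_count and total_count")
  }
  cluster$representative_count / cluster$total_count
}

#' RPM gaps down a ranked list
#'
#' For ranked RPM values `r_1 >= r_2 >= ...`, gap `k` is
#' `r_k - r_{k+1}`; the last gap is the last RPM itself (distance to an
#' absent next cluster).
#'
#' @param ranked A ranked data.frame from [rank_clusters()], or a numeric
#'   vector of RPM values in rank order.
#' @return Numeric vector of gaps, same length as the input.
#' @export
rpm_gap <- function(ranked) {
  rpm <- if (is.numeric(ranked)) ranked else ranked$rpm
  if (length(rpm) == 0L) return(numeric(0))
  c(-diff(rpm), rpm[length(rpm)])
}

#' Candidate report for the final selection round
#'
#' Ranks final-round clusters by RPM and reports, for the top `top_n`,
#' the lineage id, representative sequence, RPM, seed dominance and RPM
#' gap to the next-ranked cluster, together with run metadata.
#'
#' @param tracked A `selex_tracking` object.
#' @param final_round Round label (default: last round).
#' @param top_n Number of candidates reported (default 100; the study's
#'   convention is a top-100 pass then a top-10 shortlist).
#' @return A list of class `candidate_report` with `candidates`
#'   (data.frame) and `metadata`.
#' @export
candidate_report <- function(tracked, final_round = NULL, top_n = 100L) {
  ranked <- rank_clusters(tracked, final_round)
  if (is.null(final_round)) final_round <- tracked$rounds[length(tracked$rounds)]
  gaps <- rpm_gap(ranked)
  keep <- head(seq_len(nrow(ranked)), top_n)
  candidates <- data.frame(
    rank = ranked$rank[keep],
    uc_id = ranked$uc_id[keep],
    representative = ranked$representative[keep],
    rpm = ranked$rpm[keep],
    total_count = ranked$total_count[keep],
    seed_fraction = ranked$representative_count[keep] / ranked$total_count[keep],
    rpm_gap_to_next = gaps[keep],
    stringsAsFactors = FALSE
  )
  structure(list(
    candidates = candidates,
    metadata = list(final_round = final_round,
                    rounds_analyzed = tracked$rounds,
                    n_clusters_final = nrow(ranked),
                    score_threshold = tracked$config$score_threshold,
                    top_n = as.integer(top_n))
  ), class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("candidate report, round %s (%d clusters; top %d shown)\n",
              x$metadata$final_round, x$metadata$n_clusters_final,
              nrow(x$candidates)))
  print(head(x$candidates, 10L), digits = 4)
  invisible(x)
}

#' Write a candidate report
#'
#' @param report A `candidate_report`.
#' @param tsv_path Optional TSV output path for the candidate table.
#' @param json_path Optional JSON output path for the full report.
#' @param fasta_path Optional FASTA path for representative sequences
#'   (input for external multiple alignment / structure tools).
#' @return The report, invisibly.
#' @export
write_candidate_report <- function(report, tsv_path = NULL, json_path = NULL,
                                   fasta_path = NULL) {
  stopifnot(inherits(report, "candidate_report"))
  if (!is.null(tsv_path)) {
    write.table(report$candidates, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::DNAStringSet(report$candidates$representative)
    names(seqs) <- report$candidates$uc_id
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
  invisible(report)
}
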