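#' Run the full SELEX enrichment analysis on per-round FASTQ files
#'
#' Convenience driver chaining the whole pipeline: read preparation per
#' round, greedy identity clustering, per-round statistics, cross-round
#' cluster tracking, the round network, and the final candidate report.
#'
#' @param fastq_files Character vector of per-round FASTQ paths, in round
#'   order; names (or `R1..Rk`) become round labels.
#' @param spec A [library_spec()].
#' @param params A [prep_params()].
#' @param threshold Clustering identity threshold (default 0.90).
#' @param cfg A [tracking_config()].
#' @param top_n Candidates reported (default 100).
#' @return A list of class `selex_analysis`: `pools`, `prep_reports`,
#'   `clusters`, `stats`, `tracking`, `network`, `report`.
#' @export
run_selex_analysis <- function(fastq_files, spec = library_spec(),
                               params = prep_params(), threshold = 0.90,
                               cfg = tracking_config(), top_n = 100L) {
  labels <- names(fastq_files)
  if (is.null(labels)) labels <- paste0("R", seq_along(fastq_files))
  preps <- lapply(seq_along(fastq_files), function(i) {
    load_round(fastq_files[i], spec = spec, params = params, round_label = labels[i])
  })
  names(preps) <- labels
  pools <- lapply(preps, `[[`, "pool")
  clusters <- lapply(pools, greedy_cluster, threshold = threshold)
  stats <- mapply(round_stats, pools, clusters,
                  MoreArgs = list(var_len = spec$var_len),
                  SIMPLIFY = FALSE)
  tracking <- track_clusters(clusters, cfg = cfg)
  network <- build_network(tracking, rounds = clusters)
  report <- candidate_report(tracking, top_n = top_n)
  structure(list(pools = pools,
                 prep_reports = lapply(preps, `[[`, "report"),
                 clusters = clusters, stats = stats, tracking = tracking,
                 network = network, report = report),
            class = "selex_analysis")
}

#' @export
print.selex_analysis <- function(x, ...) {
  cat("SELEX enrichment analysis over rounds:",
      paste(names(x$pools), collapse = ", "), "\n")
  for (s in x$stats) {
    cat(sprintf("  %s: %d reads, %d clusters, enriched %.3f, Shannon %.3f\n",
                s$round_label, s$total_reads, s$n_clusters,
                s$enriched_fraction, s$shannon))
  }
  cat("top candidate:\n")
  print(head(x$report$candidates, 1L), digits = 4)
  invisible(x)
}
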