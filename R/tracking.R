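#' Alignment configuration for cluster tracking
#'
#' Scoring scheme for the Needleman--Wunsch global alignment used to map
#' cluster representatives from one round to the next, and the score
#' threshold below which a lineage is declared lost. A gap of length L
#' costs `gap_open + L * gap_extend`. Under the defaults (+1/-1, gaps
#' 2/2) two 40-mers align at score >= 30 when they differ at about five or
#' fewer positions, consistent in spirit with the 90% clustering identity.
#'
#' @param match_score Score per matched base (default +1).
#' @param mismatch_score Score per mismatched base (default -1).
#' @param gap_open Gap opening penalty (>= 0, default 2).
#' @param gap_extend Gap extension penalty per base (>= 0, default 2).
#' @param score_threshold Minimum alignment score to carry a lineage
#'   forward; a best score strictly below it means the lineage is lost
#'   (default 30).
#' @return A list of class `tracking_config`.
#' @export
tracking_config <- function(match_score = 1, mismatch_score = -1,
                            gap_open = 2, gap_extend = 2,
                            score_threshold = 30) {
  if (match_score <= mismatch_score) stop("match_score must exceed mismatch_score")
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  structure(list(match_score = match_score, mismatch_score = mismatch_score,
                 gap_open = gap_open, gap_extend = gap_extend,
                 score_threshold = score_threshold),
            class = "tracking_config")
}

#' Needleman--Wunsch global alignment score
#'
#' Optimal global alignment score of two sequences under an affine gap
#' model (Gotoh algorithm); a gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param a,b Non-empty A/C/G/T sequences.
#' @param cfg A [tracking_config()].
#' @return Numeric alignment score.
#' @examples
#' nw_score(strrep("A", 40), strrep("A", 40))  # 40
#' @export
nw_score <- function(a, b, cfg = tracking_config()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  nw_score_cpp(a, b, cfg$match_score, cfg$mismatch_score,
               cfg$gap_open, cfg$gap_extend)
}

#' Map a representative sequence onto the next round's clusters
#'
#' Returns the next-round cluster whose representative aligns best to
#' `rep`, provided the score reaches `cfg$score_threshold`; otherwise the
#' lineage is lost. Ties on score are broken by the higher-count cluster,
#' then by lexicographically smaller representative.
#'
#' @param rep Representative (seed) sequence of the current lineage.
#' @param next_round_clusters `selex_clusters` of the following round.
#' @param cfg A [tracking_config()].
#' @return A list with `lost` (logical), and when not lost
#'   `cluster_index` (row in `next_round_clusters`) and `score`.
#' @export
map_representative <- function(rep, next_round_clusters, cfg = tracking_config()) {
  stopifnot(nrow(next_round_clusters) > 0L)
  targets <- next_round_clusters$representative
  # an exact match is the unique score maximum (all-match, no penalties)
  exact <- match(rep, targets)
  if (!is.na(exact)) {
    score <- cfg$match_score * nchar(rep)
    return(list(lost = score < cfg$score_threshold,
                cluster_index = exact, score = score))
  }
  best <- nw_best_cpp(rep, targets, as.numeric(next_round_clusters$total_count),
                      cfg$match_score, cfg$mismatch_score,
                      cfg$gap_open, cfg$gap_extend)
  if (best$score < cfg$score_threshold) return(list(lost = TRUE, score = best$score))
  list(lost = FALSE, cluster_index = best$index + 1L, score = best$score)
}

#' Track clusters across SELEX rounds
#'
#' Assigns a stable lineage identifier ("UC" + integer) to every cluster
#' at the round of its first appearance and follows each lineage forward
#' by aligning its current representative to the representatives of the
#' next round. First-round clusters seed identifiers in descending
#' total-count order. At every subsequent round, live lineages are
#' processed in descending current-RPM order and each claims its
#' best-aligning unclaimed cluster (a cluster absorbs at most one
#' lineage); a lineage whose best available score falls below the
#' threshold is lost and never resumes -- a later similar sequence founds
#' a new lineage. Clusters claimed by no lineage found new identifiers in
#' descending count order.
#'
#' @param rounds Ordered named list of `selex_clusters`, one per round;
#'   names are round labels (defaults `R1..Rk` when unnamed).
#' @param cfg A [tracking_config()].
#' @return A list of class `selex_tracking` with `lineages` (data.frame:
#'   `uc_id`, `first_round`, `last_round`, `n_rounds`) and `trajectory`
#'   (long data.frame: `uc_id`, `round`, `cluster_index`,
#'   `representative`, `representative_count`, `total_count`, `rpm`).
#'   Lost rounds simply have no trajectory row.
#' @export
track_clusters <- function(rounds, cfg = tracking_config()) {
  stopifnot(is.list(rounds), length(rounds) >= 1L)
  labels <- names(rounds)
  if (is.null(labels)) labels <- paste0("R", seq_along(rounds))
  traj <- vector("list", length(rounds))
  next_id <- 1L
  # live lineage state
  live_uc <- integer(0)       # numeric part of uc id
  live_rep <- character(0)
  live_rpm <- numeric(0)
  first_round <- integer(0)   # indexed by uc number
  for (r in seq_along(rounds)) {
    cl <- rounds[[r]]
    n <- nrow(cl)
    claimed_by <- integer(n)  # uc number claiming each cluster, 0 = none
    if (r > 1L && length(live_uc) && n > 0L) {
      reps <- cl$representative
      cnts <- as.numeric(cl$total_count)
      ord <- order(-live_rpm, live_uc, method = "radix")
      for (i in ord) {
        avail <- which(claimed_by == 0L)
        if (!length(avail)) break
        # exact representative match is the unique score maximum
        exact <- match(live_rep[i], reps[avail])
        if (!is.na(exact)) {
          if (cfg$match_score * nchar(live_rep[i]) >= cfg$score_threshold) {
            claimed_by[avail[exact]] <- live_uc[i]
          }
          next
        }
        best <- nw_best_cpp(live_rep[i], reps[avail], cnts[avail],
                            cfg$match_score, cfg$mismatch_score,
                            cfg$gap_open, cfg$gap_extend,
                            threshold_filter = TRUE,
                            threshold = cfg$score_threshold)
        if (best$index >= 0L && best$score >= cfg$score_threshold) {
          claimed_by[avail[best$index + 1L]] <- live_uc[i]
        }
      }
    }
    # unclaimed clusters found new lineages, largest first
    new_idx <- if (n) which(claimed_by == 0L) else integer(0)
    if (length(new_idx)) {
      ord <- new_idx[order(-cl$total_count[new_idx], cl$representative[new_idx],
                           method = "radix")]
      for (i in ord) {
        claimed_by[i] <- next_id
        first_round[next_id] <- r
        next_id <- next_id + 1L
      }
    }
    if (n) {
      traj[[r]] <- data.frame(
        uc_id = paste0("UC", claimed_by),
        uc_num = claimed_by,
        round = labels[r],
        cluster_index = cl$cluster_index,
        representative = cl$representative,
        representative_count = cl$representative_count,
        total_count = cl$total_count,
        rpm = cl$rpm,
        stringsAsFactors = FALSE
      )
    }
    # next round's live set = lineages present in this round
    live_uc <- claimed_by
    live_rep <- cl$representative
    live_rpm <- cl$rpm
  }
  trajectory <- do.call(rbind, traj[!vapply(traj, is.null, TRUE)])
  uc_nums <- seq_len(next_id - 1L)
  by_uc <- split(trajectory$round, factor(trajectory$uc_num, levels = uc_nums))
  round_index <- function(x) match(x, labels)
  lineages <- data.frame(
    uc_id = paste0("UC", uc_nums),
    first_round = labels[first_round[uc_nums]],
    last_round = vapply(by_uc, function(x) x[which.max(round_index(x))], ""),
    n_rounds = lengths(by_uc),
    stringsAsFactors = FALSE
  )
  rownames(lineages) <- NULL
  trajectory$uc_num <- NULL
  structure(list(lineages = lineages, trajectory = trajectory,
                 rounds = labels, config = cfg),
            class = "selex_tracking")
}

#' Histogram of lineage first appearances
#'
#' @param tracked A `selex_tracking` object.
#' @return Named integer vector: number of lineage identifiers born in
#'   each round (zeros included); sums to the total number of lineages.
#' @export
first_appearance_histogram <- function(tracked) {
  stopifnot(inherits(tracked, "selex_tracking"))
  tab <- table(factor(tracked$lineages$first_round, levels = tracked$rounds))
  setNames(as.integer(tab), names(tab))
}

#' Build the round-to-round common-cluster network
#'
#' Undirected network over selection rounds. Each node is a round with a
#' `size` attribute equal to its cluster richness (pool heterogeneity);
#' each edge weight counts the tracked lineages present in both rounds.
#' Edges of weight 0 are not stored.
#'
#' @param tracked A `selex_tracking` object.
#' @param rounds Optional named list of per-round `selex_clusters` used
#'   for node sizes; defaults to cluster counts from the trajectory.
#' @return An `igraph` graph object with vertex attribute `size` and
#'   edge attribute `weight`.
#' @export
build_network <- function(tracked, rounds = NULL) {
  stopifnot(inherits(tracked, "selex_tracking"))
  labels <- tracked$rounds
  traj <- tracked$trajectory
  sizes <- if (!is.null(rounds)) {
    vapply(rounds, nrow, 0L)[labels]
  } else {
    vapply(labels, function(l) sum(traj$round == l), 0L)
  }
  pres <- table(traj$uc_id, factor(traj$round, levels = labels)) > 0
  edges <- NULL
  k <- length(labels)
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        w <- sum(pres[, i] & pres[, j])
        if (w >= 1L) edges <- rbind(edges, data.frame(
          from = labels[i], to = labels[j], weight = w, stringsAsFactors = FALSE))
      }
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, k, name = labels, size = as.numeric(sizes))
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges$from, labels), match(edges$to, labels)),
                           weight = edges$weight)
  }
  g
}

#' Export tracking results
#'
#' `write_tracking` writes the lineage trajectories as a long-format TSV;
#' `write_network` writes the round network as a weighted edge-list TSV
#' and, optionally, as GraphML.
#'
#' @param tracked A `selex_tracking` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(tracked, path) {
  write.table(tracked$trajectory, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracking
#' @param network An igraph object from [build_network()].
#' @param graphml_path Optional GraphML output path.
#' @export
write_network <- function(network, path, graphml_path = NULL) {
  df <- igraph::as_data_frame(network, what = "edges")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(network, graphml_path, format = "graphml")
  }
  invisible(path)
}
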