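#' Affinity model for simulated selection
#'
#' Maps variable-region sequences to the probability that a single read of
#' that sequence survives one selection round (capture, recovery and
#' re-amplification input). Sequences absent from the map use
#' `background_prob`. This abstracts the in-vivo binding/recovery step of a
#' cell-SELEX round into a single per-read survival probability.
#'
#' @param capture_prob Named numeric vector: sequence -> survival
#'   probability in \[0, 1\]. May be empty for a neutral model.
#' @param background_prob Survival probability for all other sequences.
#' @return An object of class `affinity_model`.
#' @export
affinity_model <- function(capture_prob = numeric(0), background_prob = 0.05) {
  if (length(capture_prob)) {
    if (is.null(names(capture_prob))) stop("capture_prob must be named by sequence")
    if (any(capture_prob < 0 | capture_prob > 1)) stop("capture probabilities must be in [0, 1]")
  }
  if (background_prob < 0 || background_prob > 1) stop("background_prob must be in [0, 1]")
  structure(list(capture_prob = capture_prob, background_prob = background_prob),
            class = "affinity_model")
}

capture_of <- function(model, seqs) {
  p <- rep(model$background_prob, length(seqs))
  if (length(model$capture_prob)) {
    hit <- match(seqs, names(model$capture_prob))
    p[!is.na(hit)] <- model$capture_prob[hit[!is.na(hit)]]
  }
  p
}

#' Generate a random starting library
#'
#' Draws `n_unique` distinct uniform-random variable regions of the
#' configured length, each with count 1 (one synthesis copy). Deterministic
#' for a fixed seed.
#'
#' @param n_unique Number of distinct library members (>= 1).
#' @param spec A [library_spec()].
#' @param seed Integer random seed; `NULL` continues the current RNG stream.
#' @return A [round_counts()] object labelled `"R0"`.
#' @export
generate_library <- function(n_unique, spec = library_spec(), seed = 1L) {
  n_unique <- as.integer(n_unique)
  if (is.na(n_unique) || n_unique < 1L) stop("n_unique must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  seqs <- random_seqs(n_unique, spec$var_len)
  # collisions are vanishingly rare in 4^40 space but keep the contract exact
  while (anyDuplicated(seqs)) {
    dup <- duplicated(seqs)
    seqs[dup] <- random_seqs(sum(dup), spec$var_len)
  }
  round_counts(setNames(rep(1L, n_unique), seqs), round_label = "R0")
}

random_seqs <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

#' Simulate one SELEX selection/amplification round
#'
#' Each read survives selection independently with its sequence's capture
#' probability (binomial thinning). Surviving counts are amplified by
#' `amp_factor` with per-sequence lognormal noise of coefficient of
#' variation `amp_noise_cv` (mean 1), then multinomially resampled to
#' `sample_depth` total reads (sequencing depth normalization).
#'
#' @param pool Input [round_counts()].
#' @param model An [affinity_model()].
#' @param sample_depth Total reads drawn for the output pool (>= 1).
#' @param amp_factor Mean amplification factor (>= 1).
#' @param amp_noise_cv Coefficient of variation of the lognormal
#'   amplification noise (0 disables it).
#' @param round_label Label for the output pool.
#' @param seed Optional integer seed; `NULL` continues the current RNG stream.
#' @return A [round_counts()] object.
#' @export
simulate_round <- function(pool, model, sample_depth, amp_factor = 10,
                           amp_noise_cv = 0.3, round_label = "R1", seed = NULL) {
  stopifnot(inherits(pool, "round_counts"), inherits(model, "affinity_model"))
  if (!is.null(seed)) set.seed(seed)
  sample_depth <- as.integer(sample_depth)
  if (is.na(sample_depth) || sample_depth < 1L) stop("sample_depth must be >= 1")
  if (amp_factor < 1) stop("amp_factor must be >= 1")
  seqs <- names(pool$counts)
  p <- capture_of(model, seqs)
  survivors <- rbinom(length(seqs), pool$counts, p)
  keep <- survivors > 0L
  if (!any(keep)) {
    stop("selection collapse: no sequence survived this round ",
         "(raise capture probabilities or pool size)")
  }
  w <- survivors[keep] * amp_factor
  if (amp_noise_cv > 0) {
    sdlog <- sqrt(log(1 + amp_noise_cv^2))
    w <- w * rlnorm(sum(keep), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  counts <- as.integer(rmultinom(1L, sample_depth, prob = w)[, 1L])
  round_counts(setNames(counts, seqs[keep]), round_label = round_label)
}

#' Emit a pool as a single-end FASTQ file
#'
#' Each read is `arm5 + variable + arm3` with independent per-base
#' substitution errors at `error_rate` and Phred+33 qualities drawn around
#' `qual_mean`. Optionally a fraction `indel_rate` of reads carries a
#' single-base insertion or deletion inside the variable region, producing
#' the 39/41-nt length spread that real SELEX libraries show.
#'
#' @param pool A [round_counts()].
#' @param spec A [library_spec()].
#' @param path Output FASTQ path.
#' @param error_rate Per-base substitution probability in \[0, 1).
#' @param qual_mean Mean Phred quality of simulated bases.
#' @param qual_sd Standard deviation of simulated base qualities.
#' @param indel_rate Fraction of reads receiving one indel in the variable
#'   region.
#' @param seed Optional integer seed; `NULL` continues the current RNG stream.
#' @return `path`, invisibly. The file has exactly `pool$total_reads`
#'   records.
#' @export
emit_fastq <- function(pool, spec, path, error_rate = 0, qual_mean = 32L,
                       qual_sd = 3, indel_rate = 0, seed = NULL) {
  stopifnot(inherits(pool, "round_counts"), inherits(spec, "library_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (indel_rate < 0 || indel_rate >= 1) stop("indel_rate must be in [0, 1)")
  vars <- rep(names(pool$counts), pool$counts)
  n <- length(vars)
  if (indel_rate > 0 && n > 0) {
    hit <- which(runif(n) < indel_rate)
    for (i in hit) {
      v <- vars[i]
      lv <- nchar(v)
      if (runif(1) < 0.5 && lv > 1L) {                      # deletion
        pos <- sample.int(lv, 1L)
        vars[i] <- paste0(substr(v, 1L, pos - 1L), substr(v, pos + 1L, lv))
      } else {                                              # insertion
        pos <- sample.int(lv + 1L, 1L) - 1L
        vars[i] <- paste0(substr(v, 1L, pos),
                          sample(c("A", "C", "G", "T"), 1L),
                          substr(v, pos + 1L, lv))
      }
    }
  }
  reads <- paste0(spec$arm5, vars, spec$arm3)
  if (error_rate > 0 && n > 0) reads <- mutate_reads_cpp(reads, error_rate)
  quals <- make_quals_cpp(nchar(reads), qual_mean, qual_sd)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (n > 0) {
    rec <- paste0("@read", seq_len(n), "\n", reads, "\n+\n", quals)
    writeLines(rec, con, sep = "\n")
  }
  invisible(path)
}

#' Default SELEX simulation configuration
#'
#' The defaults emulate the selection this package was designed around:
#' seven rounds of in-vivo selection of a 40-nt-variable-region library,
#' with one spiked high-affinity sequence holding a 10x per-round capture
#' advantage over the background pool.
#'
#' @param rounds Number of selection rounds (7 primary; 9 with the two
#'   confirmatory rounds).
#' @param n_unique Distinct sequences in the starting library.
#' @param initial_copies Copies of every library member entering round 1
#'   (pre-selection amplification of the synthesized pool). With a single
#'   copy per member, survival of any one sequence through the first
#'   selection would be a coin flip; amplified input reflects how real
#'   selections are run.
#' @param sample_depth Sequencing reads per round.
#' @param n_spiked Number of spiked high-affinity sequences.
#' @param spike_capture Per-read survival probability of spiked sequences.
#' @param background_capture Survival probability of everything else.
#' @param amp_factor,amp_noise_cv Amplification model, see [simulate_round()].
#' @param error_rate,indel_rate,qual_mean,qual_sd Sequencing model, see
#'   [emit_fastq()].
#' @param seed Integer random seed governing the whole run.
#' @return A named list of class `selex_sim_config`.
#' @export
selex_sim_config <- function(rounds = 7L, n_unique = 10000L, sample_depth = 100000L,
                             initial_copies = 100L,
                             n_spiked = 1L, spike_capture = 0.5,
                             background_capture = 0.05,
                             amp_factor = 10, amp_noise_cv = 0.3,
                             error_rate = 0.001, indel_rate = 0.005,
                             qual_mean = 32L, qual_sd = 3, seed = 1L) {
  cfg <- list(rounds = as.integer(rounds), n_unique = as.integer(n_unique),
              sample_depth = as.integer(sample_depth),
              initial_copies = as.integer(initial_copies),
              n_spiked = as.integer(n_spiked),
              spike_capture = spike_capture, background_capture = background_capture,
              amp_factor = amp_factor, amp_noise_cv = amp_noise_cv,
              error_rate = error_rate, indel_rate = indel_rate,
              qual_mean = as.integer(qual_mean), qual_sd = qual_sd,
              seed = as.integer(seed))
  if (cfg$rounds < 1L) stop("rounds must be >= 1")
  if (cfg$initial_copies < 1L) stop("initial_copies must be >= 1")
  class(cfg) <- "selex_sim_config"
  cfg
}

#' Read a flat key = value simulation config file
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys are
#' rejected. Values are coerced to the types of [selex_sim_config()].
#'
#' @param path Config file path.
#' @return A `selex_sim_config`.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  known <- names(formals(selex_sim_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- as.list(as.numeric(vals))
  names(args) <- keys
  do.call(selex_sim_config, args)
}

#' Simulate a full SELEX experiment
#'
#' Generates a random library, runs `rounds` selection/amplification rounds
#' with spiked high-affinity sequences, and (optionally) writes one FASTQ
#' per round plus a ground-truth table. The truth table holds the
#' analytically expected frequency of every library sequence at every round
#' (initial frequency repeatedly reweighted by capture probability and
#' renormalized), which the realized pools fluctuate around.
#'
#' @param config A [selex_sim_config()] (or arguments for it via `...`).
#' @param outdir Output directory for FASTQ/truth/metadata files; `NULL`
#'   keeps the simulation in memory only.
#' @param spec Library geometry, a [library_spec()].
#' @param ... Used to build a config when `config` is missing.
#' @return A list of class `selex_sim` with elements `pools` (list of
#'   [round_counts()], one per round, labels `R1..Rk`), `truth`
#'   (data.frame: sequence, round, expected_frequency, is_spiked),
#'   `spiked` (character), `fastq` (paths or NULL), `config`.
#' @export
simulate_selex <- function(config = selex_sim_config(...), outdir = NULL,
                           spec = library_spec(), ...) {
  stopifnot(inherits(config, "selex_sim_config"))
  set.seed(config$seed)
  lib <- generate_library(config$n_unique, spec, seed = NULL)
  seqs <- names(lib$counts)
  spiked <- if (config$n_spiked > 0L) sample(seqs, config$n_spiked) else character(0)
  model <- affinity_model(
    capture_prob = setNames(rep(config$spike_capture, length(spiked)), spiked),
    background_prob = config$background_capture
  )
  # analytic truth: f_r proportional to f_{r-1} * capture
  cap <- capture_of(model, seqs)
  freq <- rep(1 / length(seqs), length(seqs))
  truth_list <- vector("list", config$rounds)
  pools <- vector("list", config$rounds)
  fastq <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fastq <- file.path(outdir, sprintf("round_%d.fastq", seq_len(config$rounds)))
  }
  # pre-selection amplification: every member enters round 1 in many copies
  pool <- round_counts(setNames(rep(config$initial_copies, length(seqs)), seqs),
                       round_label = "R0")
  labels <- paste0("R", seq_len(config$rounds))
  for (r in seq_len(config$rounds)) {
    pool <- simulate_round(pool, model, config$sample_depth,
                           amp_factor = config$amp_factor,
                           amp_noise_cv = config$amp_noise_cv,
                           round_label = labels[r])
    pools[[r]] <- pool
    freq <- freq * cap
    freq <- freq / sum(freq)
    truth_list[[r]] <- data.frame(sequence = seqs, round = labels[r],
                                  expected_frequency = freq,
                                  is_spiked = seqs %in% spiked,
                                  stringsAsFactors = FALSE)
    if (!is.null(outdir)) {
      emit_fastq(pool, spec, fastq[r], error_rate = config$error_rate,
                 qual_mean = config$qual_mean, qual_sd = config$qual_sd,
                 indel_rate = config$indel_rate)
    }
  }
  names(pools) <- labels
  truth <- do.call(rbind, truth_list)
  if (!is.null(outdir)) {
    write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    meta <- unclass(config)
    jsonlite::write_json(meta, file.path(outdir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(pools = pools, truth = truth, spiked = spiked,
                 fastq = fastq, config = config, spec = spec),
            class = "selex_sim")
}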