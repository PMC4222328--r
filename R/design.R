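#' Specify an oddball block
#'
#' Defaults reproduce the study design: each block presents 630 standards
#' (including an initial 15-trial habituation run) and two deviant types 105
#' times each, with 3-5 standards between consecutive deviants and a fixed
#' 2 s stimulus onset asynchrony.
#'
#' @param standard_label label of the standard stimulus.
#' @param deviant_labels character vector of deviant labels.
#' @param n_standards total standard count, habituation included (default 630).
#' @param n_per_deviant presentations per deviant type (default 105).
#' @param gap_range inclusive integer interval of standards between
#'   consecutive deviants (default `c(3, 5)`).
#' @param habituation_len consecutive standards opening the block (default 15).
#' @param soa stimulus onset asynchrony in seconds (default 2).
#' @return A `block_spec` list.
#' @export
block_spec <- function(standard_label = "standard",
                       deviant_labels = c("deviant1", "deviant2"),
                       n_standards = 630, n_per_deviant = 105,
                       gap_range = c(3, 5), habituation_len = 15,
                       soa = 2) {
  stopifnot(n_per_deviant >= 0, length(gap_range) == 2,
            gap_range[1] >= 1, gap_range[2] >= gap_range[1],
            habituation_len <= n_standards, habituation_len >= 0, soa > 0)
  structure(list(standard_label = standard_label,
                 deviant_labels = as.character(deviant_labels),
                 n_standards = as.integer(n_standards),
                 n_per_deviant = as.integer(n_per_deviant),
                 gap_range = as.integer(gap_range),
                 habituation_len = as.integer(habituation_len),
                 soa = soa),
            class = "block_spec")
}

#' Generate an oddball trial sequence
#'
#' Produces a block with exact label counts. The habituation run opens the
#' block; deviant types are interleaved in seeded random order with exact
#' per-type counts; the number of standards between consecutive deviants
#' lies in `gap_range` except for the minimal number of gaps relaxed
#' downward (never below 1) needed to make the published counts satisfiable
#' (with the defaults, 615 post-habituation standards cannot fill 209 gaps
#' of >= 3, so exactly 12 gaps are relaxed to 2). Counts are authoritative
#' and never traded for gap satisfaction.
#'
#' @param spec a [block_spec()].
#' @param seed integer seed; sequences are fully reproducible from it.
#' @param block_id text identifier attached to the sequence.
#' @return A `trial_sequence`: data.frame `trials` with columns `label`,
#'   `onset` (s), `is_habituation`, `is_post_deviant`, plus fields
#'   `block_id`, `relaxed_gap_count`, `standard_label`, `deviant_labels`,
#'   `soa`.
#' @export
generate_block <- function(spec, seed, block_id = "block1") {
  stopifnot(inherits(spec, "block_spec"))
  rng <- local_rng(seed)
  n_dev <- length(spec$deviant_labels) * spec$n_per_deviant
  n_std_free <- spec$n_standards - spec$habituation_len
  relaxed <- 0L
  if (n_dev == 0L) {
    labels <- rep(spec$standard_label, spec$n_standards)
  } else {
    dev_order <- rng(rand_subset(rep(spec$deviant_labels, each = spec$n_per_deviant)))
    n_gaps <- n_dev - 1L  # inter-deviant gaps; head/tail unconstrained
    lo <- spec$gap_range[1]; hi <- spec$gap_range[2]
    gaps <- rep(lo, n_gaps)
    budget <- n_std_free - sum(gaps)
    head_std <- 0L; tail_std <- 0L
    if (budget < 0) {
      ## relax the fewest gaps, one unit at a time, never below 1
      deficit <- -budget
      if (deficit > n_gaps * (lo - 1L))
        stop("design error: ", spec$n_standards, " standards (",
             n_std_free, " after habituation) cannot fill ", n_gaps,
             " gaps of >= 1; need >= ",
             spec$habituation_len + n_gaps, " standards", call. = FALSE)
      while (deficit > 0L) {
        cand <- which(gaps > 1L)
        take <- rng(rand_subset(cand, min(deficit, length(cand))))
        gaps[take] <- gaps[take] - 1L
        deficit <- deficit - length(take)
      }
      relaxed <- sum(gaps < lo)
    } else if (budget > 0) {
      ## spread surplus into gaps up to the upper bound, then head, then tail
      while (budget > 0L && any(gaps < hi)) {
        cand <- which(gaps < hi)
        take <- rng(rand_subset(cand, min(budget, length(cand))))
        gaps[take] <- gaps[take] + 1L
        budget <- budget - length(take)
      }
      if (budget > 0L) {
        head_std <- rng(sample.int(budget + 1L, 1L)) - 1L
        tail_std <- budget - head_std
        if (tail_std == 0L && head_std > 0L) { # end on a standard if possible
          tail_std <- 1L; head_std <- head_std - 1L
        }
      }
    }
    runs <- c(head_std, gaps, tail_std)
    labels <- character(0)
    for (i in seq_len(n_dev)) {
      labels <- c(labels, rep(spec$standard_label, runs[i]), dev_order[i])
    }
    labels <- c(rep(spec$standard_label, spec$habituation_len), labels,
                rep(spec$standard_label, runs[n_dev + 1L]))
  }
  trials <- data.frame(
    label = labels,
    onset = (seq_along(labels) - 1) * spec$soa,
    is_habituation = seq_along(labels) <= spec$habituation_len &
      labels == spec$standard_label,
    is_post_deviant = FALSE,
    stringsAsFactors = FALSE)
  seq <- structure(list(trials = trials, block_id = block_id,
                        relaxed_gap_count = relaxed,
                        standard_label = spec$standard_label,
                        deviant_labels = spec$deviant_labels,
                        soa = spec$soa),
                   class = "trial_sequence")
  mark_analysis_trials(seq)
}

## size-safe sample (never treats a length-1 x as 1:x)
rand_subset <- function(x, size = length(x)) x[sample.int(length(x), size)]

## run code under a private RNG stream, leaving the global state untouched
local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr
  }
}

#' Flag trials excluded from analysis
#'
#' Sets the post-deviant flag on every standard that immediately follows a
#' deviant; habituation flags are preserved. Analyzable standards are
#' standards minus habituation minus post-deviant standards; deviants are
#' never flagged.
#'
#' @param seq a `trial_sequence`.
#' @return The sequence with flags set.
#' @export
mark_analysis_trials <- function(seq) {
  stopifnot(inherits(seq, "trial_sequence"))
  lab <- seq$trials$label
  is_dev <- lab %in% seq$deviant_labels
  post <- c(FALSE, is_dev[-length(is_dev)]) & !is_dev
  seq$trials$is_post_deviant <- post
  seq
}

#' @export
print.trial_sequence <- function(x, ...) {
  tab <- table(x$trials$label)
  cat(sprintf("<trial_sequence> '%s': %d trials (%s); %d relaxed gap(s)\n",
              x$block_id, nrow(x$trials),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              x$relaxed_gap_count))
  invisible(x)
}

#' Counterbalanced block order for a participant
#'
#' Assigns each participant a block order by alternating counterbalance over
#' the participant index: even indices (0, 2, ...) receive the blocks as
#' given, odd indices the rotated order.
#'
#' @param blocks list of `trial_sequence` objects (>= 1).
#' @param participant_index 0-based participant index.
#' @return The list of blocks in this participant's order.
#' @export
concat_experiment <- function(blocks, participant_index) {
  stopifnot(length(blocks) >= 1, participant_index >= 0)
  k <- participant_index %% length(blocks)
  if (k == 0) blocks else blocks[c((k + 1):length(blocks), 1:k)]
}

#' Write a trial sequence to an event CSV
#'
#' Columns: `onset_s`, `label`, `is_habituation`, `is_post_deviant`.
#'
#' @param seq a `trial_sequence`.
#' @param path output CSV path.
#' @export
write_events <- function(seq, path) {
  df <- data.frame(onset_s = seq$trials$onset, label = seq$trials$label,
                   is_habituation = seq$trials$is_habituation,
                   is_post_deviant = seq$trials$is_post_deviant)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
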