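# Experimental-design generation for the discriminative fear-conditioning
# task: alternating reinforcement/nonreinforcement contexts, complexity
# halves within each block, seeded trial orders and inter-trial intervals,
# and a partial reinforcement schedule on the CS+.

#' Design parameters for the fear-conditioning task
#'
#' Defaults reproduce the task structure: 8 blocks of 24 trials in
#' alternating contexts, stimuli of 4 s duration, inter-trial intervals
#' drawn from \{7, 9, 11\} s, and a 50% partial-reinforcement schedule on
#' the CS+. Each block presents one complexity (simple or complex) in its
#' first half and the other in its second half; within each half the two
#' members of the stimulus pair each appear half the time, in a seeded
#' random order.
#'
#' @param n_blocks Even number of blocks (contexts alternate block-to-block).
#' @param trials_per_block Trials per block; must be divisible by 4 (two
#'   complexity halves, two pair members per half).
#' @param stimulus_duration Stimulus duration in seconds.
#' @param iti_set Candidate inter-trial intervals in seconds, sampled
#'   uniformly per trial.
#' @param reinforcement_rate Fraction of CS+ trials (per complexity
#'   condition) followed by the unconditioned stimulus.
#' @param start_context Context of block 1, `"reinforcement"` or
#'   `"nonreinforcement"` (counterbalanced across participants in a study).
#' @param simple_first Logical; if `TRUE` the first half of every block is
#'   the simple pair (counterbalanced across participants in a study).
#' @param block_gap Gap in seconds inserted between blocks when onsets are
#'   accumulated (0 in pure simulation).
#' @param seed Integer seed controlling within-half trial order, intervals
#'   and the reinforcement schedule.
#' @return A list of class `"fc_design_params"`.
#' @export
#' @examples
#' p <- design_params(seed = 1)
#' p$n_blocks
design_params <- function(n_blocks = 8L, trials_per_block = 24L,
                          stimulus_duration = 4, iti_set = c(7, 9, 11),
                          reinforcement_rate = 0.5,
                          start_context = c("reinforcement", "nonreinforcement"),
                          simple_first = TRUE, block_gap = 0, seed = 1L) {
  start_context <- match.arg(start_context)
  check_param(length(iti_set) >= 1, "`iti_set` must be non-empty")
  check_param(n_blocks >= 2 && n_blocks %% 2 == 0, "`n_blocks` must be even and >= 2")
  check_param(trials_per_block %% 4 == 0,
              "`trials_per_block` must be divisible by 4")
  check_param(reinforcement_rate >= 0 && reinforcement_rate <= 1,
              "`reinforcement_rate` must be in [0, 1]")
  cs_plus_per_complexity <- n_blocks / 2 * trials_per_block / 4
  check_param(abs(reinforcement_rate * cs_plus_per_complexity -
                    round(reinforcement_rate * cs_plus_per_complexity)) < 1e-9,
              "`reinforcement_rate` times the CS+ count per complexity must be an integer")
  structure(list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    stimulus_duration = stimulus_duration,
    iti_set = iti_set,
    reinforcement_rate = reinforcement_rate,
    start_context = start_context,
    simple_first = simple_first,
    block_gap = block_gap,
    seed = as.integer(seed)
  ), class = "fc_design_params")
}

# Stimulus label from context and pair role: in the reinforcement context
# the pair is CS- (S1) / CS+ (S2); in the nonreinforcement context NS1/NS2.
stimulus_label <- function(context, pair_role) {
  ifelse(context == "reinforcement",
         ifelse(pair_role == "S1", "CS-", "CS+"),
         ifelse(pair_role == "S1", "NS1", "NS2"))
}

#' Generate the full trial table of the fear-conditioning experiment
#'
#' Produces the chronological trial list: block and context assignment,
#' complexity halves, seeded within-half orders of the two pair members,
#' onsets accumulated from stimulus durations and seeded inter-trial
#' intervals, required key-press responses (tied to pair role, so they are
#' matched across context and complexity), and — unless
#' `reinforce = FALSE` — the partial reinforcement schedule on the CS+.
#'
#' @param params A [design_params()] object.
#' @param reinforce Logical; apply [assign_reinforcement()] before returning.
#' @return A list of class `"fc_design"` with elements `trials` (a
#'   `data.frame`, one row per trial in chronological order) and `params`.
#'   Trial columns: `index` (0-based chronological), `block`, `context`,
#'   `complexity`, `pair_role`, `label` (CS+/CS-/NS1/NS2), `stimulus`
#'   (one of the 8 distinct identities), `onset`, `duration`, `iti_after`,
#'   `reinforced`, `required_response`.
#' @export
#' @examples
#' d <- generate_design(design_params(seed = 1))
#' table(d$trials$stimulus)      # 24 presentations each
#' sum(d$trials$reinforced)      # 24 reinforced CS+ in total
generate_design <- function(params = design_params(), reinforce = TRUE) {
  stopifnot(inherits(params, "fc_design_params"))
  n_half <- params$trials_per_block / 2L
  n_quarter <- params$trials_per_block / 4L
  contexts <- c("reinforcement", "nonreinforcement")
  if (params$start_context == "nonreinforcement") contexts <- rev(contexts)
  complexities <- if (params$simple_first) c("simple", "complex") else c("complex", "simple")

  seeds <- spawn_seeds(params$seed, 3L)  # orders, ITIs, reinforcement
  roles <- with_seed(seeds[1], {
    lapply(seq_len(params$n_blocks), function(b)
      c(sample(rep(c("S1", "S2"), each = n_quarter)),
        sample(rep(c("S1", "S2"), each = n_quarter))))
  })
  itis <- with_seed(seeds[2], {
    matrix(sample(params$iti_set, params$n_blocks * params$trials_per_block,
                  replace = TRUE),
           nrow = params$n_blocks, byrow = TRUE)
  })

  rows <- vector("list", params$n_blocks)
  onset <- 0
  idx <- 0L
  for (b in seq_len(params$n_blocks)) {
    context <- contexts[(b - 1L) %% 2L + 1L]
    complexity <- rep(complexities, each = n_half)
    pair_role <- roles[[b]]
    iti_after <- itis[b, ]
    onsets <- onset + cumsum(c(0, (params$stimulus_duration + iti_after)[-params$trials_per_block]))
    rows[[b]] <- data.frame(
      index = idx + seq_len(params$trials_per_block) - 1L,
      block = b,
      context = context,
      complexity = complexity,
      pair_role = pair_role,
      onset = onsets,
      duration = params$stimulus_duration,
      iti_after = iti_after,
      stringsAsFactors = FALSE
    )
    onset <- onsets[params$trials_per_block] + params$stimulus_duration +
      iti_after[params$trials_per_block] + params$block_gap
    idx <- idx + params$trials_per_block
  }
  trials <- do.call(rbind, rows)
  trials$label <- stimulus_label(trials$context, trials$pair_role)
  trials$stimulus <- paste(trials$label, trials$complexity, sep = "_")
  trials$reinforced <- FALSE
  trials$required_response <- ifelse(trials$pair_role == "S1", "key1", "key2")
  trials <- trials[, c("index", "block", "context", "complexity", "pair_role",
                       "label", "stimulus", "onset", "duration", "iti_after",
                       "reinforced", "required_response")]
  design <- structure(list(trials = trials, params = params), class = "fc_design")
  if (reinforce) design <- assign_reinforcement(design, seed = seeds[3])
  design
}

#' Assign the partial reinforcement schedule to CS+ trials
#'
#' Flags `reinforcement_rate` of the CS+ trials within each complexity
#' condition as reinforced (followed by the unconditioned stimulus), by a
#' seeded random draw. Trials in the nonreinforcement context and CS-
#' trials are never flagged.
#'
#' @param design An `"fc_design"` object.
#' @param seed Integer seed for the draw (defaults to a child of the design
#'   seed, so [generate_design()] is fully determined by its own seed).
#' @return The design with the `reinforced` column set.
#' @export
assign_reinforcement <- function(design, seed = spawn_seeds(design$params$seed, 3L)[3]) {
  stopifnot(inherits(design, "fc_design"))
  trials <- design$trials
  trials$reinforced <- FALSE
  rate <- design$params$reinforcement_rate
  is_csp <- trials$label == "CS+"
  check_param(any(is_csp) || rate == 0, "design contains no CS+ trials")
  picks <- with_seed(seed, {
    unlist(lapply(unique(trials$complexity), function(cx) {
      pool <- which(is_csp & trials$complexity == cx)
      n_flag <- round(rate * length(pool))
      if (n_flag > 0) sample(pool, n_flag) else integer(0)
    }))
  })
  trials$reinforced[picks] <- TRUE
  design$trials <- trials
  design
}

#' @export
print.fc_design <- function(x, ...) {
  t <- x$trials
  cat("<fc_design> ", nrow(t), " trials, ", x$params$n_blocks, " blocks (",
      x$params$trials_per_block, " trials each)\n", sep = "")
  cat("  contexts: ", paste(unique(t$context[!duplicated(t$block)]), collapse = ", "),
      " (alternating)\n", sep = "")
  cat("  per-stimulus counts: ", paste(unique(table(t$stimulus)), collapse = ", "),
      "; reinforced CS+: ", sum(t$reinforced), "\n", sep = "")
  invisible(x)
}

#' Write a design as a BIDS-style events table
#'
#' Columns: `onset`, `duration`, `trial_type`, `block`, `context`,
#' `complexity`, `reinforced` (tab-separated, one row per trial).
#'
#' @param design An `"fc_design"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(design, path) {
  stopifnot(inherits(design, "fc_design"))
  t <- design$trials
  out <- data.frame(onset = t$onset, duration = t$duration,
                    trial_type = t$stimulus, block = t$block,
                    context = t$context, complexity = t$complexity,
                    reinforced = as.integer(t$reinforced))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events table back into a trial table
#'
#' Inverse of [write_events_tsv()]: reconstructs the chronological trial
#' `data.frame` (pair roles and required responses are recovered from the
#' `trial_type` labels). The returned object carries no generator
#' parameters.
#'
#' @param path Events TSV path.
#' @return An `"fc_design"` object with `params = NULL`.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type", "block", "context", "complexity", "reinforced")
  check_param(all(need %in% names(ev)),
              paste("events table must have columns:", paste(need, collapse = ", ")))
  ev <- ev[order(ev$onset), ]
  label <- sub("_[^_]+$", "", ev$trial_type)
  pair_role <- ifelse(label %in% c("CS-", "NS1"), "S1", "S2")
  trials <- data.frame(
    index = seq_len(nrow(ev)) - 1L, block = ev$block, context = ev$context,
    complexity = ev$complexity, pair_role = pair_role, label = label,
    stimulus = ev$trial_type, onset = ev$onset, duration = ev$duration,
    iti_after = c(diff(ev$onset) - ev$duration[-nrow(ev)], NA),
    reinforced = as.logical(ev$reinforced),
    required_response = ifelse(pair_role == "S1", "key1", "key2"),
    stringsAsFactors = FALSE
  )
  structure(list(trials = trials, params = NULL), class = "fc_design")
}
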