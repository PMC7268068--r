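# End-to-end simulation-and-analysis pipeline: design -> patterns (betas
# or time series + GLM) -> per-condition decoding with permutation chance
# -> cross-decoding -> group factorial inference. One master seed spawns
# per-participant and per-stage child seeds, so any stage can be rerun in
# isolation.

#' Pipeline configuration
#'
#' Bundles and validates all stage parameters. Per-participant trial
#' orders are used by default (`fixed_order = TRUE` reuses one order for
#' everyone, as in a fixed-sequence study protocol).
#'
#' @param n_participants Number of simulated participants (>= 1).
#' @param design A [design_params()] object (its seed is re-derived per
#'   participant unless `fixed_order = TRUE`).
#' @param synth A [synth_params()] object (its seed is re-derived per
#'   participant and hemisphere).
#' @param mode `"beta"` (simulate trial patterns directly) or
#'   `"timeseries"` (simulate BOLD series and re-estimate betas by GLM).
#' @param tr Repetition time for time-series mode, seconds.
#' @param highpass_cutoff High-pass cutoff for the GLM, seconds.
#' @param n_perm Label permutations per condition.
#' @param n_subsample_reps Neutral-pair subsample repetitions.
#' @param cost SVM cost parameter.
#' @param hemispheres Hemisphere labels; each gets an independent voxel
#'   set with shared synthesis parameters.
#' @param fixed_order Logical; reuse one trial order for all participants.
#' @param run_cross_decoding Logical; also run [cross_decode()].
#' @param seed Master integer seed.
#' @param out_dir Optional directory for TSV outputs.
#' @return A validated list of class `"fc_config"`.
#' @export
run_config <- function(n_participants = 20L,
                       design = design_params(),
                       synth = synth_params(),
                       mode = c("beta", "timeseries"),
                       tr = 2.5, highpass_cutoff = 128,
                       n_perm = 1000L, n_subsample_reps = 100L, cost = 1,
                       hemispheres = c("left", "right"),
                       fixed_order = FALSE,
                       run_cross_decoding = TRUE,
                       seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  problems <- character(0)
  if (!(is.numeric(n_participants) && n_participants >= 1))
    problems <- c(problems, "n_participants must be >= 1")
  if (!inherits(design, "fc_design_params"))
    problems <- c(problems, "design must be a design_params() object")
  if (!inherits(synth, "fc_synth_params"))
    problems <- c(problems, "synth must be a synth_params() object")
  if (!(n_perm >= 1)) problems <- c(problems, "n_perm must be >= 1")
  if (!(n_subsample_reps >= 1)) problems <- c(problems, "n_subsample_reps must be >= 1")
  if (!(tr > 0)) problems <- c(problems, "tr must be > 0")
  if (!(cost > 0)) problems <- c(problems, "cost must be > 0")
  if (length(hemispheres) < 1) problems <- c(problems, "need at least one hemisphere")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  structure(list(n_participants = as.integer(n_participants), design = design,
                 synth = synth, mode = mode, tr = tr,
                 highpass_cutoff = highpass_cutoff,
                 n_perm = as.integer(n_perm),
                 n_subsample_reps = as.integer(n_subsample_reps), cost = cost,
                 hemispheres = hemispheres, fixed_order = fixed_order,
                 run_cross_decoding = run_cross_decoding,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "fc_config")
}

#' Simulate and decode one participant
#'
#' Generates (or reuses) a design, simulates each hemisphere's voxel data,
#' estimates betas via the GLM in time-series mode, and runs the
#' four-condition decoding with permutation chance, plus optional
#' cross-decoding.
#'
#' @param config An `"fc_config"`.
#' @param participant Participant index (1-based).
#' @param design Optional pre-built design (used when `fixed_order`).
#' @return A list: `accuracy` (rows per context x complexity x hemisphere),
#'   `cross` (cross-decoding rows or `NULL`), `design`.
#' @export
simulate_participant <- function(config, participant, design = NULL) {
  stopifnot(inherits(config, "fc_config"))
  p_seed <- spawn_seeds(config$seed, config$n_participants + 1L)[participant]
  stage_seeds <- spawn_seeds(p_seed, 2L + 3L * length(config$hemispheres))
  if (is.null(design)) {
    dp <- config$design
    if (!config$fixed_order) dp$seed <- stage_seeds[1]
    design <- generate_design(dp)
  }
  acc <- list()
  cross <- list()
  for (h in seq_along(config$hemispheres)) {
    hemi <- config$hemispheres[h]
    sp <- config$synth
    sp$seed <- stage_seeds[2L + 3L * (h - 1L)]
    basis <- make_pattern_basis(sp)
    B <- if (config$mode == "beta") {
      simulate_betas(design, basis, sp)
    } else {
      Y <- simulate_timeseries(design, basis, sp, tr = config$tr)
      dm <- build_design_matrix(design, tr = config$tr,
                                highpass_cutoff = config$highpass_cutoff)
      estimate_trial_betas(Y, dm)
    }
    attr(B, "trials") <- design$trials
    res <- decode_all_conditions(B, n_perm = config$n_perm,
                                 n_subsample_reps = config$n_subsample_reps,
                                 seed = stage_seeds[3L + 3L * (h - 1L)],
                                 cost = config$cost)
    res$participant <- participant
    res$hemisphere <- hemi
    acc[[h]] <- res
    if (config$run_cross_decoding) {
      cd_seed <- stage_seeds[4L + 3L * (h - 1L)]
      cd_seeds <- spawn_seeds(cd_seed, 2L)
      cd <- rbind(
        cross_decode(B, context = "reinforcement", n_perm = config$n_perm,
                     seed = cd_seeds[1], cost = config$cost),
        cross_decode(B, context = "nonreinforcement", n_perm = config$n_perm,
                     seed = cd_seeds[2], cost = config$cost))
      cd$participant <- participant
      cd$hemisphere <- hemi
      cross[[h]] <- cd
    }
  }
  list(accuracy = do.call(rbind, acc),
       cross = if (length(cross)) do.call(rbind, cross) else NULL,
       design = design)
}

#' Run the full simulation-and-inference pipeline
#'
#' Simulates `n_participants` datasets, decodes every context x
#' complexity x hemisphere condition with its permutation chance level,
#' optionally cross-decodes across complexity, and fits the group-level
#' within-subject factorial model on excess accuracies. Per-participant
#' failures are isolated and reported rather than aborting the run.
#'
#' @param config An `"fc_config"` from [run_config()].
#' @return A list of class `"fc_pipeline_result"`: `accuracy` (per
#'   participant/condition table), `effects` (factorial effect table),
#'   `cross` and `cross_effects` (or `NULL`), `config`, `errors`
#'   (per-participant failure messages, if any). Tables are also written
#'   as TSVs to `config$out_dir` when set.
#' @export
#' @examples
#' cfg <- run_config(n_participants = 2, synth = synth_params(n_voxels = 30),
#'                   n_perm = 10, n_subsample_reps = 2,
#'                   run_cross_decoding = FALSE, seed = 7)
#' res <- run_pipeline(cfg)
#' head(res$accuracy)
run_pipeline <- function(config) {
  stopifnot(inherits(config, "fc_config"))
  shared_design <- if (config$fixed_order) generate_design(config$design) else NULL
  acc <- list(); cross <- list(); errors <- character(0)
  for (p in seq_len(config$n_participants)) {
    r <- tryCatch(simulate_participant(config, p, design = shared_design),
                  error = function(e) e)
    if (inherits(r, "error")) {
      errors <- c(errors, sprintf("participant %d: %s", p, conditionMessage(r)))
      next
    }
    acc[[length(acc) + 1L]] <- r$accuracy
    if (!is.null(r$cross)) cross[[length(cross) + 1L]] <- r$cross
  }
  if (!length(acc)) stop("all participants failed:\n", paste(errors, collapse = "\n"))
  accuracy <- do.call(rbind, acc)
  accuracy$value <- accuracy$excess_accuracy
  effects <- if (length(unique(accuracy$participant)) >= 2 &&
                 length(config$hemispheres) >= 2) {
    factorial_accuracy_model(accuracy)
  } else NULL
  cross_tab <- if (length(cross)) do.call(rbind, cross) else NULL
  cross_effects <- NULL
  if (!is.null(cross_tab) && length(unique(cross_tab$participant)) >= 2) {
    ctab <- cross_tab
    ctab$value <- ctab$excess_accuracy
    # collapse hemispheres by averaging for the context x direction model
    ctab <- stats::aggregate(value ~ participant + context + direction,
                             data = ctab, FUN = mean)
    cross_effects <- factorial_accuracy_model(ctab, factors = c("context", "direction"))
  }
  out <- structure(list(accuracy = accuracy, effects = effects,
                        cross = cross_tab, cross_effects = cross_effects,
                        config = config, errors = errors),
                   class = "fc_pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) if (!is.null(x))
      utils::write.table(x, file.path(config$out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wt(accuracy, "decoding_results.tsv")
    wt(effects, "factorial_effects.tsv")
    wt(cross_tab, "cross_decoding_results.tsv")
    wt(cross_effects, "cross_factorial_effects.tsv")
  }
  out
}

#' @export
print.fc_pipeline_result <- function(x, ...) {
  cat("<fc_pipeline_result> ", length(unique(x$accuracy$participant)),
      " participants, mode=", x$config$mode, ", seed=", x$config$seed, "\n", sep = "")
  agg <- stats::aggregate(excess_accuracy ~ context, data = x$accuracy, FUN = mean)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  mean excess accuracy (%s): %.3f\n",
                agg$context[i], agg$excess_accuracy[i]))
  if (!is.null(x$effects)) {
    cat("  factorial effects on excess accuracy:\n")
    print(x$effects, row.names = FALSE)
  }
  if (length(x$errors)) cat("  errors:", length(x$errors), "\n")
  invisible(x)
}
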