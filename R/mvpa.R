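# Core decoding analysis: per-voxel z-scoring, running-index threefold
# cross-validation with unequal class counts, linear SVM decoding,
# label-permutation chance with neutral-pair subsampling, excess accuracy,
# and cross-decoding across stimulus complexity.
#
# Class imbalance is intrinsic here: reinforced CS+ trials are excluded, so
# the reinforcement-context condition has 24 CS- but only 12 CS+ trials and
# a classifier biased to the majority class beats 50% on permuted labels.
# All chance levels are therefore taken from the empirical permutation
# null, never assumed to be 0.5.

#' Indices of trials retained for pattern analysis
#'
#' Reinforced trials are excluded from decoding to avoid contamination of
#' their response estimates by the unconditioned stimulus.
#'
#' @param trials A trial `data.frame` (from an `"fc_design"` or the
#'   `trials` attribute of a beta matrix).
#' @param context,complexity Optional filters.
#' @return Integer row indices into `trials`, in chronological order.
#' @export
retained_trials <- function(trials, context = NULL, complexity = NULL) {
  keep <- !trials$reinforced
  if (!is.null(context)) keep <- keep & trials$context == context
  if (!is.null(complexity)) keep <- keep & trials$complexity == complexity
  which(keep)
}

#' Z-score response estimates per voxel across trials
#'
#' Each voxel column is standardized to mean 0, sd 1 across all trials of
#' the input, before any fold split. Constant voxels are set to zero with a
#' warning.
#'
#' @param B Trials x voxels matrix.
#' @return Matrix of the same shape (attributes preserved).
#' @export
zscore_across_trials <- function(B) {
  check_param(nrow(B) >= 2, "need at least 2 trials to z-score")
  mu <- colMeans(B)
  sdv <- apply(B, 2, stats::sd)
  flat <- sdv == 0 | !is.finite(sdv)
  if (any(flat)) {
    warning(sum(flat), " zero-variance voxel(s) set to 0", call. = FALSE)
    sdv[flat] <- 1
  }
  Z <- sweep(sweep(B, 2, mu), 2, sdv, "/")
  Z[, flat] <- 0
  dimnames(Z) <- dimnames(B)
  for (a in c("trials", "spacing_mm"))
    if (!is.null(attr(B, a))) attr(Z, a) <- attr(B, a)
  Z
}

#' Running-index threefold cross-validation folds
#'
#' Within each stimulus class, trials are numbered 0, 1, 2, ... in
#' chronological order; the trial with running index i is tested in fold
#' `i mod 3` and used for training in the other two folds. Both training
#' and test data are thereby drawn from the whole duration of the
#' experiment, which matters when representations change over learning.
#'
#' @param labels Stimulus identity per retained trial, in chronological
#'   order.
#' @param n_folds Number of folds (3 by default).
#' @return List of `n_folds` lists with integer elements `train`, `test`.
#' @export
#' @examples
#' f <- make_running_index_folds(rep(c("a", "b"), each = 6))
#' f[[1]]$test  # every third trial of each class
make_running_index_folds <- function(labels, n_folds = 3L) {
  n <- length(labels)
  counts <- table(labels)
  if (any(counts < n_folds))
    stop("every stimulus needs at least ", n_folds, " trials; got ",
         paste(names(counts)[counts < n_folds], collapse = ", "), call. = FALSE)
  run_idx <- integer(n)
  for (lv in names(counts)) {
    at <- which(labels == lv)
    run_idx[at] <- seq_along(at) - 1L
  }
  fold_of <- run_idx %% n_folds
  lapply(seq_len(n_folds) - 1L, function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

# Linear SVM fit/predict for one fold. Decision values exactly 0 are
# resolved to the training-majority class (deterministic tie rule).
svm_fold_predict <- function(xtr, ytr, xte, cost = 1) {
  ytr <- factor(ytr)
  if (nlevels(droplevels(ytr)) < 2)
    stop("training data contain a single class; cannot fit a classifier",
         call. = FALSE)
  m <- e1071::svm(xtr, ytr, kernel = "linear", cost = cost, scale = FALSE)
  p <- stats::predict(m, xte, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  classes <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  majority <- names(which.max(table(ytr)))
  out <- ifelse(dv[, 1] > 0, classes[1], classes[2])
  out[dv[, 1] == 0] <- majority
  out
}

#' Cross-validated decoding accuracy for one task condition
#'
#' Fits a linear support-vector classifier (cost 1, no class weighting) on
#' each fold's training rows and pools test predictions across folds.
#'
#' @param B Trials x voxels matrix (z-scored).
#' @param labels Binary class labels per row of `B`.
#' @param folds Fold list from [make_running_index_folds()].
#' @param cost SVM cost parameter.
#' @return Pooled fraction of correct test predictions, in `[0, 1]`.
#' @export
decode_condition <- function(B, labels, folds, cost = 1) {
  check_param(length(unique(labels)) == 2, "labels must be binary")
  check_param(length(labels) == nrow(B), "labels must match rows of B")
  correct <- 0L
  total <- 0L
  for (f in folds) {
    pred <- svm_fold_predict(B[f$train, , drop = FALSE], labels[f$train],
                             B[f$test, , drop = FALSE], cost)
    correct <- correct + sum(pred == labels[f$test])
    total <- total + length(f$test)
  }
  correct / total
}

#' Subsample neutral-pair trials to mirror the CS class imbalance
#'
#' In the nonreinforcement context all trials are usable (no US), giving
#' balanced classes; to make neutral-pair decoding structurally analogous
#' to the CS condition, half the trials of one randomly selected class are
#' removed.
#'
#' @param labels NS class labels in chronological order (two classes).
#' @param seed Integer seed for the class choice and trial draw.
#' @param remove_n Number of trials to remove; default half the selected
#'   class's count; 0 returns all indices unchanged.
#' @return Sorted integer indices of retained trials.
#' @export
#' @examples
#' idx <- subsample_ns(rep(c("NS1", "NS2"), 24), seed = 7)
#' table(rep(c("NS1", "NS2"), 24)[idx])  # counts {24, 12}
subsample_ns <- function(labels, seed, remove_n = NULL) {
  classes <- unique(labels)
  check_param(length(classes) == 2, "labels must have exactly two classes")
  with_seed(seed, {
    victim <- sample(classes, 1)
    pool <- which(labels == victim)
    if (is.null(remove_n)) remove_n <- length(pool) %/% 2L
    check_param(remove_n <= length(pool), "`remove_n` exceeds class count")
    if (remove_n == 0) {
      seq_along(labels)
    } else {
      drop <- sample(pool, remove_n)
      sort(setdiff(seq_along(labels), drop))
    }
  })
}

#' Empirical chance level by label permutation
#'
#' Permutes the class labels over the retained trials (preserving the label
#' multiset), recomputes running-index folds on the permuted labels, and
#' reruns the identical decoding procedure. For subsampled (neutral-pair)
#' conditions, each permutation is averaged over fresh subsamples. With
#' unequal class counts the resulting chance mean generally exceeds 0.5,
#' which is why it is estimated rather than assumed.
#'
#' @param B Trials x voxels matrix of the condition's full trial set
#'   (z-scored; for NS conditions, before subsampling).
#' @param labels Class labels per row of `B`.
#' @param n_perm Number of label permutations (>= 1).
#' @param seed Integer seed; the null is deterministic given it.
#' @param subsample Logical; apply [subsample_ns()] within each permutation.
#' @param n_subsample_reps Subsample repetitions averaged per permutation
#'   when `subsample = TRUE`.
#' @param remove_n Passed to [subsample_ns()].
#' @param cost SVM cost parameter.
#' @return List: `chance_mean`, `chance_sd`, `null` (length `n_perm`).
#' @export
permutation_chance <- function(B, labels, n_perm = 1000L, seed = 1L,
                               subsample = FALSE, n_subsample_reps = 100L,
                               remove_n = NULL, cost = 1) {
  check_param(n_perm >= 1, "`n_perm` must be >= 1")
  seeds <- spawn_seeds(seed, n_perm)
  null <- vapply(seq_len(n_perm), function(p) {
    with_seed(seeds[p], {
      if (subsample) {
        mean(vapply(seq_len(n_subsample_reps), function(r) {
          idx <- subsample_ns(labels, seed = sample.int(.Machine$integer.max - 1L, 1),
                              remove_n = remove_n)
          lab <- sample(labels[idx])
          decode_condition(B[idx, , drop = FALSE], lab,
                           make_running_index_folds(lab), cost)
        }, numeric(1)))
      } else {
        lab <- sample(labels)
        decode_condition(B, lab, make_running_index_folds(lab), cost)
      }
    })
  }, numeric(1))
  list(chance_mean = mean(null), chance_sd = stats::sd(null), null = null)
}

#' Decode one task condition with its permutation chance level
#'
#' Runs the full single-condition procedure: (optional) neutral-pair
#' subsampling, running-index folds, linear-SVM decoding, and the
#' label-permutation null, returning raw accuracy, chance statistics and
#' excess accuracy (raw minus chance mean).
#'
#' @param B Trials x voxels matrix of the condition's retained trials,
#'   chronological order, already z-scored.
#' @param labels Class labels per row of `B`.
#' @param n_perm Permutations for the chance estimate.
#' @param seed Integer seed.
#' @param subsample Apply neutral-pair subsampling (for NS conditions).
#' @param n_subsample_reps Subsample repetitions per permutation; the raw
#'   accuracy is averaged over the same number of subsamples.
#' @param remove_n Passed to [subsample_ns()].
#' @param cost SVM cost parameter.
#' @return A one-row `data.frame`: `raw_accuracy`, `chance_mean`,
#'   `chance_sd`, `excess_accuracy`, plus attribute `"null"` holding the
#'   permutation distribution.
#' @export
decode_with_chance <- function(B, labels, n_perm = 1000L, seed = 1L,
                               subsample = FALSE, n_subsample_reps = 100L,
                               remove_n = NULL, cost = 1) {
  seeds <- spawn_seeds(seed, 2L)
  raw <- if (subsample) {
    rep_seeds <- spawn_seeds(seeds[1], n_subsample_reps)
    mean(vapply(rep_seeds, function(s) {
      idx <- subsample_ns(labels, seed = s, remove_n = remove_n)
      lab <- labels[idx]
      decode_condition(B[idx, , drop = FALSE], lab,
                       make_running_index_folds(lab), cost)
    }, numeric(1)))
  } else {
    decode_condition(B, labels, make_running_index_folds(labels), cost)
  }
  ch <- permutation_chance(B, labels, n_perm = n_perm, seed = seeds[2],
                           subsample = subsample,
                           n_subsample_reps = n_subsample_reps,
                           remove_n = remove_n, cost = cost)
  out <- data.frame(raw_accuracy = raw, chance_mean = ch$chance_mean,
                    chance_sd = ch$chance_sd,
                    excess_accuracy = raw - ch$chance_mean)
  attr(out, "null") <- ch$null
  out
}

#' Excess accuracy: raw accuracy minus the permutation chance mean
#'
#' @param raw_accuracy Cross-validated accuracy with correct labels.
#' @param chance_mean Mean accuracy over label permutations computed on the
#'   identical trial set.
#' @return `raw_accuracy - chance_mean`.
#' @export
excess_accuracy <- function(raw_accuracy, chance_mean) {
  check_param(all(raw_accuracy >= 0 & raw_accuracy <= 1), "accuracy must be in [0,1]")
  raw_accuracy - chance_mean
}

#' Decode all four task conditions of one dataset
#'
#' Z-scores the retained trials once per voxel, then decodes the stimulus
#' pair within each context x complexity condition. Reinforcement-context
#' conditions use the imbalanced retained set (all CS- plus unreinforced
#' CS+); nonreinforcement conditions use subsampling to mirror that
#' imbalance.
#'
#' @param B Trials x voxels beta matrix carrying a `trials` attribute
#'   (from [simulate_betas()] or [estimate_trial_betas()]), or a plain
#'   matrix with `trials` supplied.
#' @param trials Trial table if not attached to `B`.
#' @param n_perm Permutations per condition.
#' @param n_subsample_reps Neutral-pair subsample repetitions.
#' @param seed Integer seed.
#' @param cost SVM cost parameter.
#' @return A `data.frame` with one row per condition: `context`,
#'   `complexity`, `raw_accuracy`, `chance_mean`, `chance_sd`,
#'   `excess_accuracy`.
#' @export
decode_all_conditions <- function(B, trials = attr(B, "trials"),
                                  n_perm = 1000L, n_subsample_reps = 100L,
                                  seed = 1L, cost = 1) {
  check_param(!is.null(trials), "`trials` metadata is required")
  keep <- retained_trials(trials)
  Z <- zscore_across_trials(B[keep, , drop = FALSE])
  t_keep <- trials[keep, ]
  conds <- expand.grid(context = c("reinforcement", "nonreinforcement"),
                       complexity = c("simple", "complex"),
                       stringsAsFactors = FALSE)
  seeds <- spawn_seeds(seed, nrow(conds))
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    sel <- t_keep$context == conds$context[i] & t_keep$complexity == conds$complexity[i]
    res <- decode_with_chance(Z[sel, , drop = FALSE], t_keep$label[sel],
                              n_perm = n_perm, seed = seeds[i],
                              subsample = conds$context[i] == "nonreinforcement",
                              n_subsample_reps = n_subsample_reps, cost = cost)
    cbind(conds[i, ], res, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Cross-decoding across stimulus complexity
#'
#' Trains on all retained trials of one complexity and tests on all of the
#' other, within a context, probing whether the same patterns separate the
#' pair for both stimulus families. For the reinforcement context the
#' labels are CS+/CS-; for the nonreinforcement control the NS are labeled
#' by their required key press, so that any motor-response contribution is
#' matched between contexts. Train and test sets are disjoint by
#' construction, so no cross-validation folds are used; chance is estimated
#' by permuting labels independently within the training and test sets.
#'
#' @param B Trials x voxels beta matrix with `trials` attribute (all
#'   trials; retained ones are selected internally).
#' @param trials Trial table if not attached to `B`.
#' @param context `"reinforcement"` (CS) or `"nonreinforcement"`
#'   (response-matched NS control).
#' @param n_perm Permutations for each direction's chance estimate.
#' @param seed Integer seed.
#' @param cost SVM cost parameter.
#' @return A `data.frame` with one row per direction
#'   (`simple_to_complex`, `complex_to_simple`): `context`, `direction`,
#'   `raw_accuracy`, `chance_mean`, `chance_sd`, `excess_accuracy`.
#' @export
cross_decode <- function(B, trials = attr(B, "trials"),
                         context = c("reinforcement", "nonreinforcement"),
                         n_perm = 1000L, seed = 1L, cost = 1) {
  context <- match.arg(context)
  check_param(!is.null(trials), "`trials` metadata is required")
  keep_all <- retained_trials(trials)
  Z_all <- zscore_across_trials(B[keep_all, , drop = FALSE])
  t_all <- trials[keep_all, ]
  sel <- t_all$context == context
  Z <- Z_all[sel, , drop = FALSE]
  t_keep <- t_all[sel, ]
  check_param(all(c("simple", "complex") %in% t_keep$complexity),
              "both complexity conditions must be present")
  labels <- if (context == "reinforcement") t_keep$label else t_keep$required_response

  one_direction <- function(train_cx, test_cx, seed) {
    tr <- which(t_keep$complexity == train_cx)
    te <- which(t_keep$complexity == test_cx)
    pred <- svm_fold_predict(Z[tr, , drop = FALSE], labels[tr],
                             Z[te, , drop = FALSE], cost)
    raw <- mean(pred == labels[te])
    perm_seeds <- spawn_seeds(seed, n_perm)
    null <- vapply(perm_seeds, function(s) with_seed(s, {
      lab_tr <- sample(labels[tr])
      lab_te <- sample(labels[te])
      mean(svm_fold_predict(Z[tr, , drop = FALSE], lab_tr,
                            Z[te, , drop = FALSE], cost) == lab_te)
    }), numeric(1))
    data.frame(context = context,
               direction = paste0(train_cx, "_to_", test_cx),
               raw_accuracy = raw, chance_mean = mean(null),
               chance_sd = stats::sd(null),
               excess_accuracy = raw - mean(null))
  }
  seeds <- spawn_seeds(seed, 2L)
  rbind(one_direction("simple", "complex", seeds[1]),
        one_direction("complex", "simple", seeds[2]))
}
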