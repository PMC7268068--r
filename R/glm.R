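# Beta-series GLM: one regressor per trial, HRF-convolved unit sticks,
# per-run US regressors, discrete-cosine high-pass drift, ordinary least
# squares per voxel.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak minus a scaled
#' undershoot), the standard canonical HRF parameterization: delays 6 and
#' 16 s, unit dispersions, undershoot ratio 1/6, 32 s support. The kernel
#' is normalized to unit peak and is exactly 0 at t = 0.
#'
#' @param dt Sampling step in seconds (0 < dt <= 1); convolution is done at
#'   this microtime resolution before resampling to scan times.
#' @param peak_delay,undershoot_delay Gamma delays in seconds.
#' @param peak_disp,undershoot_disp Gamma dispersions.
#' @param ratio Peak-to-undershoot amplitude ratio (undershoot weight is
#'   `1/ratio`; `Inf` gives a pure, everywhere-nonnegative gamma response).
#' @param duration Kernel support in seconds.
#' @return A list of class `"fc_hrf"`: `dt`, `values` (length
#'   `duration/dt`), `duration`.
#' @export
#' @examples
#' h <- canonical_hrf(0.1)
#' h$values[1]                       # 0 at onset
#' (which.max(h$values) - 1) * h$dt  # peak near 5 s
canonical_hrf <- function(dt, peak_delay = 6, undershoot_delay = 16,
                          peak_disp = 1, undershoot_disp = 1,
                          ratio = 6, duration = 32) {
  check_param(dt > 0 && dt <= 1, "`dt` must be in (0, 1]")
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp)
  if (is.finite(ratio) && ratio > 0)
    h <- h - stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                           scale = undershoot_disp) / ratio
  h <- h / max(h)
  structure(list(dt = dt, values = h, duration = duration), class = "fc_hrf")
}

# Convolved unit-stick regressors for a set of event onsets: sticks are
# placed on a microtime grid at resolution hrf$dt, convolved with the
# kernel, then sampled at scan acquisition times 0, tr, 2*tr, ...
# Returns an n_scans x length(onsets) matrix.
trial_regressors <- function(onsets, tr, n_scans, hrf) {
  dt <- hrf$dt
  n_fine <- ceiling((n_scans - 1) * tr / dt) + length(hrf$values) + 1L
  scan_fine_idx <- round((seq_len(n_scans) - 1) * tr / dt) + 1L
  k <- length(hrf$values)
  out <- matrix(0, n_scans, length(onsets))
  for (j in seq_along(onsets)) {
    fine <- numeric(n_fine)
    i0 <- round(onsets[j] / dt) + 1L
    span <- i0:(i0 + k - 1L)
    keep <- span <= n_fine
    fine[span[keep]] <- fine[span[keep]] + hrf$values[keep]
    out[, j] <- fine[scan_fine_idx]
  }
  out
}

#' Discrete-cosine high-pass drift basis
#'
#' Cosine regressors spanning fluctuations slower than the cutoff period,
#' including the constant. The number of columns is
#' `floor(2 * duration / cutoff) + 1`.
#'
#' @param n_scans Number of scans.
#' @param tr Repetition time in seconds.
#' @param cutoff High-pass cutoff period in seconds.
#' @return An n_scans x K matrix with orthonormal columns.
#' @export
dct_drift_basis <- function(n_scans, tr, cutoff = 128) {
  check_param(cutoff > 0, "`cutoff` must be > 0")
  duration <- n_scans * tr
  K <- floor(2 * duration / cutoff) + 1L
  s <- seq_len(n_scans)
  X <- vapply(seq_len(K) - 1L, function(k) {
    col <- cos(pi * (2 * s - 1) * k / (2 * n_scans))
    col / sqrt(sum(col^2))
  }, numeric(n_scans))
  colnames(X) <- paste0("drift_", seq_len(K) - 1L)
  X
}

#' Build the single-trial design matrix
#'
#' One HRF-convolved unit-stick regressor per trial, one US regressor per
#' run (sticks at the US times of all reinforced trials of that run,
#' convolved with the same kernel), and discrete-cosine drift columns up to
#' the high-pass cutoff.
#'
#' @param design An `"fc_design"` object.
#' @param tr Repetition time in seconds.
#' @param n_scans Number of scans; default covers the last trial plus the
#'   HRF support.
#' @param hrf Kernel from [canonical_hrf()]; default microtime `tr/16`.
#' @param highpass_cutoff High-pass cutoff period in seconds (`Inf` keeps
#'   only the constant).
#' @param runs Integer vector mapping each block to a run for the US
#'   regressors; default one run per block-pair (`ceiling(block / 2)`).
#' @param us_delay US onset relative to trial onset in seconds; default the
#'   stimulus duration (US at sound offset).
#' @return A list of class `"fc_design_matrix"`: `X` (scans x columns,
#'   named `trial_<index>`, `us_run<r>`, `drift_<k>`), `trial_cols`,
#'   `tr`, `n_scans`.
#' @export
build_design_matrix <- function(design, tr = 2.5, n_scans = NULL,
                                hrf = canonical_hrf(tr / 16),
                                highpass_cutoff = 128,
                                runs = NULL, us_delay = NULL) {
  stopifnot(inherits(design, "fc_design"), inherits(hrf, "fc_hrf"))
  t <- design$trials
  if (is.null(n_scans))
    n_scans <- ceiling((max(t$onset) + t$duration[nrow(t)] + hrf$duration) / tr)
  late <- which(t$onset > (n_scans - 1) * tr)
  if (length(late))
    stop("trial ", t$index[late[1]], " has onset ", t$onset[late[1]],
         " s, beyond the scan window", call. = FALSE)
  Xt <- trial_regressors(t$onset, tr, n_scans, hrf)
  colnames(Xt) <- sprintf("trial_%04d", t$index)

  if (is.null(runs)) runs <- ceiling(seq_len(max(t$block)) / 2)
  if (is.null(us_delay)) us_delay <- t$duration[1]
  run_of_trial <- runs[t$block]
  Xus <- vapply(sort(unique(runs)), function(r) {
    ons <- t$onset[t$reinforced & run_of_trial == r] + us_delay
    if (!length(ons)) return(numeric(n_scans))
    rowSums(trial_regressors(ons, tr, n_scans, hrf))
  }, numeric(n_scans))
  colnames(Xus) <- paste0("us_run", sort(unique(runs)))

  Xd <- if (is.finite(highpass_cutoff)) dct_drift_basis(n_scans, tr, highpass_cutoff)
        else dct_drift_basis(n_scans, tr, 2 * n_scans * tr + 1)
  X <- cbind(Xt, Xus, Xd)
  structure(list(X = X, trial_cols = colnames(Xt), tr = tr, n_scans = n_scans),
            class = "fc_design_matrix")
}

#' Estimate single-trial response amplitudes by ordinary least squares
#'
#' Fits the full design matrix per voxel via the minimum-norm pseudoinverse
#' and returns the trial coefficients only, ordered as the design. Betas
#' from reinforced trials are estimated like any others; downstream
#' analyses exclude them (see [retained_trials()]).
#'
#' @param Y Scans x voxels data matrix (e.g. from [simulate_timeseries()]).
#' @param dm An `"fc_design_matrix"` from [build_design_matrix()].
#' @return Trials x voxels matrix of amplitude estimates, row names the
#'   trial columns' indices; carries the `trials` attribute of `Y` if
#'   present.
#' @export
estimate_trial_betas <- function(Y, dm) {
  stopifnot(inherits(dm, "fc_design_matrix"))
  Y <- as.matrix(Y)
  X <- dm$X
  check_param(nrow(Y) == nrow(X), "rows of Y and the design matrix must match")
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  if (!all(pos))
    warning("design matrix is rank deficient (rank ", sum(pos), " of ",
            ncol(X), "); minimum-norm solution returned", call. = FALSE)
  # pinv(X) %*% Y without forming pinv explicitly
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
  rownames(coef) <- colnames(X)
  B <- coef[dm$trial_cols, , drop = FALSE]
  rownames(B) <- as.character(as.integer(sub("^trial_", "", dm$trial_cols)))
  colnames(B) <- colnames(Y)
  if (!is.null(attr(Y, "trials"))) attr(B, "trials") <- attr(Y, "trials")
  B
}
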