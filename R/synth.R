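# Ground-truth voxel patterns and synthetic trial-wise data.
#
# Each stimulus pair (context x complexity) is separated by a "physical
# stimulus" pattern component; the CS pair in the reinforcement context can
# additionally be separated by a "threat association" component, encoding
# the hypothesis that conditioned threat is represented over and above the
# physical stimulus difference. Components are signed: the two members of a
# pair sit at +/- the component direction, so every pair is separated by
# exactly twice the component norm and CS and NS pairs are exchangeable
# whenever the threat amplitude is zero.

#' Parameters of the synthetic pattern generator
#'
#' @param n_voxels Number of voxels per simulated region (>= 2).
#' @param stimulus_amp Norm of each pair's physical-stimulus component;
#'   either a scalar or a length-2 vector `c(simple, complex)`. The default
#'   gives the simple pairs a larger physical separation than the complex
#'   pairs, so simple sounds decode better — the qualitative complexity
#'   effect the simulation is meant to reproduce.
#' @param threat_amp Norm of the threat-association component added (with
#'   opposite signs) to CS+ and CS- mean patterns; 0 makes CS and NS pairs
#'   statistically exchangeable.
#' @param noise_sd Standard deviation of i.i.d. Gaussian trial/voxel noise.
#' @param basis_mode `"gaussian_random"` (independent Gaussian directions)
#'   or `"orthogonal"` (mutually orthogonal component directions).
#' @param shared_threat Logical; if `TRUE` (default) the same threat
#'   component separates the simple and the complex CS pair, so threat
#'   encoding is stimulus-invariant and cross-decodable. If `FALSE` each
#'   complexity gets an independent threat component.
#' @param baseline Scalar baseline added to every mean pattern.
#' @param spacing_mm Voxel spacing of the simulated grid (isotropic, mm).
#' @param seed Integer seed.
#' @return A list of class `"fc_synth_params"`.
#' @export
synth_params <- function(n_voxels = 200L, stimulus_amp = c(simple = 1.3, complex = 0.8),
                         threat_amp = 1.5,
                         noise_sd = 2, basis_mode = c("gaussian_random", "orthogonal"),
                         shared_threat = TRUE, baseline = 0,
                         spacing_mm = 1.5, seed = 1L) {
  basis_mode <- match.arg(basis_mode)
  check_param(n_voxels >= 2, "`n_voxels` must be >= 2")
  check_param(length(stimulus_amp) %in% c(1L, 2L),
              "`stimulus_amp` must have length 1 or 2 (simple, complex)")
  if (length(stimulus_amp) == 1L) stimulus_amp <- rep(stimulus_amp, 2)
  stimulus_amp <- stats::setNames(as.numeric(stimulus_amp), c("simple", "complex"))
  check_param(all(stimulus_amp >= 0) && threat_amp >= 0, "amplitudes must be >= 0")
  check_param(noise_sd >= 0, "`noise_sd` must be >= 0")
  structure(list(n_voxels = as.integer(n_voxels), stimulus_amp = stimulus_amp,
                 threat_amp = threat_amp, noise_sd = noise_sd,
                 basis_mode = basis_mode, shared_threat = shared_threat,
                 baseline = baseline, spacing_mm = spacing_mm,
                 seed = as.integer(seed)),
            class = "fc_synth_params")
}

# Unit-norm component directions: independent Gaussian or columns of a QR
# orthonormalization of a Gaussian matrix.
component_directions <- function(n_voxels, n_comp, mode) {
  if (mode == "orthogonal") {
    check_param(n_voxels >= n_comp,
                "orthogonal mode needs `n_voxels` >= number of components")
    q <- qr.Q(qr(matrix(stats::rnorm(n_voxels * n_comp), n_voxels, n_comp)))
    lapply(seq_len(n_comp), function(j) q[, j])
  } else {
    lapply(seq_len(n_comp), function(j) {
      v <- stats::rnorm(n_voxels)
      v / sqrt(sum(v^2))
    })
  }
}

#' Build the ground-truth pattern basis
#'
#' Draws one physical-stimulus direction per stimulus pair (4 pairs:
#' context x complexity) and one threat direction per complexity (or a
#' single shared one, see `shared_threat`), each scaled to its amplitude
#' parameter. The mean pattern of a stimulus is
#' `baseline + role_sign * stimulus_component` plus, for the CS pair only,
#' `threat_sign * threat_component` (CS+ positive, CS- negative).
#'
#' @param params A [synth_params()] object.
#' @return A list of class `"fc_basis"`: `means` (8 x n_voxels matrix, rows
#'   named by stimulus identity), `stimulus_components` and
#'   `threat_components` (stored separately), and `params`.
#' @export
#' @examples
#' b <- make_pattern_basis(synth_params(n_voxels = 50, seed = 2))
#' rownames(b$means)
make_pattern_basis <- function(params) {
  stopifnot(inherits(params, "fc_synth_params"))
  pairs <- expand.grid(context = c("reinforcement", "nonreinforcement"),
                       complexity = c("simple", "complex"),
                       stringsAsFactors = FALSE)
  n_threat <- if (params$shared_threat) 1L else 2L
  dirs <- with_seed(params$seed,
                    component_directions(params$n_voxels, nrow(pairs) + n_threat,
                                         params$basis_mode))
  stim_comp <- lapply(seq_len(nrow(pairs)), function(i)
    params$stimulus_amp[[pairs$complexity[i]]] * dirs[[i]])
  names(stim_comp) <- paste(pairs$context, pairs$complexity, sep = "_")
  threat_dirs <- dirs[nrow(pairs) + seq_len(n_threat)]
  threat_comp <- if (params$shared_threat) {
    list(simple = params$threat_amp * threat_dirs[[1]],
         complex = params$threat_amp * threat_dirs[[1]])
  } else {
    list(simple = params$threat_amp * threat_dirs[[1]],
         complex = params$threat_amp * threat_dirs[[2]])
  }

  grid <- expand.grid(pair_role = c("S1", "S2"),
                      context = c("reinforcement", "nonreinforcement"),
                      complexity = c("simple", "complex"),
                      stringsAsFactors = FALSE)
  grid$label <- stimulus_label(grid$context, grid$pair_role)
  grid$stimulus <- paste(grid$label, grid$complexity, sep = "_")
  means <- t(vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    role_sign <- if (g$pair_role == "S1") 1 else -1
    m <- params$baseline + role_sign * stim_comp[[paste(g$context, g$complexity, sep = "_")]]
    if (g$context == "reinforcement") {
      threat_sign <- if (g$label == "CS+") 1 else -1
      m <- m + threat_sign * threat_comp[[g$complexity]]
    }
    m
  }, numeric(params$n_voxels)))
  rownames(means) <- grid$stimulus
  structure(list(means = means, stimulus_components = stim_comp,
                 threat_components = threat_comp, params = params),
            class = "fc_basis")
}

#' Voxel coordinates of a compact simulated region
#'
#' Arranges `n_voxels` on an integer grid filling a near-cubic cuboid, the
#' default geometry of a simulated region of interest.
#'
#' @param n_voxels Number of voxels.
#' @return Integer matrix (n_voxels x 3) of grid coordinates, 1-based.
#' @export
cuboid_coords <- function(n_voxels) {
  side <- ceiling(n_voxels^(1 / 3))
  g <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
  as.matrix(g[seq_len(n_voxels), , drop = FALSE])
}

#' Simulate trial-wise voxel-pattern estimates
#'
#' Each trial's row is its stimulus's ground-truth mean pattern plus
#' i.i.d. Gaussian noise, emulating single-trial response-amplitude
#' estimates.
#'
#' @param design An `"fc_design"` object.
#' @param basis An `"fc_basis"` from [make_pattern_basis()].
#' @param params The [synth_params()] (for `noise_sd`).
#' @param seed Seed for the noise draw (default: a child of `params$seed`).
#' @return A trials x voxels numeric matrix with attributes `trials` (the
#'   design's trial table) and `spacing_mm`; row names are trial indices,
#'   column names voxel ids.
#' @export
simulate_betas <- function(design, basis, params = basis$params,
                           seed = spawn_seeds(params$seed, 2L)[2]) {
  stopifnot(inherits(design, "fc_design"), inherits(basis, "fc_basis"))
  t <- design$trials
  check_param(all(t$stimulus %in% rownames(basis$means)),
              "design and basis use different stimulus sets")
  mu <- basis$means[t$stimulus, , drop = FALSE]
  noise <- with_seed(seed, matrix(stats::rnorm(length(mu), sd = params$noise_sd),
                                  nrow = nrow(mu)))
  B <- mu + noise
  dimnames(B) <- list(t$index, paste0("v", seq_len(ncol(B))))
  attr(B, "trials") <- t
  attr(B, "spacing_mm") <- params$spacing_mm
  B
}

#' Simulate voxel-wise BOLD time series from the design
#'
#' Per voxel, the signal is the sum over trials of the trial amplitude (the
#' stimulus's mean-pattern value at that voxel) times an HRF-convolved unit
#' stick at the trial onset, sampled on the scan grid, plus optional slow
#' sinusoidal drift and Gaussian (optionally AR(1)) noise. US events on
#' reinforced trials contribute through a separate amplitude.
#'
#' @param design An `"fc_design"` object.
#' @param basis An `"fc_basis"`.
#' @param params The [synth_params()].
#' @param tr Repetition time of the scan grid in seconds.
#' @param hrf HRF kernel from [canonical_hrf()]; default `canonical_hrf(tr / 16)`.
#' @param drift_amp Amplitude of an added sinusoidal drift (period
#'   `drift_period` s) shared by all voxels; 0 disables.
#' @param drift_period Drift period in seconds.
#' @param us_amp Amplitude of the US response added at reinforced-trial
#'   offsets, identical across voxels.
#' @param ar1 AR(1) coefficient of the temporal noise (0 = white).
#' @param seed Seed for the noise draw.
#' @return A scans x voxels matrix with attributes `tr`, `n_scans`,
#'   `trials`.
#' @export
simulate_timeseries <- function(design, basis, params = basis$params, tr = 2.5,
                                hrf = canonical_hrf(tr / 16),
                                drift_amp = 0, drift_period = 300,
                                us_amp = 0, ar1 = 0,
                                seed = spawn_seeds(params$seed, 2L)[2]) {
  stopifnot(inherits(design, "fc_design"), inherits(basis, "fc_basis"), tr > 0)
  t <- design$trials
  total_dur <- max(t$onset) + t$duration[nrow(t)] + hrf$duration
  n_scans <- ceiling(total_dur / tr)
  X <- trial_regressors(t$onset, tr, n_scans, hrf)
  A <- basis$means[t$stimulus, , drop = FALSE]     # trials x voxels amplitudes
  Y <- X %*% A
  if (us_amp != 0 && any(t$reinforced)) {
    us_reg <- rowSums(trial_regressors(t$onset[t$reinforced] + t$duration[t$reinforced],
                                       tr, n_scans, hrf))
    Y <- Y + us_amp * us_reg
  }
  if (drift_amp != 0) {
    scan_t <- (seq_len(n_scans) - 1) * tr
    Y <- Y + drift_amp * sin(2 * pi * scan_t / drift_period)
  }
  if (params$noise_sd > 0) {
    noise <- with_seed(seed, {
      e <- matrix(stats::rnorm(n_scans * ncol(Y), sd = params$noise_sd), n_scans)
      if (ar1 != 0) {
        e <- apply(e, 2, function(x) as.numeric(stats::filter(x, ar1, method = "recursive")))
        e <- e * sqrt(1 - ar1^2)  # keep marginal sd at noise_sd
      }
      e
    })
    Y <- Y + noise
  }
  dimnames(Y) <- list(NULL, paste0("v", seq_len(ncol(Y))))
  attr(Y, "tr") <- tr
  attr(Y, "n_scans") <- n_scans
  attr(Y, "trials") <- t
  Y
}
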