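test_that("pattern basis components have the requested geometry", {
  sp <- synth_params(n_voxels = 60, stimulus_amp = 2, threat_amp = 1.5, seed = 21)
  b <- make_pattern_basis(sp)

  # component norms equal their amplitude parameters
  for (comp in b$stimulus_components)
    expect_equal(sqrt(sum(comp^2)), 2)
  for (comp in b$threat_components)
    expect_equal(sqrt(sum(comp^2)), 1.5)

  # with threat_amp = 0, every pair is separated by exactly the same norm
  sp0 <- synth_params(n_voxels = 60, stimulus_amp = 2, threat_amp = 0, seed = 21)
  m <- make_pattern_basis(sp0)$means
  pair_sep <- c(
    sqrt(sum((m["CS+_simple", ] - m["CS-_simple", ])^2)),
    sqrt(sum((m["CS+_complex", ] - m["CS-_complex", ])^2)),
    sqrt(sum((m["NS2_simple", ] - m["NS1_simple", ])^2)),
    sqrt(sum((m["NS2_complex", ] - m["NS1_complex", ])^2)))
  expect_equal(pair_sep, rep(pair_sep[1], 4))

  # determinism in the seed
  expect_identical(make_pattern_basis(sp)$means, b$means)
})

test_that("orthogonal mode yields mutually orthogonal components", {
  sp <- synth_params(n_voxels = 40, basis_mode = "orthogonal",
                     shared_threat = FALSE, seed = 22)
  b <- make_pattern_basis(sp)
  comps <- c(b$stimulus_components,
             b$threat_components[!duplicated(b$threat_components)])
  for (i in seq_along(comps))
    for (j in seq_along(comps))
      if (i < j) expect_lt(abs(sum(comps[[i]] * comps[[j]])), 1e-10)

  expect_error(make_pattern_basis(synth_params(n_voxels = 3,
                                               basis_mode = "orthogonal")),
               "orthogonal")
})

test_that("random components are near-orthogonal at realistic voxel counts", {
  # |corr| of two independent Gaussian directions is O(1/sqrt(n))
  cors <- sapply(1:30, function(s) {
    b <- make_pattern_basis(synth_params(n_voxels = 500, seed = s))
    abs(stats::cor(b$stimulus_components[[1]], b$stimulus_components[[2]]))
  })
  expect_lt(mean(cors), 3 / sqrt(500))
})

test_that("simulated betas follow the generating model", {
  d <- default_design(seed = 2)
  sp0 <- synth_params(n_voxels = 25, noise_sd = 0, seed = 23)
  b0 <- make_pattern_basis(sp0)
  B0 <- simulate_betas(d, b0, sp0)
  expect_equal(bare(B0), bare(b0$means[d$trials$stimulus, ]))

  # with unit noise, per-condition sample means deviate ~ noise_sd/sqrt(24)
  sp1 <- synth_params(n_voxels = 400, stimulus_amp = 1, threat_amp = 0,
                      noise_sd = 1, seed = 24)
  b1 <- make_pattern_basis(sp1)
  B1 <- simulate_betas(d, b1, sp1)
  sel <- d$trials$stimulus == "NS1_simple"
  dev <- colMeans(B1[sel, ]) - b1$means["NS1_simple", ]
  se <- 1 / sqrt(sum(sel))
  expect_equal(stats::sd(dev), se, tolerance = 0.15)
  expect_lt(abs(mean(dev)), 4 * se / sqrt(400))
})

test_that("a dominant threat component makes CS trials perfectly separable", {
  d <- default_design(seed = 2)
  sp <- synth_params(n_voxels = 30, stimulus_amp = 0, threat_amp = 10,
                     noise_sd = 0.1, seed = 25)
  B <- simulate_betas(d, make_pattern_basis(sp), sp)
  keep <- retained_trials(d$trials, context = "reinforcement", complexity = "simple")
  Z <- zscore_across_trials(B[keep, ])
  lab <- d$trials$label[keep]
  acc <- decode_condition(Z, lab, make_running_index_folds(lab))
  expect_equal(acc, 1.0)
})

test_that("time-series simulation matches the HRF model", {
  # single trial, zero noise: the voxel time course is proportional to the
  # HRF sampled on the scan grid
  dp <- design_params(n_blocks = 2, trials_per_block = 4,
                      reinforcement_rate = 0, seed = 6)
  d <- generate_design(dp)
  d$trials <- d$trials[1, ]
  d$trials$onset <- 0
  sp <- synth_params(n_voxels = 3, noise_sd = 0, seed = 26)
  b <- make_pattern_basis(sp)
  tr <- 2.5
  hrf <- canonical_hrf(tr / 16)
  Y <- simulate_timeseries(d, b, sp, tr = tr, hrf = hrf)
  kernel_at_scans <- hrf$values[round((seq_len(nrow(Y)) - 1) * tr / hrf$dt) + 1]
  kernel_at_scans[is.na(kernel_at_scans)] <- 0
  amp <- b$means[d$trials$stimulus, 1]
  expect_equal(Y[, 1], amp * kernel_at_scans[seq_len(nrow(Y))], tolerance = 1e-12)
})

test_that("noiseless round-trip through the GLM recovers amplitudes", {
  d <- tiny_design(seed = 7)
  sp <- synth_params(n_voxels = 6, noise_sd = 0, seed = 27)
  b <- make_pattern_basis(sp)
  Y <- simulate_timeseries(d, b, sp, tr = 2.5)
  dm <- build_design_matrix(d, tr = 2.5)
  B <- estimate_trial_betas(Y, dm)
  expect_lt(max(abs(B - b$means[d$trials$stimulus, ])), 1e-6)
})

test_that("modelled drift improves recovery when data contain drift", {
  d <- tiny_design(seed = 8)
  sp <- synth_params(n_voxels = 4, noise_sd = 0, seed = 28)
  b <- make_pattern_basis(sp)
  # slow sinusoid inside the 128 s high-pass band
  Y <- simulate_timeseries(d, b, sp, tr = 2.5, drift_amp = 3, drift_period = 300)
  truth <- b$means[d$trials$stimulus, ]
  dm_hp <- build_design_matrix(d, tr = 2.5, highpass_cutoff = 128)
  dm_none <- build_design_matrix(d, tr = 2.5, highpass_cutoff = Inf)
  err_hp <- max(abs(estimate_trial_betas(Y, dm_hp) - truth))
  err_none <- max(abs(estimate_trial_betas(Y, dm_none) - truth))
  expect_lt(err_hp, err_none)
})

test_that("decoding accuracy is monotone in the signal amplitudes", {
  d <- default_design(seed = 2)
  acc_at <- function(stim_amp, threat_amp) {
    accs <- sapply(1:4, function(s) {
      sp <- synth_params(n_voxels = 30, stimulus_amp = stim_amp,
                         threat_amp = threat_amp, noise_sd = 2, seed = 30 + s)
      B <- simulate_betas(d, make_pattern_basis(sp), sp)
      keep <- retained_trials(d$trials, context = "reinforcement",
                              complexity = "simple")
      Z <- zscore_across_trials(B[keep, ])
      lab <- d$trials$label[keep]
      decode_condition(Z, lab, make_running_index_folds(lab))
    })
    mean(accs)
  }
  ladder_stim <- c(acc_at(0.2, 0), acc_at(1, 0), acc_at(4, 0))
  expect_true(all(diff(ladder_stim) >= 0))
  ladder_threat <- c(acc_at(0.5, 0.2), acc_at(0.5, 2), acc_at(0.5, 6))
  expect_true(all(diff(ladder_threat) >= 0))
})
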