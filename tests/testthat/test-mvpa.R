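test_that("z-scoring standardizes every voxel across trials", {
  set.seed(51)
  B <- matrix(rnorm(60, mean = 3, sd = 2), 12, 5)
  Z <- zscore_across_trials(B)
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-10)
  # idempotence
  expect_equal(zscore_across_trials(Z), Z, tolerance = 1e-10)
  # constant voxel: zeroed with a warning
  B[, 2] <- 7
  expect_warning(Z2 <- zscore_across_trials(B), "zero-variance")
  expect_true(all(Z2[, 2] == 0))
})

test_that("running-index folds follow the i mod 3 rule and partition trials", {
  # 6 trials of one stimulus: fold-0 test = running indices {0, 3}
  lab <- rep("a", 6)
  f <- make_running_index_folds(c(lab, rep("b", 6)))
  expect_equal(f[[1]]$test[1:2], c(1, 4))

  # reinforcement condition: 24 CS- + 12 unreinforced CS+ -> 24 train / 12 test
  d <- default_design(seed = 2)
  keep <- retained_trials(d$trials, context = "reinforcement", complexity = "simple")
  labels <- d$trials$label[keep]
  folds <- make_running_index_folds(labels)
  for (fd in folds) {
    expect_length(fd$train, 24)
    expect_length(fd$test, 12)
    expect_length(intersect(fd$train, fd$test), 0)
    # per-fold class composition: 8 CS-, 4 CS+
    tab <- table(labels[fd$test])
    expect_equal(unname(tab["CS-"]), 8)
    expect_equal(unname(tab["CS+"]), 4)
  }
  # the three test sets partition the retained set
  test_union <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(test_union, seq_along(labels))

  expect_error(make_running_index_folds(c("a", "a", "b", "b")), "at least 3")
})

test_that("decoding matches a hand-computed margin rule on a toy set", {
  # two voxels; training clusters around x=0 (class a) and x=4 (class b);
  # support vectors at x=1 and x=3 put the max-margin boundary at x=2
  xtr <- rbind(c(0, 0), c(0, 1), c(1, 0), c(4, 0), c(4, 1), c(3, 0))
  ytr <- rep(c("a", "b"), each = 3)
  xte <- rbind(c(0.5, 0.5), c(3.5, 0), c(2.5, 0))
  yte <- c("a", "b", "a")  # third point lies on b's side: hand count 2/3
  B <- rbind(xtr, xte)
  folds <- list(list(train = 1:6, test = 7:9))
  expect_equal(decode_condition(B, c(ytr, yte), folds), 2 / 3)

  # independent geometric oracle on separable clusters: prediction must
  # equal the side of the midline for every point far from the boundary
  set.seed(52)
  n <- 12
  x <- rbind(matrix(rnorm(n, sd = 0.3), ncol = 2),
             matrix(rnorm(n, 4, sd = 0.3), ncol = 2))
  y <- rep(c("a", "b"), each = n / 2)
  fds <- make_running_index_folds(y)
  expect_equal(decode_condition(x, y, fds), 1.0)

  # single-class training folds are rejected
  bad <- list(list(train = 1:3, test = 4:6))
  expect_error(decode_condition(x, y, bad), "single class")
})

test_that("neutral-pair subsampling mirrors the CS imbalance", {
  labels <- rep(c("NS1", "NS2"), 24)
  idx <- subsample_ns(labels, seed = 7)
  expect_length(idx, 36)
  expect_equal(sort(as.vector(table(labels[idx]))), c(12, 24))

  # either class is selected for removal about half the time
  victims <- sapply(1:200, function(s) {
    names(which.min(table(labels[subsample_ns(labels, seed = s)])))
  })
  expect_gt(mean(victims == "NS1"), 0.4)
  expect_lt(mean(victims == "NS1"), 0.6)

  # zero removal returns the input unchanged
  expect_equal(subsample_ns(labels, seed = 1, remove_n = 0), seq_along(labels))
})

test_that("permutation chance is reproducible and not assumed to be 0.5", {
  d <- default_design(seed = 2)
  B <- noise_betas(d, n_voxels = 20, seed = 53)
  keep <- retained_trials(d$trials, context = "reinforcement", complexity = "simple")
  Z <- zscore_across_trials(B[keep, ])
  lab <- d$trials$label[keep]

  ch1 <- permutation_chance(Z, lab, n_perm = 30, seed = 9)
  ch2 <- permutation_chance(Z, lab, n_perm = 30, seed = 9)
  expect_identical(ch1$null, ch2$null)
  expect_length(ch1$null, 30)

  # with a 2:1 imbalance the empirical chance sits above 0.5: the pipeline
  # must take it from the null, not assume a binomial 50%
  ch <- permutation_chance(Z, lab, n_perm = 60, seed = 10)
  expect_gt(ch$chance_mean, 0.5)

  # balanced classes, labels independent of data: chance near 0.5
  yb <- rep(c("a", "b"), 12)
  Zb <- matrix(rnorm(24 * 15), 24, 15)
  chb <- permutation_chance(Zb, yb, n_perm = 80, seed = 11)
  expect_lt(abs(chb$chance_mean - 0.5), 0.05)
})

test_that("true-label accuracy behaves correctly against the null", {
  d <- default_design(seed = 2)
  keep <- retained_trials(d$trials, context = "reinforcement", complexity = "simple")
  lab <- d$trials$label[keep]

  # strongly separable data: accuracy exceeds the entire null distribution
  Bs <- separable_betas(d, stimulus_amp = 6, threat_amp = 6, noise_sd = 0.3,
                        seed = 54)
  Zs <- zscore_across_trials(Bs[keep, ])
  res <- decode_with_chance(Zs, lab, n_perm = 50, seed = 12)
  expect_equal(res$raw_accuracy, 1.0)
  expect_gt(res$raw_accuracy, max(attr(res, "null")))
  expect_equal(res$excess_accuracy, res$raw_accuracy - res$chance_mean)

  # pure noise: the true-label accuracy falls inside the central 95% of
  # the null for most datasets (calibration at reduced scale)
  inside <- sapply(1:25, function(s) {
    Bn <- noise_betas(d, n_voxels = 15, seed = 100 + s)
    Zn <- zscore_across_trials(Bn[keep, ])
    r <- decode_with_chance(Zn, lab, n_perm = 60, seed = s)
    q <- stats::quantile(attr(r, "null"), c(0.025, 0.975))
    r$raw_accuracy >= q[1] && r$raw_accuracy <= q[2]
  })
  expect_gte(mean(inside), 0.84)
})

test_that("excess accuracy is plain chance subtraction with guards", {
  expect_equal(excess_accuracy(0.75, 0.60), 0.15)
  expect_equal(excess_accuracy(0.60, 0.60), 0)
  expect_error(excess_accuracy(1.2, 0.5), "accuracy")
})

test_that("cross-decoding transfers shared but not independent threat patterns", {
  # moderate signal-to-noise: with a very large threat amplitude, minute
  # noise-driven misalignments of the training weights are amplified by the
  # test-set separation, so the independent-component case is only
  # near-zero in expectation at realistic effect sizes
  d <- default_design(seed = 2)

  shared <- separable_betas(d, n_voxels = 100, stimulus_amp = 0.5,
                            threat_amp = 2.5, noise_sd = 1.5,
                            seed = 55, shared_threat = TRUE)
  cd_sh <- cross_decode(shared, context = "reinforcement", n_perm = 25, seed = 13)
  expect_true(all(cd_sh$excess_accuracy > 0.1))

  cd_in <- lapply(1:2, function(s) {
    indep <- separable_betas(d, n_voxels = 100, stimulus_amp = 0.5,
                             threat_amp = 2.5, noise_sd = 1.5,
                             seed = 55 + s, shared_threat = FALSE)
    cross_decode(indep, context = "reinforcement", n_perm = 25, seed = 13 + s)
  })
  ex_in <- do.call(rbind, cd_in)$excess_accuracy
  expect_lt(abs(mean(ex_in)), 0.12)
  expect_true(all(abs(ex_in) < 0.25))
  expect_lt(mean(ex_in), min(cd_sh$excess_accuracy))

  # NS control uses key-press-matched labels
  cd_ns <- cross_decode(shared, context = "nonreinforcement", n_perm = 10, seed = 15)
  expect_equal(cd_ns$context, rep("nonreinforcement", 2))
  expect_true(all(cd_ns$raw_accuracy >= 0 & cd_ns$raw_accuracy <= 1))
})

test_that("condition decoding is deterministic given the seed", {
  d <- default_design(seed = 2)
  B <- separable_betas(d, seed = 57)
  a <- decode_all_conditions(B, n_perm = 10, n_subsample_reps = 2, seed = 16)
  b <- decode_all_conditions(B, n_perm = 10, n_subsample_reps = 2, seed = 16)
  expect_identical(a, b)
  expect_equal(nrow(a), 4)
  expect_true(all(a$raw_accuracy >= 0 & a$raw_accuracy <= 1))
})
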