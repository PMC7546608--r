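# Time binning, pattern extraction and the split-half PCA RDM estimator.

test_that("the default grid has 34 bins of 12 samples at 250 Hz", {
  grid <- make_time_bins(rdm_config(), fs = 250)
  expect_equal(nrow(grid), 34)
  expect_equal(attr(grid, "samples_per_bin"), 12L)
  expect_equal(grid$start_ms[1], -250)
  expect_equal(grid$end_ms[34], 1450)
  # contiguous, equal width, non-overlapping
  expect_true(all(diff(grid$start_ms) == 50))
  expect_equal(grid$end_ms - grid$start_ms, rep(50, 34))
  expect_true(all(grid$start_sample[-1] == grid$end_sample[-34] + 1))

  one <- make_time_bins(rdm_config(bin_width_ms = 1700), fs = 250)
  expect_equal(nrow(one), 1)
  expect_error(rdm_config(bin_width_ms = 48), "multiple")
})

test_that("bin patterns unfold channel-major into channels x samples features", {
  # 63 channels x 12 samples -> 756 features
  set.seed(21)
  data <- array(rnorm(4 * 63 * 425), dim = c(4, 63, 425))
  ep <- epoch_set(data, fs = 250, t0 = -250, face_label = c("a", "a", "b", "b"))
  grid <- make_time_bins(rdm_config(), fs = 250)
  pat <- extract_bin_patterns(ep, grid, 8)
  expect_equal(dim(pat$patterns), c(4, 756))
  expect_equal(pat$labels, c("a", "a", "b", "b"))

  # hand-unfolded 2-channel, 3-sample case
  data2 <- array(seq_len(1 * 2 * 6), dim = c(1, 2, 6))
  ep2 <- epoch_set(data2, fs = 1000, t0 = -3, face_label = "a")
  grid2 <- make_time_bins(rdm_config(bin_width_ms = 3, epoch_start_ms = -3,
                                     epoch_end_ms = 3), fs = 1000)
  pat2 <- extract_bin_patterns(ep2, grid2, 2)
  expect_equal(pat2$patterns[1, ],
               c(data2[1, 1, 4:6], data2[1, 2, 4:6]))

  # single channel, single sample -> one feature equal to that sample
  data3 <- array(c(2.5, -1), dim = c(2, 1, 2))
  ep3 <- epoch_set(data3, fs = 1000, t0 = -1,
                   face_label = c("a", "b"))
  grid3 <- make_time_bins(rdm_config(bin_width_ms = 1, epoch_start_ms = -1,
                                     epoch_end_ms = 1), fs = 1000)
  pat3 <- extract_bin_patterns(ep3, grid3, 1)
  expect_equal(dim(pat3$patterns), c(2, 1))
  expect_equal(pat3$patterns[, 1], data3[, 1, 1])

  # a bin outside the recorded epoch errors
  short <- epoch_set(array(0, dim = c(2, 1, 100)), fs = 250, t0 = -250,
                     face_label = c("a", "b"))
  expect_error(extract_bin_patterns(short, grid, 34), "outside")
})

test_that("split-half PCA estimator matches the straight-line oracle", {
  cfg <- rdm_config(n_repetitions = 1, variance_threshold = 0.99)
  for (s in 1:10) {
    set.seed(s + 100)
    x <- matrix(rnorm(16 * 10), 16, 10)
    labels <- rep(sprintf("c%02d", 1:4), each = 4)
    est <- split_half_pca_rdm(x, labels, cfg, seed = s)
    ora <- oracle_split_half_rdm(x, labels, n_repetitions = 1,
                                 variance_threshold = 0.99, seed = s)
    expect_equal(unclass(est), ora, tolerance = 1e-10)
  }
  # also with several repetitions and odd trial counts
  set.seed(7)
  x <- matrix(rnorm(15 * 8), 15, 8)
  labels <- rep(c("a", "b", "c"), times = c(5, 5, 5))
  est <- split_half_pca_rdm(x, labels, rdm_config(n_repetitions = 5), seed = 3)
  ora <- oracle_split_half_rdm(x, labels, n_repetitions = 5,
                               variance_threshold = 0.99, seed = 3)
  expect_equal(unclass(est), ora, tolerance = 1e-10)
})

test_that("estimator output is a valid RDM and deterministic given the seed", {
  set.seed(11)
  x <- matrix(rnorm(24 * 12), 24, 12)
  labels <- rep(letters[1:6], each = 4)
  cfg <- rdm_config(n_repetitions = 3)
  d1 <- split_half_pca_rdm(x, labels, cfg, seed = 42)
  d2 <- split_half_pca_rdm(x, labels, cfg, seed = 42)
  expect_identical(d1, d2)
  expect_true(all(is.na(diag(d1))))
  v <- vectorize_lower(d1)
  expect_true(all(v >= -1e-9 & v <= 2 + 1e-9))
  expect_equal(unclass(d1), t(unclass(d1)))
  # different seed, different splits
  expect_false(identical(d1, split_half_pca_rdm(x, labels, cfg, seed = 43)))
})

test_that("noiseless template data behave as the estimator contract demands", {
  # identical templates for two conditions -> dissimilarity ~ 0
  set.seed(3)
  tpl <- matrix(rnorm(4 * 30), 4, 30)
  tpl[2, ] <- tpl[1, ]
  dat <- template_patterns(tpl, n_trials = 4, noise_sd = 0)
  d <- split_half_pca_rdm(dat$patterns, dat$labels,
                          rdm_config(n_repetitions = 1), seed = 1)
  expect_lt(abs(d["c01", "c02"]), 1e-8)

  # with sensor-space reconstruction ("denoise") and threshold 1, noiseless
  # estimates equal 1 - cor between the raw templates exactly, and the
  # whole estimator agrees with the no-PCA oracle
  q <- qr.Q(qr(matrix(rnorm(40 * 6), 40, 6)))
  tpl2 <- t(q) # 6 orthonormal templates, 40 features
  dat2 <- template_patterns(tpl2, n_trials = 4, noise_sd = 0)
  cfg <- rdm_config(n_repetitions = 1, variance_threshold = 1,
                    projection = "denoise")
  d2 <- split_half_pca_rdm(dat2$patterns, dat2$labels, cfg, seed = 5)
  expect_equal(unclass(d2), oracle_no_pca_rdm(dat2$patterns, dat2$labels,
                                              seed = 5),
               tolerance = 1e-6)
  ref <- 1 - cor(t(tpl2))
  diag(ref) <- NA
  dimnames(ref) <- dimnames(d2)
  expect_equal(unclass(d2), ref, tolerance = 1e-6)
})

test_that("more sensor noise decorrelates the estimate from the geometry", {
  set.seed(1234)
  tpl <- matrix(rnorm(6 * 40), 6, 40)
  ref <- rdm(1 - cor(t(tpl)), sprintf("c%02d", 1:6))
  mean_rho <- function(noise_sd) {
    mean(sapply(1:20, function(s) {
      dat <- template_patterns(tpl, n_trials = 4, noise_sd = noise_sd,
                               seed = 1000 + s)
      d <- split_half_pca_rdm(dat$patterns, dat$labels,
                              rdm_config(n_repetitions = 2), seed = s)
      spearman_fit(d, ref)$rho
    }))
  }
  rhos <- sapply(c(0.5, 2, 8), mean_rho)
  # the template geometry is recovered at low noise and washed out (the
  # cross-validated correlations attenuate toward chance) as noise grows
  expect_true(all(diff(rhos) < 0))
  expect_gt(rhos[1], 0.5)
  expect_lt(abs(rhos[3]), 0.25)
})

test_that("degenerate inputs are rejected or flagged", {
  x <- matrix(rnorm(10 * 4), 10, 4)
  labels <- c("a", rep("b", 9))
  expect_error(split_half_pca_rdm(x, labels, rdm_config(n_repetitions = 1)),
               "'a' has 1 trial")
  # two conditions force a single retained component; 1-element condition
  # means have no defined correlation -> flagged NA
  tpl <- matrix(rnorm(2 * 10), 2, 10)
  dat <- template_patterns(tpl, n_trials = 4, noise_sd = 0)
  d <- split_half_pca_rdm(dat$patterns, dat$labels,
                          rdm_config(n_repetitions = 1), seed = 2)
  expect_true(is.na(d["c01", "c02"]))
})

test_that("rdm_timecourse yields one RDM per bin, shared labels, reproducible", {
  cfg_sim <- sim_config(n_participants = 1, n_faces = 6, n_blocks = 2,
                        n_channels = 4, seed = 8)
  faces <- generate_faces(cfg_sim)
  beh <- generate_behavior(faces, cfg_sim, 1)
  ep <- generate_epochs(faces, beh, cfg_sim, 1)$epochs
  cfg <- rdm_config(n_repetitions = 1, seed = 99)
  tc1 <- rdm_timecourse(ep, cfg)
  expect_length(tc1, 34)
  expect_true(all(vapply(tc1, function(d) identical(rownames(d), faces$face_id),
                         logical(1))))
  tc2 <- rdm_timecourse(ep, cfg)
  expect_identical(tc1, tc2)

  # single-bin config equals a direct split_half_pca_rdm call on that bin
  cfg1 <- rdm_config(bin_width_ms = 1700, n_repetitions = 1, seed = 99)
  tc3 <- rdm_timecourse(ep, cfg1)
  expect_length(tc3, 1)
  grid1 <- make_time_bins(cfg1, ep$fs)
  pat <- extract_bin_patterns(ep, grid1, 1)
  direct <- split_half_pca_rdm(pat$patterns, pat$labels, cfg1,
                               seed = rsatime:::derive_seed(99, "bin", 1),
                               conditions = sort(unique(ep$face_label)))
  expect_identical(unclass(tc3[[1]]), unclass(direct))
})
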