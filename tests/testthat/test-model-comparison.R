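# Spearman and partial Spearman comparison of neural and predictor RDMs.

# Build a symmetric RDM whose vectorize_lower() equals v.
rdm_from_vec <- function(v, n, labels = sprintf("c%02d", seq_len(n))) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  rdm(m, labels = labels)
}

test_that("vectorize_lower returns the documented row-major lower triangle", {
  d <- rdm(matrix(c(NA, 1, 2, 1, NA, 3, 2, 3, NA), 3, 3), letters[1:3])
  expect_equal(vectorize_lower(d), c(1, 2, 3)) # (2,1), (3,1), (3,2)
  expect_length(vectorize_lower(abs_diff_rdm(rnorm(100), sprintf("f%d", 1:100))),
                4950)
  expect_equal(vectorize_lower(d), vectorize_lower(rdm(t(unclass(d)),
                                                       letters[1:3])))
  v <- c(5, 4, 3, 2, 1, 0)
  expect_equal(vectorize_lower(rdm_from_vec(v, 4)), v)
})

test_that("plain Spearman fits behave like rank correlations", {
  set.seed(2)
  neural <- random_rdm(8)
  self <- spearman_fit(neural, neural)
  expect_equal(self$rho, 1)
  # rank reversal
  rev_rdm <- rdm_from_vec(-vectorize_lower(neural), 8,
                          labels = rdm_labels(neural))
  expect_equal(spearman_fit(neural, rev_rdm)$rho, -1)
  # z is atanh of (clipped) rho
  pred <- random_rdm(8)
  fit <- spearman_fit(neural, pred)
  expect_equal(fit$z, atanh(fit$rho))
  expect_equal(fit$rho,
               cor(vectorize_lower(neural), vectorize_lower(pred),
                   method = "spearman"),
               tolerance = 1e-12)
  # frozen hand computation with average-rank ties:
  # rx = (1, 2.5, 2.5, 4, 5, 6), ry = (3, 1, 4.5, 4.5, 6, 2) -> 3.25/17
  x <- rdm_from_vec(c(1, 2, 2, 4, 5, 6), 4)
  y <- rdm_from_vec(c(3, 1, 4, 4, 6, 2), 4)
  expect_equal(spearman_fit(x, y)$rho, 3.25 / 17, tolerance = 1e-12)
  # constant predictor -> flagged
  flat <- rdm_from_vec(rep(1, 28), 8, labels = rdm_labels(neural))
  expect_true(is.na(spearman_fit(neural, flat)$rho))
})

test_that("rank invariance: monotone rescaling of either RDM changes nothing", {
  set.seed(5)
  neural <- random_rdm(9)
  pred <- random_rdm(9, labels = rdm_labels(neural))
  base <- spearman_fit(neural, pred)$rho
  shifted <- rdm_from_vec(3 + 2 * vectorize_lower(pred), 9,
                          labels = rdm_labels(neural))
  expect_equal(spearman_fit(neural, shifted)$rho, base, tolerance = 1e-12)
  cubed <- rdm_from_vec(vectorize_lower(neural)^3, 9,
                        labels = rdm_labels(neural))
  expect_equal(spearman_fit(cubed, pred)$rho, base, tolerance = 1e-12)
})

test_that("partial Spearman matches the closed-form single-control formula", {
  set.seed(77)
  for (i in 1:100) {
    neural <- random_rdm(8)
    pred <- random_rdm(8, labels = rdm_labels(neural))
    ctrl <- random_rdm(8, labels = rdm_labels(neural))
    got <- partial_spearman_fit(neural, pred, list(ctrl))$rho
    want <- oracle_partial_on_ranks(vectorize_lower(neural),
                                    vectorize_lower(pred),
                                    vectorize_lower(ctrl))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("partial Spearman degenerate and structural properties hold", {
  set.seed(10)
  neural <- random_rdm(10)
  pred <- random_rdm(10, labels = rdm_labels(neural))
  # self-control annihilates the predictor (no unique variance -> rho 0)
  expect_equal(partial_spearman_fit(neural, pred, list(pred))$rho, 0)
  # zero controls equals the plain fit exactly
  expect_identical(partial_spearman_fit(neural, pred, list()),
                   spearman_fit(neural, pred))
  # collinear controls are dropped with a warning, result well-defined
  ctrl <- random_rdm(10, labels = rdm_labels(neural))
  ctrl2 <- rdm_from_vec(2 * vectorize_lower(ctrl) + 1, 10,
                        labels = rdm_labels(neural))
  expect_warning(fit <- partial_spearman_fit(neural, pred, list(ctrl, ctrl2)),
                 "collinear")
  expect_equal(fit$rho, partial_spearman_fit(neural, pred, list(ctrl))$rho,
               tolerance = 1e-10)
  # predictor independent of the neural RDM given the control (here:
  # independent of both) -> partial rho ~ 0 in expectation
  set.seed(11)
  rhos <- replicate(100, {
    z <- runif(45)
    neu <- rdm_from_vec(z + 0.3 * runif(45), 10)
    prd <- rdm_from_vec(runif(45), 10)
    con <- rdm_from_vec(z, 10)
    partial_spearman_fit(neu, prd, list(con))$rho
  })
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("flagged entries are removed pairwise, consistently across vectors", {
  set.seed(12)
  v1 <- runif(15)
  v2 <- runif(15)
  neural <- rdm_from_vec(v1, 6)
  pred <- rdm_from_vec(v2, 6)
  v1_na <- v1
  v1_na[c(2, 9)] <- NA
  neural_na <- rdm_from_vec(v1_na, 6)
  fit <- spearman_fit(neural_na, pred)
  expect_equal(fit$n_pairs, 13)
  expect_equal(fit$rho, cor(rank(v1[-c(2, 9)]), rank(v2[-c(2, 9)])),
               tolerance = 1e-12)
})

test_that("fit_timecourse fits every requested analysis for every bin", {
  cfg_sim <- sim_config(n_participants = 1, n_faces = 6, n_blocks = 2,
                        n_channels = 4, seed = 15)
  faces <- generate_faces(cfg_sim)
  beh <- generate_behavior(faces, cfg_sim, 1)
  ep <- generate_epochs(faces, beh, cfg_sim, 1)$epochs
  tc <- rdm_timecourse(ep, rdm_config(n_repetitions = 1, seed = 4))
  preds <- build_predictor_suite(faces, aggregate_responses(beh, faces))
  fit <- fit_timecourse(tc, preds, list(list(predictor = "db_rating"),
                                        list(predictor = "yesno"),
                                        list(predictor = "rating")))
  expect_s3_class(fit, "rsa_fit")
  expect_equal(nrow(fit), 3 * 34)
  expect_equal(dim(coef(fit)), c(34, 3))
  expect_equal(fit$z, atanh(pmin(pmax(fit$rho, -1 + 1e-12), 1 - 1e-12)))

  # controlling a predictor by itself -> flat ~0 timecourse
  fit_self <- fit_timecourse(tc, preds, list(list(predictor = "rating",
                                                  controls = "rating")))
  expect_true(all(abs(fit_self$rho) < 1e-8))

  # no randomness: identical output on a second run
  fit2 <- fit_timecourse(tc, preds, list(list(predictor = "db_rating"),
                                         list(predictor = "yesno"),
                                         list(predictor = "rating")))
  expect_identical(as.data.frame(fit), as.data.frame(fit2))

  expect_error(fit_timecourse(tc, preds, list(list(predictor = "nope"))),
               "unknown predictor")
})
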