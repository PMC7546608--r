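# Small programmatic fixtures shared across test files.

toy_faces <- function(n = 6, seed = 42) {
  cfg <- sim_config(n_faces = n, seed = seed)
  generate_faces(cfg)
}

# Trials x features matrix with given per-condition templates + noise.
template_patterns <- function(templates, n_trials = 4, noise_sd = 0,
                              seed = 1) {
  n_cond <- nrow(templates)
  set.seed(seed)
  labels <- rep(sprintf("c%02d", seq_len(n_cond)), each = n_trials)
  x <- templates[rep(seq_len(n_cond), each = n_trials), , drop = FALSE] +
    matrix(rnorm(length(labels) * ncol(templates), 0, noise_sd),
           ncol = ncol(templates))
  list(patterns = x, labels = labels)
}

# Forge an rsa_fit object from a per-bin z vector (single analysis), for
# group-level tests that do not need the estimator.
fake_fit <- function(z, grid, analysis = "pred", controls = "", pid = "p01") {
  df <- data.frame(
    analysis = analysis, predictor = analysis, controls = controls,
    bin = grid$bin, start_ms = grid$start_ms, end_ms = grid$end_ms,
    rho = tanh(z), z = z, stringsAsFactors = FALSE)
  structure(df, grid = grid, participant_id = pid, analyses = analysis,
            class = c("rsa_fit", "data.frame"))
}

default_grid <- function(fs = 250) make_time_bins(rdm_config(), fs)

temp_path <- function(name) file.path(tempdir(), name)
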