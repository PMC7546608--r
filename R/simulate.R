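#' Simulation configuration
#'
#' Defaults emulate the canonical study design: 23 participants, 100 faces
#' shown once per block in 7 blocks (700 trials), 63-channel EEG at 250 Hz
#' epoched from -250 to 1450 ms. Behaviour is generated from a latent
#' per-face preference `u = lambda * standardized(db_rating) +
#' (1 - lambda) * idiosyncratic`, so `shared_taste_weight` (lambda) sets how
#' strongly individual taste tracks the group-average rating; the default
#' lambda = 0.3 (with rating slope 1.5 and trial noise sd 1) yields
#' participant-vs-database rating correlations around 0.35, i.e. the
#' "moderate idiosyncrasy" regime. EEG epochs mix zero or more injected
#' representational geometries (see [geometry_spec]) with white noise.
#'
#' @param n_participants,n_faces,n_blocks Design counts.
#' @param fs Sampling rate (Hz).
#' @param epoch_start_ms,epoch_end_ms Epoch window relative to stimulus onset.
#' @param n_channels Number of EEG channels.
#' @param noise_sd SD of the white sensor noise per channel and sample, in
#'   units of the (unit-RMS) injected signal.
#' @param shared_taste_weight Lambda in \[0, 1\].
#' @param rating_noise_sd SD of the per-trial response noise (used for both
#'   the rating and the yes/no decision variable).
#' @param rating_slope Gain mapping the latent preference onto the 1-7 scale.
#' @param p_reference Probability that a face belongs to the reference
#'   ethnicity category.
#' @param geometries List of [geometry_spec]s to inject into the EEG.
#' @param seed Integer master seed; all substreams derive from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_participants = 23, n_faces = 100, n_blocks = 7,
                       fs = 250, epoch_start_ms = -250, epoch_end_ms = 1450,
                       n_channels = 63, noise_sd = 1,
                       shared_taste_weight = 0.3, rating_noise_sd = 1,
                       rating_slope = 1.5, p_reference = 0.7,
                       geometries = list(), seed = 1L) {
  for (nm in c("n_participants", "n_faces", "n_blocks", "fs", "n_channels")) {
    v <- get(nm)
    check_number(v, nm, lower = 1)
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(shared_taste_weight, "shared_taste_weight", 0, 1)
  check_number(rating_noise_sd, "rating_noise_sd", lower = 0)
  check_number(p_reference, "p_reference", 0, 1)
  if (epoch_start_ms > 0 || epoch_end_ms <= 0) {
    stop_fmt("epoch window must cover stimulus onset")
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_faces = as.integer(n_faces), n_blocks = as.integer(n_blocks),
         fs = fs, epoch_start_ms = epoch_start_ms,
         epoch_end_ms = epoch_end_ms, n_channels = as.integer(n_channels),
         noise_sd = noise_sd, shared_taste_weight = shared_taste_weight,
         rating_noise_sd = rating_noise_sd, rating_slope = rating_slope,
         p_reference = p_reference, geometries = geometries,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Injected representational geometry
#'
#' Describes one source of structured signal in the simulated EEG: a target
#' RDM (either a literal [rdm] or the name of a predictor that is resolved
#' per participant: `"rating"`, `"yesno"`, `"db_rating"`, `"sex"`,
#' `"ethnicity"`, `"age"`), the latent dimensionality `q` of its embedding,
#' and a piecewise-linear temporal envelope rising from 0 at `onset_ms` to
#' `amplitude` at `peak_ms` and back to 0 at `offset_ms`. Envelopes are
#' deliberately schematic: recovery tests need controllable onsets, not
#' biophysically realistic waveforms.
#'
#' @param name Geometry name (used in the ground-truth record).
#' @param source An [rdm] or one of the predictor keywords above.
#' @param q Latent embedding dimension (<= n_faces - 1).
#' @param onset_ms,peak_ms,offset_ms Envelope breakpoints (onset < peak <
#'   offset).
#' @param amplitude Peak signal weight (>= 0).
#' @return A list of class `"geometry_spec"`.
#' @export
geometry_spec <- function(name, source, q = 5, onset_ms, peak_ms, offset_ms,
                          amplitude = 1) {
  keywords <- c("rating", "yesno", "db_rating", "sex", "ethnicity", "age")
  if (!is_rdm(source) &&
      !(is.character(source) && length(source) == 1L && source %in% keywords)) {
    stop_fmt("geometry source must be an rdm or one of: %s",
             paste(keywords, collapse = ", "))
  }
  check_number(q, "q", lower = 1)
  if (!(onset_ms < peak_ms && peak_ms < offset_ms)) {
    stop_fmt("envelope must satisfy onset < peak < offset")
  }
  check_number(amplitude, "amplitude", lower = 0)
  structure(list(name = name, source = source, q = as.integer(q),
                 onset_ms = onset_ms, peak_ms = peak_ms,
                 offset_ms = offset_ms, amplitude = amplitude),
            class = "geometry_spec")
}

envelope_weights <- function(spec, times_ms) {
  w <- numeric(length(times_ms))
  up <- times_ms >= spec$onset_ms & times_ms < spec$peak_ms
  down <- times_ms >= spec$peak_ms & times_ms < spec$offset_ms
  w[up] <- (times_ms[up] - spec$onset_ms) / (spec$peak_ms - spec$onset_ms)
  w[down] <- (spec$offset_ms - times_ms[down]) /
    (spec$offset_ms - spec$peak_ms)
  w * spec$amplitude
}

#' Generate a synthetic face set
#'
#' Face attributes are drawn independently: sex Bernoulli(0.5), ethnicity
#' Bernoulli(`p_reference`) over reference/other, age Uniform(18, 50),
#' database rating Normal(3.5, 0.8) clipped to \[1, 7\].
#'
#' @param config A [sim_config].
#' @return A [face_set] of `n_faces` rows, deterministic given the seed.
#' @export
generate_faces <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_faces
  with_seed(derive_seed(config$seed, "faces"), {
    face_set(data.frame(
      face_id = sprintf("f%04d", seq_len(n)),
      sex = sample(c("male", "female"), n, replace = TRUE),
      ethnicity = sample(c("reference", "other"), n, replace = TRUE,
                         prob = c(config$p_reference, 1 - config$p_reference)),
      age = stats::runif(n, 18, 50),
      db_rating = pmin(pmax(stats::rnorm(n, 3.5, 0.8), 1), 7),
      stringsAsFactors = FALSE))
  })
}

#' Generate one participant's behavioural session
#'
#' The participant's latent preference for face f is
#' `u(f) = lambda * standardized(db_rating(f)) + (1 - lambda) * e(f)` with
#' idiosyncratic `e(f) ~ N(0, 1)` fixed for the whole session. Each trial's
#' rating is `clip(round(3.5 + slope * u(f) + eps), 1, 7)` and the yes/no
#' response is 1 ("yes") when `u(f) + eps' > 0`, else 2, with independent
#' `eps, eps' ~ N(0, rating_noise_sd)` per trial. Trials form `n_blocks`
#' blocks, each a fresh random permutation of all faces.
#'
#' @param faces A [face_set] (typically from [generate_faces]).
#' @param config A [sim_config].
#' @param participant Participant index (selects the RNG substream).
#' @return A [session_behavior] with `n_blocks * n_faces` rows.
#' @export
generate_behavior <- function(faces, config, participant = 1L) {
  stopifnot(inherits(faces, "face_set"), inherits(config, "sim_config"))
  n <- nrow(faces)
  lam <- config$shared_taste_weight
  with_seed(derive_seed(config$seed, "behavior", participant), {
    db_std <- if (stats::sd(faces$db_rating) > 0) {
      as.vector(scale(faces$db_rating))
    } else {
      numeric(n)
    }
    u <- lam * db_std + (1 - lam) * stats::rnorm(n)
    order_idx <- unlist(lapply(seq_len(config$n_blocks),
                               function(b) sample.int(n)))
    n_trials <- length(order_idx)
    eps <- stats::rnorm(n_trials, 0, config$rating_noise_sd)
    eps2 <- stats::rnorm(n_trials, 0, config$rating_noise_sd)
    rating <- pmin(pmax(round(3.5 + config$rating_slope * u[order_idx] + eps),
                        1), 7)
    yesno <- ifelse(u[order_idx] + eps2 > 0, 1, 2)
    session_behavior(data.frame(
      trial_index = seq_len(n_trials),
      face_id = faces$face_id[order_idx],
      yesno = yesno,
      rating = rating,
      stringsAsFactors = FALSE), faces)
  })
}

#' Embed an RDM into Euclidean coordinates
#'
#' Classical multidimensional scaling (double-centre the squared
#' dissimilarities, eigendecompose, keep the top `q` non-negative
#' components), via [stats::cmdscale]. Negative eigenvalues -- which arise
#' for non-Euclidean RDMs such as absolute-difference matrices -- are
#' truncated: if fewer than `q` positive dimensions exist, the remaining
#' coordinate columns are zero. Pairwise distances of the coordinates
#' reproduce the RDM exactly whenever it is Euclidean-embeddable in `q`
#' dimensions.
#'
#' @param x An [rdm] (flagged entries are not allowed here).
#' @param q Number of dimensions (<= n - 1).
#' @return An n x q coordinate matrix with the RDM's labels as rownames.
#' @export
rdm_to_coordinates <- function(x, q) {
  stopifnot(is_rdm(x))
  n <- nrow(x)
  check_number(q, "q", lower = 1, upper = n - 1)
  q <- as.integer(q)
  d <- unclass(x)
  diag(d) <- 0
  if (any(!is.finite(d))) stop_fmt("cannot embed an RDM with flagged entries")
  if (all(d == 0)) {
    coords <- matrix(0, n, q)
  } else {
    fit <- suppressWarnings(stats::cmdscale(d, k = q))
    coords <- matrix(0, n, q)
    got <- min(ncol(fit), q)
    coords[, seq_len(got)] <- fit[, seq_len(got)]
    coords[is.na(coords)] <- 0
  }
  rownames(coords) <- rdm_labels(x)
  coords
}

# Resolve a geometry's source RDM for one participant.
resolve_geometry_source <- function(spec, faces, responses) {
  if (is_rdm(spec$source)) return(spec$source)
  labels <- faces$face_id
  switch(spec$source,
    rating = abs_diff_rdm(responses$mean_rating, labels),
    yesno = abs_diff_rdm(responses$mean_yesno, labels),
    db_rating = abs_diff_rdm(faces$db_rating, labels),
    sex = categorical_rdm(faces$sex, labels),
    ethnicity = categorical_rdm(
      ifelse(faces$ethnicity == "reference", "reference", "other"), labels),
    age = abs_diff_rdm(faces$age, labels))
}

#' Generate one participant's EEG epochs with injected geometry
#'
#' Forward model: each geometry's source RDM is embedded into `q`
#' coordinates ([rdm_to_coordinates]), the coordinates are centred and
#' scaled to unit total variance across faces, and mixed into channel space
#' by a random channels x q matrix (entries N(0, 1/q), fixed per participant
#' and geometry). The resulting per-face channel pattern is modulated over
#' time by the geometry's envelope, summed across geometries, and white
#' Gaussian noise with SD `noise_sd` is added independently per trial,
#' channel and sample. Each trial carries the pattern of the face shown on
#' that trial of `behavior`.
#'
#' @param faces A [face_set].
#' @param behavior The participant's [session_behavior] (defines the trial
#'   sequence and, for response-derived geometries, the source RDM).
#' @param config A [sim_config] (uses its `geometries` unless overridden).
#' @param participant Participant index (RNG substream).
#' @param geometries Optional list of [geometry_spec]s overriding
#'   `config$geometries`.
#' @return List with `epochs` (an [epoch_set]) and `sources` (named list of
#'   resolved source [rdm]s, for ground-truth scoring).
#' @export
generate_epochs <- function(faces, behavior, config, participant = 1L,
                            geometries = NULL) {
  stopifnot(inherits(faces, "face_set"), inherits(config, "sim_config"))
  geometries <- geometries %||% config$geometries
  n_faces <- nrow(faces)
  n_trials <- nrow(behavior)
  n_ch <- config$n_channels
  n_smp <- as.integer(round((config$epoch_end_ms - config$epoch_start_ms) *
                              config$fs / 1000))
  times <- config$epoch_start_ms + (seq_len(n_smp) - 1L) * 1000 / config$fs
  responses <- if (length(geometries)) aggregate_responses(behavior, faces)
  # per-face signal template: faces x channels x samples
  signal <- array(0, dim = c(n_faces, n_ch, n_smp))
  sources <- list()
  for (k in seq_along(geometries)) {
    spec <- geometries[[k]]
    stopifnot(inherits(spec, "geometry_spec"))
    src <- resolve_geometry_source(spec, faces, responses)
    sources[[spec$name]] <- src
    coords <- rdm_to_coordinates(src, spec$q)
    coords <- scale(coords, center = TRUE, scale = FALSE)
    tot <- sum(apply(coords, 2L, stats::var))
    if (tot > 0) coords <- coords / sqrt(tot)
    mix <- with_seed(derive_seed(config$seed, "mixing", participant, k),
                     matrix(stats::rnorm(n_ch * spec$q, 0, 1 / sqrt(spec$q)),
                            n_ch, spec$q))
    g <- coords %*% t(mix) # faces x channels
    w <- envelope_weights(spec, times)
    for (f in seq_len(n_faces)) {
      signal[f, , ] <- signal[f, , ] + outer(g[f, ], w)
    }
  }
  face_idx <- match(behavior$face_id, faces$face_id)
  data <- with_seed(
    derive_seed(config$seed, "noise", participant),
    array(stats::rnorm(n_trials * n_ch * n_smp, 0, config$noise_sd),
          dim = c(n_trials, n_ch, n_smp)))
  for (i in seq_len(n_trials)) {
    data[i, , ] <- data[i, , ] + signal[face_idx[i], , ]
  }
  epochs <- epoch_set(data, fs = config$fs, t0 = config$epoch_start_ms,
                      face_label = behavior$face_id,
                      participant_id = sprintf("sim%02d", participant))
  list(epochs = epochs, sources = sources)
}

#' Generate a full multi-participant dataset
#'
#' Draws one face set and, for every participant, a behavioural session and
#' an epoch set with the configured injected geometries. Everything is
#' deterministic given the master seed. The ground-truth record stores the
#' geometry specs and each participant's resolved source RDMs so recovery
#' can be scored later.
#'
#' @param config A [sim_config].
#' @return A list of class `"rsa_simulation"` with `faces`, `participants`
#'   (each a list with `behavior`, `epochs`), `ground_truth` (list with
#'   `geometries` and per-participant `sources`), and `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  faces <- generate_faces(config)
  participants <- vector("list", config$n_participants)
  sources <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    behavior <- generate_behavior(faces, config, p)
    sim <- generate_epochs(faces, behavior, config, p)
    participants[[p]] <- list(behavior = behavior, epochs = sim$epochs)
    sources[[p]] <- sim$sources
  }
  structure(
    list(faces = faces, participants = participants,
         ground_truth = list(geometries = config$geometries,
                             sources = sources),
         config = config),
    class = "rsa_simulation")
}

#' @export
print.rsa_simulation <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Simulated RSA dataset: %d participants, %d faces x %d blocks, %d channels @ %g Hz\n",
    cfg$n_participants, cfg$n_faces, cfg$n_blocks, cfg$n_channels, cfg$fs))
  if (length(cfg$geometries)) {
    for (g in cfg$geometries) {
      cat(sprintf("  geometry '%s': onset %g ms, peak %g ms, offset %g ms, amplitude %g\n",
                  g$name, g$onset_ms, g$peak_ms, g$offset_ms, g$amplitude))
    }
  } else {
    cat("  no injected geometry (pure noise)\n")
  }
  invisible(x)
}
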