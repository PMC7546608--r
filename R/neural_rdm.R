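#' Configuration for the cross-validated neural RDM estimator
#'
#' Defaults reproduce the standard design for a 250 Hz recording epoched from
#' -250 to 1450 ms: 34 contiguous 50 ms bins of 12 samples each, split-half
#' PCA retaining 99% of the fitting-half variance, 50 random split
#' repetitions.
#'
#' @param bin_width_ms Time-bin width in ms.
#' @param epoch_start_ms,epoch_end_ms Analysis window relative to stimulus
#'   onset; the span must be a multiple of `bin_width_ms`.
#' @param variance_threshold Fraction of variance (in the fitting half) the
#'   retained principal components must explain, in (0, 1].
#' @param n_repetitions Number of random split repetitions to average over.
#' @param seed Integer master seed; every random split is derived from it.
#' @param projection Either `"scores"` (correlate condition means in the
#'   retained component space; the default) or `"denoise"` (project patterns
#'   onto the retained basis, reconstruct back into sensor space, and
#'   correlate there). See the methods vignette for the trade-off.
#' @return A list of class `"rdm_config"`.
#' @export
rdm_config <- function(bin_width_ms = 50, epoch_start_ms = -250,
                       epoch_end_ms = 1450, variance_threshold = 0.99,
                       n_repetitions = 50, seed = 1L,
                       projection = c("scores", "denoise")) {
  check_number(bin_width_ms, "bin_width_ms")
  if (bin_width_ms <= 0) stop_fmt("bin_width_ms must be positive")
  check_number(epoch_start_ms, "epoch_start_ms")
  check_number(epoch_end_ms, "epoch_end_ms")
  span <- epoch_end_ms - epoch_start_ms
  if (span <= 0) stop_fmt("epoch_end_ms must exceed epoch_start_ms")
  if (abs(span / bin_width_ms - round(span / bin_width_ms)) > 1e-9) {
    stop_fmt("epoch span (%g ms) is not a multiple of bin width (%g ms)",
             span, bin_width_ms)
  }
  check_number(variance_threshold, "variance_threshold")
  if (variance_threshold <= 0 || variance_threshold > 1) {
    stop_fmt("variance_threshold must be in (0, 1], got %g", variance_threshold)
  }
  check_number(n_repetitions, "n_repetitions", lower = 1)
  structure(
    list(bin_width_ms = bin_width_ms, epoch_start_ms = epoch_start_ms,
         epoch_end_ms = epoch_end_ms, variance_threshold = variance_threshold,
         n_repetitions = as.integer(n_repetitions), seed = as.integer(seed),
         projection = match.arg(projection)),
    class = "rdm_config")
}

#' Build the time-bin grid for an epoch
#'
#' Bins are contiguous, non-overlapping and of equal width, covering
#' `[epoch_start_ms, epoch_end_ms)`. Each bin holds
#' `floor(bin_width_ms * fs / 1000)` samples and consecutive bins advance by
#' exactly that many samples, so at 250 Hz a 50 ms bin contributes 12 time
#' points (the nominal 12.5 is rounded down; see the vignette).
#'
#' @param config An [rdm_config].
#' @param fs Sampling rate in Hz.
#' @return A data frame of class `"time_bin_grid"` with one row per bin
#'   (`bin`, `start_ms`, `end_ms`, `start_sample`, `end_sample`; samples are
#'   1-based offsets from `epoch_start_ms`) and attributes `samples_per_bin`
#'   and `fs`.
#' @examples
#' make_time_bins(rdm_config(), fs = 250) # 34 bins of 12 samples
#' @export
make_time_bins <- function(config, fs) {
  stopifnot(inherits(config, "rdm_config"))
  check_number(fs, "fs")
  if (fs <= 0) stop_fmt("fs must be positive, got %g", fs)
  span <- config$epoch_end_ms - config$epoch_start_ms
  n_bins <- as.integer(round(span / config$bin_width_ms))
  spb <- floor(config$bin_width_ms * fs / 1000)
  if (spb < 1) {
    stop_fmt("bin width %g ms holds no samples at %g Hz",
             config$bin_width_ms, fs)
  }
  b <- seq_len(n_bins)
  grid <- data.frame(
    bin = b,
    start_ms = config$epoch_start_ms + (b - 1) * config$bin_width_ms,
    end_ms = config$epoch_start_ms + b * config$bin_width_ms,
    start_sample = (b - 1L) * spb + 1L,
    end_sample = b * spb)
  attr(grid, "samples_per_bin") <- as.integer(spb)
  attr(grid, "fs") <- fs
  attr(grid, "epoch_start_ms") <- config$epoch_start_ms
  class(grid) <- c("time_bin_grid", "data.frame")
  grid
}

#' Extract per-trial response patterns for one time bin
#'
#' Slices the bin's samples out of the epoch array and unfolds each trial's
#' channels x samples segment into a single feature vector, channel-major
#' (channel 1's samples first, then channel 2's, ...). With 63 channels and 12
#' samples per bin this yields the familiar 756-element response vector.
#'
#' @param epochs An [epoch_set].
#' @param grid A [make_time_bins] grid (built at `epochs$fs`).
#' @param bin Bin number (row of `grid`).
#' @return List with `patterns` (trials x features matrix, rows in trial
#'   order) and `labels` (per-trial face ids).
#' @export
extract_bin_patterns <- function(epochs, grid, bin) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(grid, "time_bin_grid"))
  if (!(bin %in% grid$bin)) stop_fmt("bin %s is not on the grid", format(bin))
  row <- grid[grid$bin == bin, ]
  # sample index of the grid's epoch start within this epoch_set
  offset <- round((attr(grid, "epoch_start_ms") - epochs$t0) *
                    epochs$fs / 1000)
  smp <- offset + row$start_sample:row$end_sample
  n_samples <- dim(epochs$data)[3L]
  if (smp[1L] < 1L || smp[length(smp)] > n_samples) {
    stop_fmt("bin %d (%g..%g ms) falls outside the recorded epoch",
             bin, row$start_ms, row$end_ms)
  }
  slice <- epochs$data[, , smp, drop = FALSE]
  spb <- length(smp)
  n_trials <- dim(slice)[1L]
  n_channels <- dim(slice)[2L]
  m <- aperm(slice, c(1L, 3L, 2L)) # trials x samples x channels
  dim(m) <- c(n_trials, spb * n_channels) # feature = (ch-1)*spb + sample
  list(patterns = m, labels = epochs$face_label)
}

# Randomly split trial indices into two halves with an equal number of trials
# per condition; a condition's surplus trial (odd count) joins a random half.
# Must be called with the RNG already seeded.
split_half_assign <- function(labels, conditions) {
  a <- integer(0)
  b <- integer(0)
  for (cond in conditions) {
    idx <- which(labels == cond)
    n <- length(idx)
    perm <- idx[sample.int(n)]
    h <- n %/% 2L
    a <- c(a, perm[seq_len(h)])
    b <- c(b, perm[h + seq_len(h)])
    if (n %% 2L == 1L) {
      if (stats::runif(1) < 0.5) a <- c(a, perm[n]) else b <- c(b, perm[n])
    }
  }
  list(a = a, b = b)
}

# One direction of the split-half PCA estimate: fit PCA on the `fit` rows,
# centre both halves by the fitting half's feature means, project the held-out
# rows on the smallest leading component set reaching the variance threshold,
# average per condition and return 1 - Pearson correlation between condition
# means. With projection = "denoise" the projections are mapped back into
# sensor space (and the fitting means added back) before correlating.
pca_half_rdm <- function(x, labels, fit, held, conditions,
                         variance_threshold, projection) {
  mu <- colMeans(x[fit, , drop = FALSE])
  xc_fit <- sweep(x[fit, , drop = FALSE], 2L, mu)
  sv <- svd(xc_fit, nu = 0)
  tot <- sum(sv$d^2)
  if (tot <= 0) {
    # degenerate fitting half (all rows identical): keep raw features
    proj <- sweep(x[held, , drop = FALSE], 2L, mu)
    if (projection == "denoise") proj <- sweep(proj, 2L, mu, `+`)
  } else {
    cum <- cumsum(sv$d^2) / tot
    k <- which(cum >= variance_threshold - 1e-12)[1L]
    v <- sv$v[, seq_len(k), drop = FALSE]
    proj <- sweep(x[held, , drop = FALSE], 2L, mu) %*% v
    if (projection == "denoise") {
      proj <- sweep(proj %*% t(v), 2L, mu, `+`)
    }
  }
  f <- factor(labels[held], levels = conditions)
  means <- rowsum(proj, f) / as.vector(table(f))
  r <- suppressWarnings(stats::cor(t(means)))
  1 - r
}

#' Split-half PCA estimate of a neural RDM
#'
#' The cross-validated correlation-distance estimator: trials are split at
#' random into two halves with an equal number of trials per condition. A PCA
#' is fitted on the first half's trial-level feature vectors; the second
#' half, centred by the first half's feature means, is projected onto the
#' smallest set of leading components explaining at least
#' `variance_threshold` of the fitting-half variance. Projected trials are
#' averaged per condition and each condition pair's entry is 1 minus the
#' Pearson correlation of the two condition means. The roles of the halves
#' are then swapped and the two RDMs averaged; the whole procedure is
#' repeated `n_repetitions` times with fresh random splits and the RDMs
#' averaged across repetitions. Deterministic given `seed`.
#'
#' Entries are in \[0, 2\]; the diagonal is empty. A condition mean with zero
#' variance across features yields an undefined correlation and is flagged
#' (NA) rather than guessed.
#'
#' @param patterns Trials x features numeric matrix (see
#'   [extract_bin_patterns]).
#' @param labels Per-trial condition (face) labels; every condition needs at
#'   least 2 trials.
#' @param config An [rdm_config] (uses `variance_threshold`, `n_repetitions`,
#'   `projection`, and `seed` unless overridden).
#' @param seed Integer seed for the random splits; defaults to `config$seed`.
#' @param conditions Condition order for the output RDM; defaults to sorted
#'   unique labels.
#' @return An [rdm] over `conditions`.
#' @export
split_half_pca_rdm <- function(patterns, labels, config = rdm_config(),
                               seed = config$seed,
                               conditions = sort(unique(labels))) {
  stopifnot(is.matrix(patterns), inherits(config, "rdm_config"))
  labels <- as.character(labels)
  if (length(labels) != nrow(patterns)) {
    stop_fmt("labels length %d does not match %d pattern rows",
             length(labels), nrow(patterns))
  }
  counts <- table(factor(labels, levels = conditions))
  if (any(counts < 2L)) {
    bad <- names(counts)[counts < 2L][1L]
    stop_fmt("condition '%s' has %d trial(s); the split-half estimator needs >= 2",
             bad, counts[[bad]])
  }
  n <- length(conditions)
  acc <- matrix(0, n, n)
  for (rep in seq_len(config$n_repetitions)) {
    halves <- with_seed(derive_seed(seed, "split", rep),
                        split_half_assign(labels, conditions))
    d1 <- pca_half_rdm(patterns, labels, halves$a, halves$b, conditions,
                       config$variance_threshold, config$projection)
    d2 <- pca_half_rdm(patterns, labels, halves$b, halves$a, conditions,
                       config$variance_threshold, config$projection)
    acc <- acc + (d1 + d2) / 2
  }
  rdm(acc / config$n_repetitions, labels = conditions, tol = 1e-6)
}

#' Neural RDM timecourse
#'
#' Runs [split_half_pca_rdm] independently for every bin of the grid implied
#' by `config` and the epoch sampling rate, with per-bin seeds derived
#' deterministically from `config$seed`. All RDMs share the same condition
#' order (sorted face ids).
#'
#' @param epochs An [epoch_set].
#' @param config An [rdm_config].
#' @return A list of class `"rdm_timecourse"`: one [rdm] per bin, with the
#'   [make_time_bins] grid in `attr(, "grid")`.
#' @export
rdm_timecourse <- function(epochs, config = rdm_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  grid <- make_time_bins(config, epochs$fs)
  conditions <- sort(unique(epochs$face_label))
  out <- vector("list", nrow(grid))
  for (b in grid$bin) {
    pat <- extract_bin_patterns(epochs, grid, b)
    out[[b]] <- split_half_pca_rdm(pat$patterns, pat$labels, config,
                                   seed = derive_seed(config$seed, "bin", b),
                                   conditions = conditions)
  }
  names(out) <- sprintf("%g_%g", grid$start_ms, grid$end_ms)
  structure(out, grid = grid, participant_id = epochs$participant_id,
            class = "rdm_timecourse")
}

#' @export
print.rdm_timecourse <- function(x, ...) {
  grid <- attr(x, "grid")
  cat(sprintf("Neural RDM timecourse: %d bins of %g ms (%g to %g ms), %d conditions\n",
              nrow(grid), grid$end_ms[1L] - grid$start_ms[1L],
              grid$start_ms[1L], grid$end_ms[nrow(grid)], nrow(x[[1L]])))
  invisible(x)
}
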