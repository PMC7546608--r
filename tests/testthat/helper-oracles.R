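# Independent straight-line oracles used to pin down the numerical behaviour
# of the estimators. They deliberately use a different code path than the
# package (prcomp/predict, explicit double loops, textbook formulas).

# Split-half PCA RDM, steps written out one by one. Mirrors the package's
# documented RNG discipline (per-repetition seed, one permutation per
# condition, a uniform draw for an odd condition's surplus trial) so that the
# same seed yields the same random splits.
oracle_split_half_rdm <- function(patterns, labels, n_repetitions = 1,
                                  variance_threshold = 0.99, seed = 1L) {
  conds <- sort(unique(labels))
  n <- length(conds)
  total <- matrix(0, n, n)
  for (rep in seq_len(n_repetitions)) {
    set.seed(rsatime:::derive_seed(seed, "split", rep))
    a <- integer(0)
    b <- integer(0)
    for (cond in conds) {
      idx <- which(labels == cond)
      perm <- idx[sample.int(length(idx))]
      h <- length(idx) %/% 2
      a <- c(a, perm[seq_len(h)])
      b <- c(b, perm[h + seq_len(h)])
      if (length(idx) %% 2 == 1) {
        if (runif(1) < 0.5) a <- c(a, perm[length(idx)]) else
          b <- c(b, perm[length(idx)])
      }
    }
    rep_rdm <- matrix(0, n, n)
    for (half in list(list(fit = a, held = b), list(fit = b, held = a))) {
      pca <- prcomp(patterns[half$fit, , drop = FALSE], center = TRUE,
                    scale. = FALSE)
      ev <- pca$sdev^2 / sum(pca$sdev^2)
      k <- which(cumsum(ev) >= variance_threshold - 1e-12)[1]
      proj <- predict(pca, patterns[half$held, , drop = FALSE])[, seq_len(k),
                                                               drop = FALSE]
      cm <- matrix(0, n, ncol(proj))
      for (i in seq_len(n)) {
        cm[i, ] <- colMeans(proj[labels[half$held] == conds[i], ,
                                 drop = FALSE])
      }
      d <- matrix(0, n, n)
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (i != j) d[i, j] <- 1 - cor(cm[i, ], cm[j, ])
        }
      }
      rep_rdm <- rep_rdm + d / 2
    }
    total <- total + rep_rdm
  }
  out <- total / n_repetitions
  diag(out) <- NA
  dimnames(out) <- list(conds, conds)
  out
}

# No-PCA split-half estimate: split, average per condition in the held half,
# correlate condition means in raw sensor space, 1 - r, swap, average.
oracle_no_pca_rdm <- function(patterns, labels, seed = 1L) {
  conds <- sort(unique(labels))
  n <- length(conds)
  set.seed(rsatime:::derive_seed(seed, "split", 1))
  a <- integer(0)
  b <- integer(0)
  for (cond in conds) {
    idx <- which(labels == cond)
    perm <- idx[sample.int(length(idx))]
    h <- length(idx) %/% 2
    a <- c(a, perm[seq_len(h)])
    b <- c(b, perm[h + seq_len(h)])
    if (length(idx) %% 2 == 1) {
      if (runif(1) < 0.5) a <- c(a, perm[length(idx)]) else
        b <- c(b, perm[length(idx)])
    }
  }
  d_of <- function(held) {
    cm <- t(sapply(conds, function(cc) {
      colMeans(patterns[held, , drop = FALSE][labels[held] == cc, ,
                                              drop = FALSE])
    }))
    1 - cor(t(cm))
  }
  out <- (d_of(b) + d_of(a)) / 2
  diag(out) <- NA
  dimnames(out) <- list(conds, conds)
  out
}

# Textbook first-order partial correlation, computed on average ranks.
oracle_partial_on_ranks <- function(x, y, z) {
  rx <- rank(x)
  ry <- rank(y)
  rz <- rank(z)
  rxy <- cor(rx, ry)
  rxz <- cor(rx, rz)
  ryz <- cor(ry, rz)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Hand-rolled Benjamini-Hochberg step-up adjustment.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# Random symmetric dissimilarity matrix as an rdm.
random_rdm <- function(n, labels = sprintf("c%02d", seq_len(n))) {
  m <- matrix(runif(n * n), n, n)
  rdm((m + t(m)) / 2, labels = labels)
}
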