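# Model comparison: (partial) Spearman correlation between neural and
# predictor RDMs, per time bin and participant.

# Align a predictor RDM to the neural RDM's label order.
align_rdm <- function(x, labels, what) {
  if (is.null(rdm_labels(x)) || !setequal(rdm_labels(x), labels)) {
    stop_fmt("%s RDM labels do not match the neural RDM", what)
  }
  x[labels, labels, drop = FALSE]
}

clip_rho <- function(rho) {
  lim <- 1 - 1e-12 # keep atanh finite on degenerate (|rho| = 1) inputs
  pmin(pmax(rho, -lim), lim)
}

#' Partial Spearman correlation between RDMs
#'
#' The workhorse of RDM model comparison. All RDMs are vectorized
#' ([vectorize_lower]); entries that are flagged (NA) in any vector are
#' removed pairwise so all vectors stay aligned. Every vector is then
#' rank-transformed (average ranks, the standard convention for the heavily
#' tied 0/1 and 1-7 predictors), the neural and predictor ranks are
#' least-squares residualized on an intercept plus the control ranks, and the
#' Pearson correlation of the two residual vectors is returned together with
#' its Fisher z transform (`atanh`, with rho clipped away from +/-1). With no
#' controls this reduces exactly to the plain Spearman correlation.
#'
#' Collinear control columns are dropped via a rank-revealing QR
#' decomposition, with a warning.
#'
#' @param neural Neural [rdm].
#' @param predictor Predictor [rdm] (same labels, any order).
#' @param controls List of control [rdm]s to partial out of both sides
#'   (possibly empty).
#' @return List with `rho`, `z`, and `n_pairs` (pairs used after NA removal).
#'   A constant vector makes the correlation undefined; `rho` and `z` are
#'   then NA (flagged). If the controls explain one side completely (no
#'   residual variance, e.g. a predictor controlled by itself), the partial
#'   correlation is 0 by convention.
#' @export
partial_spearman_fit <- function(neural, predictor, controls = list()) {
  labels <- rdm_labels(neural)
  vecs <- c(list(vectorize_lower(neural),
                 vectorize_lower(align_rdm(predictor, labels, "predictor"))),
            lapply(seq_along(controls), function(i) {
              vectorize_lower(align_rdm(controls[[i]], labels,
                                        sprintf("control %d", i)))
            }))
  keep <- Reduce(`&`, lapply(vecs, is.finite))
  if (sum(keep) < 3L) {
    warning("fewer than 3 usable RDM entries; correlation flagged NA",
            call. = FALSE)
    return(list(rho = NA_real_, z = NA_real_, n_pairs = sum(keep)))
  }
  ranks <- lapply(vecs, function(v) rank(v[keep], ties.method = "average"))
  y1 <- ranks[[1L]]
  y2 <- ranks[[2L]]
  pre1 <- sqrt(sum((y1 - mean(y1))^2))
  pre2 <- sqrt(sum((y2 - mean(y2))^2))
  if (pre1 == 0 || pre2 == 0) {
    # a constant RDM vector has no defined rank correlation
    return(list(rho = NA_real_, z = NA_real_, n_pairs = sum(keep)))
  }
  if (length(controls)) {
    x <- cbind(1, do.call(cbind, ranks[-(1:2)]))
    qx <- qr(x)
    if (qx$rank < ncol(x)) {
      warning(sprintf("dropping %d collinear control column(s)",
                      ncol(x) - qx$rank), call. = FALSE)
    }
    y1 <- qr.resid(qx, y1)
    y2 <- qr.resid(qx, y2)
  } else {
    y1 <- y1 - mean(y1)
    y2 <- y2 - mean(y2)
  }
  s1 <- sqrt(sum(y1^2))
  s2 <- sqrt(sum(y2^2))
  if (s1 < 1e-8 * pre1 || s2 < 1e-8 * pre2) {
    # the controls explain one side completely (e.g. a predictor controlled
    # by itself): no unique variance left, so the partial correlation is 0
    return(list(rho = 0, z = 0, n_pairs = sum(keep)))
  }
  rho <- sum(y1 * y2) / (s1 * s2)
  list(rho = rho, z = atanh(clip_rho(rho)), n_pairs = sum(keep))
}

#' Spearman correlation between two RDMs
#'
#' Plain rank correlation of the vectorized lower triangles with average-rank
#' tie handling, plus its Fisher z transform. Equivalent to
#' [partial_spearman_fit] with an empty control set.
#'
#' @inheritParams partial_spearman_fit
#' @return List with `rho`, `z`, `n_pairs`.
#' @export
spearman_fit <- function(neural, predictor) {
  partial_spearman_fit(neural, predictor, controls = list())
}

#' Fit predictor RDMs to a neural RDM timecourse
#'
#' For each requested analysis (a predictor plus an optional set of control
#' predictors) and each time bin, computes the (partial) Spearman correlation
#' between the bin's neural RDM and the predictor RDM. This covers the three
#' standard analysis families: plain fits of each predictor, individual
#' judgment predictors controlling for the group-average rating, and
#' attractiveness predictors controlling for face attributes and/or
#' activation-layer RDMs.
#'
#' @param neural_rdms An [rdm_timecourse] (or plain list of [rdm]s with a
#'   `grid` attribute).
#' @param predictors Named list of predictor [rdm]s (see
#'   [build_predictor_suite]).
#' @param analyses List of analyses; each element is a list (or character
#'   vector) with `predictor` (a name in `predictors`) and optional
#'   `controls` (character vector of names in `predictors`).
#' @param participant_id Identifier carried into the result; defaults to the
#'   timecourse's.
#' @return An object of class `"rsa_fit"`: a data frame with one row per
#'   analysis x bin (`predictor`, `controls`, `bin`, `start_ms`, `end_ms`,
#'   `rho`, `z`), with the bin grid and analysis labels as attributes.
#'   Deterministic (no randomness).
#' @export
fit_timecourse <- function(neural_rdms, predictors, analyses,
                           participant_id = NULL) {
  grid <- attr(neural_rdms, "grid")
  if (is.null(grid)) stop_fmt("neural_rdms must carry a time-bin grid")
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    stop_fmt("'predictors' must be a named list of RDMs")
  }
  participant_id <- participant_id %||%
    (attr(neural_rdms, "participant_id") %||% "p01")
  rows <- list()
  for (an in analyses) {
    an <- as.list(an)
    pred_name <- an$predictor
    ctrl_names <- an$controls %||% character(0)
    unknown <- setdiff(c(pred_name, ctrl_names), names(predictors))
    if (length(unknown)) {
      stop_fmt("unknown predictor name(s): %s", paste(unknown, collapse = ", "))
    }
    label <- analysis_label(pred_name, ctrl_names)
    ctrl <- predictors[ctrl_names]
    fits <- lapply(grid$bin, function(b) {
      partial_spearman_fit(neural_rdms[[b]], predictors[[pred_name]],
                           controls = ctrl)
    })
    rows[[label]] <- data.frame(
      analysis = label,
      predictor = pred_name,
      controls = paste(ctrl_names, collapse = "+"),
      bin = grid$bin,
      start_ms = grid$start_ms,
      end_ms = grid$end_ms,
      rho = vapply(fits, `[[`, numeric(1), "rho"),
      z = vapply(fits, `[[`, numeric(1), "z"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, grid = grid, participant_id = participant_id,
            analyses = names(rows), class = c("rsa_fit", "data.frame"))
}

analysis_label <- function(predictor, controls) {
  if (length(controls)) {
    paste0(predictor, " | ", paste(controls, collapse = "+"))
  } else {
    predictor
  }
}

#' @export
print.rsa_fit <- function(x, ...) {
  grid <- attr(x, "grid")
  cat(sprintf("RSA timecourse fit for participant '%s'\n",
              attr(x, "participant_id")))
  cat(sprintf("  %d analyses x %d bins (%g to %g ms)\n",
              length(attr(x, "analyses")), nrow(grid),
              grid$start_ms[1L], grid$end_ms[nrow(grid)]))
  for (a in attr(x, "analyses")) {
    z <- x$z[x$analysis == a]
    cat(sprintf("  %-28s peak z = %6.3f at %g ms\n", a,
                max(z, na.rm = TRUE),
                x$start_ms[x$analysis == a][which.max(z)]))
  }
  invisible(x)
}

#' @export
coef.rsa_fit <- function(object, measure = c("z", "rho"), ...) {
  measure <- match.arg(measure)
  grid <- attr(object, "grid")
  analyses <- attr(object, "analyses")
  m <- vapply(analyses, function(a) object[[measure]][object$analysis == a],
              numeric(nrow(grid)))
  rownames(m) <- sprintf("%g_%g", grid$start_ms, grid$end_ms)
  m
}

#' @export
plot.rsa_fit <- function(x, measure = "rho", ...) {
  grid <- attr(x, "grid")
  m <- coef(x, measure = measure)
  mid <- (grid$start_ms + grid$end_ms) / 2
  graphics::matplot(mid, m, type = "l", lty = 1, lwd = 1.5,
                    xlab = "time (ms)", ylab = sprintf("Spearman %s", measure),
                    ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  graphics::legend("topleft", legend = colnames(m), lty = 1, lwd = 1.5,
                   col = seq_len(ncol(m)), bty = "n", cex = 0.8)
  invisible(x)
}
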