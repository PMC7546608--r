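# Group-level inference: one-sided t-tests on Fisher-z correlations across
# participants, BH-FDR across time bins, effect sizes, peak summaries.

#' One-sided one-sample t-test against zero
#'
#' Tests whether the group mean of per-participant Fisher-z correlations is
#' greater than zero (the conventional direction for RSA model fits).
#'
#' @param z_values Numeric vector, one value per participant (n >= 2).
#' @return List with `t`, `df` (= n - 1) and the upper-tail `p`. Zero
#'   variance across participants makes the statistic undefined; all fields
#'   are then NA (flagged).
#' @export
ttest_onesided <- function(z_values) {
  z_values <- z_values[is.finite(z_values)]
  n <- length(z_values)
  if (n < 2L) stop_fmt("need at least 2 participants, got %d", n)
  if (stats::sd(z_values) == 0) {
    return(list(t = NA_real_, df = n - 1L, p = NA_real_))
  }
  tt <- stats::t.test(z_values, mu = 0, alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Cohen's d from a one-sample t statistic
#'
#' For a one-sample t-test, `d = mean / sd = t / sqrt(n)`. Returned at full
#' precision; rounding (2 decimals) is a reporting choice made in the print
#' methods.
#'
#' @param t t statistic.
#' @param n Number of participants.
#' @return Cohen's d.
#' @examples
#' cohens_d_from_t(5.08, 23) # ~1.06
#' @export
cohens_d_from_t <- function(t, n) {
  check_number(n, "n", lower = 1)
  t / sqrt(n)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up BH adjustment (with the usual monotonicity enforcement, via
#' [stats::p.adjust]) across a family of p-values -- here, the time bins of
#' one analysis.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (NAs allowed,
#'   propagated).
#' @param q FDR level for the significance mask.
#' @return List with `p_adj` (adjusted p-values) and `significant`
#'   (`p_adj < q`).
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.5))$p_adj # 0.04 0.04 0.04 0.50
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  ok <- is.finite(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop_fmt("p-values must lie in [0, 1]")
  }
  p_adj <- stats::p.adjust(pvals, method = "BH")
  list(p_adj = p_adj, significant = !is.na(p_adj) & p_adj < q)
}

#' Group statistics for RSA timecourse fits
#'
#' Combines per-participant [fit_timecourse] results into group-level
#' inference, separately for each analysis: per bin, a one-sided t-test of
#' the participants' Fisher-z values against zero; BH-FDR correction across
#' bins; Cohen's d (= t / sqrt(n)); and two summaries per analysis -- the
#' earliest bin whose corrected p falls below `alpha` (the "onset" bin) and
#' the peak bin (maximal t among significant bins; if no bin survives
#' correction, the global maximum-t bin is reported and flagged
#' `peak_significant = FALSE`).
#'
#' @param fits List of `rsa_fit` objects, one per participant, sharing the
#'   same bin grid and analyses.
#' @param alpha Significance level applied to the corrected p-values.
#' @param fdr_scope Either `"all"` (correct across every bin, including
#'   pre-stimulus ones; the default) or `"post_stimulus"` (bins starting at
#'   or after 0 ms form the FDR family; earlier bins get `p_corr = NA`).
#' @return An object of class `"rsa_group"`: a list with `table` (per
#'   analysis x bin: `mean_z`, `t`, `df`, `p`, `p_corr`, `d`, `significant`),
#'   `peaks` (one row per analysis: onset and peak windows, peak t/p/p_corr/d),
#'   `n` (participants), and `alpha`.
#' @export
group_summary <- function(fits, alpha = 0.05,
                          fdr_scope = c("all", "post_stimulus")) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(length(fits) >= 2L)
  grid <- attr(fits[[1L]], "grid")
  analyses <- attr(fits[[1L]], "analyses")
  for (f in fits) {
    if (!inherits(f, "rsa_fit")) stop_fmt("'fits' must contain rsa_fit objects")
    g <- attr(f, "grid")
    if (!isTRUE(all.equal(g$start_ms, grid$start_ms)) ||
        !identical(attr(f, "analyses"), analyses)) {
      stop_fmt("participants have mismatched bin grids or analyses")
    }
  }
  n <- length(fits)
  tabs <- list()
  peaks <- list()
  for (a in analyses) {
    zmat <- vapply(fits, function(f) f$z[f$analysis == a],
                   numeric(nrow(grid))) # bins x participants
    tests <- apply(zmat, 1L, function(z) ttest_onesided(z))
    tab <- data.frame(
      analysis = a,
      predictor = fits[[1L]]$predictor[fits[[1L]]$analysis == a][1L],
      controls = fits[[1L]]$controls[fits[[1L]]$analysis == a][1L],
      bin = grid$bin,
      start_ms = grid$start_ms,
      end_ms = grid$end_ms,
      mean_z = rowMeans(zmat),
      t = vapply(tests, `[[`, numeric(1), "t"),
      df = vapply(tests, `[[`, numeric(1), "df"),
      p = vapply(tests, `[[`, numeric(1), "p"),
      stringsAsFactors = FALSE)
    in_family <- if (fdr_scope == "post_stimulus") tab$start_ms >= 0 else
      rep(TRUE, nrow(tab))
    tab$p_corr <- NA_real_
    corr <- fdr_bh(tab$p[in_family], q = alpha)
    tab$p_corr[in_family] <- corr$p_adj
    tab$d <- cohens_d_from_t(tab$t, n)
    tab$significant <- !is.na(tab$p_corr) & tab$p_corr < alpha
    sig <- which(tab$significant)
    if (length(sig)) {
      peak <- sig[which.max(tab$t[sig])]
      peak_sig <- TRUE
    } else {
      peak <- which.max(tab$t)
      peak_sig <- FALSE
    }
    onset <- if (length(sig)) sig[1L] else NA_integer_
    peaks[[a]] <- data.frame(
      analysis = a,
      predictor = tab$predictor[1L],
      controls = tab$controls[1L],
      onset_start_ms = if (is.na(onset)) NA_real_ else tab$start_ms[onset],
      onset_end_ms = if (is.na(onset)) NA_real_ else tab$end_ms[onset],
      peak_start_ms = tab$start_ms[peak],
      peak_end_ms = tab$end_ms[peak],
      peak_t = tab$t[peak],
      df = tab$df[peak],
      peak_p = tab$p[peak],
      peak_p_corr = tab$p_corr[peak],
      peak_d = tab$d[peak],
      peak_significant = peak_sig,
      stringsAsFactors = FALSE)
    tabs[[a]] <- tab
  }
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL
  peaks <- do.call(rbind, peaks)
  rownames(peaks) <- NULL
  structure(list(table = table, peaks = peaks, n = n, alpha = alpha,
                 fdr_scope = fdr_scope, grid = grid),
            class = "rsa_group")
}

#' @export
print.rsa_group <- function(x, ...) {
  cat(sprintf("Group RSA results: n = %d participants, %d bins, FDR alpha = %g (%s bins)\n",
              x$n, nrow(x$grid), x$alpha,
              if (x$fdr_scope == "all") "all" else "post-stimulus"))
  p <- x$peaks
  for (i in seq_len(nrow(p))) {
    onset <- if (is.na(p$onset_start_ms[i])) "no significant bin" else
      sprintf("from %g-%g ms", p$onset_start_ms[i], p$onset_end_ms[i])
    cat(sprintf(
      "  %-28s %s; peak %g-%g ms, t[%d] = %.2f, p %s, p_corr %s, d = %.2f%s\n",
      p$analysis[i], onset, p$peak_start_ms[i], p$peak_end_ms[i], p$df[i],
      p$peak_t[i], format_p(p$peak_p[i]), format_p(p$peak_p_corr[i]),
      round(p$peak_d[i], 2),
      if (p$peak_significant[i]) "" else " (peak not FDR-significant)"))
  }
  invisible(x)
}

format_p <- function(p) {
  if (is.na(p)) return("= NA")
  if (p < 0.001) "< 0.001" else sprintf("= %.3f", p)
}

#' @export
summary.rsa_group <- function(object, ...) {
  object$peaks
}

#' @export
plot.rsa_group <- function(x, ...) {
  tab <- x$table
  analyses <- unique(tab$analysis)
  mid <- (x$grid$start_ms + x$grid$end_ms) / 2
  m <- vapply(analyses, function(a) tab$mean_z[tab$analysis == a],
              numeric(nrow(x$grid)))
  graphics::matplot(mid, m, type = "l", lty = 1, lwd = 1.5,
                    xlab = "time (ms)", ylab = "group mean Fisher z", ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  for (j in seq_along(analyses)) {
    sig <- tab$significant[tab$analysis == analyses[j]]
    if (any(sig)) {
      graphics::points(mid[sig], rep(graphics::par("usr")[3L] * 0.9, sum(sig)) +
                         j * 0.002, pch = 15, col = j, cex = 0.5)
    }
  }
  graphics::legend("topleft", legend = analyses, lty = 1, lwd = 1.5,
                   col = seq_along(analyses), bty = "n", cex = 0.8)
  invisible(x)
}
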