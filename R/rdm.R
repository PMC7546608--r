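#' Representational dissimilarity matrices
#'
#' An `rdm` is a symmetric condition-by-condition matrix of pairwise
#' dissimilarities with an empty (NA) diagonal. It is the common currency
#' between the neural side of the pipeline (cross-validated correlation
#' distances between response patterns, bounded in \[0, 2\]) and the predictor
#' side (absolute rating differences, 0/1 category mismatches, 1 - r between
#' activation vectors). Individual off-diagonal entries may be NA to flag
#' undefined dissimilarities (e.g. a zero-variance pattern); such entries are
#' removed pairwise when RDMs are compared.
#'
#' @param values Square numeric matrix of dissimilarities. Must be symmetric
#'   up to `tol`; the diagonal is ignored and stored as NA.
#' @param labels Character vector of condition identifiers, one per row.
#'   Defaults to the rownames of `values`.
#' @param tol Tolerance for the symmetry check.
#' @return A matrix of class `"rdm"` with condition labels as dimnames and an
#'   NA diagonal.
#' @examples
#' rdm(matrix(c(0, 1, 1, 0), 2, 2), labels = c("a", "b"))
#' @export
rdm <- function(values, labels = rownames(values), tol = 1e-8) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_fmt("an RDM requires a numeric matrix")
  }
  n <- nrow(values)
  if (ncol(values) != n) {
    stop_fmt("RDM matrix must be square, got %d x %d", n, ncol(values))
  }
  if (is.null(labels)) labels <- sprintf("c%03d", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop_fmt("expected %d labels, got %d", n, length(labels))
  }
  if (anyDuplicated(labels)) {
    stop_fmt("duplicate condition label: '%s'", labels[duplicated(labels)][1L])
  }
  off <- abs(values - t(values))
  off[is.na(off)] <- 0 # NA entries must simply be NA on both sides
  na_sym <- is.na(values) != is.na(t(values))
  diag(na_sym) <- FALSE
  if (any(na_sym) || max(off, na.rm = TRUE) > tol) {
    stop_fmt("RDM matrix is not symmetric (max |d - t(d)| = %g)",
             max(off, na.rm = TRUE))
  }
  values <- (values + t(values)) / 2
  values[is.na(t(values))] <- NA_real_
  diag(values) <- NA_real_
  dimnames(values) <- list(labels, labels)
  class(values) <- c("rdm", class(matrix()))
  values
}

#' @export
print.rdm <- function(x, ...) {
  v <- vectorize_lower(x)
  cat(sprintf("RDM: %d conditions, %d pairs\n", nrow(x), length(v)))
  cat(sprintf("  range [%s, %s], %d flagged (NA) entries\n",
              format(suppressWarnings(min(v, na.rm = TRUE)), digits = 4),
              format(suppressWarnings(max(v, na.rm = TRUE)), digits = 4),
              sum(is.na(v))))
  invisible(x)
}

#' @rdname rdm
#' @param x An object to test / an [rdm] to query.
#' @export
is_rdm <- function(x) inherits(x, "rdm")

#' @rdname rdm
#' @export
rdm_labels <- function(x) rownames(x)

#' Vectorize the lower triangle of an RDM
#'
#' Extracts the n(n-1)/2 below-diagonal entries in row-major order (row 2:
#' (2,1); row 3: (3,1), (3,2); ...). The diagonal is always discarded. The
#' same fixed order is used everywhere in the package, so any two vectorized
#' RDMs over the same labels are aligned entry by entry. Flagged (NA) entries
#' are preserved and removed pairwise by the correlation routines.
#'
#' @param x An [rdm] (or symmetric matrix).
#' @return Numeric vector of length `n(n-1)/2`.
#' @examples
#' d <- abs_diff_rdm(c(1, 4, 7), c("a", "b", "c"))
#' vectorize_lower(d) # entries (2,1), (3,1), (3,2)
#' @export
vectorize_lower <- function(x) {
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    stop_fmt("vectorize_lower() expects a square matrix")
  }
  # row-major traversal of the lower triangle == column-major traversal of the
  # upper triangle of the transpose
  tx <- t(x)
  unname(tx[upper.tri(tx)])
}

#' Write / read an RDM as delimited text
#'
#' RDMs are serialized as comma-separated text with a header row and a leading
#' column of condition labels. The empty diagonal (and any flagged entry) is
#' written as the sentinel `NA`, keeping the empty-diagonal invariant visible
#' on disk. Round-trips are exact up to formatting precision (15 significant
#' digits).
#'
#' @param x An [rdm].
#' @param path File path.
#' @return `read_rdm` returns an [rdm]; `write_rdm` returns `path` invisibly.
#' @export
write_rdm <- function(x, path) {
  if (!is_rdm(x)) x <- rdm(as.matrix(x)) # validates symmetry
  m <- format(unclass(x), digits = 15, trim = TRUE, scientific = TRUE)
  m[is.na(unclass(x))] <- "NA"
  df <- data.frame(label = rownames(x), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("label", colnames(x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_fmt("'%s' does not look like an RDM file", path)
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) {
    stop_fmt("non-square RDM in '%s': %d x %d", path, nrow(m), ncol(m))
  }
  if (!identical(labels, colnames(m))) {
    stop_fmt("row and column labels disagree in '%s'", path)
  }
  rdm(m, labels = labels, tol = 1e-6)
}
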