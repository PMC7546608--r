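#' Aggregate trial-level responses per face
#'
#' Each face is shown several times per session (once per block) and the
#' binary judgment may flip across repetitions, so one summary per face is
#' needed before building predictor RDMs. The arithmetic mean is used for
#' both the yes/no codes (giving a graded value in \[1, 2\]) and the 1-7
#' ratings.
#'
#' @param behavior A [session_behavior].
#' @param faces Optional [face_set]; when supplied the output rows follow its
#'   face order and every face must have at least one trial.
#' @return Data frame of class `"per_face_responses"` with columns `face_id`,
#'   `mean_yesno`, `mean_rating`, `n_trials`.
#' @export
aggregate_responses <- function(behavior, faces = NULL) {
  stopifnot(inherits(behavior, "session_behavior"))
  if (nrow(behavior) == 0L) stop_fmt("cannot aggregate an empty session")
  ids <- if (is.null(faces)) sort(unique(behavior$face_id)) else faces$face_id
  f <- factor(behavior$face_id, levels = ids)
  n <- as.vector(table(f))
  if (any(n == 0L)) {
    stop_fmt("face '%s' has no trials in the behaviour table",
             ids[n == 0L][1L])
  }
  out <- data.frame(
    face_id = ids,
    mean_yesno = as.vector(tapply(behavior$yesno, f, mean)),
    mean_rating = as.vector(tapply(behavior$rating, f, mean)),
    n_trials = n,
    stringsAsFactors = FALSE)
  class(out) <- c("per_face_responses", "data.frame")
  out
}

#' Absolute-difference predictor RDM
#'
#' The standard predictor construction for graded variables (attractiveness
#' ratings, mean yes/no codes, age): entry (i, j) is `|v_i - v_j|`.
#'
#' @param values One numeric value per condition.
#' @param labels Condition identifiers.
#' @return An [rdm] (non-negative, satisfies the triangle inequality).
#' @examples
#' abs_diff_rdm(c(1, 4, 7), c("a", "b", "c"))
#' @export
abs_diff_rdm <- function(values, labels) {
  if (any(is.na(values))) {
    stop_fmt("missing value for condition '%s'", labels[is.na(values)][1L])
  }
  if (length(values) != length(labels)) {
    stop_fmt("got %d values for %d labels", length(values), length(labels))
  }
  rdm(abs(outer(values, values, `-`)), labels = labels)
}

#' Categorical (same/different) predictor RDM
#'
#' Binary dissimilarity for categorical attributes such as sex or (binarized)
#' ethnicity: 0 when two conditions share the category, 1 otherwise.
#'
#' @param categories One category per condition (any atomic type).
#' @param labels Condition identifiers.
#' @return An [rdm] with 0/1 off-diagonal entries (a pseudometric).
#' @export
categorical_rdm <- function(categories, labels) {
  if (any(is.na(categories))) {
    stop_fmt("missing category for condition '%s'", labels[is.na(categories)][1L])
  }
  if (length(categories) != length(labels)) {
    stop_fmt("got %d categories for %d labels", length(categories),
             length(labels))
  }
  categories <- as.character(categories)
  rdm(1 * outer(categories, categories, `!=`), labels = labels)
}

#' Correlation-distance RDM from feature activations
#'
#' For a faces x features activation matrix (one model layer), entry (i, j)
#' is 1 minus the Pearson correlation between the two activation vectors. A
#' zero-variance activation vector has no defined correlation; its entries
#' are flagged NA.
#'
#' @param acts Numeric matrix, rows = conditions (in RDM label order),
#'   columns = features (at least 2).
#' @param labels Condition identifiers; default rownames of `acts`.
#' @return An [rdm] with entries in \[0, 2\].
#' @export
activation_rdm <- function(acts, labels = rownames(acts)) {
  stopifnot(is.matrix(acts))
  if (ncol(acts) < 2L) stop_fmt("activation matrix needs >= 2 features")
  if (is.null(labels)) stop_fmt("activation matrix needs row labels")
  r <- suppressWarnings(stats::cor(t(acts)))
  rdm(1 - r, labels = labels, tol = 1e-8)
}

#' Build the full predictor RDM suite
#'
#' Constructs, in one shared condition order (the face order of `faces`), the
#' three attractiveness predictors (`db_rating` from the group-average
#' database rating; `yesno` and `rating` from the participant's aggregated
#' responses, all absolute-difference RDMs), the three high-level attribute
#' controls (`sex` and `ethnicity` as same/different RDMs, with ethnicity
#' binarized into a reference category versus everything else; `age` as
#' absolute difference), and one correlation-distance RDM per supplied
#' activation layer.
#'
#' @param faces A [face_set].
#' @param responses A [aggregate_responses] table in the same face order.
#' @param activations Optional named list of faces x features matrices (rows
#'   in the same face order), one per model layer.
#' @param ethnicity_reference Category treated as the reference when
#'   binarizing ethnicity; defaults to the most frequent category.
#' @return Named list of [rdm]s: `db_rating`, `yesno`, `rating`, `sex`,
#'   `ethnicity`, `age`, plus one entry per activation layer.
#' @export
build_predictor_suite <- function(faces, responses, activations = NULL,
                                  ethnicity_reference = NULL) {
  stopifnot(inherits(faces, "face_set"),
            inherits(responses, "per_face_responses"))
  if (!identical(faces$face_id, responses$face_id)) {
    stop_fmt("face order mismatch between faces and responses")
  }
  labels <- faces$face_id
  if (is.null(ethnicity_reference)) {
    tab <- table(faces$ethnicity)
    ethnicity_reference <- names(tab)[which.max(tab)]
  }
  eth_bin <- ifelse(faces$ethnicity == ethnicity_reference,
                    ethnicity_reference, "other")
  out <- list(
    db_rating = abs_diff_rdm(faces$db_rating, labels),
    yesno = abs_diff_rdm(responses$mean_yesno, labels),
    rating = abs_diff_rdm(responses$mean_rating, labels),
    sex = categorical_rdm(faces$sex, labels),
    ethnicity = categorical_rdm(eth_bin, labels),
    age = abs_diff_rdm(faces$age, labels))
  if (!is.null(activations)) {
    if (is.null(names(activations)) || any(names(activations) == "")) {
      stop_fmt("activation matrices must be a named list (layer names)")
    }
    for (layer in names(activations)) {
      acts <- activations[[layer]]
      if (nrow(acts) != length(labels)) {
        stop_fmt("activation layer '%s' has %d rows for %d faces", layer,
                 nrow(acts), length(labels))
      }
      if (!is.null(rownames(acts)) && !identical(rownames(acts), labels)) {
        stop_fmt("activation layer '%s' row order does not match the face order",
                 layer)
      }
      out[[layer]] <- activation_rdm(acts, labels)
    }
  }
  out
}
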