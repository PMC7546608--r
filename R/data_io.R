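#' Face metadata tables
#'
#' A `face_set` holds the stimulus identities that form the condition axis of
#' every RDM: one row per face with its sex, ethnicity (kept verbatim here;
#' binarization into reference/other is an analysis choice made when building
#' predictor RDMs), age in years, and the group-average ("database")
#' attractiveness rating on the 1-7 scale.
#'
#' @param df Data frame with columns `face_id`, `sex`, `ethnicity`, `age`,
#'   `db_rating`.
#' @return A validated data frame of class `"face_set"`.
#' @export
face_set <- function(df) {
  required <- c("face_id", "sex", "ethnicity", "age", "db_rating")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_fmt("face metadata is missing column(s): %s",
             paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df$face_id <- as.character(df$face_id)
  if (anyDuplicated(df$face_id)) {
    stop_fmt("duplicate face_id: '%s'", df$face_id[duplicated(df$face_id)][1L])
  }
  for (col in required) {
    bad <- which(is.na(df[[col]]))
    if (length(bad)) stop_fmt("missing %s in row %d", col, bad[1L])
  }
  bad <- which(df$db_rating < 1 | df$db_rating > 7)
  if (length(bad)) {
    stop_fmt("rating out of range: db_rating = %g for face '%s' (row %d)",
             df$db_rating[bad[1L]], df$face_id[bad[1L]], bad[1L])
  }
  bad <- which(df$age <= 0)
  if (length(bad)) {
    stop_fmt("age must be positive, got %g for face '%s' (row %d)",
             df$age[bad[1L]], df$face_id[bad[1L]], bad[1L])
  }
  df$sex <- as.character(df$sex)
  df$ethnicity <- as.character(df$ethnicity)
  rownames(df) <- NULL
  class(df) <- c("face_set", "data.frame")
  df
}

#' @param path Path to a comma-separated table with a header row.
#' @rdname face_set
#' @export
read_face_metadata <- function(path) {
  face_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname face_set
#' @export
write_face_metadata <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Behavioural response tables
#'
#' One participant's session: one row per trial with the face shown, the
#' binary attractiveness judgment (`yesno`, coded 1 = yes, 2 = no) and the
#' 1-7 attractiveness rating. Rows are sorted by `trial_index`.
#'
#' @param df Data frame with columns `trial_index`, `face_id`, `yesno`,
#'   `rating`.
#' @param faces Companion [face_set]; every `face_id` must appear in it.
#' @return A validated data frame of class `"session_behavior"`.
#' @export
session_behavior <- function(df, faces) {
  required <- c("trial_index", "face_id", "yesno", "rating")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_fmt("behaviour table is missing column(s): %s",
             paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df$face_id <- as.character(df$face_id)
  if (nrow(df) == 0L) {
    warning("empty behaviour table", call. = FALSE)
  } else {
    if (any(is.na(df$trial_index)) || any(df$trial_index < 0)) {
      stop_fmt("trial_index must be a non-negative integer (row %d)",
               which(is.na(df$trial_index) | df$trial_index < 0)[1L])
    }
    unknown <- which(!(df$face_id %in% faces$face_id))
    if (length(unknown)) {
      stop_fmt("unknown face_id '%s' in behaviour row %d",
               df$face_id[unknown[1L]], unknown[1L])
    }
    bad <- which(!(df$yesno %in% c(1, 2)))
    if (length(bad)) {
      stop_fmt("yesno must be 1 (yes) or 2 (no), got %s in row %d",
               format(df$yesno[bad[1L]]), bad[1L])
    }
    bad <- which(is.na(df$rating) | df$rating != round(df$rating) |
                   df$rating < 1 | df$rating > 7)
    if (length(bad)) {
      stop_fmt("rating must be an integer in 1..7, got %s in row %d",
               format(df$rating[bad[1L]]), bad[1L])
    }
    df <- df[order(df$trial_index), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("session_behavior", "data.frame")
  df
}

#' @param path Path to a comma-separated table with a header row.
#' @rdname session_behavior
#' @export
read_behavior <- function(path, faces) {
  session_behavior(utils::read.csv(path, stringsAsFactors = FALSE), faces)
}

#' @rdname session_behavior
#' @export
write_behavior <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Epoched EEG data
#'
#' An `epoch_set` is one participant's cleaned, epoched EEG: a trials x
#' channels x samples array in microvolts, the sampling rate, the time of the
#' first sample relative to stimulus onset, and a face label per trial.
#' Preprocessing (referencing, filtering, artifact removal) is assumed to have
#' happened upstream; the pipeline starts from this container.
#'
#' @param data Numeric trials x channels x samples array.
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample relative to stimulus onset, in ms
#'   (non-positive for a pre-stimulus baseline).
#' @param face_label Character vector, one face id per trial.
#' @param channel_names Optional channel names (defaults to ch01, ch02, ...).
#' @param participant_id Identifier stored with the data.
#' @return A list of class `"epoch_set"`.
#' @export
epoch_set <- function(data, fs, t0, face_label,
                      channel_names = NULL, participant_id = "p01") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_fmt("epoch data must be a trials x channels x samples array")
  }
  check_number(fs, "fs")
  if (fs <= 0) stop_fmt("fs must be positive, got %g", fs)
  check_number(t0, "t0")
  d <- dim(data)
  n_samples <- d[3L]
  if (t0 > 0 || t0 + (n_samples - 1) * 1000 / fs < 0) {
    stop_fmt("epoch [%g, %g] ms does not cover stimulus onset (t = 0)",
             t0, t0 + (n_samples - 1) * 1000 / fs)
  }
  face_label <- as.character(face_label)
  if (length(face_label) != d[1L]) {
    stop_fmt("face_label has length %d but there are %d trials",
             length(face_label), d[1L])
  }
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(d[2L]))
  if (length(channel_names) != d[2L]) {
    stop_fmt("channel_names has length %d but there are %d channels",
             length(channel_names), d[2L])
  }
  structure(
    list(participant_id = as.character(participant_id), data = data,
         fs = fs, t0 = t0, face_label = face_label,
         channel_names = as.character(channel_names)),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Epoched EEG '%s': %d trials x %d channels x %d samples @ %g Hz, t0 = %g ms\n",
    x$participant_id, d[1L], d[2L], d[3L], x$fs, x$t0))
  cat(sprintf("  %d distinct face labels\n", length(unique(x$face_label))))
  invisible(x)
}

#' Write / read an epoch container
#'
#' One self-describing file per participant holding the full array plus
#' sampling metadata and labels (the split-half estimator needs whole-session
#' random splits, so per-trial files would be impractical). Round-trips are
#' lossless.
#'
#' @param x An [epoch_set].
#' @param path File path (conventionally `.rds`).
#' @return `read_epochs` returns an [epoch_set]; `write_epochs` returns
#'   `path` invisibly.
#' @export
write_epochs <- function(x, path) {
  if (!inherits(x, "epoch_set")) stop_fmt("write_epochs() expects an epoch_set")
  saveRDS(unclass(x), path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  obj <- readRDS(path)
  required <- c("participant_id", "data", "fs", "t0", "face_label",
                "channel_names")
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    stop_fmt("epoch container '%s' is missing field(s): %s", path,
             paste(missing, collapse = ", "))
  }
  epoch_set(obj$data, obj$fs, obj$t0, obj$face_label, obj$channel_names,
            obj$participant_id)
}
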