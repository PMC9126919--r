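#' Scene-level pattern extraction
#'
#' fMRI samples are mapped to stimulus / speech time through a fixed
#' hemodynamic lag (`lag_trs` TRs); the TRs falling inside an interval are
#' averaged into one multivoxel pattern per parcel.
#'
#' @name scene-patterns
NULL

# 1-based TR columns whose lag-shifted sample time falls in [onset, offset).
interval_tr_index <- function(onset_s, offset_s, tr_s, lag_trs, n_tr) {
  j <- seq_len(n_tr)
  t <- (j - 1 - lag_trs) * tr_s
  idx <- j[t >= onset_s & t < offset_s]
  idx[idx >= 1 & idx <= n_tr]
}

#' Average pattern over a time interval
#'
#' Average of the TR columns whose lag-shifted sample time lies in
#' `[onset_s, offset_s)`; when the interval covers no full TR, the single
#' TR containing the interval midpoint is used.
#'
#' @param ts A [parcel_timeseries()].
#' @param onset_s,offset_s Interval in seconds (stimulus / speech time).
#' @param lag_trs Hemodynamic lag in TRs.
#' @return Named list: one feature vector per parcel.
#' @export
interval_pattern <- function(ts, onset_s, offset_s, lag_trs = 3L) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  n_tr <- ncol(ts$data[[1]])
  idx <- interval_tr_index(onset_s, offset_s, ts$tr_s, lag_trs, n_tr)
  if (length(idx) == 0) {
    mid <- (onset_s + offset_s) / 2
    j <- lag_trs + 1L + floor(mid / ts$tr_s)
    if (j < 1 || j > n_tr) {
      stop("interval [", onset_s, ", ", offset_s,
           ") lies entirely outside the run")
    }
    idx <- j
  }
  purrr::map(ts$data, function(m) rowMeans(m[, idx, drop = FALSE]))
}

#' Scene-average patterns for one run
#'
#' Pools the lag-shifted TRs of all intervals belonging to each scene and
#' averages them. For movie runs the intervals are the scene boundaries;
#' for recall runs, the utterance times of the scenes the subject
#' described.
#'
#' @param ts A [parcel_timeseries()].
#' @param intervals Tibble with columns `scene_id`, `onset_s`, `offset_s`
#'   (several rows per scene allowed).
#' @param scene_ids Scene universe defining the output rows.
#' @param cfg An [analysis_config()] (for `lag_trs`).
#' @return Named list per parcel of scenes-by-features matrices; scenes
#'   with no covering TR are `NA` rows.
#' @export
scene_patterns <- function(ts, intervals, scene_ids, cfg = analysis_config()) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  n_tr <- ncol(ts$data[[1]])
  idx_by_scene <- purrr::map(scene_ids, function(k) {
    rows <- intervals[intervals$scene_id == k, , drop = FALSE]
    sort(unique(unlist(purrr::pmap(
      list(rows$onset_s, rows$offset_s),
      function(a, b) interval_tr_index(a, b, ts$tr_s, cfg$lag_trs, n_tr)
    ))))
  })
  purrr::map(ts$data, function(m) {
    out <- matrix(NA_real_, nrow = length(scene_ids), ncol = nrow(m))
    for (ki in seq_along(scene_ids)) {
      idx <- idx_by_scene[[ki]]
      if (length(idx) > 0) out[ki, ] <- rowMeans(m[, idx, drop = FALSE])
    }
    out
  })
}

new_scene_pattern_set <- function(parcels, recalled, subject_ids, scene_ids) {
  structure(
    list(parcels = parcels, recalled = recalled,
         subject_ids = subject_ids, scene_ids = scene_ids),
    class = "scene_pattern_set"
  )
}

#' @export
print.scene_pattern_set <- function(x, ...) {
  nf <- dim(x$parcels[[1]]$movie)[3]
  cat("<scene_pattern_set> ", length(x$subject_ids), " subjects x ",
      length(x$scene_ids), " scenes x ", length(x$parcels),
      " parcels (", nf, " features)\n",
      "  recalled cells: ", sum(x$recalled), "/", length(x$recalled),
      "\n", sep = "")
  invisible(x)
}

# Map each non-Other utterance to the scenes its segment span touches.
recall_intervals <- function(transcript, seg) {
  tr <- transcript[transcript$label != "OTHER" &
                     !is.na(transcript$start_segment), , drop = FALSE]
  map <- utterance_scene_map(tr, seg)
  dplyr::inner_join(
    map,
    tr[c("subject_id", "utterance_id", "onset_s", "offset_s")],
    by = c("subject_id", "utterance_id")
  )
}

#' Assemble a scene-pattern set from movie and recall time series
#'
#' Scene-level containers for the between-subject analyses: the movie run
#' contributes one pattern per scene for every subject; the recall run
#' contributes patterns only for scenes the subject described (any
#' non-Other utterance touching the scene counts as recalling it).
#'
#' @param movie,recall Named lists of [parcel_timeseries()] keyed by
#'   subject id (same subjects in both).
#' @param transcripts Labeled transcript tibble covering those subjects.
#' @param seg Segmentation tibble.
#' @param cfg An [analysis_config()].
#' @return A `scene_pattern_set`: per parcel, `movie` and `recall` arrays
#'   of dimension subjects x scenes x features (recall rows `NA` where
#'   unrecalled), plus the `recalled` indicator matrix.
#' @export
scene_pattern_set <- function(movie, recall, transcripts, seg,
                              cfg = analysis_config()) {
  subj_ids <- names(movie)
  if (!identical(sort(subj_ids), sort(names(recall)))) {
    stop("movie and recall runs cover different subjects")
  }
  scenes <- scene_table(seg)
  scene_ids <- scenes$scene_id
  parcel_ids <- names(movie[[1]]$data)
  ns <- length(subj_ids)
  nk <- length(scene_ids)
  nf <- nrow(movie[[1]]$data[[1]])
  rec_iv <- recall_intervals(transcripts, seg)
  recalled <- matrix(FALSE, ns, nk, dimnames = list(subj_ids, scene_ids))
  parcels <- purrr::map(parcel_ids, function(p) {
    list(movie = array(NA_real_, c(ns, nk, nf)),
         recall = array(NA_real_, c(ns, nk, nf)))
  })
  names(parcels) <- parcel_ids
  movie_iv <- scenes[c("scene_id", "onset_s", "offset_s")]
  for (si in seq_along(subj_ids)) {
    sid <- subj_ids[si]
    mp <- scene_patterns(movie[[sid]], movie_iv, scene_ids, cfg)
    sub_iv <- rec_iv[rec_iv$subject_id == sid, , drop = FALSE]
    rp <- scene_patterns(recall[[sid]], sub_iv, scene_ids, cfg)
    for (p in parcel_ids) {
      parcels[[p]]$movie[si, , ] <- mp[[p]]
      parcels[[p]]$recall[si, , ] <- rp[[p]]
    }
    recalled[si, ] <- scene_ids %in% sub_iv$scene_id &
      !is.na(rp[[parcel_ids[1]]][, 1])
  }
  new_scene_pattern_set(parcels, recalled, subj_ids, scene_ids)
}
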