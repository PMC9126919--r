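#' Utterance coding: temporal precision, compression, summary bias
#'
#' An utterance's movie-segment span determines how much movie time it
#' describes. Spans whose summed micro-segment duration exceeds the
#' threshold (10 s) are coded Summary; shorter spans are Temporally
#' Precise; utterances without a span are Other and excluded from
#' downstream analyses. Word counts exclude stop words and fillers.
#'
#' @name utterance-coding
NULL

#' Count content words
#'
#' Lowercases, strips punctuation, tokenizes on whitespace, drops stop
#' words and filler non-words, and returns the remaining token count.
#' Vectorized over `text`; empty or missing text counts 0.
#'
#' @param text Character vector.
#' @param stopwords,nonwords Character vectors of tokens to drop.
#' @return Integer vector of content-word counts.
#' @examples
#' count_content_words("Um, the the uh knife")  # 1
#' @export
count_content_words <- function(text, stopwords = default_stopwords(),
                                nonwords = default_nonwords()) {
  drop <- c(tolower(stopwords), tolower(nonwords))
  vapply(text, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(0L)
    s <- tolower(s)
    s <- gsub("[^a-z0-9' ]", " ", s)
    s <- gsub("(^|\\s)'+|'+(\\s|$)", " ", s)  # bare quotes, keep it's etc.
    toks <- strsplit(trimws(s), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    length(toks[!toks %in% drop])
  }, integer(1), USE.NAMES = FALSE)
}

#' Movie time described by a segment span
#'
#' Summed duration of the micro-segments from `start_segment` to
#' `end_segment` inclusive. Vectorized; `NA` span gives `NA`.
#'
#' @param start_segment,end_segment Integer segment ids (inclusive range).
#' @param seg Segmentation tibble.
#' @return Numeric vector of seconds.
#' @export
described_duration <- function(start_segment, end_segment, seg) {
  dur <- stats::setNames(seg$offset_s - seg$onset_s, seg$segment_id)
  ids <- seg$segment_id
  mapply(function(s, e) {
    if (is.na(s) || is.na(e)) return(NA_real_)
    if (!s %in% ids) stop("described_duration(): unknown segment id ", s)
    if (!e %in% ids) stop("described_duration(): unknown segment id ", e)
    sum(dur[as.character(ids[ids >= s & ids <= e])])
  }, start_segment, end_segment, USE.NAMES = FALSE)
}

#' Automatic temporal-precision labeling
#'
#' `OTHER` when the utterance carries no segment span; otherwise `SUMMARY`
#' when the described duration exceeds `threshold_s` and `PRECISE` when it
#' falls short. Exactly at the threshold the configured `boundary_rule`
#' applies (default `LE_PRECISE`: codes `PRECISE`).
#'
#' @inheritParams described_duration
#' @param cfg An [analysis_config()].
#' @return Character vector of labels.
#' @export
auto_label <- function(start_segment, end_segment, seg,
                       cfg = analysis_config()) {
  dur <- described_duration(start_segment, end_segment, seg)
  at_boundary <- if (cfg$boundary_rule == "LE_PRECISE") "PRECISE" else "SUMMARY"
  dplyr::case_when(
    is.na(dur) ~ "OTHER",
    dur > cfg$threshold_s ~ "SUMMARY",
    dur < cfg$threshold_s ~ "PRECISE",
    TRUE ~ at_boundary
  )
}

#' Temporal compression factor
#'
#' `1 - content_words / described_seconds`: the word rate per second of
#' described movie time, subtracted from 1 so that higher values mean more
#' temporal compression (fewer words per unit of movie time). Bounded
#' above by 1; may be negative for very wordy utterances.
#'
#' @param content_words Integer vector of content-word counts.
#' @param duration_s Described movie duration in seconds (> 0).
#' @return Numeric vector; `NA` inputs propagate.
#' @export
compute_tcf <- function(content_words, duration_s) {
  bad <- which(!is.na(duration_s) & duration_s <= 0)
  if (length(bad) > 0) {
    stop("compute_tcf(): described duration must be positive (element ",
         bad[1], ")")
  }
  1 - content_words / duration_s
}

#' Code a transcript: labels, durations, word counts, TCF
#'
#' Adds `content_words`, `described_s`, `auto_label` and `tcf` columns to a
#' transcript. `tcf` is missing for utterances without a segment span.
#'
#' @param transcript Transcript tibble (one or more subjects).
#' @param seg Segmentation tibble.
#' @param cfg An [analysis_config()].
#' @return The transcript with coding columns appended.
#' @export
code_transcript <- function(transcript, seg, cfg = analysis_config()) {
  tr <- validate_transcript(transcript)
  tr$content_words <- count_content_words(tr$text, cfg$stopwords, cfg$nonwords)
  tr$described_s <- described_duration(tr$start_segment, tr$end_segment, seg)
  tr$auto_label <- auto_label(tr$start_segment, tr$end_segment, seg, cfg)
  tr$tcf <- ifelse(is.na(tr$described_s), NA_real_,
                   compute_tcf(tr$content_words, pmax(tr$described_s, 1e-12)))
  tr
}

# Expand a coded transcript to one row per (utterance, touched scene).
# An utterance touches every scene its segment span intersects; its words
# are credited in full to each touched scene (not apportioned).
utterance_scene_map <- function(transcript, seg) {
  tr <- transcript[!is.na(transcript$start_segment) &
                     !is.na(transcript$end_segment), ]
  if (nrow(tr) == 0) {
    return(tibble::tibble(subject_id = character(), utterance_id = integer(),
                          scene_id = integer()))
  }
  # scenes are contiguous blocks of ordered segments, so the touched
  # scenes run from the start segment's scene to the end segment's scene
  scene_seq <- unique(seg$scene_id)  # in temporal order
  scene_pos <- stats::setNames(seq_along(scene_seq), scene_seq)
  p1 <- scene_pos[as.character(
    seg$scene_id[match(tr$start_segment, seg$segment_id)])]
  p2 <- scene_pos[as.character(
    seg$scene_id[match(tr$end_segment, seg$segment_id)])]
  n <- p2 - p1 + 1L
  tibble::tibble(
    subject_id = rep(tr$subject_id, n),
    utterance_id = rep(tr$utterance_id, n),
    scene_id = scene_seq[unlist(mapply(seq, p1, p2, SIMPLIFY = FALSE),
                                use.names = FALSE)]
  )
}

#' Scene-level summary bias and mean TCF
#'
#' For each subject and movie scene: word counts by label, the %Summary
#' bias `words_summary / (words_summary + words_precise)` (Other words are
#' tallied but excluded from the denominator), the mean TCF of non-Other
#' utterances touching the scene, and whether the scene was recalled
#' (touched by any non-Other utterance). All scenes are returned; scenes
#' never touched get zero counts, missing bias and `recalled = FALSE`.
#'
#' @param transcript Transcript tibble carrying labels (human or
#'   automatic; choose with `label_col`).
#' @param seg Segmentation tibble.
#' @param cfg An [analysis_config()].
#' @param label_col Column holding the precision labels (default
#'   `"label"`; use `"auto_label"` after [code_transcript()]).
#' @return A scene-behavior tibble: `subject_id`, `scene_id`,
#'   `words_summary`, `words_precise`, `words_other`, `summary_bias`,
#'   `mean_tcf`, `recalled`.
#' @export
scene_summary_bias <- function(transcript, seg, cfg = analysis_config(),
                               label_col = "label") {
  tr <- transcript
  if (!all(c("content_words", "tcf") %in% names(tr))) {
    tr <- code_transcript(tr, seg, cfg)
  }
  tr$.label <- tr[[label_col]]
  map <- utterance_scene_map(tr, seg)
  touched <- dplyr::inner_join(
    map, tr[c("subject_id", "utterance_id", ".label", "content_words", "tcf")],
    by = c("subject_id", "utterance_id")
  )
  per_scene <- touched |>
    dplyr::group_by(.data$subject_id, .data$scene_id) |>
    dplyr::summarise(
      words_summary = sum(.data$content_words[.data$.label == "SUMMARY"]),
      words_precise = sum(.data$content_words[.data$.label == "PRECISE"]),
      words_other = sum(.data$content_words[.data$.label == "OTHER"]),
      mean_tcf = if (any(.data$.label != "OTHER")) {
        mean(.data$tcf[.data$.label != "OTHER"], na.rm = TRUE)
      } else NA_real_,
      recalled = any(.data$.label != "OTHER"),
      .groups = "drop"
    )
  grid <- tidyr::expand_grid(
    subject_id = unique(transcript$subject_id),
    scene_id = sort(unique(seg$scene_id))
  )
  grid |>
    dplyr::left_join(per_scene, by = c("subject_id", "scene_id")) |>
    dplyr::mutate(
      dplyr::across(dplyr::starts_with("words_"), ~ tidyr::replace_na(.x, 0L)),
      recalled = tidyr::replace_na(.data$recalled, FALSE),
      denom = .data$words_summary + .data$words_precise,
      summary_bias = ifelse(.data$denom > 0,
                            .data$words_summary / .data$denom, NA_real_),
      mean_tcf = ifelse(is.nan(.data$mean_tcf), NA_real_, .data$mean_tcf)
    ) |>
    dplyr::select("subject_id", "scene_id", "words_summary", "words_precise",
                  "words_other", "summary_bias", "mean_tcf", "recalled")
}

#' Scene-level mean TCF
#'
#' Mean temporal compression factor over non-Other utterances touching
#' each scene, per subject; missing where no such utterance exists.
#'
#' @inheritParams scene_summary_bias
#' @return Tibble `subject_id`, `scene_id`, `mean_tcf`.
#' @export
scene_mean_tcf <- function(transcript, seg, cfg = analysis_config(),
                           label_col = "label") {
  scene_summary_bias(transcript, seg, cfg, label_col)[
    c("subject_id", "scene_id", "mean_tcf")
  ]
}

#' Overlap between Summary and Precise coverage
#'
#' Per subject, the fraction of Summary utterances whose segment span
#' intersects the union of that subject's Precise spans; missing for
#' subjects with no Summary utterances.
#'
#' @param transcript Transcript tibble.
#' @param label_col Column holding the precision labels.
#' @return Tibble `subject_id`, `n_summary`, `overlap`.
#' @export
summary_precise_overlap <- function(transcript, label_col = "label") {
  tr <- transcript
  tr$.label <- tr[[label_col]]
  tr |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(d, key) {
      smry <- d[d$.label == "SUMMARY" & !is.na(d$start_segment), ]
      prec <- d[d$.label == "PRECISE" & !is.na(d$start_segment), ]
      if (nrow(smry) == 0) {
        return(tibble::tibble(n_summary = 0L, overlap = NA_real_))
      }
      covered <- unique(unlist(mapply(seq, prec$start_segment,
                                      prec$end_segment, SIMPLIFY = FALSE)))
      hit <- mapply(function(s, e) any(seq(s, e) %in% covered),
                    smry$start_segment, smry$end_segment)
      tibble::tibble(n_summary = nrow(smry), overlap = mean(hit))
    }) |>
    dplyr::ungroup()
}

#' Agreement rate between two label sequences
#'
#' @param a,b Character vectors of equal length.
#' @return Fraction of positions with identical labels.
#' @export
label_agreement <- function(a, b) {
  if (length(a) != length(b)) {
    stop("label_agreement(): lengths differ (", length(a), " vs ",
         length(b), ")")
  }
  if (length(a) == 0) stop("label_agreement(): empty input")
  mean(a == b)
}
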