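#' Run the full analysis pipeline
#'
#' Chains every stage on a dataset in the [simulate_dataset()] layout
#' (segmentation, transcripts, neural data): utterance coding and scene
#' behavior, the text-similarity validation, the reinstatement analysis
#' (when TR-level time series are present), memory transformation and the
#' bias-transformation linking.
#'
#' @param data List with `segmentation`, `transcripts` and either
#'   `patterns` (a `scene_pattern_set`) or `neural` (TR-level `movie` /
#'   `recall` time-series lists).
#' @param cfg An [analysis_config()].
#' @param seed Optional seed governing permutations and subsampling.
#' @param text Run the text-similarity validation? Default `TRUE`.
#' @param label_col Transcript column holding the precision labels.
#' @return List: `behavior`, `text` (per-subject rows and group
#'   contrasts), `reinstatement` (or `NULL`), `transformation`, `link`,
#'   `duration_control`.
#' @export
run_pipeline <- function(data, cfg = analysis_config(), seed = NULL,
                         text = TRUE, label_col = "label") {
  seg <- data$segmentation
  transcripts <- data$transcripts
  behavior <- scene_summary_bias(transcripts, seg, cfg, label_col)
  text_res <- NULL
  if (text) {
    mm <- matched_vs_mismatched(transcripts, seg, toy_embedder(),
                                cfg, seed = seed, label_col = label_col)
    text_res <- list(per_subject = mm, contrasts = group_text_contrast(mm))
  }
  reinst <- NULL
  if (!is.null(data$neural)) {
    reinst <- reinstatement_analysis(
      data$neural$movie, data$neural$recall, transcripts, seg, cfg,
      seed = seed, label_col = label_col
    )
  }
  pset <- data$patterns
  if (is.null(pset)) {
    if (is.null(data$neural)) stop("data contains no neural component")
    pset <- scene_pattern_set(data$neural$movie, data$neural$recall,
                              transcripts, seg, cfg)
  }
  transform <- transformation_scores(pset, cfg, seed = seed)
  link <- if (any(transform$parcels$positive_t)) {
    link_bias_transformation(behavior, transform, cfg)
  } else NULL
  list(
    behavior = behavior,
    text = text_res,
    reinstatement = reinst,
    transformation = transform,
    link = link,
    duration_control = control_duration_correlation(behavior, seg, cfg)
  )
}
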