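#' Analysis configuration
#'
#' Bundle of the tunable analysis parameters, with the study defaults:
#' hemodynamic lag of 3 TRs (4.5 s at TR = 1.5 s), 10-s Summary threshold,
#' 1000 permutations, FDR q = 0.05 (q = 0.10 for the Precise-vs-Summary
#' contrast map), and a minimum of 5 recallers per scene.
#'
#' @param lag_trs Hemodynamic lag in TRs applied when mapping stimulus /
#'   speech time to fMRI samples (default 3).
#' @param threshold_s Described-duration threshold separating Temporally
#'   Precise from Summary utterances, seconds (default 10).
#' @param n_perm Number of label permutations for null distributions
#'   (default 1000).
#' @param fdr_q FDR level for condition and similarity maps (default 0.05).
#' @param contrast_fdr_q More liberal FDR level for the Precise-vs-Summary
#'   reinstatement contrast map (default 0.10).
#' @param min_recallers Scenes recalled by fewer subjects are excluded from
#'   between-subject analyses (default 5).
#' @param min_scenes Minimum scenes contributing to a per-subject
#'   correlation (default 3; a 2-point correlation is degenerately +/-1).
#' @param seed Optional integer seed recorded in the config.
#' @param stopwords Stop-word list dropped before content-word counting.
#' @param nonwords Filler tokens dropped alongside stop words.
#' @param boundary_rule Tie rule at exactly `threshold_s`: `"LE_PRECISE"`
#'   (default; exactly-at-threshold codes Temporally Precise) or
#'   `"LT_PRECISE"` (codes Summary).
#' @param perm_smoothing Use add-one smoothing in permutation p-values
#'   (default `FALSE`, the literal proportion rule).
#' @param fisher_z Average reinstatement correlations on the Fisher-z scale
#'   (default `FALSE`: plain mean of raw r, the reporting convention).
#' @param mismatch_sample Optional size of a seeded subsample of
#'   mismatching segments in the text analysis; `NULL` = use all.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(lag_trs = 3L,
                            threshold_s = 10,
                            n_perm = 1000L,
                            fdr_q = 0.05,
                            contrast_fdr_q = 0.10,
                            min_recallers = 5L,
                            min_scenes = 3L,
                            seed = NULL,
                            stopwords = default_stopwords(),
                            nonwords = default_nonwords(),
                            boundary_rule = c("LE_PRECISE", "LT_PRECISE"),
                            perm_smoothing = FALSE,
                            fisher_z = FALSE,
                            mismatch_sample = NULL) {
  boundary_rule <- match.arg(boundary_rule)
  cfg <- list(
    lag_trs = as.integer(lag_trs), threshold_s = threshold_s,
    n_perm = as.integer(n_perm), fdr_q = fdr_q,
    contrast_fdr_q = contrast_fdr_q,
    min_recallers = as.integer(min_recallers),
    min_scenes = as.integer(min_scenes), seed = seed,
    stopwords = stopwords, nonwords = nonwords,
    boundary_rule = boundary_rule, perm_smoothing = perm_smoothing,
    fisher_z = fisher_z, mismatch_sample = mismatch_sample
  )
  validate_config(structure(cfg, class = "analysis_config"))
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  if (cfg$lag_trs < 0) stop("lag_trs must be >= 0")
  if (cfg$n_perm < 1) stop("n_perm must be >= 1")
  if (cfg$fdr_q <= 0 || cfg$fdr_q >= 1) stop("fdr_q must lie in (0, 1)")
  if (cfg$threshold_s <= 0) stop("threshold_s must be positive")
  cfg
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  scalars <- x[!names(x) %in% c("stopwords", "nonwords")]
  for (nm in names(scalars)) {
    v <- scalars[[nm]]
    cat("  ", nm, ": ", if (is.null(v)) "NULL" else format(v), "\n", sep = "")
  }
  cat("  stopwords: ", length(x$stopwords), " words; nonwords: ",
      length(x$nonwords), " tokens\n", sep = "")
  invisible(x)
}

#' Read / write an analysis configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_config()]: an `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("config: unknown field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param cfg An `analysis_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Default stop-word and filler lists
#'
#' Standard English function words removed before content-word counting,
#' plus spoken fillers treated as non-words. Both lists are overridable
#' through [analysis_config()] and recorded with outputs.
#'
#' @return Character vector.
#' @export
default_stopwords <- function() {
  c(
    "a", "an", "the", "and", "or", "but", "nor", "so", "yet", "for",
    "of", "in", "on", "at", "to", "from", "by", "with", "about", "as",
    "into", "onto", "over", "under", "up", "down", "out", "off", "than",
    "then", "that", "this", "these", "those", "there", "here",
    "is", "am", "are", "was", "were", "be", "been", "being",
    "do", "does", "did", "doing", "have", "has", "had", "having",
    "will", "would", "shall", "should", "can", "could", "may", "might",
    "must", "i", "me", "my", "mine", "we", "us", "our", "ours", "you",
    "your", "yours", "he", "him", "his", "she", "her", "hers", "it",
    "its", "they", "them", "their", "theirs", "who", "whom", "whose",
    "which", "what", "when", "where", "why", "how", "not", "no", "if",
    "because", "while", "just", "very", "really", "also", "too"
  )
}

#' @rdname default_stopwords
#' @export
default_nonwords <- function() {
  c("uh", "um", "er", "mm", "hmm", "mhm", "uhh", "umm")
}
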