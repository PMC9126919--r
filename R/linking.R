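#' Linking summary bias to memory transformation
#'
#' Within every parcel that shows a positive transformation effect, each
#' subject's scene-level %Summary bias is correlated with the group
#' per-scene transformation value over the scenes that subject recalled;
#' the subject-level correlations go into a random-effects one-sample
#' t-test versus zero (two-tailed) with BH-FDR across the tested parcels.
#'
#' @name linking
NULL

#' Correlate per-subject summary bias with group scene transformation
#'
#' @param behavior Scene-behavior tibble from [scene_summary_bias()].
#' @param transform A `transformation_result` from
#'   [transformation_scores()]; only its `positive_t` parcels are tested.
#' @param cfg An [analysis_config()].
#' @param method Correlation type for the subject-level association
#'   (`"pearson"` default, `"spearman"` available).
#' @param bias_col Behavioral column to correlate (default
#'   `"summary_bias"`; `"mean_tcf"` gives the compression-factor variant).
#' @return An object of class `link_result`: list with `parcels`
#'   (per-parcel tibble: `n_subjects`, `mean_r`, `t`, `df`, `p`, `d`,
#'   `ci_low`, `ci_high`, `q_value`, `significant`, `direction`) and
#'   `subject_r` (per parcel x subject correlations).
#' @export
link_bias_transformation <- function(behavior, transform,
                                     cfg = analysis_config(),
                                     method = c("pearson", "spearman"),
                                     bias_col = "summary_bias") {
  method <- match.arg(method)
  stopifnot(inherits(transform, "transformation_result"))
  tested <- transform$parcels$parcel_id[transform$parcels$positive_t]
  if (length(tested) == 0) {
    stop("no parcel with a positive transformation score to test")
  }
  beh <- behavior[behavior$recalled & !is.na(behavior[[bias_col]]), ]
  subject_rows <- list()
  parcel_rows <- list()
  dropped <- 0L
  for (p in tested) {
    st <- transform$scene_t[transform$scene_t$parcel_id == p, ]
    joined <- dplyr::inner_join(
      beh, st[c("scene_id", "t_score")], by = "scene_id"
    )
    rs <- joined |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(
        n_scenes = dplyr::n(),
        r = if (dplyr::n() >= cfg$min_scenes) {
          if (method == "pearson") {
            pearson_r(.data[[bias_col]], .data$t_score)
          } else {
            suppressWarnings(
              stats::cor(.data[[bias_col]], .data$t_score,
                         method = "spearman")
            )
          }
        } else NA_real_,
        .groups = "drop"
      )
    dropped <- dropped + sum(is.na(rs$r))
    rs_ok <- rs[!is.na(rs$r), ]
    subject_rows[[p]] <- dplyr::mutate(rs, parcel_id = p, .before = 1)
    if (nrow(rs_ok) < 2) {
      parcel_rows[[p]] <- tibble::tibble(
        parcel_id = p, n_subjects = nrow(rs_ok), mean_r = NA_real_,
        t = NA_real_, df = NA_integer_, p = NA_real_, d = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, degenerate = NA
      )
      next
    }
    gt <- one_sample_t(rs_ok$r)
    parcel_rows[[p]] <- dplyr::bind_cols(
      tibble::tibble(parcel_id = p, n_subjects = nrow(rs_ok),
                     mean_r = mean(rs_ok$r)),
      gt[c("t", "df", "p", "d", "ci_low", "ci_high", "degenerate")]
    )
  }
  if (dropped > 0) {
    warning(dropped, " subject-parcel correlation(s) dropped ",
            "(fewer than ", cfg$min_scenes,
            " contributing scenes or constant bias)", call. = FALSE)
  }
  parcels <- dplyr::bind_rows(parcel_rows)
  fdr <- bh_fdr(parcels$p, cfg$fdr_q)
  parcels$q_value <- fdr$q_value
  parcels$significant <- fdr$rejected
  parcels$direction <- ifelse(is.na(parcels$t), NA_character_,
                              ifelse(parcels$t >= 0, "POSITIVE", "NEGATIVE"))
  structure(
    list(parcels = parcels, subject_r = dplyr::bind_rows(subject_rows),
         bias_col = bias_col, method = method, config = cfg),
    class = "link_result"
  )
}

#' @export
print.link_result <- function(x, ...) {
  p <- x$parcels
  cat("<link_result> ", nrow(p), " parcels tested (", x$bias_col, ", ",
      x$method, ")\n  significant: ",
      sum(p$significant & p$direction == "POSITIVE", na.rm = TRUE),
      " positive, ",
      sum(p$significant & p$direction == "NEGATIVE", na.rm = TRUE),
      " negative\n", sep = "")
  invisible(x)
}

#' Scene duration versus summary bias (control analysis)
#'
#' Per subject, the correlation between scene duration and summary bias
#' over the subject's recalled scenes with a defined bias, then a
#' two-tailed group t-test versus zero. Confirms (on data where it holds)
#' that summary bias is not a mere proxy for scene length.
#'
#' @param behavior Scene-behavior tibble.
#' @param seg Segmentation tibble.
#' @param cfg An [analysis_config()].
#' @return List: `subject_r` tibble and `stats` (one-row group tibble).
#' @export
control_duration_correlation <- function(behavior, seg,
                                         cfg = analysis_config()) {
  dur <- scene_table(seg)[c("scene_id", "duration_s")]
  beh <- behavior[behavior$recalled & !is.na(behavior$summary_bias), ]
  rs <- beh |>
    dplyr::inner_join(dur, by = "scene_id") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_scenes = dplyr::n(),
      r = if (dplyr::n() >= cfg$min_scenes) {
        pearson_r(.data$duration_s, .data$summary_bias)
      } else NA_real_,
      .groups = "drop"
    )
  ok <- rs[!is.na(rs$r), ]
  if (nrow(ok) < 2) {
    stop("insufficient scenes: fewer than 2 subjects have ",
         cfg$min_scenes, "+ recalled scenes with defined bias")
  }
  list(subject_r = rs, stats = one_sample_t(ok$r))
}

#' Network membership of significant parcels
#'
#' Counts above-threshold parcels per canonical network and their
#' proportion of the significant total. All seven networks are listed,
#' zeros included.
#'
#' @param parcel_ids Character or integer ids of the significant parcels.
#' @param parcellation Parcellation tibble.
#' @return Tibble: `network`, `count`, `proportion`.
#' @export
network_tally <- function(parcel_ids, parcellation) {
  p <- validate_parcellation(parcellation)
  hit <- p[p$parcel_id %in% as.integer(parcel_ids), ]
  counts <- table(factor(hit$network, levels = NETWORKS))
  total <- sum(counts)
  tibble::tibble(
    network = NETWORKS,
    count = as.integer(counts),
    proportion = if (total > 0) as.numeric(counts) / total else 0
  )
}
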