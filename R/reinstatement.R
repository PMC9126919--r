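#' Within-subject encoding-to-recall reinstatement
#'
#' For every movie micro-segment later described during recall, the
#' Pearson correlation between the segment's movie pattern and the
#' (averaged) recall pattern of the utterances describing it, computed
#' separately for segments recalled in a Temporally Precise versus a
#' Summarized manner. A segment described by both recall types yields two
#' separate reinstatement scores.
#'
#' @name reinstatement
NULL

REINSTATEMENT_CONDITIONS <- c("PRECISE", "SUMMARY")

# Per-subject reinstatement rows plus, per (parcel, condition), the full
# segment-by-segment cross-correlation matrix between movie segment
# patterns and the utterance-averaged recall patterns (the diagonal is
# the observed reinstatement; off-diagonals feed the shuffle null).
subject_reinstatement <- function(movie, recall, transcript, seg,
                                  cfg = analysis_config(),
                                  label_col = "label") {
  stopifnot(inherits(movie, "parcel_timeseries"),
            inherits(recall, "parcel_timeseries"))
  tr <- transcript
  tr$.label <- tr[[label_col]]
  tr <- tr[tr$.label %in% REINSTATEMENT_CONDITIONS &
             !is.na(tr$start_segment), , drop = FALSE]
  parcel_ids <- names(movie$data)
  empty <- tibble::tibble(
    subject_id = character(), parcel_id = character(),
    segment_id = integer(), condition = character(), r = numeric()
  )
  if (nrow(tr) == 0) return(list(rows = empty, cross = NULL))
  sid <- tr$subject_id[1]

  n_tr_m <- ncol(movie$data[[1]])
  seg_idx <- purrr::pmap(list(seg$onset_s, seg$offset_s), function(a, b) {
    idx <- interval_tr_index(a, b, movie$tr_s, cfg$lag_trs, n_tr_m)
    if (length(idx) == 0) {
      j <- cfg$lag_trs + 1L + floor(((a + b) / 2) / movie$tr_s)
      idx <- j[j >= 1 & j <= n_tr_m]
    }
    idx
  })
  movie_pats <- purrr::map(movie$data, function(m) {
    vapply(seg_idx, function(idx) rowMeans(m[, idx, drop = FALSE]),
           numeric(nrow(m)))
  })
  n_tr_r <- ncol(recall$data[[1]])
  utt_idx <- purrr::pmap(list(tr$onset_s, tr$offset_s), function(a, b) {
    idx <- interval_tr_index(a, b, recall$tr_s, cfg$lag_trs, n_tr_r)
    if (length(idx) == 0) {
      j <- cfg$lag_trs + 1L + floor(((a + b) / 2) / recall$tr_s)
      idx <- j[j >= 1 & j <= n_tr_r]
    }
    idx
  })
  utt_pats <- purrr::map(recall$data, function(m) {
    vapply(utt_idx, function(idx) rowMeans(m[, idx, drop = FALSE]),
           numeric(nrow(m)))
  })

  rows <- list()
  cross <- purrr::map(parcel_ids, function(p) list())
  names(cross) <- parcel_ids
  for (cond in REINSTATEMENT_CONDITIONS) {
    uids <- which(tr$.label == cond)
    if (length(uids) == 0) next
    # segment -> covering utterances of this condition
    cov <- list()
    for (u in uids) {
      segs <- seg$segment_id[seg$segment_id >= tr$start_segment[u] &
                               seg$segment_id <= tr$end_segment[u]]
      for (s in segs) {
        key <- as.character(s)
        cov[[key]] <- c(cov[[key]], u)
      }
    }
    if (length(cov) == 0) next
    seg_ids_cov <- as.integer(names(cov))
    ord <- order(seg_ids_cov)
    seg_ids_cov <- seg_ids_cov[ord]
    cov <- cov[ord]
    seg_rows <- match(seg_ids_cov, seg$segment_id)
    for (p in parcel_ids) {
      # average the covering utterance patterns first, then correlate
      rec_avg <- vapply(cov, function(u) {
        rowMeans(utt_pats[[p]][, u, drop = FALSE])
      }, numeric(nrow(utt_pats[[p]])))
      rec_avg <- matrix(rec_avg, nrow = nrow(utt_pats[[p]]))
      mv <- matrix(movie_pats[[p]][, seg_rows], nrow = nrow(rec_avg))
      cmat <- suppressWarnings(stats::cor(mv, rec_avg))
      cross[[p]][[cond]] <- cmat
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sid, parcel_id = p, segment_id = seg_ids_cov,
        condition = cond, r = diag(cmat)
      )
    }
  }
  list(rows = if (length(rows) > 0) dplyr::bind_rows(rows) else empty,
       cross = cross)
}

#' Micro-segment reinstatement scores for one subject
#'
#' For each micro-segment and recall type, the recall patterns of all
#' covering utterances of that type are averaged first, then correlated
#' with the segment's movie-viewing pattern. Segments never described
#' yield no rows; a segment described by both types yields two rows.
#'
#' @param movie,recall [parcel_timeseries()] for the two runs of one
#'   subject.
#' @param transcript Labeled transcript rows of that subject.
#' @param seg Segmentation tibble.
#' @param cfg An [analysis_config()].
#' @param label_col Column holding the precision labels.
#' @return Tibble: `subject_id`, `parcel_id`, `segment_id`, `condition`,
#'   `r`.
#' @export
segment_reinstatement <- function(movie, recall, transcript, seg,
                                  cfg = analysis_config(),
                                  label_col = "label") {
  subject_reinstatement(movie, recall, transcript, seg, cfg, label_col)$rows
}

#' Subject-level mean reinstatement per parcel and condition
#'
#' Arithmetic mean of the raw segment-level correlations (or Fisher-z
#' averaged and back-transformed when `cfg$fisher_z` is set).
#'
#' @param rows Output of [segment_reinstatement()] (any number of
#'   subjects).
#' @param cfg An [analysis_config()].
#' @return Tibble: `subject_id`, `parcel_id`, `condition`, `n_segments`,
#'   `mean_r`.
#' @export
condition_means <- function(rows, cfg = analysis_config()) {
  rows |>
    dplyr::group_by(.data$subject_id, .data$parcel_id, .data$condition) |>
    dplyr::summarise(
      n_segments = dplyr::n(),
      mean_r = if (cfg$fisher_z) {
        tanh(mean(atanh(pmin(pmax(.data$r, -1 + 1e-12), 1 - 1e-12))))
      } else mean(.data$r),
      .groups = "drop"
    )
}

#' Whole-sample reinstatement analysis with group statistics
#'
#' Runs [segment_reinstatement()] for every subject, averages within
#' subject, and computes per-parcel group statistics: two-tailed one-sample
#' t versus zero per condition, the paired Precise-minus-Summary contrast,
#' a permutation p-value per condition (shuffling, within each subject,
#' the assignment of utterance-averaged recall patterns to movie segments
#' `n_perm` times; one-tailed), BH-FDR across parcels at `cfg$fdr_q` for
#' the condition maps and, restricted to parcels reliable in either
#' condition map, at `cfg$contrast_fdr_q` for the contrast map.
#'
#' @param movie,recall Named lists of [parcel_timeseries()] keyed by
#'   subject id.
#' @param transcripts Labeled transcript tibble.
#' @param seg Segmentation tibble.
#' @param cfg An [analysis_config()].
#' @param seed Optional seed for the shuffle null.
#' @param label_col Column holding the precision labels.
#' @return An object of class `reinstatement_result`: list with
#'   `segments` (raw rows), `means` (subject x parcel x condition), and
#'   `parcels` (group statistics per parcel).
#' @export
reinstatement_analysis <- function(movie, recall, transcripts, seg,
                                   cfg = analysis_config(), seed = NULL,
                                   label_col = "label") {
  subj_ids <- names(movie)
  per_subj <- purrr::map(subj_ids, function(sid) {
    subject_reinstatement(
      movie[[sid]], recall[[sid]],
      transcripts[transcripts$subject_id == sid, , drop = FALSE],
      seg, cfg, label_col
    )
  })
  rows <- dplyr::bind_rows(purrr::map(per_subj, "rows"))
  means <- condition_means(rows, cfg)
  cross <- purrr::map(per_subj, "cross")
  parcels <- reinstatement_group_stats(means, cfg, seed = seed,
                                       cross = cross)
  structure(
    list(segments = rows, means = means, parcels = parcels, config = cfg),
    class = "reinstatement_result"
  )
}

# Null distribution of the group-mean reinstatement for one parcel and
# condition: within each subject, permute which segment's movie pattern
# is paired with which utterance-averaged recall pattern.
perm_null_group_mean <- function(cmats, n_perm) {
  vapply(seq_len(n_perm), function(b) {
    mean(vapply(cmats, function(m) {
      k <- nrow(m)
      mean(m[cbind(seq_len(k), sample.int(k))])
    }, numeric(1)))
  }, numeric(1))
}

#' Group statistics for reinstatement maps
#'
#' See [reinstatement_analysis()]; exposed separately so precomputed
#' subject means (and optionally the per-subject cross-correlation
#' matrices needed for the shuffle null) can be re-analyzed.
#'
#' @param means Output of [condition_means()].
#' @param cfg An [analysis_config()].
#' @param seed Optional seed.
#' @param cross Optional list (one element per subject) of per-parcel,
#'   per-condition segment-by-segment cross-correlation matrices; without
#'   it permutation p-values are `NA`.
#' @return Per-parcel tibble with condition means, t-statistics,
#'   permutation p-values, q-values and the paired contrast.
#' @export
reinstatement_group_stats <- function(means, cfg = analysis_config(),
                                      seed = NULL, cross = NULL) {
  if (cfg$n_perm < 1) stop("n_perm must be >= 1")
  parcel_ids <- sort(unique(means$parcel_id))
  with_seed_if(seed, {
    per_parcel <- purrr::map(parcel_ids, function(p) {
      mp <- means[means$parcel_id == p, ]
      wide <- tidyr::pivot_wider(
        mp[c("subject_id", "condition", "mean_r")],
        names_from = "condition", values_from = "mean_r"
      )
      get_col <- function(cond) {
        if (cond %in% names(wide)) wide[[cond]] else rep(NA_real_, nrow(wide))
      }
      prec <- get_col("PRECISE")
      smry <- get_col("SUMMARY")
      t_prec <- if (sum(!is.na(prec)) >= 2) one_sample_t(prec) else NULL
      t_smry <- if (sum(!is.na(smry)) >= 2) one_sample_t(smry) else NULL
      both <- !is.na(prec) & !is.na(smry)
      t_pair <- if (sum(both) >= 2) paired_t(prec[both], smry[both]) else NULL
      perm_p <- c(PRECISE = NA_real_, SUMMARY = NA_real_)
      if (!is.null(cross)) {
        for (cond in REINSTATEMENT_CONDITIONS) {
          cmats <- purrr::compact(purrr::map(cross, function(cs) {
            if (is.null(cs)) return(NULL)
            cs[[p]][[cond]]
          }))
          if (length(cmats) == 0) next
          observed <- mean(vapply(cmats, function(m) mean(diag(m)),
                                  numeric(1)))
          nulls <- perm_null_group_mean(cmats, cfg$n_perm)
          perm_p[cond] <- perm_pvalue(observed, nulls, cfg$perm_smoothing)
        }
      }
      tibble::tibble(
        parcel_id = p,
        mean_precise = mean(prec, na.rm = TRUE),
        mean_summary = mean(smry, na.rm = TRUE),
        t_precise = if (is.null(t_prec)) NA_real_ else t_prec$t,
        p_precise = if (is.null(t_prec)) NA_real_ else t_prec$p,
        t_summary = if (is.null(t_smry)) NA_real_ else t_smry$t,
        p_summary = if (is.null(t_smry)) NA_real_ else t_smry$p,
        t_paired = if (is.null(t_pair)) NA_real_ else t_pair$t,
        p_paired = if (is.null(t_pair)) NA_real_ else t_pair$p,
        p_perm_precise = unname(perm_p["PRECISE"]),
        p_perm_summary = unname(perm_p["SUMMARY"])
      )
    })
    out <- dplyr::bind_rows(per_parcel)
    fdr_p <- bh_fdr(out$p_perm_precise, cfg$fdr_q)
    fdr_s <- bh_fdr(out$p_perm_summary, cfg$fdr_q)
    out$q_precise <- fdr_p$q_value
    out$q_summary <- fdr_s$q_value
    out$sig_precise <- fdr_p$rejected
    out$sig_summary <- fdr_s$rejected
    # contrast map restricted to parcels reliable in either condition map
    in_mask <- out$sig_precise | out$sig_summary
    out$q_paired <- NA_real_
    out$sig_paired <- FALSE
    if (any(in_mask, na.rm = TRUE)) {
      idx <- which(in_mask)
      fdr_c <- bh_fdr(out$p_paired[idx], cfg$contrast_fdr_q)
      out$q_paired[idx] <- fdr_c$q_value
      out$sig_paired[idx] <- fdr_c$rejected
    }
    out
  })
}

#' @export
print.reinstatement_result <- function(x, ...) {
  m <- x$means |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_r = mean(.data$mean_r), .groups = "drop")
  cat("<reinstatement_result> ",
      length(unique(x$means$subject_id)), " subjects, ",
      length(unique(x$means$parcel_id)), " parcels\n", sep = "")
  for (i in seq_len(nrow(m))) {
    cat("  mean r (", m$condition[i], "): ", signif(m$mean_r[i], 3),
        "\n", sep = "")
  }
  invisible(x)
}
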