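#' Inter-subject memory transformation
#'
#' Scene-level between-subject pattern similarity in two directions:
#' movie-to-recall (MR; each subject's movie scene pattern against the
#' average recall pattern of the *other* subjects who recalled the scene)
#' and recall-to-recall (RR; the subject's own recall pattern against the
#' same leave-one-out average). If recall patterns are more similar
#' between individuals than to the original movie pattern (RR > MR), the
#' encoding-to-recall change is systematic rather than noise: the
#' transformation score is `T = RR - MR`, computed within a reliability
#' mask of parcels whose MR or RR beats a scene-label permutation null.
#'
#' @name memory-transformation
NULL

# Scenes eligible for between-subject analysis: recalled by at least
# `min_recallers` subjects.
eligible_scenes <- function(pset, cfg) {
  counts <- colSums(pset$recalled)
  which(counts >= cfg$min_recallers)
}

# For one parcel: per subject, the left-hand patterns over the eligible
# scenes that subject recalled, and the averaged-others recall patterns
# (excluding the subject) over *all* eligible scenes. The full
# cross-correlation matrix rows x all-eligible-columns supports both the
# observed diagonal cells and the common scene-relabeling null.
loo_cells <- function(pset, parcel, mode, cfg) {
  elig <- eligible_scenes(pset, cfg)
  ns <- length(pset$subject_ids)
  arr <- pset$parcels[[parcel]]
  nf <- dim(arr$movie)[3]
  out <- vector("list", ns)
  for (i in seq_len(ns)) {
    ks <- elig[pset$recalled[i, elig]]
    ks <- ks[colSums(pset$recalled[-i, ks, drop = FALSE]) >= 1]
    if (length(ks) == 0) {
      out[[i]] <- NULL
      next
    }
    left <- vapply(ks, function(k) {
      if (mode == "MR") arr$movie[i, k, ] else arr$recall[i, k, ]
    }, numeric(nf))
    right <- vapply(elig, function(k) {
      rec <- setdiff(which(pset$recalled[, k]), i)
      if (length(rec) == 0) return(rep(NA_real_, nf))
      m <- arr$recall[rec, k, , drop = FALSE]
      dim(m) <- c(length(rec), nf)
      colMeans(m)
    }, numeric(nf))
    out[[i]] <- list(
      scenes = ks,
      rows = match(ks, elig),  # position of each row scene among eligible
      left = matrix(left, nrow = nf),
      right = matrix(right, nrow = nf)
    )
  }
  structure(out, eligible = elig)
}

#' Between-subject scene-pattern similarity cells
#'
#' One correlation per (parcel, subject, eligible scene): in `MR` mode the
#' subject's movie pattern against the element-wise average of the recall
#' patterns of all other subjects who recalled the scene; in `RR` mode the
#' subject's own recall pattern against the same average. Cells exist only
#' for scenes the subject recalled (unrecalled scenes contribute no cells,
#' not zeros) on scenes recalled by at least `cfg$min_recallers` subjects.
#'
#' @param pset A `scene_pattern_set`.
#' @param mode `"MR"` or `"RR"`.
#' @param cfg An [analysis_config()].
#' @return Tibble: `parcel_id`, `subject_id`, `scene_id`, `mode`, `r`.
#' @export
between_subject_similarity <- function(pset, mode = c("MR", "RR"),
                                       cfg = analysis_config()) {
  mode <- match.arg(mode)
  if (length(eligible_scenes(pset, cfg)) == 0) {
    stop("no scene recalled by at least ", cfg$min_recallers, " subjects")
  }
  rows <- list()
  for (p in names(pset$parcels)) {
    cells <- loo_cells(pset, p, mode, cfg)
    for (i in seq_along(cells)) {
      ci <- cells[[i]]
      if (is.null(ci)) next
      r <- vapply(seq_along(ci$scenes), function(j) {
        stats::cor(ci$left[, j], ci$right[, ci$rows[j]])
      }, numeric(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parcel_id = p,
        subject_id = pset$subject_ids[i],
        scene_id = pset$scene_ids[ci$scenes],
        mode = mode,
        r = r
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Scene-label permutation test for between-subject similarity
#'
#' The observed parcel statistic is the mean similarity over all defined
#' (subject, scene) cells. Each null draw applies one common permutation
#' of the eligible scene labels to the averaged-others recall patterns
#' (the right-hand side) for every subject and recomputes the mean; a
#' common relabeling preserves the cross-subject dependence created by
#' the shared scene patterns and overlapping leave-one-out averages, so
#' null p-values are uniform under scene-exchangeable data. The
#' one-tailed p-value is the proportion of `n_perm` null means greater
#' than or equal to the observed mean; permutations are drawn
#' independently per parcel.
#'
#' @inheritParams between_subject_similarity
#' @param seed Optional seed.
#' @return Tibble: `parcel_id`, `mode`, `observed`, `p`.
#' @export
scene_label_permutation <- function(pset, mode = c("MR", "RR"),
                                    cfg = analysis_config(), seed = NULL) {
  mode <- match.arg(mode)
  if (cfg$n_perm < 1) stop("n_perm must be >= 1")
  with_seed_if(seed, {
    out <- purrr::map(names(pset$parcels), function(p) {
      cells <- loo_cells(pset, p, mode, cfg)
      n_elig <- length(attr(cells, "eligible"))
      info <- purrr::compact(purrr::map(cells, function(ci) {
        if (is.null(ci)) return(NULL)
        # rows: subject's scenes; columns: all eligible scene labels
        list(cmat = suppressWarnings(stats::cor(ci$left, ci$right)),
             rows = ci$rows)
      }))
      observed_cells <- unlist(purrr::map(info, function(x) {
        x$cmat[cbind(seq_along(x$rows), x$rows)]
      }))
      observed <- mean(observed_cells)
      nulls <- vapply(seq_len(cfg$n_perm), function(b) {
        perm <- sample.int(n_elig)
        mean(unlist(purrr::map(info, function(x) {
          x$cmat[cbind(seq_along(x$rows), perm[x$rows])]
        })), na.rm = TRUE)
      }, numeric(1))
      tibble::tibble(
        parcel_id = p, mode = mode, observed = observed,
        p = perm_pvalue(observed, nulls, cfg$perm_smoothing)
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Memory transformation scores with reliability masking
#'
#' Full parcel-wise pipeline: MR and RR similarity cells and parcel means,
#' scene-label permutation p-values for both maps, BH-FDR at `cfg$fdr_q`
#' across parcels per map, a reliability mask of parcels significant in
#' either map, the transformation score `T = RR - MR`, and per-scene group
#' transformation values (mean over subjects of the RR minus MR cell,
#' using only cells defined in both).
#'
#' @param pset A `scene_pattern_set`.
#' @param cfg An [analysis_config()].
#' @param seed Optional seed for the permutations.
#' @return An object of class `transformation_result`: list with
#'   `parcels` (per-parcel tibble: `mr`, `rr`, `p_mr`, `p_rr`, `q_mr`,
#'   `q_rr`, `in_reliability_mask`, `t_score`, `positive_t`), `scene_t`
#'   (per parcel x scene group transformation), and `cells` (the raw MR /
#'   RR cells).
#' @export
transformation_scores <- function(pset, cfg = analysis_config(),
                                  seed = NULL) {
  mr_cells <- between_subject_similarity(pset, "MR", cfg)
  rr_cells <- between_subject_similarity(pset, "RR", cfg)
  perm_mr <- scene_label_permutation(pset, "MR", cfg, seed = seed)
  perm_rr <- scene_label_permutation(pset, "RR", cfg, seed = NULL)
  fdr_mr <- bh_fdr(perm_mr$p, cfg$fdr_q)
  fdr_rr <- bh_fdr(perm_rr$p, cfg$fdr_q)
  parcels <- tibble::tibble(
    parcel_id = perm_mr$parcel_id,
    mr = perm_mr$observed,
    rr = perm_rr$observed,
    p_mr = perm_mr$p,
    p_rr = perm_rr$p,
    q_mr = fdr_mr$q_value,
    q_rr = fdr_rr$q_value,
    in_reliability_mask = fdr_mr$rejected | fdr_rr$rejected
  ) |>
    dplyr::mutate(
      t_score = .data$rr - .data$mr,
      positive_t = .data$in_reliability_mask & .data$t_score > 0
    )
  cells <- dplyr::inner_join(
    dplyr::rename(mr_cells[c("parcel_id", "subject_id", "scene_id", "r")],
                  mr = "r"),
    dplyr::rename(rr_cells[c("parcel_id", "subject_id", "scene_id", "r")],
                  rr = "r"),
    by = c("parcel_id", "subject_id", "scene_id")
  )
  scene_t <- cells |>
    dplyr::group_by(.data$parcel_id, .data$scene_id) |>
    dplyr::summarise(n_subjects = dplyr::n(),
                     t_score = mean(.data$rr - .data$mr),
                     .groups = "drop")
  structure(
    list(parcels = parcels, scene_t = scene_t, cells = cells, config = cfg),
    class = "transformation_result"
  )
}

#' @export
print.transformation_result <- function(x, ...) {
  p <- x$parcels
  cat("<transformation_result> ", nrow(p), " parcels\n",
      "  reliability mask: ", sum(p$in_reliability_mask), "/", nrow(p),
      "; positive transformation: ", sum(p$positive_t), "\n",
      "  mean MR = ", signif(mean(p$mr), 3),
      ", mean RR = ", signif(mean(p$rr), 3), "\n", sep = "")
  invisible(x)
}
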