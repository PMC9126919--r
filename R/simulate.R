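#' Synthetic study generator
#'
#' Generates movie segmentations, recall transcripts and parcel-wise
#' neural data with the statistical structure the downstream analyses
#' assume, together with exported ground truth for parameter-recovery
#' tests. Two generative regimes are supported for the encoding-to-recall
#' pattern change: idiosyncratic noise only (model 1), and an added
#' event-specific shift that is shared across subjects and scaled per
#' scene (model 2), where the shift magnitude tracks the group-mean
#' summary bias of the scene in designated "linked" parcels.
#'
#' @name synthetic-data
NULL

#' Generator configuration
#'
#' Defaults reproduce the study conditions: 17 subjects, 50 scenes with
#' log-normal durations matched to mean 57.7 s / SD 41.6 s (truncated to
#' 11-180 s), micro-segments matched to mean 3.95 s / SD 2.2 s, TR 1.5 s,
#' ~14-word utterances, 23.6% Other utterances.
#'
#' @param n_subjects Number of subjects (default 17).
#' @param n_scenes Number of coarse scenes (default 50).
#' @param scene_mean_s,scene_sd_s,scene_min_s,scene_max_s Scene-duration
#'   calibration (log-normal moments after truncation).
#' @param segment_mean_s,segment_sd_s Micro-segment duration calibration.
#'   Segment draws are truncated to `[1, 9.5]` s so that any single
#'   micro-segment can be described by a Temporally Precise utterance.
#' @param segments_per_scene Optional fixed micro-segment count per scene;
#'   `NULL` (default) draws durations until the scene is filled.
#' @param n_parcels,features_per_parcel Neural dimensions (defaults 4 and
#'   100 voxel features).
#' @param tr_s Repetition time, seconds (default 1.5).
#' @param movie_noise_sd,recall_noise_sd Subject-idiosyncratic pattern
#'   noise SDs at encoding and recall (defaults 1; the shared scene
#'   pattern has unit variance, so these set the SNR).
#' @param summary_noise_mult Multiplier on recall noise for TRs inside
#'   Summary utterances (default 2: summarized recall is noisier, which
#'   reproduces the weaker reinstatement of summarized micro-segments).
#' @param shift_base,shift_slope Event-specific shared-shift scaling:
#'   in linked parcels `c_k = shift_base + shift_slope * magnitude_k`, in
#'   all other parcels `c_k = shift_base`. `shift_base = 0` with no linked
#'   parcels gives model 1 (no shared shift anywhere).
#' @param linked_parcel_ids Integer ids of parcels whose shift magnitude
#'   tracks the scene's group-mean summary bias.
#' @param recall_signal Weight of the shared movie pattern in recall
#'   patterns (default 1; 0 makes recall unrelated to the movie and to the
#'   scene identity, a null regime for permutation calibration).
#' @param mean_words Mean content words per utterance (default 14).
#' @param summary_word_inflation Word-count multiplier for Summary
#'   utterances (default 1.5; summaries cover more movie time).
#' @param p_other Probability mass of Other utterances (default 0.236).
#' @param p_recall Per (subject, scene) recall probability (default 0.85).
#' @param bias_shape1,bias_shape2 Beta parameters of the scene-mean true
#'   summary bias (default Beta(50, 50): mild shared scene tendencies
#'   around 0.5).
#' @param bias_jitter SD of the per-subject jitter around the scene-mean
#'   bias (default 0.3: most bias variation is subject-idiosyncratic,
#'   the regime in which the random-effects linking test is calibrated;
#'   draws are clipped to [0, 1], so some subjects fully summarize or
#'   fully detail a scene).
#' @param summary_offtopic_frac Fraction of Summary-utterance words drawn
#'   from outside the covered segments' vocabulary (default 0.5;
#'   summaries paraphrase, so their text diverges from the annotations).
#' @param words_per_annotation Words per micro-segment annotation.
#' @param shared_vocab_frac Fraction of annotation words drawn from a
#'   small cross-scene shared vocabulary (default 0.1).
#' @param utterance_dur_mean,utterance_dur_sd Spoken utterance duration
#'   calibration, seconds (defaults 6.83 / 1.6).
#' @param lag_trs Hemodynamic lag baked into generated time series, TRs.
#' @param threshold_s Summary threshold used when constructing spans.
#' @param seed Optional default seed for [simulate_dataset()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 17L, n_scenes = 50L,
                       scene_mean_s = 57.7, scene_sd_s = 41.6,
                       scene_min_s = 11, scene_max_s = 180,
                       segment_mean_s = 3.95, segment_sd_s = 2.2,
                       segments_per_scene = NULL,
                       n_parcels = 4L, features_per_parcel = 100L,
                       tr_s = 1.5,
                       movie_noise_sd = 1, recall_noise_sd = 1,
                       summary_noise_mult = 2,
                       shift_base = 0, shift_slope = 1,
                       linked_parcel_ids = integer(0),
                       recall_signal = 1,
                       mean_words = 14, summary_word_inflation = 1.5,
                       p_other = 0.236, p_recall = 0.85,
                       bias_shape1 = 50, bias_shape2 = 50,
                       bias_jitter = 0.3,
                       summary_offtopic_frac = 0.5,
                       words_per_annotation = 8L,
                       shared_vocab_frac = 0.1,
                       utterance_dur_mean = 6.83, utterance_dur_sd = 1.6,
                       lag_trs = 3L, threshold_s = 10,
                       seed = NULL) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_subjects >= 2, cfg$n_scenes >= 1,
    cfg$movie_noise_sd >= 0, cfg$recall_noise_sd >= 0,
    cfg$summary_noise_mult >= 0, cfg$shift_base >= 0,
    cfg$summary_word_inflation >= 1,
    cfg$p_other >= 0, cfg$p_other < 1,
    cfg$p_recall > 0, cfg$p_recall <= 1,
    cfg$summary_offtopic_frac >= 0, cfg$summary_offtopic_frac <= 1,
    cfg$tr_s > 0, cfg$threshold_s > 0
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_subjects, " subjects, ", x$n_scenes, " scenes, ",
      x$n_parcels, " parcels x ", x$features_per_parcel, " features\n",
      "  noise sd: movie ", x$movie_noise_sd, ", recall ", x$recall_noise_sd,
      " (Summary x", x$summary_noise_mult, ")",
      "; shift c = ", x$shift_base, " + ", x$shift_slope,
      " * bias (linked: ",
      if (length(x$linked_parcel_ids)) {
        paste(x$linked_parcel_ids, collapse = ",")
      } else "none", ")\n", sep = "")
  invisible(x)
}

# Solve (meanlog, sdlog) so the [lo, hi]-truncated log-normal has the
# requested mean and sd; moments of the truncated distribution are closed
# form in the normal CDF.
truncated_lnorm_params <- function(mean, sd, lo, hi) {
  moments <- function(mu, sig) {
    a <- (log(lo) - mu) / sig
    b <- (log(hi) - mu) / sig
    z <- stats::pnorm(b) - stats::pnorm(a)
    m1 <- exp(mu + sig^2 / 2) *
      (stats::pnorm(b - sig) - stats::pnorm(a - sig)) / z
    m2 <- exp(2 * mu + 2 * sig^2) *
      (stats::pnorm(b - 2 * sig) - stats::pnorm(a - 2 * sig)) / z
    c(mean = m1, sd = sqrt(pmax(m2 - m1^2, 0)))
  }
  obj <- function(par) {
    mm <- moments(par[1], exp(par[2]))
    (mm["mean"] - mean)^2 + (mm["sd"] - sd)^2
  }
  sig0 <- sqrt(log(1 + (sd / mean)^2))
  mu0 <- log(mean) - sig0^2 / 2
  fit <- stats::optim(c(mu0, log(sig0)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(meanlog = fit$par[1], sdlog = exp(fit$par[2]))
}

# Inverse-CDF sampler for the truncated log-normal.
rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

scene_vocab <- function(k, n = 40L) paste0("scene", k, "w", seq_len(n))
shared_vocab <- function(n = 20L) paste0("common", seq_len(n))

#' Simulate a movie segmentation
#'
#' Scene durations are drawn from a log-normal calibrated so that the
#' truncated distribution matches the target mean and SD; each scene is
#' partitioned into contiguous micro-segments whose durations are drawn
#' from a log-normal matched to the micro-segment statistics and rescaled
#' to fill the scene exactly. Annotation text is sampled from a
#' scene-specific word pool plus a small shared vocabulary, so that text
#' similarity is higher within than between scenes.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed (default: use the current RNG stream).
#' @return A validated segmentation tibble.
#' @export
simulate_segmentation <- function(cfg = sim_config(), seed = NULL) {
  with_seed_if(seed, {
    sp <- truncated_lnorm_params(cfg$scene_mean_s, cfg$scene_sd_s,
                                 cfg$scene_min_s, cfg$scene_max_s)
    scene_dur <- rtrunc_lnorm(cfg$n_scenes, sp["meanlog"], sp["sdlog"],
                              cfg$scene_min_s, cfg$scene_max_s)
    gp <- truncated_lnorm_params(cfg$segment_mean_s, cfg$segment_sd_s,
                                 1, 9.5)
    shared <- shared_vocab()
    seg_rows <- vector("list", cfg$n_scenes)
    scene_onset <- 0
    seg_id <- 0L
    for (k in seq_len(cfg$n_scenes)) {
      if (!is.null(cfg$segments_per_scene)) {
        d <- rtrunc_lnorm(cfg$segments_per_scene, gp["meanlog"],
                          gp["sdlog"], 1, 9.5)
      } else {
        d <- numeric(0)
        while (sum(d) < scene_dur[k]) {
          d <- c(d, rtrunc_lnorm(8, gp["meanlog"], gp["sdlog"], 1, 9.5))
        }
        d <- d[seq_len(which(cumsum(d) >= scene_dur[k])[1])]
      }
      d <- d * scene_dur[k] / sum(d)
      vocab <- scene_vocab(k)
      ann <- vapply(seq_along(d), function(j) {
        n_shared <- stats::rbinom(1, cfg$words_per_annotation,
                                  cfg$shared_vocab_frac)
        paste(c(sample(vocab, cfg$words_per_annotation - n_shared,
                       replace = TRUE),
                sample(shared, n_shared, replace = TRUE)),
              collapse = " ")
      }, character(1))
      off <- scene_onset + cumsum(d)
      seg_rows[[k]] <- tibble::tibble(
        segment_id = seg_id + seq_along(d),
        scene_id = k,
        onset_s = c(scene_onset, off[-length(off)]),
        offset_s = off,
        annotation = ann
      )
      seg_id <- seg_id + length(d)
      scene_onset <- off[length(off)]
    }
    validate_segmentation(dplyr::bind_rows(seg_rows))
  })
}

# Build one scene's utterance spans so that the realized share of content
# words coming from Summary utterances tracks `beta` (predictive
# dithering: each next utterance takes the type that brings the running
# share closest to the target). Summary spans extend until their described
# duration exceeds the threshold; Precise spans take 1-2 segments while
# staying at or under it. A trailing sub-threshold span under beta = 1 is
# merged into the preceding Summary utterance so fully-summarized scenes
# emit only Summary utterances.
scene_utterances <- function(scene_seg, beta, cfg) {
  d <- scene_seg$offset_s - scene_seg$onset_s
  m <- length(d)
  w_s <- cfg$mean_words * cfg$summary_word_inflation
  w_p <- cfg$mean_words
  utts <- list()
  i <- 1L
  S <- 0
  P <- 0
  while (i <= m) {
    share_s <- (S + w_s) / (S + P + w_s)
    share_p <- S / (S + P + w_p)
    want_summary <- beta > 0 &&
      (abs(share_s - beta) < abs(share_p - beta) ||
         (abs(share_s - beta) == abs(share_p - beta) && beta >= 0.5))
    if (want_summary) {
      j <- i
      cum <- 0
      while (j <= m && cum <= cfg$threshold_s) {
        cum <- cum + d[j]
        j <- j + 1L
      }
      if (cum > cfg$threshold_s) {
        type <- "SUMMARY"
      } else if (length(utts) > 0 &&
                 utts[[length(utts)]]$label == "SUMMARY") {
        # short scene tail: absorb into the previous Summary span
        utts[[length(utts)]]$end <- m
        break
      } else {
        type <- "PRECISE"
      }
      span <- c(i, j - 1L)
    } else {
      take <- 1L + stats::rbinom(1, 1, 0.5)
      j <- i
      cum <- 0
      cnt <- 0L
      while (j <= m && cnt < take && cum + d[j] <= cfg$threshold_s) {
        cum <- cum + d[j]
        j <- j + 1L
        cnt <- cnt + 1L
      }
      if (cnt == 0L) {  # a single over-threshold segment: forced Summary
        j <- i + 1L
        type <- "SUMMARY"
      } else {
        type <- "PRECISE"
      }
      span <- c(i, j - 1L)
    }
    n_words <- max(1L, stats::rpois(1, if (type == "SUMMARY") w_s else w_p))
    utts[[length(utts) + 1L]] <- list(
      label = type, start = span[1], end = span[2], n_words = n_words
    )
    if (type == "SUMMARY") S <- S + n_words else P <- P + n_words
    i <- j
  }
  utts
}

# Content-word text for an utterance: drawn from the covered segments'
# annotation pools; Summary utterances replace a fraction with off-topic
# words (other scenes / shared vocabulary), emulating paraphrase.
utterance_text <- function(u, scene_seg, offtopic_pool, cfg) {
  pool <- unlist(strsplit(
    scene_seg$annotation[seq(u$start, u$end)], "\\s+"
  ))
  n_off <- if (u$label == "SUMMARY") {
    stats::rbinom(1, u$n_words, cfg$summary_offtopic_frac)
  } else 0L
  words <- c(sample(pool, u$n_words - n_off, replace = TRUE),
             if (n_off > 0) sample(offtopic_pool, n_off, replace = TRUE))
  words <- sample(words)
  # sprinkle two stop words; they are removed again by content counting
  paste(c("the", words[1], "and", words[-1]), collapse = " ")
}

other_utterance_text <- function(cfg) {
  fillers <- c("okay", "wait", "think", "maybe", "forgot", "anyway",
               "remember", "something", "happened", "next")
  paste(c("um", sample(fillers, 5, replace = TRUE), "uh"), collapse = " ")
}

#' Simulate recall transcripts with ground truth
#'
#' Per subject and scene, a true summary bias in `[0, 1]` is drawn
#' (scene-mean Beta(2,2) plus subject jitter); utterance spans are
#' constructed so that Summary spans exceed the duration threshold,
#' Precise spans do not, and the realized share of content words from
#' Summary utterances tracks the true bias. Word counts are Poisson,
#' inflated for Summary; Other utterances (no segment span) are
#' interleaved with probability `p_other`; utterance text is sampled from
#' the covered segments' annotation pools.
#'
#' @param cfg A [sim_config()].
#' @param seg Segmentation tibble from [simulate_segmentation()].
#' @param seed Optional seed.
#' @return List with `transcripts` (tidy utterance tibble over all
#'   subjects) and `truth` (list: `true_bias` tibble with `subject_id`,
#'   `scene_id`, `bias` (the true summary word share of the constructed
#'   utterances), `target_bias` (the latent tendency the construction
#'   aimed for; short scenes cannot realize mid-range targets, so the two
#'   differ most there), `recalled`; `scene_bias_mean`;
#'   `scene_shift_magnitude`, proportional to the group-mean bias;
#'   `linked_parcels`; `model`).
#' @export
simulate_transcripts <- function(cfg = sim_config(), seg, seed = NULL) {
  with_seed_if(seed, {
    scenes <- scene_table(seg)
    short <- scenes$duration_s <= cfg$threshold_s
    if (any(short)) {
      warning(sum(short), " scene(s) too short to admit a Summary span; ",
              "their true bias is set to 0", call. = FALSE)
    }
    mu <- stats::rbeta(nrow(scenes), cfg$bias_shape1, cfg$bias_shape2)
    mu[short] <- 0
    offtopic <- lapply(scenes$scene_id, function(k) {
      c(unlist(lapply(setdiff(scenes$scene_id, k), scene_vocab)),
        shared_vocab())
    })
    names(offtopic) <- as.character(scenes$scene_id)

    subj_ids <- sprintf("sub%02d", seq_len(cfg$n_subjects))
    truth_rows <- list()
    tr_rows <- list()
    for (si in seq_along(subj_ids)) {
      sid <- subj_ids[si]
      target <- pmin(1, pmax(0, mu + stats::rnorm(nrow(scenes), 0,
                                                  cfg$bias_jitter)))
      target[short] <- 0
      bias <- target
      recalled <- stats::runif(nrow(scenes)) < cfg$p_recall
      u_text <- character(0)
      u_start <- integer(0)
      u_end <- integer(0)
      u_label <- character(0)
      for (ki in which(recalled)) {
        k <- scenes$scene_id[ki]
        scene_seg <- seg[seg$scene_id == k, ]
        utts <- scene_utterances(scene_seg, target[ki], cfg)
        words <- vapply(utts, function(u) u$n_words, numeric(1))
        is_sum <- vapply(utts, function(u) u$label == "SUMMARY", logical(1))
        bias[ki] <- sum(words[is_sum]) / sum(words)
        u_text <- c(u_text, vapply(utts, utterance_text, character(1),
                                   scene_seg = scene_seg,
                                   offtopic_pool = offtopic[[as.character(k)]],
                                   cfg = cfg))
        u_start <- c(u_start, scene_seg$segment_id[
          vapply(utts, function(u) u$start, integer(1))])
        u_end <- c(u_end, scene_seg$segment_id[
          vapply(utts, function(u) u$end, integer(1))])
        u_label <- c(u_label, vapply(utts, function(u) u$label, character(1)))
      }
      truth_rows[[si]] <- tibble::tibble(
        subject_id = sid, scene_id = scenes$scene_id,
        bias = bias, target_bias = target, recalled = recalled
      )
      n_content <- length(u_text)
      if (n_content == 0) next
      n_other <- if (cfg$p_other > 0) {
        stats::rbinom(1, n_content, cfg$p_other / (1 - cfg$p_other))
      } else 0L
      n_tot <- n_content + n_other
      other_at <- sample.int(n_tot, n_other)
      text <- character(n_tot)
      start <- rep(NA_integer_, n_tot)
      end <- rep(NA_integer_, n_tot)
      label <- character(n_tot)
      content_at <- setdiff(seq_len(n_tot), other_at)
      text[content_at] <- u_text
      start[content_at] <- u_start
      end[content_at] <- u_end
      label[content_at] <- u_label
      if (n_other > 0) {
        text[other_at] <- vapply(seq_len(n_other), function(o) {
          other_utterance_text(cfg)
        }, character(1))
        label[other_at] <- "OTHER"
      }
      dur <- pmax(2, stats::rnorm(n_tot, cfg$utterance_dur_mean,
                                  cfg$utterance_dur_sd))
      off <- cumsum(dur + 0.3)
      tr_rows[[si]] <- tibble::tibble(
        subject_id = sid, utterance_id = seq_len(n_tot),
        onset_s = off - dur, offset_s = off, text = text,
        start_segment = start, end_segment = end, label = label
      )
    }
    transcripts <- validate_transcript(dplyr::bind_rows(tr_rows))
    true_bias <- dplyr::bind_rows(truth_rows)
    scene_bias_mean <- tapply(true_bias$bias, true_bias$scene_id, mean)
    model <- if (cfg$shift_base == 0 &&
                 (cfg$shift_slope == 0 ||
                    length(cfg$linked_parcel_ids) == 0)) "MODEL1" else "MODEL2"
    list(
      transcripts = transcripts,
      truth = list(
        true_bias = true_bias,
        scene_bias_mean = scene_bias_mean,
        scene_shift_magnitude = scene_bias_mean,
        linked_parcels = cfg$linked_parcel_ids,
        model = model
      )
    )
  })
}

# Per-parcel shift scale c_k.
parcel_shift_scale <- function(cfg, truth, parcel_id) {
  if (parcel_id %in% cfg$linked_parcel_ids) {
    cfg$shift_base + cfg$shift_slope * as.numeric(truth$scene_shift_magnitude)
  } else {
    rep(cfg$shift_base, length(truth$scene_shift_magnitude))
  }
}

#' Simulate scene-level neural patterns directly
#'
#' The generative core: for each parcel and scene `k`, a shared movie
#' pattern `m_k` (standard normal over features); subject `i`'s movie
#' pattern is `m_k + eta_ik` with idiosyncratic noise SD `movie_noise_sd`;
#' the recall pattern of a recalled scene is `recall_signal * m_k + c_k *
#' s_k + eps_ik` where `s_k` is a shared unit-normal shift drawn once per
#' (parcel, scene) and `c_k = shift_base + shift_slope * magnitude_k` in
#' linked parcels (`shift_base` elsewhere). Noise is drawn once per
#' (subject, scene), so scene-level TR averages of the generated time
#' series equal these patterns exactly. The Summary noise multiplier is a
#' TR-level feature of [simulate_neural()] and is not applied here.
#'
#' @param cfg A [sim_config()].
#' @param truth Ground-truth list from [simulate_transcripts()].
#' @param seed Optional seed.
#' @param keep_components Also return the generative components (`m`, `s`,
#'   `eta`, `eps`) for time-series construction.
#' @return A `scene_pattern_set` (see [scene_pattern_set()]).
#' @export
simulate_scene_patterns <- function(cfg = sim_config(), truth, seed = NULL,
                                    keep_components = FALSE) {
  with_seed_if(seed, {
    tb <- truth$true_bias
    subj_ids <- unique(tb$subject_id)
    scene_ids <- sort(unique(tb$scene_id))
    ns <- length(subj_ids)
    nk <- length(scene_ids)
    nf <- cfg$features_per_parcel
    recalled <- matrix(FALSE, ns, nk, dimnames = list(subj_ids, scene_ids))
    recalled[cbind(match(tb$subject_id, subj_ids),
                   match(tb$scene_id, scene_ids))] <- tb$recalled
    parcels <- list()
    components <- list()
    for (p in seq_len(cfg$n_parcels)) {
      ck <- parcel_shift_scale(cfg, truth, p)
      m <- matrix(stats::rnorm(nk * nf), nk, nf)
      s <- matrix(stats::rnorm(nk * nf), nk, nf)
      eta <- array(stats::rnorm(ns * nk * nf, sd = cfg$movie_noise_sd),
                   dim = c(ns, nk, nf))
      eps <- array(stats::rnorm(ns * nk * nf, sd = cfg$recall_noise_sd),
                   dim = c(ns, nk, nf))
      movie <- array(NA_real_, dim = c(ns, nk, nf))
      recall <- array(NA_real_, dim = c(ns, nk, nf))
      for (i in seq_len(ns)) {
        movie[i, , ] <- m + eta[i, , ]
        rec <- cfg$recall_signal * m + ck * s + eps[i, , ]
        rec[!recalled[i, ], ] <- NA_real_
        recall[i, , ] <- rec
      }
      parcels[[as.character(p)]] <- list(movie = movie, recall = recall)
      if (keep_components) {
        components[[as.character(p)]] <-
          list(m = m, s = s, eta = eta, eps = eps, ck = ck)
      }
    }
    out <- new_scene_pattern_set(parcels, recalled, subj_ids, scene_ids)
    if (keep_components) attr(out, "components") <- components
    out
  })
}

#' Simulate parcel-wise fMRI time series for movie and recall runs
#'
#' Lays the scene-level generative patterns onto TR grids. Movie-run TRs
#' whose lag-shifted stimulus time falls inside scene `k` carry that
#' subject's movie pattern for `k`; recall-run TRs inside a non-Other
#' utterance about scene `k` carry the recall pattern, with the
#' idiosyncratic noise component scaled by `summary_noise_mult` inside
#' Summary utterances. TRs outside any scene or utterance (and inside
#' Other utterances) are pure noise.
#'
#' @param cfg A [sim_config()].
#' @param seg Segmentation tibble.
#' @param transcripts Transcript tibble from [simulate_transcripts()].
#' @param truth Matching ground-truth list.
#' @param seed Optional seed.
#' @return List: `movie` and `recall` (named lists of
#'   [parcel_timeseries()] per subject) and `patterns` (the underlying
#'   `scene_pattern_set`).
#' @export
simulate_neural <- function(cfg = sim_config(), seg, transcripts, truth,
                            seed = NULL) {
  with_seed_if(seed, {
    pset <- simulate_scene_patterns(cfg, truth, seed = NULL,
                                    keep_components = TRUE)
    comp <- attr(pset, "components")
    scenes <- scene_table(seg)
    content <- transcripts[!is.na(transcripts$start_segment), ]
    unknown <- setdiff(unique(c(content$start_segment, content$end_segment)),
                       seg$segment_id)
    if (length(unknown) > 0) {
      stop("transcript references segment/scene absent from the ",
           "segmentation: ", paste(utils::head(unknown, 3), collapse = ", "))
    }
    subj_ids <- pset$subject_ids
    nf <- cfg$features_per_parcel
    lag <- cfg$lag_trs
    movie_end <- max(seg$offset_s)
    n_tr_movie <- ceiling(movie_end / cfg$tr_s) + lag
    # 0-based TR j samples stimulus time (j - lag) * tr_s
    tr_time <- (seq_len(n_tr_movie) - 1 - lag) * cfg$tr_s
    scene_of_tr <- rep(NA_integer_, n_tr_movie)
    for (ki in seq_len(nrow(scenes))) {
      inside <- tr_time >= scenes$onset_s[ki] & tr_time < scenes$offset_s[ki]
      scene_of_tr[inside] <- ki
    }
    movie_ts <- list()
    recall_ts <- list()
    for (si in seq_along(subj_ids)) {
      sid <- subj_ids[si]
      mdata <- list()
      for (p in names(pset$parcels)) {
        mat <- matrix(stats::rnorm(nf * n_tr_movie, sd = cfg$movie_noise_sd),
                      nf, n_tr_movie)
        for (ki in seq_len(nrow(scenes))) {
          cols <- which(scene_of_tr == ki)
          if (length(cols) > 0) {
            mat[, cols] <- pset$parcels[[p]]$movie[si, ki, ]
          }
        }
        mdata[[p]] <- mat
      }
      movie_ts[[sid]] <- parcel_timeseries(sid, "MOVIE", cfg$tr_s, mdata)

      utt <- transcripts[transcripts$subject_id == sid, ]
      rec_end <- if (nrow(utt) > 0) max(utt$offset_s) else cfg$tr_s
      n_tr_rec <- ceiling(rec_end / cfg$tr_s) + lag
      rt <- (seq_len(n_tr_rec) - 1 - lag) * cfg$tr_s
      rdata <- list()
      for (p in names(pset$parcels)) {
        cm <- comp[[p]]
        mat <- matrix(stats::rnorm(nf * n_tr_rec, sd = cfg$recall_noise_sd),
                      nf, n_tr_rec)
        for (ui in seq_len(nrow(utt))) {
          cols <- which(rt >= utt$onset_s[ui] & rt < utt$offset_s[ui])
          if (length(cols) == 0) next
          if (utt$label[ui] == "OTHER") next  # stays pure noise
          ki <- match(seg$scene_id[match(utt$start_segment[ui],
                                         seg$segment_id)],
                      pset$scene_ids)
          mult <- if (utt$label[ui] == "SUMMARY") cfg$summary_noise_mult else 1
          pat <- cfg$recall_signal * cm$m[ki, ] + cm$ck[ki] * cm$s[ki, ] +
            mult * cm$eps[si, ki, ]
          mat[, cols] <- pat
        }
        rdata[[p]] <- mat
      }
      recall_ts[[sid]] <- parcel_timeseries(sid, "RECALL", cfg$tr_s, rdata)
    }
    list(movie = movie_ts, recall = recall_ts, patterns = pset)
  })
}

#' Simulate a complete study
#'
#' Chains [simulate_segmentation()], [simulate_transcripts()] and the
#' neural generator under one seed. With `neural = "patterns"` only the
#' scene-level pattern set is generated (fast path for between-subject
#' analyses); `"timeseries"` additionally lays out full TR series.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed (defaults to `cfg$seed`).
#' @param neural One of `"timeseries"`, `"patterns"`, `"none"`.
#' @return List: `segmentation`, `transcripts`, `truth`, `patterns`,
#'   `neural` (or `NULL`), `config`.
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = cfg$seed,
                             neural = c("timeseries", "patterns", "none")) {
  neural <- match.arg(neural)
  with_seed_if(seed, {
    seg <- simulate_segmentation(cfg)
    tt <- simulate_transcripts(cfg, seg)
    patterns <- NULL
    ts <- NULL
    if (neural == "patterns") {
      patterns <- simulate_scene_patterns(cfg, tt$truth)
    } else if (neural == "timeseries") {
      ts <- simulate_neural(cfg, seg, tt$transcripts, tt$truth)
      patterns <- ts$patterns
      ts$patterns <- NULL
    }
    list(
      segmentation = seg,
      transcripts = tt$transcripts,
      truth = tt$truth,
      patterns = patterns,
      neural = ts,
      config = cfg
    )
  })
}
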