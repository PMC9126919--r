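# Shared fixtures and independent oracles, built in code at test time.

# Minimal two-scene segmentation: 5 micro-segments, scene 1 = [0, 13),
# scene 2 = [13, 25).
tiny_segmentation <- function() {
  tibble::tibble(
    segment_id = 1:5,
    scene_id = c(1L, 1L, 1L, 2L, 2L),
    onset_s = c(0, 4, 9, 13, 20),
    offset_s = c(4, 9, 13, 20, 25),
    annotation = c("red door opens slowly", "man walks outside",
                   "rain falls hard", "woman reads letter",
                   "phone rings twice")
  )
}

tiny_transcript <- function() {
  tibble::tibble(
    subject_id = "s1",
    utterance_id = 1:3,
    onset_s = c(0, 6, 12),
    offset_s = c(5, 11, 17),
    text = c("the door opened and a man walked out",
             "someone was reading a letter",
             "um i think that was it"),
    start_segment = c(1L, 4L, NA),
    end_segment = c(2L, 4L, NA),
    label = c("SUMMARY", "PRECISE", "OTHER")
  )
}

# A constant-pattern parcel time series for interval-averaging checks.
constant_timeseries <- function(value = 1, n_feat = 4, n_tr = 20,
                                tr_s = 1.5, subject = "s1", run = "MOVIE") {
  parcel_timeseries(subject, run, tr_s, list(
    `1` = matrix(value, n_feat, n_tr)
  ))
}

# Fully-recalled ground truth for direct scene-pattern simulation.
flat_truth <- function(n_subjects, n_scenes, bias = 0.5) {
  tb <- tidyr::expand_grid(
    subject_id = sprintf("s%02d", seq_len(n_subjects)),
    scene_id = seq_len(n_scenes)
  )
  tb$bias <- bias
  tb$target_bias <- bias
  tb$recalled <- TRUE
  list(
    true_bias = tb,
    scene_bias_mean = rep(mean(bias), n_scenes),
    scene_shift_magnitude = rep(mean(bias), n_scenes),
    linked_parcels = integer(0),
    model = "MODEL2"
  )
}

# Independent straight-loop oracle for the transformation statistic:
# plain nested loops, no shared code with the implementation.
oracle_transformation <- function(pset, min_recallers) {
  n_sub <- length(pset$subject_ids)
  out <- numeric(0)
  for (p in names(pset$parcels)) {
    arr <- pset$parcels[[p]]
    mr_vals <- c()
    rr_vals <- c()
    for (k in seq_along(pset$scene_ids)) {
      recallers <- which(pset$recalled[, k])
      if (length(recallers) < min_recallers) next
      for (i in recallers) {
        others <- recallers[recallers != i]
        if (length(others) == 0) next
        avg <- rep(0, dim(arr$recall)[3])
        for (j in others) avg <- avg + arr$recall[j, k, ]
        avg <- avg / length(others)
        mr_vals <- c(mr_vals, stats::cor(arr$movie[i, k, ], avg))
        rr_vals <- c(rr_vals, stats::cor(arr$recall[i, k, ], avg))
      }
    }
    out[p] <- mean(rr_vals) - mean(mr_vals)
  }
  out
}

# Brute-force Benjamini-Hochberg step-up: find the largest i with
# p_(i) <= i * q / m by direct enumeration, reject everything at or below.
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) {
    if (p[ord[i]] <= i * q / m) k <- i
  }
  rejected <- rep(FALSE, m)
  if (k > 0) rejected[ord[seq_len(k)]] <- TRUE
  rejected
}

# Closed-form expected between-subject similarity under the shared-shift
# model with n recallers, shift scale c and noise SDs (sm, sr).
expected_mr <- function(sm, sr, c, n) {
  1 / sqrt((1 + sm^2) * (1 + c^2 + sr^2 / (n - 1)))
}
expected_rr <- function(sm, sr, c, n) {
  (1 + c^2) / sqrt((1 + c^2 + sr^2) * (1 + c^2 + sr^2 / (n - 1)))
}

# Hand-built scene-pattern sets for transformation checks.
make_pset <- function(n_sub, n_scene, n_feat, n_parcel = 1, seed = 1,
                      recall = c("copy", "noise", "shift"),
                      recalled = NULL) {
  recall <- match.arg(recall)
  withr::with_seed(seed, {
    subj <- sprintf("s%02d", seq_len(n_sub))
    if (is.null(recalled)) {
      recalled <- matrix(TRUE, n_sub, n_scene,
                         dimnames = list(subj, seq_len(n_scene)))
    }
    parcels <- purrr::map(seq_len(n_parcel), function(p) {
      movie <- array(rnorm(n_sub * n_scene * n_feat),
                     dim = c(n_sub, n_scene, n_feat))
      rec <- switch(recall,
        copy = movie,
        noise = array(rnorm(n_sub * n_scene * n_feat),
                      dim = c(n_sub, n_scene, n_feat)),
        shift = {
          m <- array(rnorm(n_scene * n_feat), dim = c(n_scene, n_feat))
          s <- array(rnorm(n_scene * n_feat), dim = c(n_scene, n_feat))
          out <- array(NA_real_, dim = c(n_sub, n_scene, n_feat))
          for (i in seq_len(n_sub)) {
            out[i, , ] <- m + s + matrix(rnorm(n_scene * n_feat),
                                         n_scene, n_feat)
          }
          out
        }
      )
      for (i in seq_len(n_sub)) rec[i, !recalled[i, ], ] <- NA_real_
      list(movie = movie, recall = rec)
    })
    names(parcels) <- as.character(seq_len(n_parcel))
    retellr:::new_scene_pattern_set(parcels, recalled, subj,
                                    seq_len(n_scene))
  })
}

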