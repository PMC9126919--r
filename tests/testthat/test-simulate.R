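test_that("simulated segmentations have forced counts and structure", {
  cfg <- sim_config(n_scenes = 2, segments_per_scene = 3)
  seg <- simulate_segmentation(cfg, seed = 1)
  expect_equal(nrow(seg), 6)
  expect_equal(nrow(scene_table(seg)), 2)
  # contiguity already enforced by the validator it passes through
  expect_silent(validate_segmentation(seg))
})

test_that("identical seeds reproduce every output bit-for-bit", {
  cfg <- sim_config(n_subjects = 3, n_scenes = 4, n_parcels = 2,
                    features_per_parcel = 12)
  d1 <- simulate_dataset(cfg, seed = 7, neural = "timeseries")
  d2 <- simulate_dataset(cfg, seed = 7, neural = "timeseries")
  expect_identical(d1, d2)
  d3 <- simulate_dataset(cfg, seed = 8, neural = "none")
  expect_false(identical(d1$segmentation, d3$segmentation))
})

test_that("scene durations match the calibrated truncated log-normal", {
  cfg <- sim_config(n_scenes = 4000)
  seg <- simulate_segmentation(cfg, seed = 3)
  dur <- scene_table(seg)$duration_s
  expect_true(all(dur >= cfg$scene_min_s - 1e-9))
  expect_true(all(dur <= cfg$scene_max_s + 1e-9))
  se <- sd(dur) / sqrt(length(dur))
  expect_lt(abs(mean(dur) - 57.7), 3 * se)
  # SD lands near the target too (5% is ample for 4000 draws)
  expect_lt(abs(sd(dur) - 41.6) / 41.6, 0.05)
  # micro-segments average about 4 s
  seg_dur <- seg$offset_s - seg$onset_s
  expect_lt(abs(mean(seg_dur) - 4), 0.75)
})

test_that("extreme true bias forces pure utterance types", {
  cfg <- sim_config(n_subjects = 2, n_scenes = 1, scene_mean_s = 30,
                    scene_sd_s = 1e-3, scene_min_s = 29, scene_max_s = 31,
                    p_other = 0, p_recall = 1, bias_jitter = 0)
  seg <- simulate_segmentation(cfg, seed = 2)

  cfg1 <- cfg
  cfg1$bias_shape1 <- 1e6   # scene-mean bias ~ 1
  cfg1$bias_shape2 <- 1e-6
  tt <- simulate_transcripts(cfg1, seg, seed = 5)
  expect_true(all(tt$transcripts$label == "SUMMARY"))
  coded <- code_transcript(tt$transcripts, seg)
  expect_true(all(coded$described_s > 10))

  cfg0 <- cfg
  cfg0$bias_shape1 <- 1e-6  # scene-mean bias ~ 0
  cfg0$bias_shape2 <- 1e6
  tt0 <- simulate_transcripts(cfg0, seg, seed = 5)
  expect_true(all(tt0$transcripts$label == "PRECISE"))
  coded0 <- code_transcript(tt0$transcripts, seg)
  expect_true(all(coded0$described_s <= 10))
})

test_that("automatic labels reproduce ground truth exactly with p_other 0", {
  for (rep in 1:3) {
    cfg <- sim_config(n_subjects = 5, n_scenes = 6, p_other = 0)
    d <- simulate_dataset(cfg, seed = 40 + rep, neural = "none")
    coded <- code_transcript(d$transcripts, d$segmentation)
    expect_identical(coded$auto_label, coded$label)
  }
})

test_that("recomputed scene bias recovers exported ground truth", {
  devs <- c()
  for (rep in 1:20) {
    cfg <- sim_config(n_subjects = 6, n_scenes = 6)
    d <- simulate_dataset(cfg, seed = 300 + rep, neural = "none")
    beh <- scene_summary_bias(d$transcripts, d$segmentation)
    j <- dplyr::inner_join(
      beh, d$truth$true_bias, by = c("subject_id", "scene_id"),
      suffix = c("", ".truth")
    )
    j <- j[j$recalled.truth & !is.na(j$summary_bias), ]
    devs <- c(devs, abs(j$summary_bias - j$bias))
  }
  expect_lt(mean(devs), 0.1)
})

test_that("short scenes draw bias 0 with a warning", {
  cfg <- sim_config(n_subjects = 2, n_scenes = 3, scene_mean_s = 6,
                    scene_sd_s = 1, scene_min_s = 4, scene_max_s = 8,
                    p_recall = 1)
  seg <- simulate_segmentation(cfg, seed = 9)
  expect_warning(tt <- simulate_transcripts(cfg, seg, seed = 10),
                 "too short")
  expect_true(all(tt$truth$true_bias$bias == 0))
  expect_true(all(tt$transcripts$label != "SUMMARY"))
})

test_that("noiseless generation makes recall equal movie patterns", {
  cfg <- sim_config(n_subjects = 2, n_scenes = 3, n_parcels = 1,
                    features_per_parcel = 15, movie_noise_sd = 0,
                    recall_noise_sd = 0, shift_base = 0, shift_slope = 0,
                    p_other = 0, p_recall = 1, summary_noise_mult = 1)
  d <- simulate_dataset(cfg, seed = 17, neural = "timeseries")
  pset <- d$patterns
  expect_equal(pset$parcels[[1]]$movie, pset$parcels[[1]]$recall)
  rows <- segment_reinstatement(
    d$neural$movie[[1]], d$neural$recall[[1]],
    d$transcripts[d$transcripts$subject_id == "sub01", ], d$segmentation
  )
  expect_true(all(abs(rows$r - 1) < 1e-12))
})

test_that("transcripts referencing unknown scenes are rejected", {
  cfg <- sim_config(n_subjects = 2, n_scenes = 2, features_per_parcel = 5,
                    n_parcels = 1)
  d <- simulate_dataset(cfg, seed = 23, neural = "none")
  bad <- d$transcripts
  bad$start_segment[which(!is.na(bad$start_segment))[1]] <- 999L
  bad$end_segment[which(!is.na(bad$end_segment))[1]] <- 999L
  expect_error(
    simulate_neural(cfg, d$segmentation, bad, d$truth, seed = 1),
    "absent from"
  )
})

test_that("scene-pattern shortcut agrees with TR-level scene averages", {
  cfg <- sim_config(n_subjects = 3, n_scenes = 4, n_parcels = 2,
                    features_per_parcel = 10, p_other = 0, p_recall = 1,
                    summary_noise_mult = 1)
  d <- simulate_dataset(cfg, seed = 29, neural = "timeseries")
  rebuilt <- scene_pattern_set(d$neural$movie, d$neural$recall,
                               d$transcripts, d$segmentation,
                               analysis_config(lag_trs = cfg$lag_trs))
  for (p in names(rebuilt$parcels)) {
    expect_equal(rebuilt$parcels[[p]]$movie, d$patterns$parcels[[p]]$movie,
                 tolerance = 1e-10)
    expect_equal(rebuilt$parcels[[p]]$recall, d$patterns$parcels[[p]]$recall,
                 tolerance = 1e-10)
  }
  expect_equal(rebuilt$recalled, d$patterns$recalled)
})
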