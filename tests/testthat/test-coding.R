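test_that("content-word counting folds case, punctuation and fillers", {
  expect_equal(count_content_words("the detective is clever",
                                   stopwords = c("the", "is")), 2L)
  expect_equal(count_content_words(""), 0L)
  expect_equal(count_content_words(NA_character_), 0L)
  expect_equal(count_content_words("Um, the the uh knife"), 1L)
  # vectorized
  expect_equal(count_content_words(c("a knife", "two knives")), c(1L, 2L))
})

test_that("described duration sums the covered micro-segments", {
  seg <- tiny_segmentation()
  expect_equal(described_duration(1L, 2L, seg), 9)   # 4 s + 5 s
  expect_equal(described_duration(2L, 2L, seg), 5)
  # whole-range completeness: equals total movie duration
  expect_equal(described_duration(1L, 5L, seg), 25)
  expect_true(is.na(described_duration(NA, NA, seg)))
  expect_error(described_duration(1L, 99L, seg), "unknown segment")
})

test_that("automatic labels follow the 10-s rule with configurable ties", {
  seg <- tiny_segmentation()
  # 1..3 described = 13 s -> SUMMARY; 2..2 = 5 s -> PRECISE
  expect_equal(auto_label(c(1L, 2L, NA), c(3L, 2L, NA), seg),
               c("SUMMARY", "PRECISE", "OTHER"))
  # segments 1..2 span 9 s < 10 -> PRECISE even near the boundary
  expect_equal(auto_label(1L, 2L, seg), "PRECISE")
  # exactly at threshold: default LE_PRECISE codes PRECISE
  cfg9 <- analysis_config(threshold_s = 9)
  expect_equal(auto_label(1L, 2L, seg, cfg9), "PRECISE")
  cfg9lt <- analysis_config(threshold_s = 9, boundary_rule = "LT_PRECISE")
  expect_equal(auto_label(1L, 2L, seg, cfg9lt), "SUMMARY")
})

test_that("temporal compression factor follows 1 - words / seconds", {
  expect_equal(compute_tcf(5L, 10), 0.5)
  expect_equal(compute_tcf(0L, 7), 1)      # upper limit
  expect_equal(compute_tcf(20L, 10), -1)   # may go negative
  expect_error(compute_tcf(3L, 0), "positive")
})

test_that("auto labels ignore text and TCF ignores labels", {
  seg <- tiny_segmentation()
  tr <- tiny_transcript()
  coded1 <- code_transcript(tr, seg)
  tr2 <- tr
  tr2$text <- rev(tr2$text)
  tr3 <- tr
  tr3$label <- c("PRECISE", "SUMMARY", "OTHER")
  expect_equal(code_transcript(tr2, seg)$auto_label, coded1$auto_label)
  expect_equal(code_transcript(tr3, seg)$tcf, coded1$tcf)
})

test_that("scene summary bias credits words to every touched scene", {
  seg <- tiny_segmentation()
  mk <- function(words_s, words_p) {
    tibble::tibble(
      subject_id = "s1", utterance_id = 1:2, onset_s = c(0, 10),
      offset_s = c(9, 19),
      text = c(paste(rep("knife", words_s), collapse = " "),
               paste(rep("door", words_p), collapse = " ")),
      start_segment = c(1L, 2L), end_segment = c(3L, 3L),
      label = c("SUMMARY", "PRECISE")
    )
  }
  beh <- scene_summary_bias(mk(30, 70), seg)
  expect_equal(beh$summary_bias[beh$scene_id == 1], 0.3)

  # utterance spanning scenes 1-2 credits full words to both scenes
  tr <- tibble::tibble(
    subject_id = "s1", utterance_id = 1L, onset_s = 0, offset_s = 9,
    text = paste(rep("knife", 10), collapse = " "),
    start_segment = 3L, end_segment = 4L, label = "SUMMARY"
  )
  beh <- scene_summary_bias(tr, seg)
  expect_equal(beh$words_summary, c(10L, 10L))
  expect_equal(beh$summary_bias, c(1, 1))
  expect_true(all(beh$recalled))

  # scene touched only by OTHER utterances: bias missing, not recalled
  tr$label <- "OTHER"
  beh <- scene_summary_bias(tr, seg)
  expect_true(all(is.na(beh$summary_bias)))
  expect_false(any(beh$recalled))
  expect_equal(beh$words_other, c(10L, 10L))
})

test_that("bias stays in [0, 1] and collapses to 0 without SUMMARY labels", {
  cfg <- sim_config(n_subjects = 4, n_scenes = 5)
  d <- simulate_dataset(cfg, seed = 21, neural = "none")
  beh <- scene_summary_bias(d$transcripts, d$segmentation)
  ok <- !is.na(beh$summary_bias)
  expect_true(all(beh$summary_bias[ok] >= 0 & beh$summary_bias[ok] <= 1))
  flat <- d$transcripts
  flat$label[flat$label == "SUMMARY"] <- "PRECISE"
  beh0 <- scene_summary_bias(flat, d$segmentation)
  expect_true(all(beh0$summary_bias[!is.na(beh0$summary_bias)] == 0))
})

test_that("scene mean TCF averages non-Other utterances per scene", {
  seg <- tiny_segmentation()
  # two PRECISE utterances on scene 1 with known TCFs
  tr <- tibble::tibble(
    subject_id = "s1", utterance_id = 1:2, onset_s = c(0, 10),
    offset_s = c(9, 19),
    text = c(paste(rep("w", 2), collapse = " "),   # 2 words / 4 s -> 0.5
             paste(rep("w", 2), collapse = " ")),  # 2 words / 5 s -> 0.6
    start_segment = c(1L, 2L), end_segment = c(1L, 2L),
    label = c("PRECISE", "PRECISE")
  )
  got <- scene_mean_tcf(tr, seg)
  expect_equal(got$mean_tcf[got$scene_id == 1], mean(c(0.5, 0.6)))
  expect_true(is.na(got$mean_tcf[got$scene_id == 2]))
})

test_that("summary/precise overlap counts intersecting summary spans", {
  mk <- function(s_ranges, p_ranges) {
    n_s <- length(s_ranges)
    n_p <- length(p_ranges)
    tibble::tibble(
      subject_id = "s1", utterance_id = seq_len(n_s + n_p),
      onset_s = seq(0, by = 2, length.out = n_s + n_p),
      offset_s = seq(1, by = 2, length.out = n_s + n_p),
      text = "x",
      start_segment = c(vapply(s_ranges, `[`, integer(1), 1),
                        vapply(p_ranges, `[`, integer(1), 1)),
      end_segment = c(vapply(s_ranges, `[`, integer(1), 2),
                      vapply(p_ranges, `[`, integer(1), 2)),
      label = c(rep("SUMMARY", n_s), rep("PRECISE", n_p))
    )
  }
  expect_equal(summary_precise_overlap(mk(list(c(1L, 20L)),
                                          list(c(5L, 6L))))$overlap, 1)
  expect_equal(summary_precise_overlap(mk(list(c(1L, 4L)),
                                          list(c(10L, 12L))))$overlap, 0)
  expect_equal(summary_precise_overlap(mk(list(c(1L, 4L), c(8L, 12L)),
                                          list(c(3L, 5L))))$overlap, 0.5)
  none <- summary_precise_overlap(mk(list(), list(c(1L, 2L))))
  expect_true(is.na(none$overlap))
})

test_that("label agreement is the exact-match fraction", {
  expect_equal(label_agreement(c("A", "B"), c("A", "B")), 1)
  expect_equal(label_agreement(c("A", "B"), c("B", "A")), 0)
  expect_equal(label_agreement(rep("A", 4), c("A", "A", "A", "B")), 0.75)
  expect_error(label_agreement("A", c("A", "B")), "lengths differ")
})

test_that("automatic and TCF-based scene bias agree in direction", {
  cfg <- sim_config(n_subjects = 8, n_scenes = 10)
  d <- simulate_dataset(cfg, seed = 31, neural = "none")
  coded <- code_transcript(d$transcripts, d$segmentation)
  beh <- scene_summary_bias(coded, d$segmentation, label_col = "auto_label")
  ok <- beh$recalled & !is.na(beh$summary_bias) & !is.na(beh$mean_tcf)
  # summaries compress more: bias and mean TCF correlate positively
  expect_gt(pearson_r(beh$summary_bias[ok], beh$mean_tcf[ok]), 0)
})
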