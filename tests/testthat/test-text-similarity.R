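test_that("toy embedder is deterministic, normalized and near-orthogonal on
           disjoint vocabularies", {
  m <- toy_embedder(512)
  e <- m$embed(c("a b knife", "a b knife"))
  expect_equal(e[1, ], e[2, ])
  expect_equal(sum(m$embed("knife")^2), 1)
  expect_equal(cosine_similarity(m$embed("door knife")[1, ],
                                 m$embed("door knife")[1, ]), 1)
  # two 20-word texts with disjoint vocabularies: |cos| < 0.2 at dim 512
  set.seed(5)
  for (i in 1:10) {
    t1 <- paste(paste0("alpha", sample(1000, 20)), collapse = " ")
    t2 <- paste(paste0("beta", sample(1000, 20)), collapse = " ")
    e <- m$embed(c(t1, t2))
    expect_lt(abs(cosine_similarity(e[1, ], e[2, ])), 0.2)
  }
})

test_that("cosine similarity is symmetric, bounded and scale-invariant", {
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(30)
    b <- rnorm(30)
    expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
    expect_lte(abs(cosine_similarity(a, b)), 1)
    expect_equal(cosine_similarity(3.7 * a, b), cosine_similarity(a, b))
  }
  expect_true(is.na(cosine_similarity(rep(0, 3), c(1, 2, 3))))
})

test_that("utterance similarity averages cosines over covered segments", {
  seg <- tiny_segmentation()
  tr <- tibble::tibble(
    subject_id = "s1", utterance_id = 1:2, onset_s = c(0, 5),
    offset_s = c(4, 9),
    text = c(seg$annotation[4],          # verbatim copy of its segment
             "zebra quantum xylophone"), # disjoint from everything
    start_segment = c(4L, 1L), end_segment = c(4L, 1L),
    label = c("PRECISE", "PRECISE")
  )
  got <- utterance_similarity(tr, seg)
  expect_equal(got$similarity[1], 1, tolerance = 1e-12)
  expect_lt(abs(got$similarity[2]), 0.25)

  # OTHER utterance (no range) is missing
  tr$start_segment[2] <- NA
  tr$end_segment[2] <- NA
  tr$label[2] <- "OTHER"
  expect_true(is.na(utterance_similarity(tr, seg)$similarity[2]))

  # mean over two covered segments equals the average of the two cosines
  tr2 <- tibble::tibble(
    subject_id = "s1", utterance_id = 1L, onset_s = 0, offset_s = 4,
    text = seg$annotation[1], start_segment = 1L, end_segment = 2L,
    label = "SUMMARY"
  )
  model <- toy_embedder()
  e <- model$embed(c(tr2$text, seg$annotation[1], seg$annotation[2]))
  manual <- mean(c(cosine_similarity(e[1, ], e[2, ]),
                   cosine_similarity(e[1, ], e[3, ])))
  expect_equal(utterance_similarity(tr2, seg, model)$similarity[1], manual)
})

test_that("matched beats mismatched for annotation-copying transcripts", {
  seg <- tiny_segmentation()
  tr <- tibble::tibble(
    subject_id = "s1", utterance_id = 1:2, onset_s = c(0, 5),
    offset_s = c(4, 9), text = seg$annotation[c(1, 4)],
    start_segment = c(1L, 4L), end_segment = c(1L, 4L),
    label = c("PRECISE", "SUMMARY")
  )
  got <- matched_vs_mismatched(tr, seg)
  expect_equal(got$matched_mean, c(1, 1), tolerance = 1e-12)
  expect_true(all(got$mismatched_mean < 0.5))
  expect_equal(got$difference, got$matched_mean - got$mismatched_mean)

  # degenerate: a single utterance covering every segment leaves no
  # mismatching set
  tr1 <- tibble::tibble(
    subject_id = "s1", utterance_id = 1L, onset_s = 0, offset_s = 4,
    text = "anything here", start_segment = 1L, end_segment = 5L,
    label = "SUMMARY"
  )
  got1 <- matched_vs_mismatched(tr1, seg)
  expect_true(is.na(got1$mismatched_mean))
})

test_that("matched/mismatched is invariant to utterance order", {
  cfg <- sim_config(n_subjects = 3, n_scenes = 4)
  d <- simulate_dataset(cfg, seed = 13, neural = "none")
  a <- matched_vs_mismatched(d$transcripts, d$segmentation)
  shuf <- d$transcripts[sample(nrow(d$transcripts)), ]
  shuf <- dplyr::arrange(shuf, .data$subject_id, .data$onset_s)
  b <- matched_vs_mismatched(shuf, d$segmentation)
  expect_equal(dplyr::arrange(a, subject_id, label),
               dplyr::arrange(b, subject_id, label))
})

test_that("group contrasts handle degenerate difference distributions", {
  mk <- function(diffs) {
    tibble::tibble(
      subject_id = rep(sprintf("s%d", seq_along(diffs)), each = 2),
      label = rep(c("PRECISE", "SUMMARY"), length(diffs)),
      n_utterances = 2L,
      matched_mean = rep(0.5 + diffs, each = 2),
      mismatched_mean = rep(0.5, 2 * length(diffs)),
      difference = rep(diffs, each = 2)
    )
  }
  # identical positive differences: capped Inf t with p -> 0 flag
  res <- group_text_contrast(mk(c(0.1, 0.1, 0.1)))
  row <- res[res$contrast == "matched_vs_mismatched_PRECISE", ]
  expect_true(row$degenerate)
  expect_equal(row$t, Inf)
  expect_equal(row$p, 0)
  # differences symmetric around zero: p = 1
  res <- group_text_contrast(mk(c(-0.2, 0.2)))
  row <- res[res$contrast == "matched_vs_mismatched_SUMMARY", ]
  expect_equal(row$p, 1)
  expect_error(group_text_contrast(mk(0.1)), "at least 2 subjects")
})
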