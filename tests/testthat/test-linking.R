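# Minimal transformation_result carrying a chosen per-scene group T map.
fake_transform <- function(scene_t_values, parcel_id = "1") {
  parcels <- tibble::tibble(
    parcel_id = parcel_id, mr = 0.3, rr = 0.5,
    p_mr = 0.001, p_rr = 0.001, q_mr = 0.004, q_rr = 0.004,
    in_reliability_mask = TRUE, t_score = 0.2, positive_t = TRUE
  )
  scene_t <- tibble::tibble(
    parcel_id = parcel_id,
    scene_id = seq_along(scene_t_values),
    n_subjects = 5L,
    t_score = scene_t_values
  )
  structure(list(parcels = parcels, scene_t = scene_t,
                 cells = NULL, config = analysis_config()),
            class = "transformation_result")
}

fake_behavior <- function(bias_by_subject) {
  dplyr::bind_rows(purrr::imap(bias_by_subject, function(bias, sid) {
    tibble::tibble(
      subject_id = sid, scene_id = seq_along(bias),
      words_summary = 10L, words_precise = 10L, words_other = 0L,
      summary_bias = bias, mean_tcf = 0.5, recalled = !is.na(bias)
    )
  }))
}

test_that("bias proportional to scene T gives r = 1; constant bias drops", {
  tvals <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  beh <- fake_behavior(list(
    a = tvals / 2,              # perfectly proportional -> r = 1
    b = rep(0.4, 5),            # zero variance -> dropped
    c = 1 - tvals               # perfectly inverted -> r = -1
  ))
  tf <- fake_transform(tvals)
  expect_warning(res <- link_bias_transformation(beh, tf), "dropped")
  sr <- res$subject_r
  expect_equal(sr$r[sr$subject_id == "a"], 1)
  expect_equal(sr$r[sr$subject_id == "c"], -1)
  expect_true(is.na(sr$r[sr$subject_id == "b"]))
  expect_equal(res$parcels$n_subjects, 2L)
})

test_that("subjects with too few recalled scenes are excluded", {
  tvals <- c(0.1, 0.2, 0.3, 0.4)
  beh <- fake_behavior(list(
    a = c(0.1, 0.2, NA, NA),        # 2 scenes < min_scenes -> dropped
    b = tvals, c = rev(tvals), d = tvals
  ))
  tf <- fake_transform(tvals)
  expect_warning(res <- link_bias_transformation(beh, tf), "dropped")
  expect_equal(res$parcels$n_subjects, 3L)
})

test_that("linking refuses when no parcel shows positive transformation", {
  tf <- fake_transform(c(0.1, 0.2, 0.3))
  tf$parcels$positive_t <- FALSE
  beh <- fake_behavior(list(a = c(0.1, 0.2, 0.3)))
  expect_error(link_bias_transformation(beh, tf), "positive transformation")
})

test_that("duration control detects planted signal and flags degenerate
           designs", {
  seg <- tiny_segmentation()  # scene durations 13 and 12 s
  beh <- fake_behavior(list(a = c(0.9, 0.1), b = c(0.8, 0.2)))
  # only 2 scenes per subject < min_scenes -> no usable subject
  expect_error(control_duration_correlation(beh, seg),
               "insufficient scenes")

  cfg <- sim_config(n_subjects = 10, n_scenes = 8)
  d <- simulate_dataset(cfg, seed = 71, neural = "none")
  beh <- scene_summary_bias(d$transcripts, d$segmentation)
  res <- control_duration_correlation(beh, d$segmentation)
  expect_s3_class(res$stats, "tbl_df")

  # plant bias as an increasing function of duration
  dur <- scene_table(d$segmentation)
  planted <- beh
  planted$summary_bias <- dur$duration_s[match(planted$scene_id,
                                               dur$scene_id)] / 200
  res_p <- control_duration_correlation(planted, d$segmentation)
  expect_gt(res_p$stats$t, 0)
  expect_lt(res_p$stats$p, 0.001)
})

test_that("network tally lists all seven networks with proportions", {
  parc <- tibble::tibble(
    parcel_id = 1:6,
    network = c("Default", "Default", "Visual", "Visual", "SomMot",
                "Limbic"),
    name = paste0("P", 1:6)
  )
  got <- network_tally(c(1, 2, 3, 4), parc)
  expect_equal(nrow(got), 7)
  expect_equal(got$count[got$network == "Default"], 2L)
  expect_equal(got$proportion[got$network == "Visual"], 0.5)
  expect_equal(sum(got$proportion), 1)
  none <- network_tally(integer(0), parc)
  expect_true(all(none$count == 0))
  expect_true(all(none$proportion == 0))
  all_def <- network_tally(c(1, 2), parc[1:2, ])
  expect_equal(all_def$proportion[all_def$network == "Default"], 1)
})

test_that("subject correlations are invariant to positive affine maps", {
  tvals <- c(0.05, 0.4, 0.2, 0.35, 0.15)
  beh <- fake_behavior(list(a = c(0.2, 0.9, 0.4, 0.7, 0.3),
                            b = c(0.9, 0.1, 0.6, 0.2, 0.8)))
  r1 <- link_bias_transformation(beh, fake_transform(tvals))
  r2 <- link_bias_transformation(beh, fake_transform(3 * tvals + 0.4))
  expect_equal(r1$subject_r$r, r2$subject_r$r, tolerance = 1e-12)
})
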