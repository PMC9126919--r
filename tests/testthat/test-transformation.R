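test_that("identical noiseless patterns give MR = RR = 1", {
  cfg <- analysis_config(min_recallers = 2L)
  pset <- make_pset(3, 4, 10, recall = "copy", seed = 2)
  # every subject shares the same pattern per scene
  for (i in 2:3) {
    pset$parcels[[1]]$movie[i, , ] <- pset$parcels[[1]]$movie[1, , ]
    pset$parcels[[1]]$recall[i, , ] <- pset$parcels[[1]]$movie[1, , ]
  }
  pset$parcels[[1]]$recall[1, , ] <- pset$parcels[[1]]$movie[1, , ]
  mr <- between_subject_similarity(pset, "MR", cfg)
  rr <- between_subject_similarity(pset, "RR", cfg)
  expect_true(all(abs(mr$r - 1) < 1e-12))
  expect_true(all(abs(rr$r - 1) < 1e-12))
})

test_that("independent noise gives MR and RR near zero", {
  cfg <- analysis_config(min_recallers = 2L)
  pset <- make_pset(6, 8, 4000, recall = "noise", seed = 3)
  mr <- between_subject_similarity(pset, "MR", cfg)
  expect_lt(abs(mean(mr$r)), 0.01)
})

test_that("transformation matches the straight-loop oracle to 1e-10", {
  cfg <- analysis_config(min_recallers = 2L, n_perm = 50)
  for (seed in 1:3) {
    pset <- make_pset(3, 4, 10, recall = "shift", seed = seed)
    res <- transformation_scores(pset, cfg, seed = seed)
    oracle <- oracle_transformation(pset, min_recallers = 2)
    expect_equal(res$parcels$t_score, unname(oracle[res$parcels$parcel_id]),
                 tolerance = 1e-10)
  }
})

test_that("oracle equivalence holds under partial recall", {
  recalled <- matrix(TRUE, 4, 5, dimnames = list(sprintf("s%02d", 1:4), 1:5))
  recalled[1, 2] <- FALSE
  recalled[3, c(1, 4)] <- FALSE
  cfg <- analysis_config(min_recallers = 2L, n_perm = 20)
  pset <- make_pset(4, 5, 10, recall = "shift", seed = 9,
                    recalled = recalled)
  res <- transformation_scores(pset, cfg, seed = 1)
  oracle <- oracle_transformation(pset, min_recallers = 2)
  expect_equal(res$parcels$t_score, unname(oracle[res$parcels$parcel_id]),
               tolerance = 1e-10)
  # unrecalled cells contribute no rows
  cells <- between_subject_similarity(pset, "RR", cfg)
  expect_false(any(cells$subject_id == "s01" & cells$scene_id == 2))
})

test_that("MR/RR are invariant to subject order and common rescaling", {
  cfg <- analysis_config(min_recallers = 2L)
  pset <- make_pset(4, 5, 12, recall = "shift", seed = 5)
  base <- between_subject_similarity(pset, "MR", cfg)

  perm <- c(3, 1, 4, 2)
  pset2 <- pset
  pset2$subject_ids <- pset$subject_ids[perm]
  pset2$recalled <- pset$recalled[perm, ]
  pset2$parcels[[1]]$movie <- pset$parcels[[1]]$movie[perm, , ]
  pset2$parcels[[1]]$recall <- pset$parcels[[1]]$recall[perm, , ]
  got <- between_subject_similarity(pset2, "MR", cfg)
  expect_equal(dplyr::arrange(base, subject_id, scene_id)$r,
               dplyr::arrange(got, subject_id, scene_id)$r,
               tolerance = 1e-12)

  pset3 <- pset
  pset3$parcels[[1]]$movie <- pset$parcels[[1]]$movie * 4.2
  pset3$parcels[[1]]$recall <- pset$parcels[[1]]$recall * 4.2
  got3 <- between_subject_similarity(pset3, "MR", cfg)
  expect_equal(base$r, got3$r, tolerance = 1e-12)
})

test_that("permutation p hits the documented extremes", {
  cfg <- analysis_config(min_recallers = 2L, n_perm = 60)
  # perfect scene-matched structure shared by all subjects: the observed
  # mean (r = 1 on every matched cell) beats every relabeled null
  pset <- make_pset(3, 6, 60, recall = "copy", seed = 6)
  for (i in 1:3) {
    pset$parcels[[1]]$movie[i, , ] <- pset$parcels[[1]]$movie[1, , ]
    pset$parcels[[1]]$recall[i, , ] <- pset$parcels[[1]]$movie[1, , ]
  }
  pr <- scene_label_permutation(pset, "MR", cfg, seed = 1)
  expect_equal(pr$p, 0)
  cfg_s <- cfg
  cfg_s$perm_smoothing <- TRUE
  pr_s <- scene_label_permutation(pset, "MR", cfg_s, seed = 1)
  expect_equal(pr_s$p, 1 / 61)
})

test_that("reliability mask uses the either-map rule and gates positive T", {
  cfg <- analysis_config(min_recallers = 2L, n_perm = 100, fdr_q = 0.05)
  # parcel 1: strong scene-matched structure; parcel 2: pure noise
  withr::with_seed(11, {
    p1 <- make_pset(5, 8, 80, recall = "shift", seed = 21)
    p2 <- make_pset(5, 8, 80, recall = "noise", seed = 22)
    p2$parcels[[1]]$movie <- array(rnorm(5 * 8 * 80), dim = c(5, 8, 80))
  })
  pset <- p1
  pset$parcels[["2"]] <- p2$parcels[[1]]
  res <- transformation_scores(pset, cfg, seed = 4)
  p <- res$parcels
  expect_true(p$in_reliability_mask[p$parcel_id == "1"])
  expect_false(p$in_reliability_mask[p$parcel_id == "2"])
  expect_true(all(p$t_score == p$rr - p$mr))
  expect_true(all(!p$positive_t | p$in_reliability_mask))
  # shift model: recall shares m + s across subjects, so RR > MR
  expect_true(p$positive_t[p$parcel_id == "1"])
})

test_that("group T is near zero without a shared shift and positive with",
{
  cfg <- analysis_config(min_recallers = 2L)
  ts0 <- ts1 <- numeric(8)
  for (i in 1:8) {
    scfg0 <- sim_config(n_subjects = 8, n_scenes = 6, n_parcels = 1,
                        features_per_parcel = 300, p_recall = 1,
                        shift_base = 0, shift_slope = 0,
                        summary_noise_mult = 1)
    truth <- flat_truth(8, 6)
    ps0 <- simulate_scene_patterns(scfg0, truth, seed = 100 + i)
    scfg1 <- scfg0
    scfg1$shift_base <- 1
    ps1 <- simulate_scene_patterns(scfg1, truth, seed = 100 + i)
    tval <- function(ps) {
      mean(between_subject_similarity(ps, "RR", cfg)$r) -
        mean(between_subject_similarity(ps, "MR", cfg)$r)
    }
    ts0[i] <- tval(ps0)
    ts1[i] <- tval(ps1)
  }
  se0 <- sd(ts0) / sqrt(length(ts0))
  expect_lt(abs(mean(ts0)), 3 * se0)
  expect_true(all(ts1 > ts0))
})
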