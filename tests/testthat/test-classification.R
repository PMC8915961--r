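test_that("affect scores average the two items and flag reversed scales", {
  expect_equal(affect_score(2, 2), 2)
  expect_equal(affect_score(0, 1), 0.5)
  expect_equal(affect_score(c(1, -3), c(2, 3)), c(1.5, 0))

  set.seed(1)
  reversed <- data.frame(negativity = rnorm(200))
  reversed$offensiveness <- -reversed$negativity + rnorm(200, 0, 0.3)
  expect_warning(check_affect_polarity(reversed), "reversed")

  ok <- generate_rating_dataset(rating_config(n_tweets_per_class = 10,
                                              raters_per_group = 12,
                                              tweets_per_rater = 30),
                                seed = 2)$ratings
  expect_no_warning(check_affect_polarity(ok))
})

test_that("group aggregation follows the stated rules", {
  r <- rbind(
    tweet_ratings("t1",
                  list(far_left = 3, moderate_left = 3,
                       moderate_right = 3, far_right = 3),
                  list(far_left = 0, moderate_left = 0,
                       moderate_right = 0, far_right = 0),
                  per_group = 1),
    NULL)
  s <- aggregate_group_scores(r)
  expect_equal(s$orientation_mean, rep(3, 4))
  expect_equal(s$p_political, rep(1, 4))
  expect_equal(s$affect_mean, rep(0, 4))

  # {+2, "not political", +2} -> conditional mean 2, p_political 2/3
  r2 <- rbind(rec("t2", "a", "far_left", 2),
              rec("t2", "b", "far_left", NA),
              rec("t2", "c", "far_left", 2))
  s2 <- aggregate_group_scores(r2)
  expect_equal(s2$orientation_mean, 2)
  expect_equal(s2$p_political, 2 / 3)

  # a group with zero political judgments -> undefined orientation sentinel
  r3 <- rbind(rec("t3", "a", "far_left", NA), rec("t3", "b", "far_left", NA))
  expect_true(is.na(aggregate_group_scores(r3)$orientation_mean))

  expect_error(aggregate_group_scores(rec("t", "r", "far_left", 1)[0, ]),
               "no rating records")

  # records missing an affective item are excluded with a log entry
  r4 <- rbind(rec("t4", "a", "far_left", 1, neg = NA),
              rec("t4", "b", "far_left", 2, neg = 1, off = 1))
  expect_message(s4 <- aggregate_group_scores(r4), "missing affective item")
  expect_equal(s4$n_raters, 1L)
})

test_that("inclusion filter requires three raters from every group", {
  full <- tweet_ratings("keep", list(far_left = 1, moderate_left = 1,
                                     moderate_right = 1, far_right = 1),
                        list(far_left = 0, moderate_left = 0,
                             moderate_right = 0, far_right = 0))
  short <- tweet_ratings("drop", list(far_left = 1, moderate_left = 1,
                                      moderate_right = 1, far_right = 1),
                         list(far_left = 0, moderate_left = 0,
                              moderate_right = 0, far_right = 0))
  short <- short[short$rater_id != "moderate_left_3", ]
  res <- inclusion_filter(rbind(full, short))
  expect_equal(res$included, "keep")
  expect_equal(nrow(res$counts), 2)
})

test_that("covert criteria pass and fail on constructed score profiles", {
  cutoffs <- list(or_gap = 1, affect_gap = 0.8, neutral_band = 0.5,
                  not_political_majority = 0.5, moderate_affect_max = 0.5,
                  recognition_min = 0.5, overt_or_band = 0.75,
                  overt_co_affect_band = 1.5, overt_recognition_min = 0.5,
                  side_lean_min = 1)
  ideal_covert <- data.frame(co_or_gap = 2.5, co_affect_gap = 2.0,
                             mod_or_abs = 0.1, mod_p_political = 0.1,
                             mod_affect = -0.2, far_p_political = 1,
                             far_co_lean = 2.5)
  f <- evaluate_covert_criteria(ideal_covert, cutoffs)
  expect_true(all(unlist(f[c("c1", "c2", "c3", "c4", "c5", "side_match",
                             "pass")])))

  # an overt tweet: moderates recognize it -> the neutrality criterion fails
  overt_as_covert <- within(ideal_covert, {
    co_or_gap <- 0.3; mod_or_abs <- 2.2; mod_p_political <- 0.95
    mod_affect <- -1.5
  })
  f <- evaluate_covert_criteria(overt_as_covert, cutoffs)
  expect_false(f$c3)
  expect_false(f$pass)

  # apolitical: far copartisans do not recognize it
  apolit <- within(ideal_covert, {
    far_p_political <- 0.1; co_or_gap <- 0.2; far_co_lean <- 0.1
  })
  f <- evaluate_covert_criteria(apolit, cutoffs)
  expect_false(f$c5)
  expect_false(f$pass)
})

test_that("overt criteria pass and fail on constructed score profiles", {
  cutoffs <- list(affect_gap = 2, overt_or_band = 0.75,
                  overt_co_affect_band = 1.5, overt_recognition_min = 0.5,
                  side_lean_min = 1)
  ideal_overt <- data.frame(cross_or_gap = 0.1, cross_affect_gap = 3.7,
                            co_affect_gap = 0.3, min_p_political = 0.95,
                            far_co_lean = 2.5)
  f <- evaluate_overt_criteria(ideal_overt, cutoffs)
  expect_true(all(unlist(f[c("c1", "c2", "c3", "c4", "side_match",
                             "pass")])))

  # a covert tweet: moderates do not recognize it -> recognition fails
  covert_as_overt <- within(ideal_overt, min_p_political <- 0.1)
  f <- evaluate_overt_criteria(covert_as_overt, cutoffs)
  expect_false(f$c4)
  expect_false(f$pass)

  # liked equally by all groups: no cross-partisan affect gap
  bland <- within(ideal_overt, cross_affect_gap <- 0)
  f <- evaluate_overt_criteria(bland, cutoffs)
  expect_false(f$c2)
  expect_false(f$pass)
})

test_that("classification recovers planted labels and mirrors exactly", {
  rat <- generate_rating_dataset(rating_config(n_tweets_per_class = 50),
                                 seed = 8)
  labels <- classify_tweets(rat$ratings)
  planted <- rat$truth[rat$truth$archetype != "apolitical", ]
  got <- labels$category[match(planted$tweet_id, labels$tweet_id)]
  expect_gte(mean(got == planted$archetype), 0.9)

  # apolitical tweets are never selected as signals
  apolit <- rat$truth$tweet_id[rat$truth$archetype == "apolitical"]
  expect_true(all(labels$category[labels$tweet_id %in% apolit] == "none"))

  # mirroring the dataset swaps the side labels exactly
  mirrored <- classify_tweets(mirror_ratings(rat$ratings))
  swap <- c(covert_left = "covert_right", covert_right = "covert_left",
            overt_left = "overt_right", overt_right = "overt_left",
            none = "none")
  expect_identical(mirrored$category[match(labels$tweet_id,
                                           mirrored$tweet_id)],
                   unname(swap[labels$category]))

  # determinism
  expect_identical(labels, classify_tweets(rat$ratings))
})

test_that("tightening a percentile cutoff never adds candidates", {
  rat <- generate_rating_dataset(rating_config(n_tweets_per_class = 30),
                                 seed = 3)
  n_candidates <- function(th) {
    labels <- classify_tweets(rat$ratings, th)
    sum(labels$category != "none")
  }
  loose <- classification_thresholds()
  tight_or <- classification_thresholds(covert_or_gap_pctl = 85)
  tight_aff <- classification_thresholds(overt_cross_affect_gap_pctl = 80)
  expect_lte(n_candidates(tight_or), n_candidates(loose))
  expect_lte(n_candidates(tight_aff), n_candidates(loose))
})

test_that("candidate selection ranks, truncates, and breaks ties by ID", {
  labels <- data.frame(
    tweet_id = c("t3", "t1", "t2", "t4"),
    category = c("covert_left", "covert_left", "covert_left", "none"),
    covert_score_left = c(0.9, 0.9, 0.5, 0.2),
    covert_score_right = 0, overt_score_left = 0, overt_score_right = 0,
    both_flag = FALSE, stringsAsFactors = FALSE)
  th <- classification_thresholds(preselect_cap = 2)
  sel <- suppressWarnings(select_candidates(labels, th))
  expect_equal(sel$covert_left$tweet_id, c("t1", "t3"))
  expect_equal(sel$covert_left$rank, c(1, 2))
  w <- capture_warnings(select_candidates(labels, classification_thresholds()))
  expect_true(any(grepl("only .* candidate", w)))
  expect_equal(nrow(suppressWarnings(
    select_candidates(labels, classification_thresholds())$overt_left)), 0)
})
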