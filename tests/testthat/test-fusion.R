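test_that("agreeing high-priority sources short-circuit without sensors", {
  f <- toy_frame(4)
  k <- make_bayesian_bba(f, c(6, 2, 1, 1))
  i <- make_bayesian_bba(f, c(4, 3, 2, 1))
  s <- make_bayesian_bba(f, c(0, 0, 0, 1)) # would veto if consulted
  d <- fuse_full(k, i, s, fusion_config(nc = 2))
  expect_false(d$conflict)
  expect_null(d$level2)
  expect_null(d$candidates)
  expect_equal(d$final, "a")
  expect_equal(singleton_beliefs(d$level1),
               singleton_beliefs(combine_pcr5(k, i)))
})

test_that("a conflicting toy case equals its hand-traced composition", {
  f <- toy_frame(4)
  k <- make_bayesian_bba(f, c(5, 3, 1, 1))
  i <- make_bayesian_bba(f, c(1, 6, 2, 1))
  s <- make_bayesian_bba(f, c(1, 1, 7, 1))
  cfg <- fusion_config(nc = 2)
  d <- fuse_full(k, i, s, cfg)
  expect_true(d$conflict)

  # hand trace with the verified primitives
  level1 <- combine_pcr5(k, i)
  b <- singleton_beliefs(level1)
  cand <- names(sort(-b))[1:2]
  expect_setequal(d$candidates, cand)
  level2 <- combine_pcr6(lapply(list(k, i, s), restrict_bba,
                                candidates = cand))
  expect_equal(singleton_beliefs(d$level2), singleton_beliefs(level2),
               tolerance = 1e-12)
  expect_equal(d$final, argmax_activity(level2))
  expect_true(d$final %in% d$candidates)
})

test_that("the simplified variant restricts to image candidates", {
  f <- toy_frame(4)
  cfg <- fusion_config(nc = 3)
  certain <- make_bayesian_bba(f, c(0, 1, 0, 0))
  s <- make_bayesian_bba(f, c(8, 1, 1, 0))
  d <- fuse_simplified(certain, s, cfg)
  expect_equal(d$final, "b") # restriction collapses to one candidate

  img <- make_bayesian_bba(f, c(1, 1, 1, 0)) # uniform over three labels
  s2 <- make_bayesian_bba(f, c(0, 1, 0, 0))
  d2 <- fuse_simplified(img, s2, cfg)
  expect_setequal(d2$candidates, c("a", "b", "c"))
  expect_equal(d2$final, "b") # sensors break the tie

  # random case composes restrict -> PCR5 -> argmax
  set.seed(71)
  f15 <- adl_frame()
  for (rep in 1:5) {
    i15 <- rand_bayes(f15)
    s15 <- rand_bayes(f15)
    d3 <- fuse_simplified(i15, s15, fusion_config(nc = 3))
    cand <- names(sort(-singleton_beliefs(i15)))[1:3]
    manual <- combine_pcr5(restrict_bba(i15, cand), restrict_bba(s15, cand))
    expect_equal(d3$final, argmax_activity(manual))
    expect_true(d3$final %in% d3$candidates)
  }
})

test_that("with a full candidate set and forced conflict, fusion is plain PCR6", {
  set.seed(72)
  f <- toy_frame(5)
  k <- rand_bayes(f); i <- rand_bayes(f); s <- rand_bayes(f)
  # the mass rule at threshold 0 fires on any positive conflict
  cfg <- fusion_config(nc = 5, conflict_rule = "mass",
                       conflict_threshold = 0)
  d <- fuse_full(k, i, s, cfg)
  expect_true(d$conflict)
  expect_equal(singleton_beliefs(d$level2),
               singleton_beliefs(combine_pcr6(list(k, i, s))),
               tolerance = 1e-12)

  forced <- fuse_full(k, i, s, fusion_config(force_pcr6 = TRUE))
  expect_equal(singleton_beliefs(forced$level1),
               singleton_beliefs(combine_pcr6(list(k, i, s))),
               tolerance = 1e-12)
})

test_that("configuration is validated", {
  f <- toy_frame(3)
  m <- rand_bayes(f)
  expect_error(fuse_full(m, m, m, fusion_config(nc = 9)), "frame size")
  expect_error(fusion_config(nc = 0), "nc")
  other <- rand_bayes(adl_frame(c("x", "y", "z")))
  expect_error(fuse_full(m, other, m, fusion_config()), "same frame")
})

test_that("the pipeline covers every record, falls back without knowledge, and reruns identically", {
  frame4 <- adl_frame(c("walking outside", "watching TV", "reading",
                        "lying down"))
  cfg <- sim_config(seed = 201L, samples_per_class = 8, frame = frame4)
  ds <- generate_dataset(cfg)
  corp <- bot_corpus(dplyr::left_join(ds$tags,
                                      ds$labels[, c("id", "activity")],
                                      by = "id"),
                     labels = as.character(frame4))
  clf <- suppressWarnings(build_bot_classifier(corp))
  w <- window_stream(ds$imu, ds$labels$timestamp)
  ft <- extract_feature_table(w, ds$gps)
  sm <- suppressWarnings(train_sensor_model(
    ft, ds$labels$activity, cost = 16, gamma = 0.008, folds = 3, seed = 2))
  profile <- knowledge_profile(ds$knowledge$weekday, ds$knowledge$weekend)
  fcfg <- fusion_config(nc = 2)

  dec <- suppressWarnings(run_pipeline(ds, clf, sm, profile, fcfg,
                                       frame = frame4))
  expect_equal(nrow(dec), nrow(ds$tags))
  expect_true(all(dec$final %in% as.character(frame4)))
  expect_true(all(!is.na(dec$knowledge_label)))

  # no knowledge profile: the simplified path runs throughout
  dec2 <- suppressWarnings(run_pipeline(ds, clf, sm, NULL, fcfg,
                                        frame = frame4))
  expect_true(all(dec2$conflict))
  expect_true(all(is.na(dec2$knowledge_label)))

  # byte-identical decision files across reruns
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_decisions(dec, f1)
  dec_again <- suppressWarnings(run_pipeline(ds, clf, sm, profile, fcfg,
                                             frame = frame4))
  write_decisions(dec_again, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("fusion decisions tidy and glance cleanly", {
  f <- toy_frame(4)
  d <- fuse_full(make_bayesian_bba(f, c(5, 3, 1, 1)),
                 make_bayesian_bba(f, c(1, 6, 2, 1)),
                 make_bayesian_bba(f, c(1, 1, 7, 1)),
                 fusion_config(nc = 2))
  td <- tidy(d)
  expect_true(all(c("level", "focal", "mass") %in% names(td)))
  expect_setequal(unique(td$level), c(1L, 2L))
  g <- glance(d)
  expect_equal(g$final, d$final)
  expect_equal(g$n_candidates, 2L)
})
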