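# A hand-authored table in the shape of a wearer's time-activity table:
# the evening row carries the printed scores (2, 10, 1, 0, 0, 0, 3, ...,
# 9, 2) whose row-normalization is checked against the published BBA row.
evening_row <- function() {
  c("cleaning" = 2, "computer use" = 10, "eating" = 1, "entertainment" = 0,
    "lying down" = 0, "meeting" = 0, "reading" = 3, "shopping" = 2,
    "talking" = 4, "telephone use" = 3, "transportation" = 0,
    "walking outside" = 0, "washing up" = 5, "watching TV" = 9,
    "writing" = 2)
}

sample_table_df <- function() {
  rows <- list(
    c(period = "00:01–06:50"), c(period = "06:51–07:20"),
    c(period = "07:21–07:30"), c(period = "21:01–22:00"),
    c(period = "22:01–00:00"))
  df <- tibble::tibble(period = vapply(rows, `[[`, "", "period"))
  scores <- matrix(0L, nrow(df), 15,
                   dimnames = list(NULL, adl_activities$label))
  scores[1, "lying down"] <- 10L
  scores[2, ] <- c(2L, 2L, 1L, 0L, 0L, 0L, 0L, 0L, 3L, 0L, 0L, 0L, 3L, 0L, 1L)
  scores[3, "washing up"] <- 8L
  scores[4, ] <- as.integer(evening_row())
  scores[5, c("lying down", "watching TV")] <- c(5L, 9L)
  dplyr::bind_cols(df, tibble::as_tibble(scores))
}

test_that("a CSV table round-trips and canonicalizes periods", {
  tab <- knowledge_table(sample_table_df(), scope = "weekday")
  expect_s3_class(tab, "knowledge_table")
  expect_equal(nrow(tab), 5)
  expect_true("21:01–22:00" %in% tab$key)

  path <- withr::local_tempfile(fileext = ".csv")
  write_knowledge_table(tab, path)
  back <- read_knowledge_table(path, scope = "weekday")
  expect_equal(back$key, tab$key)
  expect_equal(back$.start, tab$.start)
  expect_equal(back$.end, tab$.end)
  expect_equal(as.data.frame(back[adl_activities$label]),
               as.data.frame(tab[adl_activities$label]))
})

test_that("table validation rejects malformed input", {
  df <- sample_table_df()
  bad <- df; bad[["computer use"]][2] <- 11L
  expect_error(knowledge_table(bad), "0..10")
  bad <- df; bad[["computer use"]][2] <- -1L
  expect_error(knowledge_table(bad), "0..10")
  bad <- df; names(bad)[4] <- "juggling"
  expect_error(knowledge_table(bad), "match the frame")
  bad <- df; bad$period[2] <- "06:51–07:90"
  expect_error(knowledge_table(bad), "malformed")
  bad <- df; bad$period[3] <- "06:55–07:30" # overlaps the 06:51 row
  expect_error(knowledge_table(bad), "overlap")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(read_knowledge_table(empty), "empty|parse|malformed")
})

test_that("period lookup owns start minutes and honours the gap policy", {
  tab <- knowledge_table(sample_table_df())
  expect_equal(lookup_row(tab, "21:18:00")$key, "21:01–22:00")
  # boundary: the printed start minute belongs to the starting period
  expect_equal(lookup_row(tab, "21:01:00")$key, "21:01–22:00")
  # the printed end minute is inclusive: 22:00:30 is still inside
  expect_equal(lookup_row(tab, "22:00:30")$key, "21:01–22:00")
  expect_equal(lookup_row(tab, "23:59:59")$key, "22:01–00:00")
  # the uncovered 00:00-00:01 sliver falls to the nearest period
  expect_equal(lookup_row(tab, "00:00:30")$key, "00:01–06:50")
  expect_error(lookup_row(tab, "00:00:30", gap = "error"), "gap")
  # the 07:31-21:00 hole resolves to the nearest boundary
  expect_equal(lookup_row(tab, "07:35:00")$key, "07:21–07:30")
  expect_equal(lookup_row(tab, "20:59:00")$key, "21:01–22:00")
})

test_that("the evening row normalizes to the published BBA cells", {
  tab <- knowledge_table(sample_table_df(), scope = "weekday")
  kb <- knowledge_bba(knowledge_profile(tab), "21:18:00")
  b <- singleton_beliefs(kb)
  printed <- c("cleaning" = 0.0488, "computer use" = 0.2439,
               "eating" = 0.0244, "entertainment" = 0, "lying down" = 0,
               "meeting" = 0, "reading" = 0.0732,
               "watching TV" = 0.2195, "writing" = 0.0488)
  expect_lt(max(abs(b[names(printed)] - printed)), 1e-4)
})

test_that("knowledge BBAs are Bayesian, scale-invariant, and abstain on zero rows", {
  f <- adl_frame(c("a", "b", "c"))
  mk <- function(scores) {
    df <- tibble::tibble(period = "00:01–00:00",
                         a = scores[1], b = scores[2], c = scores[3])
    knowledge_profile(knowledge_table(df, frame = f))
  }
  m1 <- knowledge_bba(mk(c(2L, 4L, 0L)), "10:00:00")
  m2 <- knowledge_bba(mk(c(1L, 2L, 0L)), "10:00:00") # halved scores
  expect_true(is_bayesian(m1))
  expect_equal(singleton_beliefs(m1), singleton_beliefs(m2))

  expect_equal(unname(singleton_beliefs(
    knowledge_bba(mk(c(0L, 0L, 10L)), "10:00:00"))), c(0, 0, 1))
  expect_warning(u <- knowledge_bba(mk(c(0L, 0L, 0L)), "10:00:00"),
                 "abstain")
  expect_equal(unname(singleton_beliefs(u)), rep(1 / 3, 3))
  uniform <- knowledge_bba(mk(c(4L, 4L, 4L)), "10:00:00")
  expect_equal(unname(singleton_beliefs(uniform)), rep(1 / 3, 3))
})

test_that("scope selection and optional tables chain by PCR5", {
  f <- adl_frame(c("work", "rest"))
  wd <- knowledge_table(
    tibble::tibble(period = "00:01–00:00", work = 9L, rest = 1L),
    frame = f, scope = "weekday")
  we <- knowledge_table(
    tibble::tibble(period = "00:01–00:00", work = 1L, rest = 9L),
    frame = f, scope = "weekend")
  loc <- knowledge_table(
    tibble::tibble(location = c("office", "home"),
                   work = c(10L, 2L), rest = c(0L, 8L)),
    frame = f, kind = "location")
  prof <- knowledge_profile(wd, we, loc)

  expect_equal(argmax_activity(knowledge_bba(prof, "10:00:00")), "work")
  expect_equal(argmax_activity(
    knowledge_bba(prof, "10:00:00", weekend = TRUE)), "rest")
  # POSIXct Saturday selects the weekend table
  sat <- as.POSIXct("2026-09-26 10:00:00", tz = "UTC")
  expect_equal(argmax_activity(knowledge_bba(prof, sat)), "rest")

  plain <- knowledge_bba(prof, "10:00:00")
  with_loc <- knowledge_bba(prof, "10:00:00", location = "office")
  manual <- combine_pcr5(
    plain, make_bayesian_bba(f, c(10, 0)))
  expect_equal(singleton_beliefs(with_loc), singleton_beliefs(manual),
               tolerance = 1e-12)

  expect_error(knowledge_profile(loc), "time-activity")
  expect_error(knowledge_profile(wd, wd), "one table per")
})
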