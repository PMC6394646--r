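two_class_corpus <- function() {
  # 2 classes x 2 documents, chosen so every factor of the weight is easy
  # to evaluate by hand
  bot_corpus(tibble::tibble(
    id = c("c1", "c2", "e1", "e2"),
    activity = c("computer use", "computer use", "eating", "eating"),
    tags = list(
      c("keyboard", "keyboard", "screen", "indoors"),
      c("keyboard", "monitor", "indoors", "indoors"),
      c("food", "plate", "indoors", "food"),
      c("food", "drink", "plate", "indoors"))),
    labels = c("computer use", "eating"))
}

test_that("corpus statistics satisfy the count identities and normalize tags", {
  corp <- bot_corpus(tibble::tibble(
    id = c("a", "b"),
    activity = c("x", "x"),
    tags = list(c("  Keyboard", "SCREEN", "keyboard"), c("screen "))))
  expect_equal(corp$vocabulary, c("keyboard", "screen"))
  expect_equal(corp$n_docs, 2)
  # pooled class count equals the sum over documents (asserted again here
  # on top of the constructor's internal check)
  kb <- corp$class_counts$n[corp$class_counts$tag == "keyboard"]
  expect_equal(kb, 2)
  expect_error(bot_corpus(tibble::tibble(id = "a", activity = "x",
                                         tags = list(character(0)))),
               "non-empty")
})

test_that("entropy factors hit their closed-form values", {
  # e1: a tag spread (2,1,1) over a class's documents
  corp <- bot_corpus(tibble::tibble(
    id = c("d1", "d2", "d3"),
    activity = "x",
    tags = list(c("w", "w"), "w", "w")))
  expect_equal(inter_class_entropy(corp, "w", "x"), 1.5)

  # e1 maximal: one occurrence in each of 4 documents -> log2(4)
  corp4 <- bot_corpus(tibble::tibble(
    id = paste0("d", 1:4), activity = "x",
    tags = rep(list(c("w", "pad")), 4)))
  expect_identical(inter_class_entropy(corp4, "w", "x"), 2)
  # e1 zero: tag confined to a single document
  expect_identical(inter_class_entropy(corp4, "w2", "x"), 0)

  # e2: document counts (3, 1) across two classes
  corp2 <- bot_corpus(tibble::tibble(
    id = paste0("d", 1:4),
    activity = c("x", "x", "x", "y"),
    tags = list(c("w", "a"), c("w", "a"), c("w", "a"), c("w", "b"))))
  expect_equal(intra_class_entropy(corp2, "w"),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_equal(round(intra_class_entropy(corp2, "w"), 4), 0.8113)
  # e2 zero when confined to one class; maximal at equal counts
  expect_identical(intra_class_entropy(corp2, "a"), 0)
  corp_eq <- bot_corpus(tibble::tibble(
    id = paste0("d", 1:4),
    activity = c("x", "x", "y", "y"),
    tags = rep(list(c("w", "pad")), 4)))
  expect_identical(intra_class_entropy(corp_eq, "w"), 1)
})

test_that("tf, idf and the assembled weight match hand computation", {
  corp <- two_class_corpus()
  # tf("keyboard", computer use) = 3 occurrences / 8 pooled tags
  expect_equal(term_frequency_idf(corp, "keyboard", "computer use"),
               (3 / 8) * log(4 / 3))
  expect_equal(term_frequency_idf(corp, "absent", "computer use"), 0)
  # a tag in all 4 documents: idf = log(4/5) < 0, weight clipped to 0
  expect_lt(term_frequency_idf(corp, "indoors", "eating"), 0)
  expect_identical(entropy_tfidf_weight(corp, "indoors", "eating"), 0)

  # full product for "keyboard" in "computer use":
  #   tf = 3/8, idf = log(4/3), e1 = entropy of (2,1), e2 = 0, R = 1
  tf <- 3 / 8
  idf <- log(4 / 3)
  e1 <- -(2 / 3 * log2(2 / 3) + 1 / 3 * log2(1 / 3))
  expect_equal(entropy_tfidf_weight(corp, "keyboard", "computer use"),
               tf * idf * e1 * 1)
  # tf of a single-class corpus of identical tags is 1
  solo <- bot_corpus(tibble::tibble(id = "d", activity = "x",
                                    tags = list(rep("w", 20))))
  expect_equal(solo$class_counts$n / solo$class_totals$total, 1)
  # single class: log2(1) = 0, lambda alone keeps R finite and positive
  expect_true(is.finite(entropy_tfidf_weight(solo, "w", "x")))
})

test_that("class centres rank discriminative tags and respect M", {
  corp <- two_class_corpus()
  clf <- suppressWarnings(build_bot_classifier(corp, M = 3))
  cu <- clf[clf$activity == "computer use", ]
  expect_equal(cu$tag[1], "keyboard")
  expect_true(all(diff(cu$weight) <= 0))
  expect_lte(nrow(cu), 3)
  # disjoint vocabularies: each centre only holds its own class's tags
  disj <- bot_corpus(tibble::tibble(
    id = paste0("d", 1:4),
    activity = c("x", "x", "y", "y"),
    tags = list(c("a1", "a2"), c("a1", "a3"), c("b1", "b2"), c("b1", "b3"))))
  cl2 <- suppressWarnings(build_bot_classifier(disj, M = 5))
  expect_true(all(startsWith(cl2$tag[cl2$activity == "x"], "a")))
  expect_true(all(startsWith(cl2$tag[cl2$activity == "y"], "b")))
  expect_warning(build_bot_classifier(corp, M = 50), "shorter than M")
})

test_that("classification produces valid BBAs with hand-checkable cosines", {
  f <- adl_frame(c("x", "y"))
  disj <- bot_corpus(tibble::tibble(
    id = paste0("d", 1:4),
    activity = c("x", "x", "y", "y"),
    tags = list(c("a1", "a2"), c("a1", "a3"), c("b1", "b2"), c("b1", "b3"))))
  clf <- suppressWarnings(build_bot_classifier(disj, M = 5))
  hit <- classify_bot(c("a1"), clf, f)
  expect_equal(unname(singleton_beliefs(hit)), c(1, 0))
  expect_false(attr(hit, "low_confidence"))

  miss <- classify_bot(c("unseen", "tags"), clf, f)
  expect_true(attr(miss, "low_confidence"))
  expect_equal(unname(singleton_beliefs(miss)), c(0.5, 0.5))

  # permuting tags never changes the BBA
  set.seed(5)
  tags <- c("a1", "b1", "a2", "b3", "a1")
  ref <- singleton_beliefs(classify_bot(tags, clf, f))
  for (i in 1:5) {
    expect_equal(singleton_beliefs(classify_bot(sample(tags), clf, f)), ref)
  }

  # three hand-set centres: cosine = dot / (|x| |w|), then sum-normalized
  f3 <- adl_frame(c("p", "q", "r"))
  hand <- structure(
    tibble::tibble(
      activity = c("p", "p", "q", "q", "r"),
      tag = c("t1", "t2", "t2", "t3", "t4"),
      weight = c(2, 1, 1, 2, 3),
      rank = c(1L, 2L, 1L, 2L, 1L)),
    labels = c("p", "q", "r"), M = 2, lambda = 0.01,
    class = c("bot_classifier", class(tibble::tibble())))
  bot <- c("t1", "t2", "t2", "t5", "t5")
  # count vector over union vocab (t1..t4): (1, 2, 0, 0), |x| = sqrt(5)
  cos_p <- (1 * 2 + 2 * 1) / (sqrt(5) * sqrt(5))
  cos_q <- (2 * 1) / (sqrt(5) * sqrt(5))
  cos_r <- 0
  got <- singleton_beliefs(classify_bot(bot, hand, f3))
  want <- c(cos_p, cos_q, cos_r) / sum(c(cos_p, cos_q, cos_r))
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("a uniformly distributed tag does not change class rankings", {
  set.seed(9)
  base <- tibble::tibble(
    id = paste0("d", 1:8),
    activity = rep(c("x", "y"), each = 4),
    tags = c(lapply(1:4, function(i) sample(c("a1", "a2", "a3"), 5, TRUE)),
             lapply(1:4, function(i) sample(c("b1", "b2", "b3"), 5, TRUE))))
  noisy <- base
  noisy$tags <- lapply(noisy$tags, c, "everywhere")
  c1 <- build_bot_classifier(bot_corpus(base), M = 3)
  c2 <- suppressWarnings(build_bot_classifier(bot_corpus(noisy), M = 3))
  expect_equal(c2$tag[c2$activity == "x"][1:2], c1$tag[c1$activity == "x"][1:2])
  expect_equal(c2$tag[c2$activity == "y"][1:2], c1$tag[c1$activity == "y"][1:2])
  w_everywhere <- c2$weight[c2$tag == "everywhere"]
  if (length(w_everywhere)) expect_lt(max(w_everywhere),
                                      min(c1$weight) * 0.05)
})

test_that("classifier JSON persistence round-trips", {
  clf <- suppressWarnings(build_bot_classifier(two_class_corpus(), M = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_bot_classifier(clf, path)
  back <- read_bot_classifier(path)
  expect_equal(back$tag, clf$tag)
  expect_equal(back$weight, clf$weight, tolerance = 1e-12)
  expect_equal(attr(back, "labels"), attr(clf, "labels"))
})
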