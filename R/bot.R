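# Bag-of-tags (BoT) image classifier: entropy-weighted TF-IDF class
# centres and cosine-similarity scoring.
#
# One BoT (the tag list of one image) is one document.  For tag i and
# activity class k:
#   tf_{i,k}  = pooled occurrences of i in class k / total tags of class k
#   idf_i     = log(|D| / (documents containing i + 1))      (natural log)
#   e1_{i,k}  = entropy of i's occurrence counts across class k's BoTs
#               (base 2; 0 when the class never contains i)
#   e2_i      = entropy of i's document counts across the K classes
#   R(e2_i)   = 1 - e2_i / (log2 K + lambda),  lambda > 0 keeps R positive
#   weight    = tf * idf * e1 * R(e2), clipped at 0 (the "+1" idf
#               smoothing makes idf negative for ubiquitous tags; negative
#               mass is meaningless in a ranking / cosine space)
#
# The terminology follows the source convention of this field: e1 is the
# "inter-class" factor although computed within one class, e2 the
# "intra-class" factor although computed across classes.

normalize_tags <- function(tags) {
  tags <- trimws(tolower(as.character(tags)))
  tags[nzchar(tags)]
}

#' Build a tag corpus from labelled bag-of-tags records
#'
#' @param records Tibble with one row per image: columns `id`, `activity`,
#'   and `tags` (a list-column of character vectors; duplicates within a
#'   bag are allowed and counted).  Tags are casefolded and trimmed; no
#'   stemming.
#' @param labels Class labels; defaults to the activities present.
#' @return A `bot_corpus`: per-(class, tag) pooled counts, per-(document,
#'   tag) counts, and per-(class, tag) document frequencies.  The count
#'   identities (pooled class counts equal the sum of document counts;
#'   total document frequency equals the sum over classes) are asserted
#'   during construction.
#' @export
bot_corpus <- function(records, labels = NULL) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("id", "activity", "tags") %in% names(records)))
  if (nrow(records) == 0) stop("empty corpus", call. = FALSE)
  records$tags <- lapply(records$tags, normalize_tags)
  if (any(lengths(records$tags) == 0)) {
    stop("every bag of tags must be non-empty", call. = FALSE)
  }
  labels <- if (is.null(labels)) sort(unique(records$activity)) else
    as.character(labels)
  if (!all(records$activity %in% labels)) {
    stop("records contain activities outside the label set", call. = FALSE)
  }
  present <- labels %in% records$activity
  if (!all(present)) {
    stop("every class needs at least one bag of tags; missing: ",
         paste(labels[!present], collapse = ", "), call. = FALSE)
  }

  long <- tidyr::unnest(
    tibble::tibble(doc = seq_len(nrow(records)),
                   activity = records$activity, tag = records$tags),
    "tag")
  doc_counts <- dplyr::count(long, .data$doc, .data$activity, .data$tag,
                             name = "n")
  class_counts <- dplyr::count(long, .data$activity, .data$tag, name = "n")
  class_totals <- dplyr::count(long, .data$activity, name = "total")
  doc_freq <- dplyr::count(dplyr::distinct(doc_counts, .data$doc,
                                           .data$activity, .data$tag),
                           .data$activity, .data$tag, name = "docs")

  # count identities: pooled class counts vs per-document counts, and
  # total document frequency vs its per-class decomposition
  chk <- dplyr::summarise(dplyr::group_by(doc_counts, .data$activity,
                                          .data$tag),
                          n = sum(.data$n), .groups = "drop")
  stopifnot(identical(
    dplyr::arrange(chk, .data$activity, .data$tag),
    dplyr::arrange(class_counts, .data$activity, .data$tag)))
  total_df <- dplyr::summarise(dplyr::group_by(doc_freq, .data$tag),
                               docs = sum(.data$docs), .groups = "drop")
  direct_df <- dplyr::count(dplyr::distinct(long, .data$doc, .data$tag),
                            .data$tag, name = "docs")
  stopifnot(identical(dplyr::arrange(total_df, .data$tag),
                      dplyr::arrange(direct_df, .data$tag)))

  structure(list(
    labels = labels,
    n_docs = nrow(records),
    docs_per_class = table(factor(records$activity, levels = labels)),
    doc_counts = doc_counts,
    class_counts = class_counts,
    class_totals = class_totals,
    doc_freq = doc_freq,
    vocabulary = sort(unique(long$tag))
  ), class = "bot_corpus")
}

#' @export
print.bot_corpus <- function(x, ...) {
  cat("<bot_corpus: ", x$n_docs, " documents, ", length(x$labels),
      " classes, ", length(x$vocabulary), " unique tags>\n", sep = "")
  invisible(x)
}

#' TF-IDF of a tag for a class
#'
#' Term frequency over the class's pooled tags times the smoothed inverse
#' document frequency over all documents (natural log; one bag of tags is
#' one document).
#'
#' @param corpus A `bot_corpus`.
#' @param tag A single tag.
#' @param class A single class label.
#' @return The (possibly negative) tf-idf value; 0 tf for an absent tag.
#' @export
term_frequency_idf <- function(corpus, tag, class) {
  tag_tf(corpus, tag, class) * tag_idf(corpus, tag)
}

tag_tf <- function(corpus, tag, class) {
  tag <- normalize_tags(tag)
  n <- corpus$class_counts$n[corpus$class_counts$activity == class &
                               corpus$class_counts$tag == tag]
  tot <- corpus$class_totals$total[corpus$class_totals$activity == class]
  if (length(n) == 0) 0 else n / tot
}

tag_idf <- function(corpus, tag) {
  tag <- normalize_tags(tag)
  docs <- corpus$doc_freq$docs[corpus$doc_freq$tag == tag]
  log(corpus$n_docs / (sum(docs) + 1))
}

entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  tot <- sum(counts)
  if (tot == 0 || length(counts) == 0) return(0)
  p <- counts / tot
  -sum(p * log2(p))
}

#' Within-one-class occurrence entropy of a tag (e1)
#'
#' Entropy (base 2) of the tag's occurrence counts across the class's bags
#' of tags; maximal, `log2` of the class size, when the tag occurs
#' uniformly in every bag; 0 when it occurs in a single bag or never.
#'
#' @inheritParams term_frequency_idf
#' @return A number in `[0, log2 |class|]`.
#' @export
inter_class_entropy <- function(corpus, tag, class) {
  tag <- normalize_tags(tag)
  sel <- corpus$doc_counts$activity == class & corpus$doc_counts$tag == tag
  entropy_bits(corpus$doc_counts$n[sel])
}

#' Across-class document entropy of a tag (e2)
#'
#' Entropy (base 2) of the tag's document frequencies across the K
#' classes; maximal, `log2 K`, when the tag appears in equally many
#' documents of every class (no discriminative power); 0 when confined to
#' one class.
#'
#' @inheritParams term_frequency_idf
#' @return A number in `[0, log2 K]`.
#' @export
intra_class_entropy <- function(corpus, tag) {
  tag <- normalize_tags(tag)
  sel <- corpus$doc_freq$tag == tag
  entropy_bits(corpus$doc_freq$docs[sel])
}

remap_e2 <- function(e2, K, lambda) 1 - e2 / (log2(K) + lambda)

#' Entropy-weighted TF-IDF of a tag for a class
#'
#' `tf * idf * e1 * R(e2)` with `R(e2) = 1 - e2/(log2 K + lambda)`;
#' negative products (ubiquitous tags with negative smoothed idf) are
#' clipped to 0.
#'
#' @inheritParams term_frequency_idf
#' @param lambda Positive remap constant keeping `R(e2)` strictly
#'   positive; default 0.01.
#' @return A non-negative weight.
#' @export
entropy_tfidf_weight <- function(corpus, tag, class, lambda = 0.01) {
  stopifnot(lambda > 0)
  w <- term_frequency_idf(corpus, tag, class) *
    inter_class_entropy(corpus, tag, class) *
    remap_e2(intra_class_entropy(corpus, tag), length(corpus$labels), lambda)
  max(w, 0)
}

#' Train the bag-of-tags classifier
#'
#' Scores every (tag, class) pair with the entropy-weighted TF-IDF and
#' keeps, per class, the `M` highest-weighted tags with positive weight as
#' the class centre.  Ties at the boundary break lexicographically by tag.
#'
#' @param corpus A `bot_corpus`.
#' @param M Tags per class centre (default 20).
#' @param lambda Remap constant (default 0.01).
#' @return A `bot_classifier`: tibble with columns `activity`, `tag`,
#'   `weight`, `rank`, weights sorted descending within class.  A class
#'   with fewer than `M` positive-weight tags yields a shorter centre with
#'   a warning.
#' @export
build_bot_classifier <- function(corpus, M = 20, lambda = 0.01) {
  stopifnot(inherits(corpus, "bot_corpus"), M >= 1, lambda > 0)
  K <- length(corpus$labels)

  cc <- dplyr::left_join(corpus$class_counts, corpus$class_totals,
                         by = "activity")
  df_tot <- dplyr::summarise(dplyr::group_by(corpus$doc_freq, .data$tag),
                             docs = sum(.data$docs), .groups = "drop")
  cc <- dplyr::left_join(cc, df_tot, by = "tag")
  e1 <- dplyr::summarise(
    dplyr::group_by(corpus$doc_counts, .data$activity, .data$tag),
    e1 = entropy_bits(.data$n), .groups = "drop")
  e2 <- dplyr::summarise(
    dplyr::group_by(corpus$doc_freq, .data$tag),
    e2 = entropy_bits(.data$docs), .groups = "drop")
  cc <- dplyr::left_join(cc, e1, by = c("activity", "tag"))
  cc <- dplyr::left_join(cc, e2, by = "tag")
  cc <- dplyr::mutate(
    cc,
    tf = .data$n / .data$total,
    idf = log(corpus$n_docs / (.data$docs + 1)),
    weight = pmax(.data$tf * .data$idf * .data$e1 *
                    remap_e2(.data$e2, K, lambda), 0))

  centers <- dplyr::filter(cc, .data$weight > 0)
  centers <- dplyr::arrange(centers, .data$activity,
                            dplyr::desc(.data$weight), .data$tag)
  centers <- dplyr::slice_head(dplyr::group_by(centers, .data$activity),
                               n = M)
  centers <- dplyr::mutate(centers, rank = dplyr::row_number())
  centers <- dplyr::ungroup(centers)
  n_per <- table(factor(centers$activity, levels = corpus$labels))
  if (any(n_per < M)) {
    warning("class centre(s) shorter than M = ", M, ": ",
            paste(names(n_per)[n_per < M], collapse = ", "), call. = FALSE)
  }
  out <- centers[, c("activity", "tag", "weight", "rank")]
  structure(out, labels = corpus$labels, M = M, lambda = lambda,
            class = c("bot_classifier", class(out)))
}

#' Classify one bag of tags into a BBA
#'
#' Embeds the bag's raw tag counts and every class centre in the union
#' vocabulary of all centres, computes cosine similarities, and
#' sum-normalizes them into a Bayesian BBA.  Out-of-vocabulary tags are
#' ignored.  A bag sharing no tag with any centre yields the uniform BBA
#' with attribute `low_confidence = TRUE`.
#'
#' @param tags Character vector of tags (one image's bag) or a one-row
#'   record with a `tags` list-column.
#' @param classifier A `bot_classifier` covering every frame label.
#' @param frame Frame of discernment.
#' @return A Bayesian `bba` with attribute `low_confidence`.
#' @export
classify_bot <- function(tags, classifier, frame = adl_frame()) {
  stopifnot(inherits(classifier, "bot_classifier"))
  frame <- as_frame(frame)
  if (is.data.frame(tags)) tags <- tags$tags[[1]]
  tags <- normalize_tags(tags)
  labels <- attr(classifier, "labels")
  if (!all(as.character(frame) %in% labels)) {
    stop("classifier must cover every frame label", call. = FALSE)
  }
  sims <- cosine_scores(tags, classifier, as.character(frame))
  if (all(sims == 0)) {
    out <- make_bayesian_bba(frame, rep(1, length(frame)))
    attr(out, "low_confidence") <- TRUE
    return(out)
  }
  out <- make_bayesian_bba(frame, sims)
  attr(out, "low_confidence") <- FALSE
  out
}

cosine_scores <- function(tags, classifier, labels) {
  vocab <- sort(unique(classifier$tag))
  x <- tabulate(match(tags, vocab), nbins = length(vocab))
  nx <- sqrt(sum(x^2))
  vapply(labels, function(k) {
    sel <- classifier$activity == k
    w <- numeric(length(vocab))
    w[match(classifier$tag[sel], vocab)] <- classifier$weight[sel]
    nw <- sqrt(sum(w^2))
    if (nx == 0 || nw == 0) 0 else sum(x * w) / (nx * nw)
  }, numeric(1))
}

#' Classify a stream of bag-of-tags records
#'
#' @param records Tibble with columns `id`, `timestamp` (optional) and
#'   `tags` (list-column).
#' @inheritParams classify_bot
#' @return The input tibble plus list-column `bba` and logical
#'   `low_confidence`.
#' @export
classify_bots <- function(records, classifier, frame = adl_frame()) {
  records <- tibble::as_tibble(records)
  out <- lapply(records$tags, classify_bot, classifier = classifier,
                frame = frame)
  records$bba <- out
  records$low_confidence <- vapply(out, attr, logical(1), "low_confidence")
  records
}

#' Persist / load a bag-of-tags classifier as JSON
#'
#' JSON form: `{class: [[tag, weight], ...], ...}` plus `M`, `lambda` and
#' the label order.
#'
#' @param classifier A `bot_classifier`.
#' @param file Path to write to / read from.
#' @return `write_bot_classifier()` returns `file` invisibly;
#'   `read_bot_classifier()` returns the classifier.
#' @export
write_bot_classifier <- function(classifier, file) {
  stopifnot(inherits(classifier, "bot_classifier"))
  centers <- split(classifier[, c("tag", "weight")], classifier$activity)
  payload <- list(
    labels = attr(classifier, "labels"),
    M = attr(classifier, "M"),
    lambda = attr(classifier, "lambda"),
    centers = lapply(centers, function(d) {
      mapply(function(t, w) list(t, w), d$tag, d$weight,
             SIMPLIFY = FALSE, USE.NAMES = FALSE)
    })
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_bot_classifier
#' @export
read_bot_classifier <- function(file) {
  x <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  rows <- dplyr::bind_rows(lapply(names(x$centers), function(k) {
    tibble::tibble(
      activity = k,
      tag = vapply(x$centers[[k]], function(p) as.character(p[[1]]),
                   character(1)),
      weight = vapply(x$centers[[k]], function(p) as.numeric(p[[2]]),
                      numeric(1)))
  }))
  rows <- dplyr::arrange(rows, .data$activity, dplyr::desc(.data$weight),
                         .data$tag)
  rows <- dplyr::mutate(dplyr::group_by(rows, .data$activity),
                        rank = dplyr::row_number())
  rows <- dplyr::ungroup(rows)
  structure(rows, labels = unlist(x$labels), M = x$M, lambda = x$lambda,
            class = c("bot_classifier", class(rows)))
}
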