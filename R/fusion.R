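# Two-level hierarchical fusion network with descending candidate sets.
#
# Level 1 fuses the two high-priority sources (knowledge, image) with
# PCR5.  If they agree there is no conflict and the level-1 arg-max is
# final; the sensors are never consulted at level 1.  On conflict, the Nc
# top-mass singletons of the level-1 BBA become the candidate set, all
# three source BBAs are restricted to it and renormalized, and a
# three-source PCR6 fusion decides among the candidates.  The simplified
# variant (no knowledge source) takes its candidates directly from the
# image BBA and fuses image with sensors by PCR5.

#' Fusion configuration
#'
#' @param nc Candidate-set size for the second level (default 3); must lie
#'   in `1..|frame|`.
#' @param conflict_rule `"argmax"` (default): level-1 sources conflict
#'   when their arg-max decisions differ (ties broken by frame order
#'   before comparison).  `"mass"`: conflict when the conjunctive conflict
#'   mass of the pair exceeds `conflict_threshold`.
#' @param conflict_threshold Threshold for the `"mass"` rule (default
#'   0.5).
#' @param force_pcr6 If `TRUE`, skip the hierarchy and fuse all available
#'   sources in one plain PCR6 step.
#' @param gap Gap policy forwarded to knowledge lookups.
#' @return A list of class `"fusion_config"`.
#' @export
fusion_config <- function(nc = 3, conflict_rule = c("argmax", "mass"),
                          conflict_threshold = 0.5, force_pcr6 = FALSE,
                          gap = "nearest") {
  conflict_rule <- match.arg(conflict_rule)
  stopifnot(nc >= 1, conflict_threshold >= 0, conflict_threshold <= 1)
  structure(list(nc = nc, conflict_rule = conflict_rule,
                 conflict_threshold = conflict_threshold,
                 force_pcr6 = force_pcr6, gap = gap),
            class = "fusion_config")
}

conjunctive_conflict <- function(m1, m2) {
  frame <- bba_frame(m1)
  mem1 <- focal_members(names(m1)); mem2 <- focal_members(names(m2))
  total <- 0
  for (i in seq_along(mem1)) for (j in seq_along(mem2)) {
    if (length(intersect(mem1[[i]], mem2[[j]])) == 0) {
      total <- total + m1[[i]] * m2[[j]]
    }
  }
  total
}

top_candidates <- function(m, nc) {
  b <- singleton_beliefs(m)
  # which/order with ties.method "first" keeps frame order at ties
  names(b)[order(-b, seq_along(b))][seq_len(min(nc, length(b)))]
}

new_decision <- function(final, level1, conflict, candidates = NULL,
                         level2 = NULL) {
  structure(list(final = final, level1 = level1, conflict = conflict,
                 candidates = candidates, level2 = level2),
            class = "fusion_decision")
}

#' @export
print.fusion_decision <- function(x, ...) {
  cat("<fusion_decision: ", x$final,
      if (x$conflict) " (level-2, candidates: " else " (level-1",
      if (x$conflict) paste(x$candidates, collapse = ", "),
      ")>\n", sep = "")
  invisible(x)
}

#' Full three-source hierarchical fusion
#'
#' @param knowledge,image,sensors `bba` objects on one shared frame.
#' @param config A [fusion_config()].
#' @return A `fusion_decision`: `final` label, `level1` BBA, `conflict`
#'   flag, and (when a second level ran) `candidates` and `level2` BBA.
#' @export
#' @examples
#' f <- adl_frame(c("a", "b", "c", "d"))
#' k <- make_bayesian_bba(f, c(5, 3, 1, 1))
#' i <- make_bayesian_bba(f, c(1, 6, 2, 1))
#' s <- make_bayesian_bba(f, c(1, 1, 7, 1))
#' fuse_full(k, i, s, fusion_config(nc = 2))
fuse_full <- function(knowledge, image, sensors, config = fusion_config()) {
  stopifnot(inherits(config, "fusion_config"))
  frame <- check_shared_frame(list(knowledge, image, sensors))
  if (config$nc > length(frame)) {
    stop("nc exceeds the frame size", call. = FALSE)
  }
  if (config$force_pcr6) {
    fused <- combine_pcr6(list(knowledge, image, sensors))
    return(new_decision(argmax_activity(fused), fused, conflict = FALSE))
  }
  level1 <- combine_pcr5(knowledge, image)
  conflict <- switch(
    config$conflict_rule,
    argmax = argmax_activity(knowledge) != argmax_activity(image),
    mass = conjunctive_conflict(knowledge, image) > config$conflict_threshold
  )
  if (!conflict) {
    return(new_decision(argmax_activity(level1), level1, conflict = FALSE))
  }
  candidates <- top_candidates(level1, config$nc)
  restricted <- lapply(list(knowledge, image, sensors), restrict_bba,
                       candidates = candidates)
  level2 <- combine_pcr6(restricted)
  new_decision(argmax_activity(level2), level1, conflict = TRUE,
               candidates = candidates, level2 = level2)
}

#' Simplified two-source fusion (no knowledge table)
#'
#' Candidates are the `nc` top-mass singletons of the image BBA; image and
#' sensor BBAs are restricted to them, renormalized and fused with PCR5.
#'
#' @param image,sensors `bba` objects on one shared frame.
#' @inheritParams fuse_full
#' @return A `fusion_decision` (always flagged as a level-2 decision).
#' @export
fuse_simplified <- function(image, sensors, config = fusion_config()) {
  stopifnot(inherits(config, "fusion_config"))
  frame <- check_shared_frame(list(image, sensors))
  if (config$nc > length(frame)) {
    stop("nc exceeds the frame size", call. = FALSE)
  }
  candidates <- top_candidates(image, config$nc)
  restricted <- lapply(list(image, sensors), restrict_bba,
                       candidates = candidates)
  level2 <- combine_pcr5(restricted[[1]], restricted[[2]])
  new_decision(argmax_activity(level2), image, conflict = TRUE,
               candidates = candidates, level2 = level2)
}

#' Run the full pipeline over an aligned dataset
#'
#' For each image record: a knowledge BBA from the profile (when
#' supplied), an image BBA from the bag-of-tags classifier, a sensor BBA
#' from the SVM, then [fuse_full()] — or [fuse_simplified()] when no
#' knowledge profile is available.
#'
#' @param dataset A list with elements `tags` (tibble `id`, `timestamp`,
#'   `tags` list-column), `imu` (IMU stream tibble), `gps` (fix tibble or
#'   `NULL`), as produced by [generate_dataset()].
#' @param bot_classifier A [build_bot_classifier()] model.
#' @param sensor_model A [train_sensor_model()] model.
#' @param profile Optional [knowledge_profile()].
#' @param config A [fusion_config()].
#' @param frame Frame of discernment.
#' @return A tibble with one row per image record: `id`, `timestamp`,
#'   `final`, `conflict`, per-source arg-max labels
#'   (`knowledge_label`, `image_label`, `sensor_label`), and list-columns
#'   with the per-source BBAs and the decision object.
#' @export
run_pipeline <- function(dataset, bot_classifier, sensor_model,
                         profile = NULL, config = fusion_config(),
                         frame = adl_frame()) {
  frame <- as_frame(frame)
  tags <- tibble::as_tibble(dataset$tags)
  stopifnot(all(c("id", "timestamp", "tags") %in% names(tags)))

  image_scored <- classify_bots(tags, bot_classifier, frame)
  windows <- window_stream(dataset$imu, tags$timestamp)
  if (nrow(windows) < nrow(tags)) {
    keep <- tags$timestamp %in% windows$image_time
    warning(sum(!keep), " record(s) skipped: no aligned IMU window",
            call. = FALSE)
    tags <- tags[keep, ]
    image_scored <- image_scored[keep, ]
  }
  feats <- extract_feature_table(windows, dataset$gps)
  sensor_scored <- predict_sensor(sensor_model, feats, frame)

  n <- nrow(tags)
  decisions <- vector("list", n)
  k_bbas <- vector("list", n)
  for (i in seq_len(n)) {
    s_bba <- sensor_scored$bba[[i]]
    i_bba <- image_scored$bba[[i]]
    if (is.null(profile)) {
      decisions[[i]] <- fuse_simplified(i_bba, s_bba, config)
    } else {
      k_bbas[[i]] <- knowledge_bba(profile, tags$timestamp[i],
                                   gap = config$gap)
      decisions[[i]] <- fuse_full(k_bbas[[i]], i_bba, s_bba, config)
    }
  }
  tibble::tibble(
    id = tags$id,
    timestamp = tags$timestamp,
    final = vapply(decisions, function(d) d$final, character(1)),
    conflict = vapply(decisions, function(d) d$conflict, logical(1)),
    knowledge_label = if (is.null(profile)) NA_character_ else
      vapply(k_bbas, argmax_activity, character(1)),
    image_label = vapply(image_scored$bba, argmax_activity, character(1)),
    sensor_label = sensor_scored$label,
    knowledge_bba = k_bbas,
    image_bba = image_scored$bba,
    sensor_bba = sensor_scored$bba,
    decision = decisions
  )
}

#' Write a decision stream as JSON-lines
#'
#' One JSON object per record: id, timestamp, final label, conflict flag,
#' candidate set, and the level-1/level-2 masses.
#'
#' @param decisions Output of [run_pipeline()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_decisions <- function(decisions, file) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(decisions))) {
    d <- decisions$decision[[i]]
    obj <- list(
      id = decisions$id[i],
      timestamp = decisions$timestamp[i],
      final = d$final,
      conflict = d$conflict,
      candidates = d$candidates,
      level1 = as.list(unclass(d$level1)),
      level2 = if (is.null(d$level2)) NULL else as.list(unclass(d$level2))
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(file)
}
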