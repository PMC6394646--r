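# User-authored knowledge tables: condition-activity association scores.
#
# A time-activity table scores each activity 0 (impossible) to 10
# (assured) per clock-time period; optional location-activity and
# activity-transition tables use the same 0-10 scale keyed by location or
# previous activity.  A printed period "a-b" is canonicalized to the
# half-open interval [a:00, b:59.999...), i.e. [a, next period's start),
# so contact-adjacent printed rows partition the day; an end time of
# "00:00" means midnight (24:00).

SECONDS_PER_DAY <- 86400L

parse_clock <- function(x) {
  m <- regmatches(x, regexec("^\\s*(\\d{1,2}):(\\d{2})\\s*$", x))[[1]]
  if (length(m) == 0) stop("malformed clock time: ", x, call. = FALSE)
  h <- as.integer(m[2]); mi <- as.integer(m[3])
  if (h > 24 || mi > 59) stop("malformed clock time: ", x, call. = FALSE)
  h * 3600L + mi * 60L
}

parse_period <- function(x) {
  parts <- strsplit(x, "–|—|-", perl = FALSE)[[1]]
  if (length(parts) != 2) stop("malformed period: ", x, call. = FALSE)
  start <- parse_clock(parts[1])
  end_min <- parse_clock(parts[2])
  end <- if (end_min == 0L) SECONDS_PER_DAY else end_min + 60L
  if (end <= start) stop("period ends before it starts: ", x, call. = FALSE)
  c(start = start, end = end)
}

#' Construct a knowledge table from a data frame
#'
#' @param df Data frame whose first column holds the row keys (periods
#'   `"HH:MM-HH:MM"` for a time table; location names or previous-activity
#'   labels otherwise) and whose remaining columns are exactly the frame
#'   labels, holding integer scores 0 (impossible) to 10 (assured).
#' @param frame Frame of discernment.
#' @param kind `"time"`, `"location"` or `"transition"`.
#' @param scope `"weekday"`, `"weekend"` or `"any"` (calendar scope of a
#'   time table).
#' @return A tibble of class `"knowledge_table"` with canonicalized period
#'   bounds (`.start`, `.end`, seconds of day) for time tables.
#' @export
knowledge_table <- function(df, frame = adl_frame(),
                            kind = c("time", "location", "transition"),
                            scope = c("any", "weekday", "weekend")) {
  kind <- match.arg(kind)
  scope <- match.arg(scope)
  frame <- as_frame(frame)
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0) stop("knowledge table has no rows", call. = FALSE)
  key <- names(df)[1]
  acts <- names(df)[-1]
  if (!setequal(acts, as.character(frame))) {
    missing <- setdiff(as.character(frame), acts)
    extra <- setdiff(acts, as.character(frame))
    stop("table columns must match the frame labels",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unknown: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  scores <- as.matrix(df[as.character(frame)])
  if (any(is.na(scores)) || any(scores != round(scores)) ||
      any(scores < 0) || any(scores > 10)) {
    stop("scores must be integers in 0..10", call. = FALSE)
  }
  out <- tibble::tibble(key = as.character(df[[key]]))
  out <- dplyr::bind_cols(out, tibble::as_tibble(scores))
  if (kind == "time") {
    bounds <- t(vapply(out$key, parse_period, c(start = 0, end = 0)))
    out$.start <- as.integer(bounds[, "start"])
    out$.end <- as.integer(bounds[, "end"])
    ord <- order(out$.start)
    out <- out[ord, ]
    overlap <- out$.end[-nrow(out)] > out$.start[-1]
    if (nrow(out) > 1 && any(overlap)) {
      stop("overlapping periods: ",
           paste(out$key[c(overlap, FALSE)], collapse = ", "), call. = FALSE)
    }
  } else if (anyDuplicated(out$key)) {
    stop("duplicate row keys", call. = FALSE)
  }
  structure(out, frame = frame, kind = kind, scope = scope,
            class = c("knowledge_table", class(out)))
}

#' Read a knowledge table from CSV
#'
#' CSV layout: header row with `period` (or `location` / `previous`)
#' followed by the frame labels; one row per period with integer scores
#' 0-10.
#'
#' @param file Path to a UTF-8 CSV file.
#' @inheritParams knowledge_table
#' @return A `knowledge_table`.
#' @export
read_knowledge_table <- function(file, frame = adl_frame(),
                                 kind = "time", scope = "any") {
  df <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("empty or malformed knowledge table: ", file, call. = FALSE)
  }
  knowledge_table(df, frame = frame, kind = kind, scope = scope)
}

#' Write a knowledge table to CSV
#'
#' @param table A `knowledge_table`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_knowledge_table <- function(table, file) {
  stopifnot(inherits(table, "knowledge_table"))
  df <- table[, c("key", as.character(attr(table, "frame")))]
  names(df)[1] <- switch(attr(table, "kind"), time = "period",
                         location = "location", transition = "previous")
  readr::write_csv(df, file, progress = FALSE)
  invisible(file)
}

seconds_of_day <- function(timestamp) {
  if (inherits(timestamp, "POSIXt")) {
    lt <- as.POSIXlt(timestamp)
    return(lt$hour * 3600L + lt$min * 60L + as.integer(lt$sec))
  }
  if (is.character(timestamp)) {
    p <- strsplit(timestamp, ":", fixed = TRUE)[[1]]
    if (!length(p) %in% 2:3) stop("malformed time: ", timestamp, call. = FALSE)
    p <- as.integer(p)
    return(p[1] * 3600L + p[2] * 60L + if (length(p) == 3) p[3] else 0L)
  }
  if (is.numeric(timestamp)) return(as.integer(timestamp) %% SECONDS_PER_DAY)
  stop("unsupported timestamp type", call. = FALSE)
}

#' Look up the score row covering a clock time
#'
#' Periods own their printed start minute (half-open convention).  A time
#' falling in an uncovered gap follows `gap`: `"nearest"` (default) picks
#' the period whose boundary is closest (circularly over the day),
#' `"error"` rejects.
#'
#' @param table A time-kind `knowledge_table`.
#' @param timestamp Clock time: `"HH:MM:SS"` string, seconds of day, or a
#'   `POSIXct`.
#' @param gap Gap policy, `"nearest"` or `"error"`.
#' @return The matching one-row tibble of scores.
#' @export
lookup_row <- function(table, timestamp, gap = c("nearest", "error")) {
  stopifnot(inherits(table, "knowledge_table"))
  if (attr(table, "kind") != "time") {
    stop("lookup_row() needs a time-activity table", call. = FALSE)
  }
  gap <- match.arg(gap)
  sec <- seconds_of_day(timestamp)
  hit <- which(table$.start <= sec & sec < table$.end)
  if (length(hit) == 0) {
    if (gap == "error") {
      stop("time ", sec, "s falls in an uncovered gap", call. = FALSE)
    }
    circ <- function(a, b) pmin(abs(a - b), SECONDS_PER_DAY - abs(a - b))
    d <- pmin(circ(sec, table$.start), circ(sec, table$.end - 1L))
    hit <- which.min(d)
  }
  table[hit[1], ]
}

#' Bundle knowledge tables into a profile
#'
#' A profile holds at least one time-activity table (per calendar scope)
#' and optionally one location-activity and one activity-transition table.
#'
#' @param ... `knowledge_table` objects.  At most one per (kind, scope).
#' @return A `knowledge_profile`.
#' @export
knowledge_profile <- function(...) {
  tables <- list(...)
  if (length(tables) == 1 && is.list(tables[[1]]) &&
      !inherits(tables[[1]], "knowledge_table")) {
    tables <- tables[[1]]
  }
  stopifnot(all(vapply(tables, inherits, logical(1), "knowledge_table")))
  kinds <- vapply(tables, attr, character(1), "kind")
  scopes <- vapply(tables, attr, character(1), "scope")
  if (!any(kinds == "time")) {
    stop("a profile needs at least one time-activity table", call. = FALSE)
  }
  if (anyDuplicated(paste(kinds, ifelse(kinds == "time", scopes, "")))) {
    stop("at most one table per (kind, scope)", call. = FALSE)
  }
  frames <- lapply(tables, attr, "frame")
  if (length(unique(lapply(frames, as.character))) != 1) {
    stop("all tables must share one frame", call. = FALSE)
  }
  structure(list(tables = tables, frame = frames[[1]]),
            class = "knowledge_profile")
}

profile_table <- function(profile, kind, scope = NULL) {
  kinds <- vapply(profile$tables, attr, character(1), "kind")
  cand <- profile$tables[kinds == kind]
  if (kind != "time") return(if (length(cand)) cand[[1]] else NULL)
  scopes <- vapply(cand, attr, character(1), "scope")
  hit <- which(scopes == scope)
  if (length(hit) == 0) hit <- which(scopes == "any")
  if (length(hit) == 0) hit <- 1L # fall back to whatever time table exists
  cand[[hit[1]]]
}

row_to_bba <- function(row, frame) {
  w <- as.numeric(row[, as.character(frame)])
  if (all(w == 0)) {
    warning("all-zero score row; source abstains (uniform BBA)",
            call. = FALSE)
    return(make_bayesian_bba(frame, rep(1, length(frame))))
  }
  make_bayesian_bba(frame, w)
}

#' Knowledge BBA for a timestamp
#'
#' Selects the time table matching the calendar scope, looks up the period
#' covering the timestamp, and row-normalizes the integer scores into a
#' Bayesian BBA.  When location / previous-activity context and the
#' corresponding optional tables are present, each yields its own BBA and
#' all are chained with [combine_pcr5()] in the fixed order time,
#' location, transition.  An all-zero row abstains (uniform BBA with a
#' warning) rather than vetoing.
#'
#' @param profile A `knowledge_profile`.
#' @param timestamp Clock time (see [lookup_row()]); a `POSIXct` also
#'   decides weekday/weekend when `weekend` is `NULL`.
#' @param weekend Logical; `NULL` derives it from a `POSIXct` timestamp
#'   (Saturday/Sunday), defaulting to weekday otherwise.
#' @param location Optional location key into the location table.
#' @param previous Optional previous-activity label for the transition
#'   table.
#' @param gap Gap policy passed to [lookup_row()].
#' @return A Bayesian `bba`.
#' @export
#' @examples
#' f <- adl_frame(c("reading", "sleeping"))
#' tab <- knowledge_table(
#'   data.frame(period = c("00:00-07:59", "08:00-21:59", "22:00-00:00"),
#'              reading = c(1L, 8L, 1L), sleeping = c(9L, 2L, 9L),
#'              check.names = FALSE),
#'   frame = f)
#' knowledge_bba(knowledge_profile(tab), "21:18:00")
knowledge_bba <- function(profile, timestamp, weekend = NULL,
                          location = NULL, previous = NULL,
                          gap = "nearest") {
  stopifnot(inherits(profile, "knowledge_profile"))
  frame <- profile$frame
  if (is.null(weekend)) {
    weekend <- inherits(timestamp, "POSIXt") &&
      as.POSIXlt(timestamp)$wday %in% c(0L, 6L)
  }
  tab <- profile_table(profile, "time",
                       scope = if (weekend) "weekend" else "weekday")
  m <- row_to_bba(lookup_row(tab, timestamp, gap = gap), frame)
  loc_tab <- profile_table(profile, "location")
  if (!is.null(location) && !is.null(loc_tab)) {
    hit <- which(loc_tab$key == location)
    if (length(hit) == 1) {
      m <- combine_pcr5(m, row_to_bba(loc_tab[hit, ], frame))
    }
  }
  tr_tab <- profile_table(profile, "transition")
  if (!is.null(previous) && !is.null(tr_tab)) {
    hit <- which(tr_tab$key == previous)
    if (length(hit) == 1) {
      m <- combine_pcr5(m, row_to_bba(tr_tab[hit, ], frame))
    }
  }
  m
}
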