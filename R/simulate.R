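# Seeded synthetic benchmark generator.
#
# Emulates the statistical structure each pipeline stage assumes, for the
# 15-activity frame: class-specific tag mixtures (signature tags diluted
# by a shared background vocabulary, so the image source is good but
# imperfect), activity-dependent IMU regimes (sedentary / periodic /
# irregular / reoriented, so locomotion-style classes are separable from
# motion alone while sedentary classes are mutually confusable), GPS
# speed regimes (log-normal; transport fast, walking moderate, sedentary
# near zero), and clock-time schedules (so the knowledge source is
# informative but ambiguous where schedules overlap).  Every distribution
# here is this package's own modelling choice; parameters live in
# default_activity_profiles() and sim_config().

#' Default per-activity simulation profiles
#'
#' One row per activity: signature tags, tag mixture weight, IMU regime
#' and parameters, GPS speed distribution, and weekday schedule windows
#' (start hour, end hour, score 0-10).
#'
#' @return A tibble with list-columns `tags`, `imu`, `gps`, `schedule`.
#' @export
default_activity_profiles <- function() {
  sig <- list(
    "cleaning"        = c("broom", "dust", "vacuum", "mop", "bucket",
                          "spray", "wipe", "floor"),
    "computer use"    = c("keyboard", "monitor", "screen", "laptop",
                          "mouse", "internet", "electronics", "office"),
    "eating"          = c("food", "plate", "fork", "meal", "drink",
                          "restaurant", "bowl", "dinner"),
    "entertainment"   = c("game", "cards", "poker", "sofa", "fun",
                          "friends", "leisure", "room"),
    "lying down"      = c("bed", "pillow", "blanket", "bedroom", "rest",
                          "sleep", "mattress", "lamp"),
    "meeting"         = c("conference", "whiteboard", "presentation",
                          "projector", "colleagues", "agenda", "office",
                          "laptop"),
    "reading"         = c("book", "page", "novel", "bookshelf", "desk",
                          "paper", "glasses", "lamp"),
    "shopping"        = c("shop", "market", "merchandise", "supermarket",
                          "cart", "shelf", "price", "stock"),
    "talking"         = c("person", "face", "conversation", "friends",
                          "portrait", "smile", "group", "room"),
    "telephone use"   = c("phone", "smartphone", "screen", "electronics",
                          "call", "touchscreen", "message", "hand"),
    "transportation"  = c("dashboard", "steering wheel", "road", "traffic",
                          "windshield", "car", "drive", "driver"),
    "walking outside" = c("street", "sidewalk", "tree", "sky", "outdoors",
                          "building", "park", "path"),
    "washing up"      = c("bathroom", "sink", "faucet", "soap", "towel",
                          "mirror", "bath", "hygiene"),
    "watching TV"     = c("television", "tv", "remote", "sofa", "show",
                          "living room", "couch", "room"),
    "writing"         = c("pen", "notebook", "paper", "handwriting",
                          "desk", "letter", "journal", "ink")
  )
  imu <- list(
    "cleaning"        = list(regime = "irregular", amp = 0.6),
    "computer use"    = list(regime = "sedentary", amp = 0.02),
    "eating"          = list(regime = "sedentary", amp = 0.03),
    "entertainment"   = list(regime = "sedentary", amp = 0.02),
    "lying down"      = list(regime = "reoriented", amp = 0.02),
    "meeting"         = list(regime = "sedentary", amp = 0.02),
    "reading"         = list(regime = "sedentary", amp = 0.02),
    "shopping"        = list(regime = "periodic", amp = 0.25, freq = 1.6),
    "talking"         = list(regime = "sedentary", amp = 0.03),
    "telephone use"   = list(regime = "sedentary", amp = 0.02),
    "transportation"  = list(regime = "sedentary", amp = 0.05),
    "walking outside" = list(regime = "periodic", amp = 0.5, freq = 2.0),
    "washing up"      = list(regime = "irregular", amp = 0.25),
    "watching TV"     = list(regime = "sedentary", amp = 0.02),
    "writing"         = list(regime = "sedentary", amp = 0.02)
  )
  gps <- list( # meanlog/sdlog of a log-normal speed (m/s)
    "transportation"  = list(meanlog = log(10), sdlog = 0.3),
    "walking outside" = list(meanlog = log(1.4), sdlog = 0.2),
    "shopping"        = list(meanlog = log(0.6), sdlog = 0.3)
  )
  conf <- list( # visually confusable neighbours: tag draws leak here
    "cleaning"        = c("washing up"),
    "computer use"    = c("telephone use", "meeting"),
    "eating"          = c("talking"),
    "entertainment"   = c("watching TV", "talking"),
    "lying down"      = c("reading"),
    "meeting"         = c("computer use", "talking"),
    "reading"         = c("writing", "lying down"),
    "shopping"        = c("walking outside"),
    "talking"         = c("meeting", "eating"),
    "telephone use"   = c("computer use"),
    "transportation"  = character(0),
    "walking outside" = c("shopping"),
    "washing up"      = c("cleaning"),
    "watching TV"     = c("entertainment"),
    "writing"         = c("reading")
  )
  sched <- list( # weekday windows: start hour, end hour, score
    "cleaning"        = list(c(9, 10, 6)),
    "computer use"    = list(c(9, 12, 9), c(14, 17, 9)),
    "eating"          = list(c(7, 8, 9), c(12, 13, 9), c(18, 19, 9)),
    "entertainment"   = list(c(20, 22, 7)),
    "lying down"      = list(c(13, 14, 5), c(22, 24, 9)),
    "meeting"         = list(c(10, 11, 8)),
    "reading"         = list(c(21, 23, 7)),
    "shopping"        = list(c(17, 18, 6)),
    "talking"         = list(c(12, 13, 7), c(19, 20, 7)),
    "telephone use"   = list(c(11, 12, 8), c(19, 20, 7)),
    "transportation"  = list(c(8, 9, 8), c(17, 18, 8)),
    "walking outside" = list(c(7, 8, 4), c(18, 19, 6)),
    "washing up"      = list(c(7, 8, 7), c(22, 23, 6)),
    "watching TV"     = list(c(19, 21, 8)),
    "writing"         = list(c(15, 17, 6))
  )
  labels <- adl_activities$label
  tibble::tibble(
    label = labels,
    tags = unname(sig[labels]),
    neighbours = unname(conf[labels]),
    imu = unname(imu[labels]),
    gps = lapply(labels, function(l) {
      gps[[l]] %||% list(meanlog = log(0.05), sdlog = 0.5)
    }),
    schedule = unname(sched[labels])
  )
}

background_vocabulary <- function() {
  c("indoors", "people", "no person", "room", "light", "wall", "table",
    "furniture", "window", "door", "floor", "ceiling", "shadow", "color",
    "blur", "closeup", "daylight", "interior", "house", "home", "object",
    "hand", "wood", "glass", "plastic", "container", "technology",
    "business", "adult", "one", "two", "many", "still life", "design",
    "contemporary", "empty", "horizontal", "vertical", "detail", "scene")
}

#' Simulation configuration
#'
#' @param frame Frame of discernment.
#' @param profiles Per-activity profiles
#'   ([default_activity_profiles()]).
#' @param samples_per_class Image records generated per activity.
#' @param L Tags per bag (default 20).
#' @param rate IMU sampling rate in Hz (default 90).
#' @param image_period Nominal image spacing in seconds (default 4; also
#'   the minimum spacing enforced between generated image timestamps).
#' @param tag_mixture Probability that a tag is drawn from the activity's
#'   signature set rather than the shared background vocabulary
#'   (default 0.5).
#' @param neighbour_rate Probability that a signature draw leaks to a
#'   visually confusable neighbour's signature (default 0.35), so the
#'   image source is good but imperfect, with errors concentrated inside
#'   confusion groups.
#' @param schedule_adherence Probability that a sample's timestamp is
#'   drawn from the activity's own schedule windows rather than uniformly
#'   over the day (default 0.8).
#' @param gps_gap_rate Fraction of image timestamps without a GPS fix,
#'   exercising carry-forward (default 0.05).
#' @param seed Mandatory integer seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(frame = adl_frame(),
                       profiles = default_activity_profiles(),
                       samples_per_class = 20, L = 20, rate = 90,
                       image_period = 4, tag_mixture = 0.5,
                       neighbour_rate = 0.35,
                       schedule_adherence = 0.8, gps_gap_rate = 0.05,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  frame <- as_frame(frame)
  stopifnot(samples_per_class >= 1, L >= 1,
            tag_mixture >= 0, tag_mixture <= 1,
            schedule_adherence >= 0, schedule_adherence <= 1,
            all(as.character(frame) %in% profiles$label))
  profiles <- profiles[match(as.character(frame), profiles$label), ]
  # neighbours outside the chosen frame cannot leak tags
  profiles$neighbours <- lapply(profiles$neighbours, intersect,
                                as.character(frame))
  structure(list(frame = frame,
                 profiles = profiles,
                 samples_per_class = samples_per_class, L = L, rate = rate,
                 image_period = image_period, tag_mixture = tag_mixture,
                 neighbour_rate = neighbour_rate,
                 schedule_adherence = schedule_adherence,
                 gps_gap_rate = gps_gap_rate, seed = as.integer(seed)),
            class = "sim_config")
}

schedule_scores <- function(windows, hours_start, hours_end) {
  # score of each table period = max score of any overlapping window
  vapply(seq_along(hours_start), function(i) {
    s <- 0
    for (w in windows) {
      if (w[1] < hours_end[i] && w[2] > hours_start[i]) s <- max(s, w[3])
    }
    as.integer(s)
  }, integer(1))
}

#' Generate weekday and weekend knowledge tables
#'
#' Hourly periods (`"HH:01"`-style rows mirroring hand-authored tables);
#' each cell scores the activity by its schedule affinity in that hour.
#' The weekend table shifts every window one hour later, emulating a
#' later weekend routine.
#'
#' @param config A [sim_config()].
#' @return A list with elements `weekday` and `weekend`
#'   (`knowledge_table` objects).
#' @export
generate_knowledge_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  frame <- config$frame
  periods <- sprintf("%02d:01–%02d:00", 0:23, c(1:23, 0))
  hours_start <- 0:23
  hours_end <- 1:24
  build <- function(shift) {
    scores <- vapply(seq_len(nrow(config$profiles)), function(k) {
      w2 <- list() # shifted windows, split at midnight when they wrap
      for (x in config$profiles$schedule[[k]]) {
        s <- x[1] + shift; e <- x[2] + shift
        if (e <= 24) {
          w2 <- c(w2, list(c(s, e, x[3])))
        } else {
          w2 <- c(w2, list(c(s, 24, x[3]), c(0, e - 24, x[3])))
        }
      }
      schedule_scores(w2, hours_start, hours_end)
    }, integer(24))
    df <- tibble::as_tibble(scores, .name_repair = "minimal")
    names(df) <- as.character(frame)
    df <- dplyr::bind_cols(tibble::tibble(period = periods), df)
    df
  }
  list(
    weekday = knowledge_table(build(0), frame = frame, kind = "time",
                              scope = "weekday"),
    weekend = knowledge_table(build(1), frame = frame, kind = "time",
                              scope = "weekend")
  )
}

sample_timestamps <- function(config) {
  frame <- as.character(config$frame)
  n <- config$samples_per_class
  acts <- rep(frame, each = n)
  t <- numeric(length(acts))
  for (i in seq_along(acts)) {
    prof <- config$profiles[config$profiles$label == acts[i], ]
    wins <- prof$schedule[[1]]
    if (stats::runif(1) < config$schedule_adherence && length(wins) > 0) {
      w <- wins[[sample.int(length(wins), 1)]]
      t[i] <- stats::runif(1, w[1] * 3600, w[2] * 3600)
    } else {
      t[i] <- stats::runif(1, 61, SECONDS_PER_DAY - 4)
    }
  }
  ord <- order(t)
  acts <- acts[ord]; t <- t[ord]
  # enforce the minimum image spacing without reordering
  for (i in seq_along(t)[-1]) {
    t[i] <- max(t[i], t[i - 1] + config$image_period)
  }
  tibble::tibble(activity = acts, timestamp = t)
}

draw_tags <- function(config, activity) {
  prof <- config$profiles[config$profiles$label == activity, ]
  signature <- prof$tags[[1]]
  neighbours <- prof$neighbours[[1]]
  bg <- background_vocabulary()
  from_sig <- stats::runif(config$L) < config$tag_mixture
  tags <- character(config$L)
  # background tags follow a mildly skewed (Zipf-like) frequency profile
  bg_w <- 1 / seq_along(bg)
  tags[!from_sig] <- sample(bg, sum(!from_sig), replace = TRUE, prob = bg_w)
  for (i in which(from_sig)) {
    # a signature draw leaks to a visually confusable neighbour's
    # signature at neighbour_rate, emulating shared objects in view
    pool <- signature
    if (length(neighbours) > 0 &&
        stats::runif(1) < config$neighbour_rate) {
      nb <- config$profiles[config$profiles$label ==
                              neighbours[sample.int(length(neighbours), 1)], ]
      pool <- nb$tags[[1]]
    }
    tags[i] <- sample(pool, 1)
  }
  tags
}

#' Generate a labelled bag-of-tags stream
#'
#' @param config A [sim_config()].
#' @param schedule Optional timestamp/activity tibble (from
#'   [sample_schedule()]); drawn fresh when omitted.
#' @return Tibble `id`, `timestamp`, `activity`, `tags` (list-column of
#'   length-`L` character vectors).
#' @export
generate_bot_stream <- function(config, schedule = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  if (is.null(schedule)) schedule <- sample_timestamps(config)
  schedule$id <- sprintf("img%05d", seq_len(nrow(schedule)))
  schedule$tags <- lapply(schedule$activity, draw_tags, config = config)
  schedule[, c("id", "timestamp", "activity", "tags")]
}

#' Sample the image schedule (timestamps and gold labels)
#'
#' @param config A [sim_config()].
#' @return Tibble `activity`, `timestamp` (seconds of day, ascending,
#'   spaced by at least `image_period`).
#' @export
sample_schedule <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sample_timestamps(config)
}

imu_segment <- function(times, regime, amp, freq = NULL) {
  n <- length(times)
  noise <- function(s) stats::rnorm(n, 0, s)
  g <- c(0, 0, 1) # gravity, in g units, device worn upright
  if (regime == "reoriented") g <- c(1, 0, 0)
  acc <- cbind(g[1] + noise(amp), g[2] + noise(amp), g[3] + noise(amp))
  gyr <- cbind(noise(amp * 50 + 1), noise(amp * 50 + 1), noise(amp * 50 + 1))
  if (regime == "periodic") {
    f <- freq * stats::runif(1, 0.9, 1.1)
    ph <- stats::runif(3, 0, 2 * pi)
    a <- amp * stats::runif(1, 0.8, 1.2)
    acc <- acc + cbind(0.5 * a * sin(2 * pi * f * times + ph[1]),
                       0.5 * a * sin(2 * pi * f * times + ph[2]),
                       a * sin(2 * pi * f * times + ph[3]))
    gyr <- gyr + 40 * a * cbind(sin(2 * pi * f * times + ph[2]),
                                sin(2 * pi * f * times + ph[3]),
                                sin(2 * pi * f * times + ph[1]))
  } else if (regime == "irregular") {
    burst <- stats::rbinom(n, 1, 0.15)
    acc <- acc + burst * cbind(stats::rnorm(n, 0, amp * 3),
                               stats::rnorm(n, 0, amp * 3),
                               stats::rnorm(n, 0, amp * 3))
    gyr <- gyr + burst * matrix(stats::rnorm(3 * n, 0, amp * 150), n)
  }
  cbind(acc, gyr)
}

#' Generate IMU and GPS streams aligned to a schedule
#'
#' Per image timestamp: a 3.2-s six-channel IMU segment at `rate` Hz in
#' the activity's motion regime, and (unless dropped by `gps_gap_rate`) a
#' GPS fix with a regime-matched log-normal speed.
#'
#' @param config A [sim_config()].
#' @param schedule Tibble from [sample_schedule()] (drawn fresh when
#'   omitted).
#' @return List with tibbles `imu` (`time, ax..gz`) and `gps`
#'   (`time, lat, lon, speed`).
#' @export
generate_imu_gps <- function(config, schedule = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  if (is.null(schedule)) schedule <- sample_timestamps(config)
  margin <- 1.6
  dt <- 1 / config$rate
  segs <- vector("list", nrow(schedule))
  gps_rows <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    t0 <- schedule$timestamp[i]
    prof <- config$profiles[config$profiles$label == schedule$activity[i], ]
    im <- prof$imu[[1]]
    times <- seq(t0 - margin, t0 + margin - dt / 2, by = dt)
    ch <- imu_segment(times - t0, im$regime, im$amp, im$freq)
    segs[[i]] <- tibble::tibble(time = times,
                                ax = ch[, 1], ay = ch[, 2], az = ch[, 3],
                                gx = ch[, 4], gy = ch[, 5], gz = ch[, 6])
    if (stats::runif(1) >= config$gps_gap_rate) {
      gp <- prof$gps[[1]]
      gps_rows[[i]] <- tibble::tibble(
        time = t0,
        lat = 40.44 + stats::rnorm(1, 0, 0.002),
        lon = -79.95 + stats::rnorm(1, 0, 0.002),
        speed = stats::rlnorm(1, gp$meanlog, gp$sdlog))
    }
  }
  imu <- dplyr::arrange(dplyr::bind_rows(segs), .data$time)
  gps <- dplyr::bind_rows(gps_rows)
  list(imu = imu, gps = gps)
}

#' Generate a complete synthetic dataset bundle
#'
#' Draws a schedule, tag stream, IMU/GPS streams and knowledge tables
#' under one seed.  With `dir`, also writes the bundle in the package's
#' external formats (JSON-lines tags, CSV tables and streams, YAML
#' manifest).
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return A list: `tags`, `imu`, `gps`, `labels` (gold
#'   `id`/`timestamp`/`activity`), `knowledge` (weekday + weekend
#'   tables), `config`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  schedule <- sample_schedule(config)
  tags <- generate_bot_stream(config, schedule)
  streams <- generate_imu_gps(config, schedule)
  knowledge <- generate_knowledge_table(config)
  labels <- tags[, c("id", "timestamp", "activity")]
  bundle <- list(tags = tags[, c("id", "timestamp", "tags")],
                 imu = streams$imu, gps = streams$gps, labels = labels,
                 knowledge = knowledge, config = config)
  if (!is.null(dir)) write_dataset(bundle, dir)
  bundle
}

write_dataset <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "tags.jsonl"), "wt")
  tags_full <- bundle$tags
  for (i in seq_len(nrow(tags_full))) {
    writeLines(jsonlite::toJSON(list(id = tags_full$id[i],
                                     timestamp = tags_full$timestamp[i],
                                     tags = tags_full$tags[[i]]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  close(con)
  readr::write_csv(bundle$imu, file.path(dir, "imu.csv"), progress = FALSE)
  readr::write_csv(bundle$gps, file.path(dir, "gps.csv"), progress = FALSE)
  readr::write_csv(bundle$labels, file.path(dir, "labels.csv"),
                   progress = FALSE)
  write_knowledge_table(bundle$knowledge$weekday,
                        file.path(dir, "knowledge_weekday.csv"))
  write_knowledge_table(bundle$knowledge$weekend,
                        file.path(dir, "knowledge_weekend.csv"))
  yaml::write_yaml(list(seed = bundle$config$seed,
                        samples_per_class = bundle$config$samples_per_class,
                        frame = as.character(bundle$config$frame)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a bag-of-tags JSON-lines stream
#'
#' One object per line: `{id, timestamp, tags: [...]}`.
#'
#' @param file Path to a `.jsonl` file.
#' @return Tibble `id`, `timestamp`, `tags` (list-column).
#' @export
read_bot_stream <- function(file) {
  lines <- readLines(file)
  rows <- lapply(lines, jsonlite::fromJSON)
  tibble::tibble(
    id = vapply(rows, function(r) as.character(r$id), character(1)),
    timestamp = vapply(rows, function(r) as.numeric(r$timestamp),
                       numeric(1)),
    tags = lapply(rows, function(r) as.character(r$tags))
  )
}
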