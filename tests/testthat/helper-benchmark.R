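# The default synthetic benchmark, built once per test run and shared by
# the fusion-property and acceptance tests.  Train and test bundles use
# disjoint seeds; classifiers are trained on the training bundle only.

.benchmark_cache <- new.env(parent = emptyenv())

default_benchmark <- function(seed = 1L, samples_per_class = 100L) {
  key <- paste0("b", seed, "_", samples_per_class)
  if (!is.null(.benchmark_cache[[key]])) return(.benchmark_cache[[key]])

  train <- generate_dataset(sim_config(seed = seed,
                                       samples_per_class = samples_per_class))
  test <- generate_dataset(sim_config(seed = seed + 5000L,
                                      samples_per_class = samples_per_class))

  corpus <- bot_corpus(
    dplyr::left_join(train$tags, train$labels[, c("id", "activity")],
                     by = "id"),
    labels = adl_activities$label)
  bot_clf <- build_bot_classifier(corpus)

  w_tr <- window_stream(train$imu, train$labels$timestamp)
  ft_tr <- extract_feature_table(w_tr, train$gps)
  sensor_model <- suppressWarnings(
    train_sensor_model(ft_tr, train$labels$activity, seed = seed))

  w_te <- window_stream(test$imu, test$labels$timestamp)
  ft_te <- extract_feature_table(w_te, test$gps)
  sensor_pred <- predict_sensor(sensor_model, ft_te)
  image_pred <- classify_bots(test$tags, bot_clf)
  profile <- knowledge_profile(train$knowledge$weekday,
                               train$knowledge$weekend)
  knowledge_pred <- lapply(test$labels$timestamp, function(t) {
    suppressWarnings(knowledge_bba(profile, t))
  })

  fused <- mapply(function(k, i, s) fuse_full(k, i, s, fusion_config()),
                  knowledge_pred, image_pred$bba, sensor_pred$bba,
                  SIMPLIFY = FALSE)

  out <- list(
    train = train, test = test, bot_clf = bot_clf,
    sensor_model = sensor_model, profile = profile,
    gold = test$labels$activity,
    knowledge_bbas = knowledge_pred,
    image_bbas = image_pred$bba,
    sensor_bbas = sensor_pred$bba,
    knowledge_labels = vapply(knowledge_pred, argmax_activity, character(1)),
    image_labels = vapply(image_pred$bba, argmax_activity, character(1)),
    sensor_labels = sensor_pred$label,
    fused = fused,
    fused_labels = vapply(fused, function(d) d$final, character(1))
  )
  .benchmark_cache[[key]] <- out
  out
}
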