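# broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a BBA into a tibble
#'
#' @param x A `bba`.
#' @param ... Unused.
#' @return Tibble with columns `focal` (canonical focal-element string),
#'   `size` (number of members) and `mass`.
#' @export
tidy.bba <- function(x, ...) {
  tibble::tibble(
    focal = names(x),
    size = lengths(focal_members(names(x))),
    mass = as.numeric(x)
  )
}

#' @export
glance.bba <- function(x, ...) {
  tibble::tibble(
    n_focal = length(x),
    bayesian = is_bayesian(x),
    max_mass = max(as.numeric(x)),
    argmax = argmax_activity(x)
  )
}

#' Tidy a fusion decision
#'
#' @param x A `fusion_decision`.
#' @param ... Unused.
#' @return One row per (level, focal element) with its mass.
#' @export
tidy.fusion_decision <- function(x, ...) {
  out <- dplyr::mutate(tidy(x$level1), level = 1L, .before = 1)
  if (!is.null(x$level2)) {
    out <- dplyr::bind_rows(out, dplyr::mutate(tidy(x$level2), level = 2L,
                                               .before = 1))
  }
  out
}

#' @export
glance.fusion_decision <- function(x, ...) {
  tibble::tibble(
    final = x$final,
    conflict = x$conflict,
    n_candidates = if (is.null(x$candidates)) NA_integer_ else
      length(x$candidates)
  )
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The per-class precision/recall/F1 tibble.
#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    accuracy = x$accuracy,
    macro_precision = x$macro_precision,
    macro_recall = x$macro_recall,
    macro_f1 = x$macro_f1
  )
}

#' @export
tidy.bot_classifier <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.sensor_model <- function(x, ...) {
  tibble::tibble(
    classes = length(x$classes),
    cost = x$cost,
    gamma = x$gamma,
    cv_accuracy = max(x$grid$accuracy)
  )
}

#' Plot a BBA as a mass bar chart
#'
#' @param object A `bba`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bba <- function(object, ...) {
  d <- tidy(object)
  d$focal <- factor(d$focal, levels = d$focal)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$focal, y = .data$mass)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "mass") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot an evaluation report as a confusion heatmap
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- tibble::as_tibble(as.table(object$confusion), .name_repair = "minimal")
  names(d) <- c("truth", "prediction", "n")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 2.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "prediction", y = "truth") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
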