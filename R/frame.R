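#' The default frame of discernment: 15 activities of daily living
#'
#' A tibble describing the activities over which all belief assignments are
#' defined, in the fixed order used for deterministic tie-breaking
#' throughout the package.
#'
#' @format A tibble with 15 rows and two columns: `label` (the canonical
#'   activity identifier, e.g. `"computer use"`) and `code` (a two-letter
#'   display abbreviation, e.g. `"CU"`).
#' @export
#' @examples
#' adl_activities
adl_activities <- tibble::tibble(
  label = c(
    "cleaning", "computer use", "eating", "entertainment", "lying down",
    "meeting", "reading", "shopping", "talking", "telephone use",
    "transportation", "walking outside", "washing up", "watching TV",
    "writing"
  ),
  code = c(
    "CN", "CU", "ET", "EM", "LD", "MT", "RD", "SP", "TK", "TU",
    "TP", "WO", "WU", "TV", "WT"
  )
)

#' Construct a frame of discernment
#'
#' A frame is an ordered character vector of unique activity labels.  The
#' order is total and fixed: it defines canonical focal-element strings and
#' breaks all ties (arg-max, candidate selection) deterministically.
#'
#' @param labels Character vector of at least two unique activity labels.
#'   Defaults to the 15 ADLs in [adl_activities].
#' @return A character vector with class `"adl_frame"`.
#' @export
#' @examples
#' adl_frame()            # the 15 default ADLs
#' adl_frame(c("a", "b")) # a toy 2-activity frame
adl_frame <- function(labels = adl_activities$label) {
  labels <- as.character(labels)
  if (anyNA(labels) || any(!nzchar(labels))) {
    stop("frame labels must be non-missing, non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("frame labels must be unique", call. = FALSE)
  }
  if (length(labels) < 2) {
    stop("a frame needs at least 2 labels", call. = FALSE)
  }
  structure(labels, class = c("adl_frame", "character"))
}

as_frame <- function(x) {
  if (inherits(x, "adl_frame")) x else adl_frame(x)
}

#' @export
print.adl_frame <- function(x, ...) {
  cat("<frame of discernment: ", length(x), " activities>\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}
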