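# Basic belief assignments over a frame of discernment.
#
# A `bba` is a named numeric vector: names are canonical focal-element
# strings (subset members in frame order, joined by " + "), values are
# masses in [0, 1] summing to 1, with no mass on the empty set.  The model
# is the power set (Shafer model): distinct singletons intersect to the
# empty set; the full frame is an admissible focal element, so vacuous
# BBAs exist.  Intersections of distinct hypotheses (the free-DSm part of
# the hyper-power set) are never populated by any source in this pipeline
# and are not enumerated.

FOCAL_SEP <- " + "

# sums deviating from 1 by <= MASS_TOL_EXACT pass silently; by
# <= MASS_TOL_RENORM they are renormalized with a warning (inputs printed
# at 4 decimals land here); larger deviations are errors.
MASS_TOL_EXACT <- 1e-9
MASS_TOL_RENORM <- 1e-3

canonical_focal <- function(members, frame) {
  members <- unique(as.character(members))
  idx <- match(members, frame)
  if (anyNA(idx)) {
    stop("focal element members must be frame labels: ",
         paste(members[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  paste(frame[sort(idx)], collapse = FOCAL_SEP)
}

focal_members <- function(name) {
  strsplit(name, FOCAL_SEP, fixed = TRUE)
}

#' Construct a basic belief assignment
#'
#' @param masses Named numeric vector.  Names are focal elements: either a
#'   single activity label or several labels joined by `" + "` (a subset of
#'   the frame).  Values are non-negative masses.  Sums deviating from 1 by
#'   at most `1e-3` (e.g. inputs rounded to 4 decimals) are renormalized
#'   with a warning; larger deviations are an error.
#' @param frame A frame of discernment ([adl_frame()]) or character vector
#'   of labels.
#' @return An object of class `"bba"`.
#' @seealso [make_bayesian_bba()], [vacuous_bba()], [combine_pcr5()]
#' @export
#' @examples
#' f <- adl_frame(c("reading", "writing", "watching TV"))
#' bba(c("reading" = 0.6, "writing" = 0.3, "reading + writing" = 0.1), f)
bba <- function(masses, frame) {
  frame <- as_frame(frame)
  if (is.null(names(masses)) || any(!nzchar(names(masses)))) {
    stop("masses must be a fully named numeric vector", call. = FALSE)
  }
  if (any(!is.finite(masses))) stop("masses must be finite", call. = FALSE)
  if (any(masses < 0)) stop("masses must be non-negative", call. = FALSE)
  canon <- vapply(focal_members(names(masses)), canonical_focal,
                  character(1), frame = frame)
  m <- vapply(split(as.numeric(masses), canon), sum, numeric(1))
  m <- m[m > 0]
  if (length(m) == 0) stop("a BBA needs positive mass somewhere", call. = FALSE)
  total <- sum(m)
  if (abs(total - 1) > MASS_TOL_RENORM) {
    stop(sprintf("masses sum to %.6f; more than %g away from 1", total,
                 MASS_TOL_RENORM), call. = FALSE)
  }
  if (abs(total - 1) > MASS_TOL_EXACT) {
    warning(sprintf("masses sum to %.6f; renormalizing", total), call. = FALSE)
  }
  m <- m / total
  # order focal elements deterministically: by size then frame position
  mem <- focal_members(names(m))
  key <- vapply(mem, function(s) {
    idx <- match(s, frame)
    sum(2^(idx - 1))
  }, numeric(1))
  m <- m[order(lengths(mem), key)]
  structure(m, frame = frame, class = "bba")
}

#' Build a Bayesian BBA from non-negative weights
#'
#' Normalizes a weight per activity into singleton masses, e.g. a row of a
#' time-activity table scored 0-10 per activity.
#'
#' @param frame Frame of discernment.
#' @param weights Non-negative numeric vector, one per frame label, at
#'   least one positive.  An all-zero vector is a degenerate source and is
#'   rejected.
#' @return A Bayesian `bba` (all focal elements singletons).
#' @export
#' @examples
#' make_bayesian_bba(adl_frame(c("a", "b", "c")), c(2, 1, 1))
make_bayesian_bba <- function(frame, weights) {
  frame <- as_frame(frame)
  weights <- as.numeric(weights)
  if (length(weights) != length(frame)) {
    stop("need exactly one weight per frame label", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and non-negative", call. = FALSE)
  }
  if (all(weights == 0)) {
    stop("degenerate source: all weights are zero", call. = FALSE)
  }
  m <- weights / sum(weights)
  names(m) <- frame
  out <- m[m > 0]
  structure(out, frame = frame, class = "bba")
}

#' The vacuous BBA (total ignorance)
#'
#' All mass on the full frame; neutral element of conjunctive combination.
#'
#' @inheritParams make_bayesian_bba
#' @return A `bba` with a single focal element, the whole frame.
#' @export
vacuous_bba <- function(frame) {
  frame <- as_frame(frame)
  m <- stats::setNames(1, paste(frame, collapse = FOCAL_SEP))
  structure(m, frame = frame, class = "bba")
}

#' @export
print.bba <- function(x, digits = 4, ...) {
  frame <- attr(x, "frame")
  cat("<bba over ", length(frame), " activities; ",
      length(x), " focal element(s)",
      if (is_bayesian(x)) "; Bayesian" else "", ">\n", sep = "")
  v <- round(as.numeric(x), digits)
  names(v) <- names(x)
  print(v, ...)
  invisible(x)
}

bba_frame <- function(m) attr(m, "frame")

#' Is a BBA Bayesian?
#'
#' A BBA is Bayesian when every focal element is a singleton.
#'
#' @param m A `bba`.
#' @return Logical scalar.
#' @export
is_bayesian <- function(m) {
  stopifnot(inherits(m, "bba"))
  all(lengths(focal_members(names(m))) == 1L)
}

#' Reduce a BBA to singleton beliefs
#'
#' Returns, for every frame label, the sum of the masses of all focal
#' elements containing it (for a Bayesian BBA this is the mass itself; for
#' set-valued focal elements it credits each member in full, i.e. the
#' plausibility of the singleton).
#'
#' @param m A `bba`.
#' @return Named numeric vector over the full frame.
#' @export
singleton_beliefs <- function(m) {
  stopifnot(inherits(m, "bba"))
  frame <- bba_frame(m)
  out <- stats::setNames(numeric(length(frame)), frame)
  mem <- focal_members(names(m))
  for (i in seq_along(mem)) out[mem[[i]]] <- out[mem[[i]]] + m[[i]]
  out
}

#' Arg-max decision from a BBA
#'
#' The label with the highest singleton belief (see [singleton_beliefs()]);
#' ties are broken by frame order (earliest label wins).
#'
#' @param m A `bba`.
#' @return A single activity label.
#' @export
#' @examples
#' f <- adl_frame(c("a", "b", "c"))
#' argmax_activity(make_bayesian_bba(f, c(0.1, 0.8, 0.1)))
argmax_activity <- function(m) {
  b <- singleton_beliefs(m)
  names(b)[which.max(b)] # which.max takes the first maximum: frame order
}

#' Restrict a BBA to a candidate set and renormalize
#'
#' Intersects every focal element with the candidate set, drops emptied
#' elements, and renormalizes the surviving mass to 1.  If the whole mass
#' would be dropped, returns the uniform BBA over the candidates and marks
#' the result with attribute `degenerate = TRUE`.
#'
#' @param m A `bba`.
#' @param candidates Non-empty subset of the frame labels.
#' @return A `bba` over the same frame whose focal elements are subsets of
#'   `candidates`; attribute `degenerate` is `TRUE` when all original mass
#'   was lost.
#' @export
restrict_bba <- function(m, candidates) {
  stopifnot(inherits(m, "bba"))
  frame <- bba_frame(m)
  candidates <- unique(as.character(candidates))
  if (length(candidates) == 0) stop("empty candidate set", call. = FALSE)
  if (any(!candidates %in% frame)) {
    stop("candidates must be frame labels", call. = FALSE)
  }
  mem <- focal_members(names(m))
  kept <- lapply(mem, intersect, candidates)
  keep <- lengths(kept) > 0
  if (!any(keep)) {
    out <- make_bayesian_bba(frame, as.numeric(frame %in% candidates))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  nm <- vapply(kept[keep], canonical_focal, character(1), frame = frame)
  v <- vapply(split(as.numeric(m)[keep], nm), sum, numeric(1))
  out <- bba(v / sum(v), frame)
  attr(out, "degenerate") <- FALSE
  out
}

#' Serialize / deserialize a BBA as JSON
#'
#' The JSON form is `{"frame": [labels], "masses": {focal-string: mass}}`.
#'
#' @param m A `bba`.
#' @return `bba_to_json()`: a JSON string; `bba_from_json()`: a `bba`.
#' @export
bba_to_json <- function(m) {
  stopifnot(inherits(m, "bba"))
  jsonlite::toJSON(
    list(frame = as.character(bba_frame(m)), masses = as.list(unclass(m))),
    auto_unbox = TRUE, digits = NA
  )
}

#' @param json A JSON string produced by [bba_to_json()].
#' @rdname bba_to_json
#' @export
bba_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  bba(unlist(x$masses), adl_frame(x$frame))
}
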