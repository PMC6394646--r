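# Combination rules: conjunctive consensus with proportional conflict
# redistribution (PCR5 for two sources, PCR6 for two or more).
#
# Both rules share the tuple view: every s-tuple of focal elements, one per
# source, contributes the product of its masses.  A tuple whose members
# intersect to a non-empty set A adds the product to m(A) (conjunctive
# consensus).  A conflicting tuple (empty intersection) has its product
# redistributed back to the focal elements that generated it, each source i
# receiving the share m_i(X_i) / sum_j m_j(X_j).  For s = 2 this is PCR5;
# PCR6 generalizes the same redistribution to any s and reduces exactly to
# PCR5 at s = 2.  A redistribution term with zero denominator necessarily
# has a zero numerator and is defined as 0.

check_shared_frame <- function(sources) {
  frames <- lapply(sources, bba_frame)
  ref <- frames[[1]]
  ok <- vapply(frames, function(f) identical(as.character(f),
                                             as.character(ref)), logical(1))
  if (!all(ok)) stop("all sources must share the same frame", call. = FALSE)
  ref
}

#' Combine two BBAs with the PCR5 rule
#'
#' Conjunctive consensus plus proportional redistribution of each
#' conflicting product to its two generating focal elements, in proportion
#' to their masses.  Symmetric in its arguments; the vacuous BBA is
#' neutral.
#'
#' @param m1,m2 `bba` objects on the same frame.
#' @param trace If `TRUE`, attach a `"trace"` attribute: a tibble with one
#'   row per redistribution share of each conflicting product (columns
#'   `focal_1`, `focal_2`, `product`, `receiver`, `share`).  Diagnostic
#'   only.
#' @return The combined `bba`.
#' @export
#' @examples
#' f <- adl_frame(c("a", "b"))
#' m1 <- make_bayesian_bba(f, c(0.7, 0.3))
#' m2 <- make_bayesian_bba(f, c(0.2, 0.8))
#' combine_pcr5(m1, m2)
combine_pcr5 <- function(m1, m2, trace = FALSE) {
  stopifnot(inherits(m1, "bba"), inherits(m2, "bba"))
  check_shared_frame(list(m1, m2))
  # canonicalize the argument order so m1 (+) m2 and m2 (+) m1 are
  # bit-identical, not merely equal up to summation order
  key <- vapply(list(m1, m2), function(m) {
    paste(names(m), format(unclass(m), digits = 17), collapse = ";")
  }, character(1))
  src <- if (key[1] <= key[2]) list(m1, m2) else list(m2, m1)
  combine_pcr6(src, trace = trace)
}

#' Combine two or more BBAs with the PCR6 rule
#'
#' Conjunctive consensus over all focal-element tuples plus, for every
#' conflicting tuple, proportional redistribution of its product to each
#' generating focal element.  Invariant under permutation of the sources;
#' identical to [combine_pcr5()] when exactly two sources are given.
#'
#' @param sources List of at least two `bba` objects on the same frame.
#' @inheritParams combine_pcr5
#' @return The combined `bba`.
#' @export
combine_pcr6 <- function(sources, trace = FALSE) {
  if (!is.list(sources) || length(sources) < 2) {
    stop("need at least 2 sources", call. = FALSE)
  }
  stopifnot(all(vapply(sources, inherits, logical(1), "bba")))
  frame <- check_shared_frame(sources)
  s <- length(sources)

  # represent focal elements as bitmasks over the frame (|frame| <= 31)
  bits <- function(m) {
    vapply(focal_members(names(m)), function(mem) {
      sum(2^(match(mem, frame) - 1))
    }, numeric(1))
  }
  fbits <- lapply(sources, bits)
  fmass <- lapply(sources, as.numeric)

  tuples <- expand.grid(lapply(fbits, seq_along), KEEP.OUT.ATTRS = FALSE)
  bmat <- mapply(function(b, idx) b[idx], fbits, tuples)
  mmat <- mapply(function(v, idx) v[idx], fmass, tuples)
  if (nrow(tuples) == 1) { bmat <- t(bmat); mmat <- t(mmat) }
  inter <- Reduce(bitwAnd, lapply(seq_len(s), function(i) as.integer(bmat[, i])))
  prod_mass <- apply(mmat, 1, prod)

  acc <- new.env(parent = emptyenv())
  add_mass <- function(bit, value) {
    key <- as.character(bit)
    acc[[key]] <- (acc[[key]] %||% 0) + value
  }

  consensus <- inter != 0L
  for (i in which(consensus)) add_mass(inter[i], prod_mass[i])

  trace_rows <- list()
  conflicting <- which(!consensus & prod_mass > 0)
  for (i in conflicting) {
    denom <- sum(mmat[i, ])
    shares <- prod_mass[i] * mmat[i, ] / denom
    for (j in seq_len(s)) add_mass(bmat[i, j], shares[j])
    if (trace) {
      trace_rows[[length(trace_rows) + 1L]] <- tibble::tibble(
        tuple = i,
        focal = vapply(seq_len(s), function(j) bit_label(bmat[i, j], frame),
                       character(1)),
        source = seq_len(s),
        product = prod_mass[i],
        share = shares
      )
    }
  }

  keys <- ls(acc)
  masses <- vapply(keys, function(k) acc[[k]], numeric(1))
  names(masses) <- vapply(as.numeric(keys), bit_label, character(1),
                          frame = frame)
  out <- bba(masses, frame)
  if (trace) {
    tr <- if (length(trace_rows)) dplyr::bind_rows(trace_rows) else
      tibble::tibble(tuple = integer(), focal = character(),
                     source = integer(), product = numeric(),
                     share = numeric())
    attr(out, "trace") <- tr
    attr(out, "conflict_total") <- sum(prod_mass[!consensus])
  }
  out
}

bit_label <- function(bit, frame) {
  idx <- which(bitwAnd(as.integer(bit), 2^(seq_along(frame) - 1)) != 0)
  paste(frame[idx], collapse = FOCAL_SEP)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Batch PCR6 for Bayesian sources
#'
#' Vectorized combination of `s` Bayesian sources over `n` independent
#' cases at once: each source is an `n x K` matrix of singleton masses in
#' frame order (rows summing to 1).  Used for high-throughput fusion and
#' for large-scale cross-checking against [combine_pcr6()].
#'
#' @param masses List of `s >= 2` numeric matrices of equal dimension
#'   `n x K`; rows are cases, columns singleton masses in frame order.
#' @return An `n x K` matrix of combined singleton masses.
#' @export
combine_pcr6_bayesian <- function(masses) {
  if (!is.list(masses) || length(masses) < 2) {
    stop("need at least 2 sources", call. = FALSE)
  }
  masses <- lapply(masses, function(m) {
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    m
  })
  dims <- unique(lapply(masses, dim))
  if (length(dims) != 1) stop("sources must have identical dimensions",
                              call. = FALSE)
  n <- dims[[1]][1]; K <- dims[[1]][2]; s <- length(masses)
  res <- matrix(0, n, K)
  tuples <- as.matrix(expand.grid(rep(list(seq_len(K)), s),
                                  KEEP.OUT.ATTRS = FALSE))
  for (t in seq_len(nrow(tuples))) {
    idx <- tuples[t, ]
    p <- masses[[1]][, idx[1]]
    for (i in 2:s) p <- p * masses[[i]][, idx[i]]
    if (all(idx == idx[1])) {
      res[, idx[1]] <- res[, idx[1]] + p
    } else {
      d <- masses[[1]][, idx[1]]
      for (i in 2:s) d <- d + masses[[i]][, idx[i]]
      w <- ifelse(d > 0, p / d, 0)
      for (i in seq_len(s)) {
        res[, idx[i]] <- res[, idx[i]] + w * masses[[i]][, idx[i]]
      }
    }
  }
  res
}
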