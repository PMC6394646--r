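# Independent brute-force oracles for the combination rules, written in a
# different (focal-element-centric) formulation than the package's
# tuple-centric accumulation, so indexing bugs in one cannot hide in the
# other.  All oracles assume Bayesian inputs given as plain mass vectors
# in frame order.

# two sources: conjunctive consensus plus, per focal element A, the two
# redistribution terms summed over the conflicting partners of A
pcr5_oracle_bayes <- function(p, q) {
  K <- length(p)
  out <- numeric(K)
  for (a in seq_len(K)) {
    out[a] <- p[a] * q[a]
    for (x in seq_len(K)[-a]) {
      if (p[a] + q[x] > 0) out[a] <- out[a] + p[a]^2 * q[x] / (p[a] + q[x])
      if (q[a] + p[x] > 0) out[a] <- out[a] + q[a]^2 * p[x] / (q[a] + p[x])
    }
  }
  out
}

# s sources: per focal element A and per source i, sum the redistribution
# over all (s-1)-tuples of the other sources' focal elements that
# conflict with A (for singletons: any tuple not all equal to A)
pcr6_oracle_bayes <- function(sources) {
  s <- length(sources)
  K <- length(sources[[1]])
  out <- numeric(K)
  for (a in seq_len(K)) {
    out[a] <- prod(vapply(sources, function(m) m[a], numeric(1)))
    for (i in seq_len(s)) {
      mi <- sources[[i]][a]
      if (mi == 0) next
      others <- sources[-i]
      tuples <- as.matrix(expand.grid(rep(list(seq_len(K)), s - 1)))
      for (r in seq_len(nrow(tuples))) {
        xs <- tuples[r, ]
        if (all(xs == a)) next # non-conflicting tuple
        pr <- prod(vapply(seq_len(s - 1),
                          function(j) others[[j]][xs[j]], numeric(1)))
        if (pr == 0) next
        den <- mi + sum(vapply(seq_len(s - 1),
                               function(j) others[[j]][xs[j]], numeric(1)))
        out[a] <- out[a] + mi^2 * pr / den
      }
    }
  }
  out
}

# random Bayesian BBA over a frame, with a controllable number of zeros
rand_bayes <- function(frame, zeros = 0) {
  K <- length(frame)
  w <- stats::rexp(K)
  if (zeros > 0) w[sample.int(K, zeros)] <- 0
  if (all(w == 0)) w[1] <- 1
  make_bayesian_bba(frame, w)
}

# random BBA with set-valued focal elements (power-set model)
rand_setvalued <- function(frame, n_focal = 4) {
  K <- length(frame)
  repeat {
    sets <- unique(lapply(seq_len(n_focal), function(i) {
      sort(sample.int(K, sample.int(min(3, K), 1)))
    }))
    if (length(sets) >= 2) break
  }
  w <- stats::rexp(length(sets))
  masses <- stats::setNames(w / sum(w), vapply(sets, function(s) {
    paste(as.character(frame)[s], collapse = " + ")
  }, character(1)))
  bba(masses, frame)
}

bayes_vector <- function(m) {
  unname(singleton_beliefs(m))
}

toy_frame <- function(K) adl_frame(letters[seq_len(K)])
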