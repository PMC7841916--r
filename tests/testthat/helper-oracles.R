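# Shared fixtures and independent oracles, built in code at test time.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n, alphabet = AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Exhaustive weighted-interval-scheduling oracle: enumerate every subset of
# candidates, keep those whose starts are pairwise >= min_dist apart, and
# return the best by (total score, count, lexicographically smallest starts).
brute_force_wis <- function(starts, scores, min_dist = 16L) {
  n <- length(starts)
  best <- list(score = 0, starts = integer(0))
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    st <- sort(starts[sel])
    if (length(st) > 1L && any(diff(st) < min_dist)) next
    cand <- list(score = sum(scores[sel]), starts = st)
    better <- FALSE
    if (cand$score > best$score) better <- TRUE
    else if (cand$score == best$score) {
      if (length(cand$starts) > length(best$starts)) better <- TRUE
      else if (length(cand$starts) == length(best$starts) &&
               length(cand$starts) > 0L) {
        d <- cand$starts - best$starts
        nz <- which(d != 0)
        if (length(nz) > 0L && d[nz[1L]] < 0) better <- TRUE
      }
    }
    if (better) best <- cand
  }
  best
}

# Exhaustive bipartite matching oracle for the evaluator: maximum number of
# one-to-one (predicted, reference) pairs whose 16-residue windows overlap
# by >= min_overlap.
brute_force_matching <- function(pred, ref, min_overlap = 8L) {
  compatible <- outer(pred, ref, function(p, r) {
    pmin(p, r) + 16L - pmax(p, r) >= min_overlap
  })
  recurse <- function(j, used) {
    if (j > length(ref)) return(0L)
    best <- recurse(j + 1L, used)  # leave ref j unmatched
    for (i in seq_along(pred)) {
      if (!used[i] && compatible[i, j]) {
        used2 <- used
        used2[i] <- TRUE
        best <- max(best, 1L + recurse(j + 1L, used2))
      }
    }
    best
  }
  recurse(1L, logical(length(pred)))
}

# Independent regex-based sequon oracle (lookahead keeps overlapping sites).
regex_sequons <- function(seq) {
  m <- gregexpr("N(?=[^P][ST])", seq, perl = TRUE)[[1]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

# Small trained matrix shared across tests (deterministic).
toy_trained_matrix <- function(n_segments = 300, seed = 7) {
  spec <- synthetic_spec(n_sequences = 0, seed = seed)
  train_matrix(generate_training_set(spec, n_segments))
}
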