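# Scan ectodomains with the scoring matrix, then keep the non-overlapping
# candidate group with the highest total score (weighted interval
# scheduling). Internally every coordinate is 0-based half-open; file
# writers convert to 1-based inclusive.

score_all_windows <- function(matrix, residues) {
  L <- nchar(residues)
  n_win <- L - HCS_LENGTH + 1L
  if (n_win <= 0L) return(numeric(0))
  idx <- match(seq_chars(residues), AA_ALPHABET)  # NA for 'X'
  scores <- numeric(n_win)
  w <- matrix$weights
  for (k in seq_len(HCS_LENGTH)) {
    col <- idx[k:(k + n_win - 1L)]
    contrib <- ifelse(is.na(col), 0, w[k, ifelse(is.na(col), 1L, col)])
    scores <- scores + contrib
  }
  scores
}

#' Scan a sequence for candidate HCS windows
#'
#' Scores every 16-residue window and keeps those at or above the threshold.
#'
#' @param matrix an \code{lrr_pssm}.
#' @param seq character scalar (one validated sequence).
#' @param threshold score cutoff; defaults to the matrix's stored threshold.
#' @return data.frame with columns \code{start} (0-based window offset) and
#'   \code{score}, sorted by start. Sequences shorter than 16 give zero rows.
#' @export
scan_candidates <- function(matrix, seq, threshold = matrix$threshold) {
  if (length(threshold) != 1L || is.na(threshold)) {
    stop("threshold is not calibrated; supply one or run calibrate_threshold",
         call. = FALSE)
  }
  seq <- validate_residues(seq)
  scores <- score_all_windows(matrix, seq)
  keep <- which(scores >= threshold)
  data.frame(start = keep - 1L, score = scores[keep])
}

# Lexicographic "is solution a better than b": higher total score, then more
# motifs, then smaller start tuple. Solutions are lists(score, starts).
solution_better <- function(a, b) {
  if (a$score != b$score) return(a$score > b$score)
  if (length(a$starts) != length(b$starts)) {
    return(length(a$starts) > length(b$starts))
  }
  d <- a$starts - b$starts
  nz <- which(d != 0)
  if (length(nz) == 0L) return(FALSE)
  d[nz[1L]] < 0
}

#' Resolve overlapping candidates into the best non-overlapping group
#'
#' Two 16-residue windows conflict when they share at least one position
#' (start difference < \code{min_start_distance}, default 16). Among all
#' conflict-free subsets the one with the maximal summed score is returned;
#' ties are broken towards more motifs, then the lexicographically smallest
#' start tuple. Solved by weighted-interval-scheduling dynamic programming.
#'
#' @param candidates data.frame with \code{start}, \code{score}, sorted by
#'   start (as returned by \code{\link{scan_candidates}}).
#' @param min_start_distance minimum allowed difference between kept starts.
#' @return the selected subset of \code{candidates}, sorted by start.
#' @export
resolve_overlaps <- function(candidates, min_start_distance = HCS_LENGTH) {
  n <- nrow(candidates)
  if (n == 0L) return(candidates)
  ord <- order(candidates$start)
  starts <- candidates$start[ord]
  scores <- candidates$score[ord]
  # next_ok[i]: first j > i with starts[j] >= starts[i] + min_start_distance
  next_ok <- findInterval(starts + min_start_distance - 0.5, starts) + 1L
  # dp[i]: best solution over candidates i..n; dp[n+1] empty
  dp <- vector("list", n + 1L)
  dp[[n + 1L]] <- list(score = 0, starts = integer(0), idx = integer(0))
  for (i in n:1) {
    nxt <- dp[[next_ok[i]]]
    take <- list(score = scores[i] + nxt$score,
                 starts = c(starts[i], nxt$starts),
                 idx = c(i, nxt$idx))
    skip <- dp[[i + 1L]]
    dp[[i]] <- if (solution_better(skip, take)) skip else take
  }
  out <- candidates[ord[dp[[1L]]$idx], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibrate the score threshold from the training segments
#'
#' The cutoff is set to a low percentile of the training segments' own
#' scores, so that (by construction) nearly all curated repeats would be
#' re-detected. Default: the 1st percentile.
#'
#' @param matrix an \code{lrr_pssm}.
#' @param training a \code{segment_set}.
#' @param percentile percentile in [0, 100], default 1.
#' @return the matrix with its \code{threshold} set.
#' @export
calibrate_threshold <- function(matrix, training, percentile = 1) {
  if (length(training) == 0L) {
    stop("cannot calibrate from an empty training set; ",
         "pass an absolute threshold instead", call. = FALSE)
  }
  stopifnot(percentile >= 0, percentile <= 100)
  scores <- vapply(as.character(training),
                   function(s) score_window(matrix, s), numeric(1))
  matrix$threshold <- unname(stats::quantile(scores, percentile / 100,
                                             type = 7))
  matrix
}

#' Predict the LRR motifs of one or more sequences
#'
#' Full pipeline: scan all 16-residue windows, keep candidates at or above
#' the threshold, resolve overlaps to the maximum-score non-overlapping
#' group, and materialize each kept window as a repeat with a 24-residue
#' span (truncated at the sequence end) and a 1-based index from the N- to
#' the C-terminus.
#'
#' @param sequences a \code{seq_records} object, or a single character
#'   sequence.
#' @param matrix an \code{lrr_pssm} with a calibrated threshold.
#' @param threshold optional absolute override of the matrix threshold.
#' @param min_start_distance see \code{\link{resolve_overlaps}}.
#' @param span repeat span in residues counted from each HCS start
#'   (default 24).
#' @return data.frame with columns \code{seq_id}, \code{lrr_index},
#'   \code{start} (0-based), \code{span_end} (0-based exclusive),
#'   \code{score}, \code{hcs_seq}.
#' @examples
#' spec <- synthetic_spec(n_sequences = 2, seed = 1)
#' corpus <- generate_corpus(spec)
#' m <- train_matrix(generate_training_set(spec, 200))
#' predict_lrrs(corpus$sequences, m)
#' @export
predict_lrrs <- function(sequences, matrix, threshold = matrix$threshold,
                         min_start_distance = HCS_LENGTH, span = LRR_SPAN) {
  if (!inherits(sequences, "seq_records")) {
    sequences <- seq_records(sequences)
  }
  res <- lapply(names(sequences), function(id) {
    s <- sequences[[id]]
    cand <- scan_candidates(matrix, s, threshold = threshold)
    kept <- resolve_overlaps(cand, min_start_distance = min_start_distance)
    n <- nrow(kept)
    if (n == 0L) {
      return(data.frame(seq_id = character(0), lrr_index = integer(0),
                        start = integer(0), span_end = integer(0),
                        score = numeric(0), hcs_seq = character(0)))
    }
    data.frame(
      seq_id = id,
      lrr_index = seq_len(n),
      start = kept$start,
      span_end = pmin(kept$start + span, nchar(s)),
      score = kept$score,
      hcs_seq = substring(s, kept$start + 1L, kept$start + HCS_LENGTH)
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write predictions as a TSV (1-based inclusive coordinates)
#'
#' Columns: seq_id, lrr_index, start, hcs_end, span_end, score (4 decimals),
#' hcs_seq.
#'
#' @param predictions data.frame from \code{\link{predict_lrrs}}.
#' @param path output file.
#' @export
write_predictions_tsv <- function(predictions, path) {
  out <- data.frame(
    seq_id = predictions$seq_id,
    lrr_index = predictions$lrr_index,
    start = predictions$start + 1L,
    hcs_end = predictions$start + HCS_LENGTH,
    span_end = predictions$span_end,
    score = sprintf("%.4f", predictions$score),
    hcs_seq = predictions$hcs_seq
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predictions TSV back to the internal 0-based representation
#' @param path file written by \code{\link{write_predictions_tsv}}.
#' @return data.frame as returned by \code{\link{predict_lrrs}}.
#' @export
read_predictions_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  data.frame(
    seq_id = as.character(tab$seq_id),
    lrr_index = as.integer(tab$lrr_index),
    start = as.integer(tab$start) - 1L,
    span_end = as.integer(tab$span_end),
    score = as.numeric(tab$score),
    hcs_seq = as.character(tab$hcs_seq)
  )
}

#' Write predictions as GFF3 repeat_region features
#'
#' @inheritParams write_predictions_tsv
#' @export
write_predictions_gff3 <- function(predictions, path) {
  lines <- "##gff-version 3"
  if (nrow(predictions) > 0L) {
    lines <- c(lines, sprintf(
      "%s\tlrrscan\trepeat_region\t%d\t%d\t%.4f\t.\t.\tID=%s.LRR%d;hcs_seq=%s",
      predictions$seq_id,
      predictions$start + 1L,
      predictions$span_end,
      predictions$score,
      predictions$seq_id,
      predictions$lrr_index,
      predictions$hcs_seq))
  }
  writeLines(lines, path)
  invisible(path)
}
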