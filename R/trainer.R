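# Two-round training: round 1 from curated 16-mers, round 2 a bootstrap
# that predicts repeats on an expansion corpus, accepts high-scoring
# segments (plus plain-file include/exclude overrides standing in for
# manual verification), merges them with the curated set and retrains.

#' Extract 16-residue HCS segments at given motif starts
#'
#' @param sequences a \code{seq_records} object.
#' @param motifs prediction data.frame (\code{seq_id}, \code{start}, ...).
#' @param source_tag provenance label for the resulting set.
#' @return a \code{segment_set}; motifs whose window would run past the
#'   sequence end, or whose window contains \code{X}, are dropped with a
#'   warning.
#' @export
extract_hcs_segments <- function(sequences, motifs,
                                 source_tag = "extracted") {
  segs <- character(0)
  n_skipped <- 0L
  for (i in seq_len(nrow(motifs))) {
    id <- motifs$seq_id[i]
    s <- sequences[[id]]
    start <- motifs$start[i]
    if (is.null(s) || start < 0L || start > nchar(s) - HCS_LENGTH) {
      n_skipped <- n_skipped + 1L
      next
    }
    seg <- substring(s, start + 1L, start + HCS_LENGTH)
    if (grepl("X", seg, fixed = TRUE)) {
      n_skipped <- n_skipped + 1L
      next
    }
    segs <- c(segs, seg)
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " motif window(s) skipped (out of bounds or 'X')",
            call. = FALSE)
  }
  structure(segs, source_tag = source_tag,
            rejected = data.frame(segment = character(0),
                                  reason = character(0)),
            class = "segment_set")
}

#' Train a scoring matrix from validated segments
#'
#' Composes \code{\link{build_pfm}}, \code{\link{pfm_to_ppm}},
#' \code{\link{estimate_background}}, \code{\link{ppm_to_pssm}} and
#' \code{\link{calibrate_threshold}}.
#'
#' @param segments a \code{segment_set}.
#' @param background_source optional \code{seq_records} whose letter
#'   frequencies give the background; with NULL the training segments
#'   themselves are used (uniform 1/20 if those are empty too).
#' @param pseudocount Laplace pseudocount, default 1.
#' @param threshold_percentile percentile of training-segment scores used as
#'   the cutoff (default 1); NA leaves the matrix uncalibrated.
#' @return an \code{lrr_pssm}.
#' @export
train_matrix <- function(segments, background_source = NULL,
                         pseudocount = 1, threshold_percentile = 1) {
  pfm <- build_pfm(segments)
  ppm <- pfm_to_ppm(pfm, pseudocount = pseudocount)
  bg_seqs <- if (is.null(background_source)) as.character(segments) else
    background_source
  bg <- estimate_background(bg_seqs)
  m <- ppm_to_pssm(ppm, background = bg,
                   source_tag = attr(segments, "source_tag") %||%
                     "unspecified")
  if (!is.na(threshold_percentile) && length(segments) > 0L) {
    m <- calibrate_threshold(m, segments, percentile = threshold_percentile)
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an include/exclude overrides file
#'
#' TSV with header \code{seq_id}, \code{start} (1-based in the file),
#' \code{action} (include|exclude).
#'
#' @param path file path; NULL gives empty overrides.
#' @return list with data.frames \code{include} and \code{exclude}, both
#'   with 0-based \code{start}.
#' @export
read_overrides <- function(path = NULL) {
  empty <- data.frame(seq_id = character(0), start = integer(0))
  if (is.null(path)) return(list(include = empty, exclude = empty))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("seq_id", "start", "action") %in% names(tab)))
  tab$start <- as.integer(tab$start) - 1L
  inc <- tab[tab$action == "include", c("seq_id", "start")]
  exc <- tab[tab$action == "exclude", c("seq_id", "start")]
  key <- function(d) paste(d$seq_id, d$start)
  if (length(intersect(key(inc), key(exc))) > 0L) {
    stop("overrides include and exclude sets overlap", call. = FALSE)
  }
  list(include = inc, exclude = exc)
}

#' One bootstrap training round
#'
#' Predicts motifs on an expansion corpus with the current matrix, keeps
#' segments scoring at or above \code{accept_threshold}, applies the
#' include/exclude overrides, unions the accepted segments with the current
#' training set, and retrains. With an empty expansion the inputs are
#' returned unchanged (a fixed point).
#'
#' @param matrix the current \code{lrr_pssm}.
#' @param round1_segments the current training \code{segment_set}.
#' @param expansion a \code{seq_records} corpus to mine for new segments.
#' @param accept_threshold score at or above which predicted segments are
#'   accepted; default the matrix threshold.
#' @param overrides list as returned by \code{\link{read_overrides}}.
#' @param pseudocount,threshold_percentile passed to
#'   \code{\link{train_matrix}} for the retrain.
#' @return list with \code{segments} (the merged \code{segment_set}) and
#'   \code{matrix} (the retrained \code{lrr_pssm}).
#' @export
bootstrap_round <- function(matrix, round1_segments, expansion,
                            accept_threshold = matrix$threshold,
                            overrides = read_overrides(NULL),
                            pseudocount = 1, threshold_percentile = 1) {
  if (is.null(expansion) || length(expansion) == 0L) {
    warning("empty expansion set; returning inputs unchanged", call. = FALSE)
    return(list(segments = round1_segments, matrix = matrix))
  }
  preds <- predict_lrrs(expansion, matrix)
  preds <- preds[preds$score >= accept_threshold, , drop = FALSE]
  # overrides stand in for manual verification
  key <- paste(preds$seq_id, preds$start)
  exc_key <- paste(overrides$exclude$seq_id, overrides$exclude$start)
  preds <- preds[!key %in% exc_key, , drop = FALSE]
  if (nrow(overrides$include) > 0L) {
    inc <- overrides$include
    inc_rows <- data.frame(seq_id = inc$seq_id, start = inc$start)
    preds <- rbind(preds[, c("seq_id", "start")], inc_rows)
  } else {
    preds <- preds[, c("seq_id", "start")]
  }
  new_segs <- extract_hcs_segments(expansion, preds, source_tag = "round2")
  # segment sets are multisets: duplicates carry weight in the PFM, so the
  # union concatenates rather than deduplicates
  merged <- c(as.character(round1_segments), as.character(new_segs))
  merged <- structure(merged,
                      source_tag = paste0(attr(round1_segments,
                                               "source_tag") %||% "round1",
                                          "+round2"),
                      rejected = data.frame(segment = character(0),
                                            reason = character(0)),
                      class = "segment_set")
  if (length(merged) == length(round1_segments) &&
      all(as.character(merged) == as.character(round1_segments))) {
    # no new accepted segments: reproduce the input matrix bit for bit
    return(list(segments = round1_segments, matrix = matrix))
  }
  m2 <- train_matrix(merged, pseudocount = pseudocount,
                     threshold_percentile = threshold_percentile)
  list(segments = merged, matrix = m2)
}
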