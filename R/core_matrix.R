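# Position-specific scoring matrix over the 16-residue highly conserved
# segment (HCS) of plant LRRs: counts -> Laplace-smoothed probabilities ->
# log2 odds against a background residue distribution.

#' Validate candidate 16-residue training segments
#'
#' Keeps only strings that are exactly 16 residues over the canonical
#' 20-letter alphabet (no \code{X}); everything else is rejected with a
#' reason, not an error, so bulk training files degrade gracefully.
#'
#' @param raw character vector of candidate segments.
#' @param source_tag provenance label stored with the set (e.g. "round1").
#' @return a \code{segment_set}: character vector of validated segments with
#'   attributes \code{source_tag} and \code{rejected} (data.frame with
#'   columns \code{segment}, \code{reason}).
#' @examples
#' validate_segments(c("LSDLNLSNNSLSGPIP", "TOOSHORT"))
#' @export
validate_segments <- function(raw, source_tag = "unspecified") {
  stopifnot(!is.null(raw))
  raw <- toupper(trimws(as.character(raw)))
  raw <- raw[nzchar(raw)]
  reason <- character(length(raw))
  for (i in seq_along(raw)) {
    if (nchar(raw[i]) != HCS_LENGTH) {
      reason[i] <- sprintf("length %d != %d", nchar(raw[i]), HCS_LENGTH)
    } else if (!all(seq_chars(raw[i]) %in% AA_ALPHABET)) {
      ch <- seq_chars(raw[i])
      bad <- ch[!ch %in% AA_ALPHABET][1L]
      reason[i] <- sprintf("illegal residue '%s'", bad)
    }
  }
  keep <- reason == ""
  rejected <- data.frame(segment = raw[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0L) {
    warning(nrow(rejected), " segment(s) rejected during validation",
            call. = FALSE)
  }
  segments <- raw[keep]
  if (length(segments) == 0L) {
    warning("no valid segments after validation", call. = FALSE)
  }
  structure(segments, source_tag = source_tag, rejected = rejected,
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat("segment_set:", length(x), "x", HCS_LENGTH, "residues",
      sprintf("(source: %s)\n", attr(x, "source_tag")))
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej) > 0L) cat("  rejected:", nrow(rej), "\n")
  invisible(x)
}

#' @export
`[.segment_set` <- function(x, i) {
  structure(unclass(x)[i], source_tag = attr(x, "source_tag"),
            rejected = attr(x, "rejected"), class = "segment_set")
}

#' Read training segments from a plain-text or TSV file
#'
#' Accepts one 16-mer per line with \code{#} comments, or a one-column TSV
#' whose header is \code{segment}.
#'
#' @param path file path.
#' @inheritParams validate_segments
#' @return a \code{segment_set}.
#' @export
read_segments <- function(path, source_tag = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L && tolower(lines[1L]) == "segment") {
    lines <- lines[-1L]
  }
  validate_segments(lines, source_tag = source_tag)
}

#' Write training segments as plain text
#' @param segments a \code{segment_set} or character vector.
#' @param path output file.
#' @export
write_segments <- function(segments, path) {
  writeLines(c("segment", as.character(segments)), path)
  invisible(path)
}

segments_to_index_matrix <- function(segments) {
  if (length(segments) == 0L) {
    return(matrix(integer(0), nrow = 0, ncol = HCS_LENGTH))
  }
  m <- do.call(rbind, strsplit(as.character(segments), "", fixed = TRUE))
  matrix(match(m, AA_ALPHABET), nrow = nrow(m), ncol = HCS_LENGTH)
}

#' Build a position frequency matrix from validated segments
#'
#' @param segments a \code{segment_set} (all length 16).
#' @return 16 x 20 integer matrix of class \code{lrr_pfm}; rows are HCS
#'   positions, columns the alphabet; attribute \code{n_segments}.
#' @export
build_pfm <- function(segments) {
  idx <- segments_to_index_matrix(segments)
  counts <- matrix(0L, nrow = HCS_LENGTH, ncol = length(AA_ALPHABET),
                   dimnames = list(paste0("pos", seq_len(HCS_LENGTH)),
                                   AA_ALPHABET))
  for (pos in seq_len(HCS_LENGTH)) {
    tab <- tabulate(idx[, pos], nbins = length(AA_ALPHABET))
    counts[pos, ] <- tab
  }
  structure(counts, n_segments = nrow(idx), class = c("lrr_pfm", "matrix"))
}

#' Convert a frequency matrix to Laplace-smoothed probabilities
#'
#' \code{probs[i,a] = (counts[i,a] + pseudocount) / (n + 20 * pseudocount)},
#' which keeps every entry strictly inside (0,1) for any training set
#' (including the empty one, which gives the uniform 1/20).
#'
#' @param pfm an \code{lrr_pfm}.
#' @param pseudocount positive real, default 1 (classic Laplace).
#' @return 16 x 20 matrix of class \code{lrr_ppm} with attribute
#'   \code{pseudocount}.
#' @export
pfm_to_ppm <- function(pfm, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      !is.finite(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be a positive real", call. = FALSE)
  }
  n <- attr(pfm, "n_segments")
  probs <- (unclass(pfm) + pseudocount) /
    (n + length(AA_ALPHABET) * pseudocount)
  structure(probs, pseudocount = pseudocount,
            n_segments = n, class = c("lrr_ppm", "matrix"))
}

#' Estimate background residue frequencies
#'
#' Laplace-smoothed letter frequencies over a sequence corpus;
#' \code{X} residues are excluded from the totals. With no sequences the
#' uniform 1/20 background is returned.
#'
#' @param sequences a \code{seq_records} object or character vector; may be
#'   empty or NULL for the uniform fallback.
#' @return named numeric vector of 20 probabilities summing to 1.
#' @export
estimate_background <- function(sequences = NULL) {
  k <- length(AA_ALPHABET)
  if (is.null(sequences) || length(sequences) == 0L) {
    return(stats::setNames(rep(1 / k, k), AA_ALPHABET))
  }
  ch <- unlist(strsplit(toupper(as.character(sequences)), "", fixed = TRUE))
  ch <- ch[ch %in% AA_ALPHABET]
  counts <- tabulate(match(ch, AA_ALPHABET), nbins = k)
  stats::setNames((counts + 1) / (length(ch) + k), AA_ALPHABET)
}

#' Turn a probability matrix into a log-odds scoring matrix
#'
#' \code{weights[i,a] = log2(probs[i,a] / background[a])} (bits).
#'
#' @param ppm an \code{lrr_ppm}.
#' @param background named numeric vector of 20 strictly positive
#'   frequencies summing to 1 (see \code{\link{estimate_background}}).
#' @param threshold score cutoff stored on the matrix; defaults to
#'   \code{NA} until calibrated (see \code{\link{calibrate_threshold}}).
#' @param source_tag provenance label.
#' @return an object of class \code{lrr_pssm}: list with elements
#'   \code{weights} (16 x 20), \code{background}, \code{pseudocount},
#'   \code{threshold}, \code{n_training_segments}, \code{source_tag}.
#' @export
ppm_to_pssm <- function(ppm, background = estimate_background(),
                        threshold = NA_real_, source_tag = "unspecified") {
  background <- background[AA_ALPHABET]
  if (any(!is.finite(background)) || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9) {
    stop("background must be 20 strictly positive frequencies summing to 1",
         call. = FALSE)
  }
  probs <- unclass(ppm)
  attr(probs, "pseudocount") <- NULL
  attr(probs, "n_segments") <- NULL
  weights <- log2(sweep(probs, 2, background, "/"))
  structure(list(
    weights = weights,
    background = background,
    pseudocount = attr(ppm, "pseudocount"),
    threshold = threshold,
    n_training_segments = attr(ppm, "n_segments"),
    source_tag = source_tag
  ), class = "lrr_pssm")
}

#' @export
print.lrr_pssm <- function(x, ...) {
  cat("lrr_pssm: 16 x 20 log2-odds matrix\n")
  cat("  trained on", x$n_training_segments, "segments",
      sprintf("(source: %s)\n", x$source_tag))
  cat("  pseudocount:", x$pseudocount, " threshold:",
      format(x$threshold, digits = 4), "\n")
  invisible(x)
}

#' Score one 16-residue window under a scoring matrix
#'
#' The score is the sum of per-position weights; positions holding the
#' unknown residue \code{X} contribute 0, so fragmentary sequences remain
#' scannable.
#'
#' @param matrix an \code{lrr_pssm}.
#' @param window character scalar of exactly 16 residues.
#' @return numeric score in bits.
#' @examples
#' m <- train_matrix(validate_segments("LSDLNLSNNSLSGPIP"))
#' score_window(m, "LSDLNLSNNSLSGPIP")
#' @export
score_window <- function(matrix, window) {
  stopifnot(inherits(matrix, "lrr_pssm"))
  if (nchar(window) != HCS_LENGTH) {
    stop("window must be exactly ", HCS_LENGTH, " residues", call. = FALSE)
  }
  idx <- match(seq_chars(toupper(window)), AA_ALPHABET)
  known <- !is.na(idx)
  sum(matrix$weights[cbind(which(known), idx[known])])
}

#' Serialize a scoring matrix to JSON
#'
#' Full-precision single-document JSON: \code{alphabet}, \code{weights}
#' (16 arrays of 20 reals), \code{background}, \code{pseudocount},
#' \code{threshold}, \code{n_training_segments}, \code{source_tag}.
#' Round-trips are value-exact to at least 12 significant digits.
#'
#' @param matrix an \code{lrr_pssm}.
#' @param path output path.
#' @export
write_matrix_json <- function(matrix, path) {
  stopifnot(inherits(matrix, "lrr_pssm"))
  doc <- list(
    alphabet = paste(AA_ALPHABET, collapse = ""),
    weights = lapply(seq_len(HCS_LENGTH),
                     function(i) unname(matrix$weights[i, ])),
    background = unname(matrix$background),
    pseudocount = matrix$pseudocount,
    threshold = matrix$threshold,
    n_training_segments = matrix$n_training_segments,
    source_tag = matrix$source_tag
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a scoring matrix back from JSON
#' @param path file written by \code{\link{write_matrix_json}}.
#' @return an \code{lrr_pssm}.
#' @export
read_matrix_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$alphabet, paste(AA_ALPHABET, collapse = ""))) {
    stop("matrix file uses an unexpected alphabet", call. = FALSE)
  }
  w <- doc$weights
  weights <- if (is.matrix(w)) w else do.call(rbind, w)
  dimnames(weights) <- list(paste0("pos", seq_len(HCS_LENGTH)), AA_ALPHABET)
  # an uncalibrated matrix serializes its NA threshold as JSON null
  thr <- if (is.null(doc$threshold)) NA_real_ else
    suppressWarnings(as.numeric(doc$threshold))
  structure(list(
    weights = weights,
    background = stats::setNames(doc$background, AA_ALPHABET),
    pseudocount = doc$pseudocount,
    threshold = thr,
    n_training_segments = doc$n_training_segments,
    source_tag = doc$source_tag
  ), class = "lrr_pssm")
}
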