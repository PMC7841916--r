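# Crystal-structure-style accuracy evaluation: predictions are matched
# one-to-one against curated structure-derived repeat starts; a pair
# matches when the two 16-residue HCS windows overlap by at least
# min_overlap residues. Accuracy = matched / reference.

#' Read a reference LRR annotation table
#'
#' TSV with header \code{protein_id}, \code{pdb_code}, \code{start}
#' (1-based HCS start per row).
#'
#' @param path file path.
#' @return named list of reference annotations, each a list with
#'   \code{protein_id}, \code{source}, \code{lrr_starts} (sorted, 0-based).
#' @export
read_reference_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "pdb_code", "start") %in% names(tab)))
  by_prot <- split(tab, tab$protein_id)
  lapply(by_prot, function(t) {
    starts <- sort(as.integer(t$start)) - 1L
    if (any(duplicated(starts))) {
      stop("duplicate reference starts for ", t$protein_id[1L],
           call. = FALSE)
    }
    list(protein_id = t$protein_id[1L], source = t$pdb_code[1L],
         lrr_starts = starts)
  })
}

#' Match predicted repeats against a structure-derived reference
#'
#' Both lists are sorted and internally non-overlapping, so greedy
#' left-to-right matching is optimal: walk both lists, pair the current
#' heads when their 16-residue windows overlap by at least
#' \code{min_overlap} residues, otherwise advance the list whose head
#' starts first.
#'
#' @param predicted data.frame of predictions for one protein (column
#'   \code{start}, 0-based), or an integer vector of starts.
#' @param reference list with \code{lrr_starts} (0-based, sorted) as from
#'   \code{\link{read_reference_tsv}}, or an integer vector of starts.
#' @param min_overlap minimum window overlap in residues, default 8.
#' @return list of class \code{lrr_match}: \code{n_reference},
#'   \code{n_predicted}, \code{n_matched}, \code{accuracy},
#'   \code{unmatched_reference}, \code{unmatched_predicted} (0-based start
#'   vectors).
#' @export
match_reference <- function(predicted, reference, min_overlap = 8L) {
  p <- if (is.data.frame(predicted)) sort(predicted$start) else
    sort(as.integer(predicted))
  r <- if (is.list(reference) && !is.data.frame(reference))
    reference$lrr_starts else sort(as.integer(reference))
  if (length(r) == 0L) {
    stop("empty reference annotation: accuracy undefined", call. = FALSE)
  }
  i <- 1L; j <- 1L
  matched_p <- logical(length(p))
  matched_r <- logical(length(r))
  while (i <= length(p) && j <= length(r)) {
    ov <- min(p[i], r[j]) + HCS_LENGTH - max(p[i], r[j])
    if (ov >= min_overlap) {
      matched_p[i] <- TRUE
      matched_r[j] <- TRUE
      i <- i + 1L; j <- j + 1L
    } else if (p[i] < r[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  structure(list(
    n_reference = length(r),
    n_predicted = length(p),
    n_matched = sum(matched_r),
    accuracy = sum(matched_r) / length(r),
    unmatched_reference = r[!matched_r],
    unmatched_predicted = p[!matched_p]
  ), class = "lrr_match")
}

#' @export
print.lrr_match <- function(x, ...) {
  cat(sprintf("lrr_match: %d/%d reference repeats matched (%.1f%%), %d predicted\n",
              x$n_matched, x$n_reference, 100 * x$accuracy, x$n_predicted))
  invisible(x)
}

#' Per-protein accuracy report with a set average
#'
#' One row per protein (matched count, predicted count, accuracy percent)
#' plus an unweighted mean-accuracy \code{average} row, the layout of a
#' structure-benchmark table.
#'
#' @param runs named list; each element a list with \code{predicted} and
#'   \code{reference} as accepted by \code{\link{match_reference}}.
#' @param min_overlap passed through to \code{\link{match_reference}}.
#' @return data.frame: protein, n_reference, n_predicted, n_matched,
#'   accuracy_percent; last row "average" carries the unweighted mean.
#' @export
accuracy_table <- function(runs, min_overlap = 8L) {
  stopifnot(length(runs) >= 1L)
  rows <- lapply(names(runs), function(id) {
    m <- match_reference(runs[[id]]$predicted, runs[[id]]$reference,
                         min_overlap = min_overlap)
    data.frame(protein = id, n_reference = m$n_reference,
               n_predicted = m$n_predicted, n_matched = m$n_matched,
               accuracy_percent = 100 * m$accuracy)
  })
  out <- do.call(rbind, rows)
  avg <- data.frame(protein = "average", n_reference = NA_integer_,
                    n_predicted = NA_integer_, n_matched = NA_integer_,
                    accuracy_percent = mean(out$accuracy_percent))
  rbind(out, avg)
}

#' Write an accuracy report as TSV
#' @param report data.frame from \code{\link{accuracy_table}}.
#' @param path output file.
#' @export
write_accuracy_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
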