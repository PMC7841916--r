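#' @keywords internal
"_PACKAGE"

# Canonical 20-letter amino-acid alphabet, alphabetical, fixed so that every
# serialized matrix is bit-comparable. 'X' (unknown) is tolerated in
# sequences but never in training segments.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

HCS_LENGTH <- 16L   # highly conserved segment scanned by the matrix
LRR_SPAN   <- 24L   # full repeat span counted from each HCS start

#' Split a sequence string into single residues
#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Validate residues of a sequence, allowing 'X'
#'
#' @param residues character scalar.
#' @param id identifier used in error messages.
#' @return the uppercased sequence, invisibly errors on illegal letters.
#' @noRd
validate_residues <- function(residues, id = "<sequence>") {
  residues <- toupper(residues)
  if (nchar(residues) == 0L) {
    stop("sequence '", id, "' is empty", call. = FALSE)
  }
  ch <- seq_chars(residues)
  bad <- which(!ch %in% c(AA_ALPHABET, "X"))
  if (length(bad) > 0L) {
    stop("sequence '", id, "' contains illegal residue '", ch[bad[1L]],
         "' at position ", bad[1L], call. = FALSE)
  }
  residues
}

#' Construct a set of validated protein sequence records
#'
#' A light container for ectodomain sequences: a named character vector of
#' uppercase residues over the 20 canonical amino acids plus \code{X} for
#' unknown positions, with an optional description per record.
#'
#' @param residues character vector of sequences.
#' @param id character vector of unique identifiers.
#' @param description optional character vector of free-text descriptions.
#' @return an object of class \code{seq_records}: named character vector with
#'   a \code{description} attribute.
#' @examples
#' seq_records("LSDLNLSNNSLSGPIP", id = "toy")
#' @export
seq_records <- function(residues, id = names(residues), description = NULL) {
  if (is.null(id)) id <- paste0("seq", seq_along(residues))
  stopifnot(length(id) == length(residues))
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ", id[duplicated(id)][1L], call. = FALSE)
  }
  residues <- vapply(seq_along(residues), function(i) {
    validate_residues(residues[[i]], id[[i]])
  }, character(1))
  names(residues) <- id
  if (is.null(description)) description <- rep("", length(residues))
  attr(residues, "description") <- description
  class(residues) <- "seq_records"
  residues
}

#' @export
print.seq_records <- function(x, ...) {
  cat("seq_records with", length(x), "sequence(s)\n")
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    cat(sprintf("  %-20s %6d aa\n", names(x)[i], nchar(x[[i]])))
  }
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' @export
`[.seq_records` <- function(x, i) {
  out <- unclass(x)[i]
  attr(out, "description") <- attr(x, "description")[i]
  class(out) <- "seq_records"
  out
}
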