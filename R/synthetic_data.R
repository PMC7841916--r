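# Ground-truthed generator of LRR-RLK-like ectodomains: tandem 24(+)-residue
# repeats whose first 16 residues follow the plant consensus
# LxxLxLxxNxL(s/t)GxIP with tunable positional noise, variable 5-13 residue
# tails, optional island insertions, terminal caps, and planted NxS/T
# sequons, with every true motif start recorded.

# Template over the 16 HCS positions: a fixed letter, "st" for the S/T
# toggle at position 12, or NA for a variable (x) position.
HCS_TEMPLATE <- c("L", NA, NA, "L", NA, "L", NA, NA, "N", NA,
                  "L", "st", "G", NA, "I", "P")
HCS_FIXED_POS <- which(!is.na(HCS_TEMPLATE))

# Plant-LRR-flavoured filler for variable positions, islands, tails and
# caps: enriched in S, N, L, D, K, E, T, G, F so toy matrices carry
# realistic information content.
FILLER_RESIDUES <- c("S", "N", "L", "D", "K", "E", "T", "G", "F")
FILLER_WEIGHTS <- c(3, 2.5, 2.5, 2, 2, 2, 2, 1.5, 1.5)
default_filler <- function() {
  w <- rep(0.25, length(AA_ALPHABET))
  names(w) <- AA_ALPHABET
  w[FILLER_RESIDUES] <- w[FILLER_RESIDUES] + FILLER_WEIGHTS
  w / sum(w)
}

#' Parameters of the synthetic ectodomain generator
#'
#' Defaults describe a realistic plant LRR-RLK ectodomain family: 5-25
#' repeats per sequence, 2\% substitution noise at the conserved template
#' positions and 10\% at the variable ones, inter-repeat tails of 5-13
#' residues (so successive HCS starts are 21-29 apart), occasional island
#' insertions and unstructured terminal caps.
#'
#' @param n_sequences number of ectodomains to generate.
#' @param lrr_count_range integer range of repeats per sequence.
#' @param noise_conserved substitution probability at fixed template
#'   positions.
#' @param noise_variable substitution probability at variable (x) positions
#'   (a draw from the full alphabet instead of the filler mix).
#' @param tail_length_range range of the variable tail after each 16-residue
#'   HCS.
#' @param island_prob probability of a non-LRR island insertion after any
#'   given repeat.
#' @param island_length_range island length range.
#' @param cap_length_range length range of the N- and C-terminal caps.
#' @param sequon_plants data.frame with columns \code{lrr} (repeat ordinal)
#'   and \code{pos_in_lrr} (1..22) at which an NxS/T sequon is forced,
#'   applied to every sequence that has that repeat; NULL for none.
#' @param groups character vector of subgroup labels cycled over sequences.
#' @param filler named probability vector over the alphabet used for
#'   variable positions, tails, islands and caps.
#' @param seed mandatory integer seed.
#' @return an object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_sequences,
                           lrr_count_range = c(5L, 25L),
                           noise_conserved = 0.02,
                           noise_variable = 0.10,
                           tail_length_range = c(5L, 13L),
                           island_prob = 0.05,
                           island_length_range = c(30L, 70L),
                           cap_length_range = c(10L, 60L),
                           sequon_plants = NULL,
                           groups = "SG_synth",
                           filler = default_filler(),
                           seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_sequences >= 0,
            length(lrr_count_range) == 2, lrr_count_range[1] >= 1,
            diff(lrr_count_range) >= 0,
            noise_conserved >= 0, noise_conserved <= 1,
            noise_variable >= 0, noise_variable <= 1,
            tail_length_range[1] >= 0, diff(tail_length_range) >= 0,
            island_prob >= 0, island_prob <= 1,
            cap_length_range[1] >= 0)
  if (!is.null(sequon_plants)) {
    stopifnot(all(c("lrr", "pos_in_lrr") %in% names(sequon_plants)))
    # the Asn and the S/T two positions later must both be writable without
    # destroying a fixed consensus letter other than the sequon itself
    bad <- sequon_plants$pos_in_lrr < 1 | sequon_plants$pos_in_lrr > 22
    if (any(bad)) {
      stop("sequon plants must satisfy 1 <= pos_in_lrr <= 22", call. = FALSE)
    }
    # a fixed consensus position other than the invariant Asn cannot host
    # the sequon's N without contradicting the template
    cannot_host <- setdiff(HCS_FIXED_POS, 9L)
    if (any(sequon_plants$pos_in_lrr %in% cannot_host)) {
      stop("sequon plant at a fixed consensus position that cannot host N",
           call. = FALSE)
    }
  }
  filler <- filler[AA_ALPHABET]
  filler[is.na(filler)] <- 0
  if (sum(filler) <= 0) stop("filler distribution is empty", call. = FALSE)
  structure(list(
    n_sequences = as.integer(n_sequences),
    lrr_count_range = as.integer(lrr_count_range),
    noise_conserved = noise_conserved,
    noise_variable = noise_variable,
    tail_length_range = as.integer(tail_length_range),
    island_prob = island_prob,
    island_length_range = as.integer(island_length_range),
    cap_length_range = as.integer(cap_length_range),
    sequon_plants = sequon_plants,
    groups = groups,
    filler = filler / sum(filler),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

draw_filler <- function(spec, n) {
  if (n <= 0L) return(character(0))
  sample(AA_ALPHABET, n, replace = TRUE, prob = spec$filler)
}

rand_int <- function(range, n = 1L) {
  if (range[1] == range[2]) rep(range[1], n) else
    sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Draw one LRR unit (HCS + tail) from the generator's emission model
#'
#' @param spec a \code{synthetic_spec}. Uses the current RNG state.
#' @return list with \code{unit} (full 16+tail residue string) and
#'   \code{hcs} (its first 16 residues).
#' @export
sample_lrr_unit <- function(spec) {
  hcs <- character(HCS_LENGTH)
  for (i in seq_len(HCS_LENGTH)) {
    tpl <- HCS_TEMPLATE[i]
    if (is.na(tpl)) {
      hcs[i] <- if (stats::runif(1) < spec$noise_variable)
        sample(AA_ALPHABET, 1) else draw_filler(spec, 1)
    } else {
      base <- if (identical(tpl, "st")) sample(c("S", "T"), 1) else tpl
      hcs[i] <- if (stats::runif(1) < spec$noise_conserved)
        sample(AA_ALPHABET, 1) else base
    }
  }
  tail_len <- rand_int(spec$tail_length_range)
  tail <- draw_filler(spec, tail_len)
  hcs <- paste(hcs, collapse = "")
  list(unit = paste0(hcs, paste(tail, collapse = "")), hcs = hcs)
}

plant_sequon <- function(unit_chars, pos_in_lrr) {
  # force N at pos, x (non-P) unchanged unless P, S/T at pos+2
  unit_chars[pos_in_lrr] <- "N"
  if (unit_chars[pos_in_lrr + 1L] == "P") unit_chars[pos_in_lrr + 1L] <- "G"
  if (!unit_chars[pos_in_lrr + 2L] %in% c("S", "T")) {
    unit_chars[pos_in_lrr + 2L] <- "S"
  }
  unit_chars
}

#' Generate a ground-truthed synthetic ectodomain corpus
#'
#' Reproducible given the spec's seed. The truth table is consistent with
#' the emitted sequences: re-reading each sequence at a recorded start
#' yields the recorded HCS string.
#'
#' @param spec a \code{synthetic_spec}.
#' @return list with \code{sequences} (a \code{seq_records}),
#'   \code{truth} (data.frame seq_id, ordinal, start (0-based), hcs_seq),
#'   \code{sequons} (data.frame seq_id, pos (0-based), lrr, pos_in_lrr for
#'   planted sequons), and \code{metadata} (data.frame seq_id, group,
#'   species).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  seq_list <- character(0)
  truth <- list()
  sequons <- list()
  meta <- list()
  for (s in seq_len(spec$n_sequences)) {
    id <- sprintf("synth%04d", s)
    n_lrr <- rand_int(spec$lrr_count_range)
    parts <- character(0)
    offset <- 0L
    cap_n <- rand_int(spec$cap_length_range)
    parts <- c(parts, paste(draw_filler(spec, cap_n), collapse = ""))
    offset <- offset + cap_n
    starts <- integer(n_lrr)
    hcs_seqs <- character(n_lrr)
    seq_sequons <- list()
    for (k in seq_len(n_lrr)) {
      u <- sample_lrr_unit(spec)
      unit_chars <- seq_chars(u$unit)
      if (!is.null(spec$sequon_plants)) {
        hits <- spec$sequon_plants[spec$sequon_plants$lrr == k, ,
                                   drop = FALSE]
        for (r in seq_len(nrow(hits))) {
          p <- hits$pos_in_lrr[r]
          if (p + 2L <= length(unit_chars)) {
            unit_chars <- plant_sequon(unit_chars, p)
            seq_sequons[[length(seq_sequons) + 1L]] <- data.frame(
              seq_id = id, pos = offset + p - 1L, lrr = k, pos_in_lrr = p)
          }
        }
      }
      unit <- paste(unit_chars, collapse = "")
      starts[k] <- offset
      hcs_seqs[k] <- substring(unit, 1L, HCS_LENGTH)
      parts <- c(parts, unit)
      offset <- offset + nchar(unit)
      if (k < n_lrr && stats::runif(1) < spec$island_prob) {
        isl <- rand_int(spec$island_length_range)
        parts <- c(parts, paste(draw_filler(spec, isl), collapse = ""))
        offset <- offset + isl
      }
    }
    cap_c <- rand_int(spec$cap_length_range)
    parts <- c(parts, paste(draw_filler(spec, cap_c), collapse = ""))
    seq_list[id] <- paste(parts, collapse = "")
    truth[[s]] <- data.frame(seq_id = id, ordinal = seq_len(n_lrr),
                             start = starts, hcs_seq = hcs_seqs)
    if (length(seq_sequons) > 0L) {
      sequons[[length(sequons) + 1L]] <- do.call(rbind, seq_sequons)
    }
    grp <- spec$groups[((s - 1L) %% length(spec$groups)) + 1L]
    meta[[s]] <- data.frame(seq_id = id, group = grp, species = "SYNTH")
  }
  empty_truth <- data.frame(seq_id = character(0), ordinal = integer(0),
                            start = integer(0), hcs_seq = character(0))
  empty_seq <- data.frame(seq_id = character(0), pos = integer(0),
                          lrr = integer(0), pos_in_lrr = integer(0))
  list(
    sequences = if (length(seq_list) > 0L) seq_records(seq_list) else
      structure(character(0), description = character(0),
                class = "seq_records"),
    truth = if (length(truth) > 0L) do.call(rbind, truth) else empty_truth,
    sequons = if (length(sequons) > 0L) do.call(rbind, sequons) else
      empty_seq,
    metadata = if (length(meta) > 0L) do.call(rbind, meta) else
      data.frame(seq_id = character(0), group = character(0),
                 species = character(0))
  )
}

#' Draw a standalone training set of 16-mers from the emission model
#'
#' A stand-in for a curated training table when working offline: segments
#' are sampled exactly as the HCS part of \code{\link{sample_lrr_unit}}.
#'
#' @param spec a \code{synthetic_spec} (its seed is offset so the training
#'   draw does not collide with the corpus draw).
#' @param n_segments number of segments.
#' @return a \code{segment_set} tagged \code{synthetic}.
#' @export
generate_training_set <- function(spec, n_segments) {
  stopifnot(n_segments > 0)
  set.seed(spec$seed + 104729L)  # distinct stream from generate_corpus
  segs <- vapply(seq_len(n_segments),
                 function(i) sample_lrr_unit(spec)$hcs, character(1))
  validate_segments(segs, source_tag = "synthetic")
}

#' Write a generated corpus to FASTA plus truth/metadata TSVs
#'
#' Files are 1-based: truth TSV columns seq_id, ordinal, start, hcs_seq;
#' sequon TSV seq_id, pos, lrr, pos_in_lrr; metadata TSV seq_id, group,
#' species.
#'
#' @param corpus list from \code{\link{generate_corpus}}.
#' @param out_prefix path prefix; writes <prefix>.fasta, <prefix>.truth.tsv,
#'   <prefix>.sequons.tsv, <prefix>.meta.tsv.
#' @return invisibly, the vector of paths written.
#' @export
write_corpus <- function(corpus, out_prefix) {
  paths <- c(fasta = paste0(out_prefix, ".fasta"),
             truth = paste0(out_prefix, ".truth.tsv"),
             sequons = paste0(out_prefix, ".sequons.tsv"),
             meta = paste0(out_prefix, ".meta.tsv"))
  write_fasta(corpus$sequences, paths["fasta"])
  truth <- corpus$truth
  truth$start <- truth$start + 1L
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  seqn <- corpus$sequons
  seqn$pos <- seqn$pos + 1L
  utils::write.table(seqn, paths["sequons"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(corpus$metadata, paths["meta"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
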