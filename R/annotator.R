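# Ectodomain annotation on top of predicted repeats: canonical
# N-glycosylation sequons (NxS/T, x != P), N+/N- classification with the
# invariant consensus Asn (HCS position 9) flagged, superhelix side and
# terminal-region mapping, per-100-residue densities, positional
# histograms, accessibility window means, residue logos and grouped
# summaries.

# Superhelix side partition of the 24 in-repeat positions:
# 1-9 LxxLxLxxN inner face, 10-13 xLs/tG lateral face, 14-24 external.
SIDE_INTERNAL_END <- 9L
SIDE_LATERAL_END <- 13L

#' Find canonical N-glycosylation sequons in a sequence
#'
#' A canonical site is Asn-x-Ser/Thr with x != Pro. Sites whose sequon
#' would run past the sequence end cannot complete and are never emitted.
#'
#' @param seq character scalar (validated sequence).
#' @return data.frame with \code{pos} (0-based Asn position) and
#'   \code{sequon} ("NxS" or "NxT").
#' @examples
#' find_sequons("LNGSA")
#' @export
find_sequons <- function(seq) {
  seq <- validate_residues(seq)
  ch <- seq_chars(seq)
  L <- length(ch)
  pos <- which(ch == "N")
  pos <- pos[pos + 2L <= L]
  pos <- pos[ch[pos + 1L] != "P" & ch[pos + 2L] %in% c("S", "T")]
  data.frame(pos = pos - 1L,
             sequon = ifelse(ch[pos + 2L] == "S", "NxS", "NxT"))
}

#' Map a residue position onto a predicted repeat
#'
#' A position is in-repeat iff some motif has
#' \code{start <= pos < start + 24} (half-open). When spans overlap the
#' motif with the largest qualifying start wins, keeping \code{pos_in_lrr}
#' small.
#'
#' @param pos 0-based residue position.
#' @param motifs prediction data.frame for one sequence, sorted by start.
#' @param span repeat span, default 24.
#' @return list with \code{lrr_index} and \code{pos_in_lrr} (1..span), both
#'   NA when the position lies outside every repeat.
#' @export
map_to_lrr <- function(pos, motifs, span = LRR_SPAN) {
  hit <- which(motifs$start <= pos & pos < motifs$start + span)
  if (length(hit) == 0L) {
    return(list(lrr_index = NA_integer_, pos_in_lrr = NA_integer_))
  }
  h <- hit[which.max(motifs$start[hit])]
  list(lrr_index = motifs$lrr_index[h],
       pos_in_lrr = pos - motifs$start[h] + 1L)
}

#' Superhelix side of an in-repeat position
#'
#' Positions 1-9 (the LxxLxLxxN segment) face the inner side of the
#' superhelix, 10-13 (xLs/tG, the plant-specific second beta strand) the
#' lateral side, and 14-24 the external side.
#'
#' @param pos_in_lrr integer vector in 1..24.
#' @return character vector: "internal", "lateral" or "external".
#' @export
assign_side <- function(pos_in_lrr) {
  if (any(!is.na(pos_in_lrr) &
          (pos_in_lrr < 1L | pos_in_lrr > LRR_SPAN))) {
    stop("pos_in_lrr must lie in 1..", LRR_SPAN, call. = FALSE)
  }
  out <- ifelse(pos_in_lrr <= SIDE_INTERNAL_END, "internal",
                ifelse(pos_in_lrr <= SIDE_LATERAL_END, "lateral",
                       "external"))
  out[is.na(pos_in_lrr)] <- NA_character_
  out
}

#' Terminal region of a repeat within its ectodomain
#'
#' Index terciles: the first ceil(n/3) repeats are "N", the last ceil(n/3)
#' are "C", the remainder "middle". With fewer than three repeats, index 1
#' is "N" and the last is "C".
#'
#' @param lrr_index 1-based repeat index (vectorized).
#' @param n_lrrs total repeats in the ectodomain.
#' @return character vector: "N", "middle" or "C".
#' @export
assign_terminal <- function(lrr_index, n_lrrs) {
  stopifnot(all(is.na(lrr_index) |
                (lrr_index >= 1L & lrr_index <= n_lrrs)))
  if (n_lrrs < 3L) {
    out <- ifelse(lrr_index == 1L, "N", "C")
  } else {
    k <- ceiling(n_lrrs / 3)
    out <- ifelse(lrr_index <= k, "N",
                  ifelse(lrr_index > n_lrrs - k, "C", "middle"))
  }
  out[is.na(lrr_index)] <- NA_character_
  out
}

#' Classify every asparagine of a sequence
#'
#' Emits one row per Asn with its sequon class (N+ iff canonical), repeat
#' mapping, superhelix side, terminal region, and the \code{conserved9}
#' flag marking the invariant consensus Asn at HCS position 9 — downstream
#' N- statistics must drop \code{conserved9} sites.
#'
#' @param seq character scalar.
#' @param motifs prediction data.frame for this sequence (may be empty).
#' @param seq_id identifier recorded in the output.
#' @return data.frame with columns \code{seq_id}, \code{pos} (0-based),
#'   \code{residue}, \code{sequon}, \code{canonical}, \code{lrr_index},
#'   \code{pos_in_lrr}, \code{side}, \code{terminal}, \code{conserved9}.
#' @export
classify_asn_sites <- function(seq, motifs, seq_id = "seq") {
  seq <- validate_residues(seq)
  ch <- seq_chars(seq)
  asn <- which(ch == "N") - 1L
  canon <- find_sequons(seq)
  n <- length(asn)
  if (n == 0L) {
    return(data.frame(seq_id = character(0), pos = integer(0),
                      residue = character(0), sequon = character(0),
                      canonical = logical(0), lrr_index = integer(0),
                      pos_in_lrr = integer(0), side = character(0),
                      terminal = character(0), conserved9 = logical(0)))
  }
  sequon <- rep("none", n)
  m <- match(asn, canon$pos)
  sequon[!is.na(m)] <- canon$sequon[m[!is.na(m)]]
  n_lrrs <- nrow(motifs)
  mapped <- lapply(asn, map_to_lrr, motifs = motifs)
  lrr_index <- vapply(mapped, `[[`, integer(1), "lrr_index")
  pos_in_lrr <- vapply(mapped, `[[`, integer(1), "pos_in_lrr")
  side <- assign_side(pos_in_lrr)
  terminal <- if (n_lrrs > 0L) assign_terminal(lrr_index, n_lrrs) else
    rep(NA_character_, n)
  data.frame(
    seq_id = seq_id, pos = asn, residue = "N", sequon = sequon,
    canonical = sequon != "none", lrr_index = lrr_index,
    pos_in_lrr = pos_in_lrr, side = side, terminal = terminal,
    conserved9 = !is.na(pos_in_lrr) & pos_in_lrr == 9L
  )
}

#' Per-ectodomain profile: repeat and sequon counts and densities
#'
#' Densities are per 100 residues of the ectodomain.
#'
#' @param seq character scalar.
#' @param motifs prediction data.frame for the sequence.
#' @param sites Asn classification from \code{\link{classify_asn_sites}};
#'   computed if NULL.
#' @param seq_id identifier.
#' @param group,species optional metadata labels.
#' @return one-row data.frame: seq_id, ecd_length, n_lrrs, lrr_density,
#'   n_plus_count, n_plus_density, nxs_count, nxt_count, group, species.
#' @export
profile_ecd <- function(seq, motifs, sites = NULL, seq_id = "seq",
                        group = NA_character_, species = NA_character_) {
  seq <- validate_residues(seq)
  L <- nchar(seq)
  if (L == 0L) stop("zero-length sequence", call. = FALSE)
  if (is.null(sites)) sites <- classify_asn_sites(seq, motifs, seq_id)
  n_lrrs <- nrow(motifs)
  nxs <- sum(sites$sequon == "NxS")
  nxt <- sum(sites$sequon == "NxT")
  data.frame(
    seq_id = seq_id, ecd_length = L, n_lrrs = n_lrrs,
    lrr_density = 100 * n_lrrs / L,
    n_plus_count = nxs + nxt,
    n_plus_density = 100 * (nxs + nxt) / L,
    nxs_count = nxs, nxt_count = nxt,
    group = group, species = species
  )
}

#' Positional histogram of N+ or N- sites along the 24 repeat positions
#'
#' Counts in-repeat sites per \code{pos_in_lrr} bin. For \code{which =
#' "N-"} the invariant consensus Asn (\code{conserved9}) is excluded, as
#' it otherwise dominates the non-canonical counts.
#'
#' @param sites Asn classification table (one or many sequences).
#' @param which "N+" (canonical) or "N-" (non-canonical).
#' @return data.frame with \code{pos_in_lrr} 1..24, \code{side},
#'   \code{count} and \code{fraction} (of all in-repeat sites counted;
#'   0 when none).
#' @export
position_histogram <- function(sites, which = c("N+", "N-")) {
  which <- match.arg(which)
  keep <- if (which == "N+") sites$canonical else
    !sites$canonical & !sites$conserved9
  s <- sites[keep & !is.na(sites$pos_in_lrr), , drop = FALSE]
  counts <- tabulate(s$pos_in_lrr, nbins = LRR_SPAN)
  total <- sum(counts)
  data.frame(
    pos_in_lrr = seq_len(LRR_SPAN),
    side = assign_side(seq_len(LRR_SPAN)),
    count = counts,
    fraction = if (total > 0) counts / total else rep(0, LRR_SPAN)
  )
}

#' Read per-residue solvent accessibility tracks
#'
#' TSV with header \code{seq_id}, \code{pos} (1-based), \code{acc_value}
#' (0-100). Lengths are checked strictly against the sequences.
#'
#' @param path file path.
#' @param sequences \code{seq_records} used for length validation.
#' @return named list of numeric vectors, one per seq_id.
#' @export
read_accessibility_tsv <- function(path, sequences) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("seq_id", "pos", "acc_value") %in% names(tab)))
  tracks <- split(tab, tab$seq_id)
  lapply(tracks, function(t) {
    id <- t$seq_id[1L]
    s <- sequences[[id]]
    if (is.null(s)) stop("accessibility track for unknown sequence '",
                         id, "'", call. = FALSE)
    if (nrow(t) != nchar(s) || !all(sort(t$pos) == seq_len(nchar(s)))) {
      stop("accessibility track for '", id,
           "' does not cover every residue exactly once", call. = FALSE)
    }
    t$acc_value[order(t$pos)]
  })
}

#' Mean accessibility around Asn sites, by side and N+/N- class
#'
#' For each group (superhelix side x canonical class) the arithmetic mean
#' accessibility at each offset -5..+5 from the Asn is reported. Offsets
#' falling outside the sequence are skipped, not zero-filled, so means are
#' over observed residues only. \code{conserved9} sites are excluded from
#' the N- class.
#'
#' @param tracks named list of numeric accessibility vectors (one per
#'   seq_id, 1-based indexing along the sequence).
#' @param sites Asn classification table (column \code{seq_id} present).
#' @param offsets integer offsets, default -5..5.
#' @return data.frame: \code{side}, \code{class} ("N+"/"N-"),
#'   \code{offset}, \code{mean_acc}, \code{n} (residues averaged).
#' @export
accessibility_window_means <- function(tracks, sites, offsets = -5:5) {
  sites <- sites[!is.na(sites$side), , drop = FALSE]
  sites <- sites[sites$canonical | !sites$conserved9, , drop = FALSE]
  have <- sites$seq_id %in% names(tracks)
  if (any(!have)) {
    warning("no accessibility track for: ",
            paste(unique(sites$seq_id[!have]), collapse = ", "),
            "; those sequences skipped", call. = FALSE)
    sites <- sites[have, , drop = FALSE]
  }
  cls <- ifelse(sites$canonical, "N+", "N-")
  out <- list()
  for (side in c("internal", "lateral", "external")) {
    for (cl in c("N+", "N-")) {
      sel <- sites[sites$side == side & cls == cl, , drop = FALSE]
      for (off in offsets) {
        vals <- numeric(0)
        for (i in seq_len(nrow(sel))) {
          track <- tracks[[sel$seq_id[i]]]
          p <- sel$pos[i] + off + 1L  # 1-based into the track
          if (p >= 1L && p <= length(track)) vals <- c(vals, track[p])
        }
        out[[length(out) + 1L]] <- data.frame(
          side = side, class = cl, offset = off,
          mean_acc = if (length(vals) > 0L) mean(vals) else NA_real_,
          n = length(vals))
      }
    }
  }
  do.call(rbind, out)
}

#' Per-site residue frequencies and information content of aligned segments
#'
#' For a set of equal-length segments (gaps '-' allowed and excluded from
#' the frequencies) returns per-site residue frequencies and the
#' information content log2(20) - H (bits), the quantity drawn by sequence
#' logos.
#'
#' @param segments character vector of equal-length strings.
#' @return list with \code{freq} (sites x 20 matrix) and \code{info}
#'   (numeric vector of per-site bits, 0 for all-gap sites).
#' @export
logo_profile <- function(segments) {
  stopifnot(length(segments) > 0L)
  lens <- nchar(segments)
  if (length(unique(lens)) != 1L) {
    stop("segments must all have the same length", call. = FALSE)
  }
  L <- lens[1L]
  m <- do.call(rbind, strsplit(toupper(segments), "", fixed = TRUE))
  freq <- matrix(0, nrow = L, ncol = length(AA_ALPHABET),
                 dimnames = list(paste0("site", seq_len(L)), AA_ALPHABET))
  info <- numeric(L)
  for (i in seq_len(L)) {
    col <- m[, i]
    col <- col[col != "-"]
    bad <- col[!col %in% AA_ALPHABET]
    if (length(bad) > 0L) {
      stop("illegal residue '", bad[1L], "' at site ", i, call. = FALSE)
    }
    if (length(col) == 0L) next
    f <- tabulate(match(col, AA_ALPHABET),
                  nbins = length(AA_ALPHABET)) / length(col)
    freq[i, ] <- f
    p <- f[f > 0]
    info[i] <- log2(length(AA_ALPHABET)) + sum(p * log2(p))
  }
  list(freq = freq, info = info)
}

#' Grouped subgroup/species summaries of ectodomain profiles
#'
#' Long-format table per (group, species): sequence counts, the percentage
#' of each group within its species (summing to 100 per species), and mean
#' repeat counts and densities — the shape heatmap plotters expect.
#'
#' @param profiles data.frame of rows from \code{\link{profile_ecd}}.
#' @return data.frame: group, species, n_sequences, pct_of_species,
#'   mean_n_lrrs, mean_lrr_density, mean_n_plus_density.
#' @export
group_summaries <- function(profiles) {
  g <- profiles$group
  s <- profiles$species
  g[is.na(g)] <- "ungrouped"
  s[is.na(s)] <- "unspecified"
  key <- interaction(g, s, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sel <- key == k
    sub <- profiles[sel, , drop = FALSE]
    data.frame(
      group = g[sel][1L], species = s[sel][1L],
      n_sequences = nrow(sub),
      mean_n_lrrs = mean(sub$n_lrrs),
      mean_lrr_density = mean(sub$lrr_density),
      mean_n_plus_density = mean(sub$n_plus_density)
    )
  })
  out <- do.call(rbind, rows)
  species_totals <- tapply(out$n_sequences, out$species, sum)
  out$pct_of_species <-
    100 * out$n_sequences / as.numeric(species_totals[out$species])
  out[, c("group", "species", "n_sequences", "pct_of_species",
          "mean_n_lrrs", "mean_lrr_density", "mean_n_plus_density")]
}

#' Write an Asn sites table as TSV (1-based positions)
#' @param sites classification table.
#' @param path output file.
#' @export
write_sites_tsv <- function(sites, path) {
  out <- sites
  out$pos <- out$pos + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a seq_id/group/species metadata table
#' @param path TSV with header seq_id, group, species.
#' @return data.frame.
#' @export
read_metadata_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot(all(c("seq_id", "group", "species") %in% names(tab)))
  tab
}
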