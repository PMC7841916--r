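# Sequon detection, Asn classification, side/terminal mapping, densities,
# histograms, accessibility windows, logos and grouped summaries.

test_that("sequon finder applies the NxS/T (x != P) rule", {
  expect_equal(nrow(find_sequons("NPT")), 0L)   # x = P excluded
  s <- find_sequons("NGS")
  expect_equal(s$pos, 0L)
  expect_equal(s$sequon, "NxS")
  expect_equal(find_sequons("NGT")$sequon, "NxT")
  # sequons at the last two residues cannot complete
  expect_equal(nrow(find_sequons("AANG")), 0L)
  expect_equal(nrow(find_sequons("AAN")), 0L)

  # equivalence with an independent regex oracle on random sequences
  set.seed(77)
  for (i in 1:40) {
    seq <- random_protein(1000)
    expect_equal(find_sequons(seq)$pos, regex_sequons(seq))
  }
})

test_that("positions map onto repeats with the half-open plus-24 rule", {
  motifs <- data.frame(lrr_index = c(1L, 2L), start = c(10L, 30L))
  expect_equal(map_to_lrr(13L, motifs)$pos_in_lrr, 4L)   # start+3 -> 4
  expect_equal(map_to_lrr(10L, motifs)$lrr_index, 1L)
  # boundary exactness: start+23 in, start+24 out (of motif 2)
  expect_equal(map_to_lrr(53L, motifs)$pos_in_lrr, 24L)
  expect_true(is.na(map_to_lrr(54L, motifs)$lrr_index))
  # overlapping spans: the later motif wins; 20 apart, pos = start2 + 1
  close_motifs <- data.frame(lrr_index = c(1L, 2L), start = c(0L, 20L))
  hit <- map_to_lrr(21L, close_motifs)
  expect_equal(hit$lrr_index, 2L)
  expect_equal(hit$pos_in_lrr, 2L)
  # enumeration over every position of the overlap region agrees with the
  # largest-qualifying-start rule
  for (pos in 0:43) {
    got <- map_to_lrr(pos, close_motifs)
    expected <- if (pos >= 20L) 2L else 1L
    expect_equal(got$lrr_index, expected)
  }
})

test_that("side partition is total over 1..24 with bounds 9 and 13", {
  expect_equal(assign_side(9L), "internal")    # LxxLxLxxN face
  expect_equal(assign_side(12L), "lateral")    # xLs/tG face
  expect_equal(assign_side(13L), "lateral")
  expect_equal(assign_side(14L), "external")
  sides <- assign_side(1:24)
  expect_equal(as.integer(table(sides)[c("internal", "lateral",
                                         "external")]),
               c(9L, 4L, 11L))
  expect_error(assign_side(0L), "1..24")
  expect_error(assign_side(25L), "1..24")
})

test_that("terminal terciles follow the ceil(n/3) rule", {
  expect_equal(assign_terminal(1:3, 3L), c("N", "middle", "C"))
  expect_equal(assign_terminal(1:24, 24L),
               c(rep("N", 8), rep("middle", 8), rep("C", 8)))
  expect_equal(assign_terminal(1L, 1L), "N")
  expect_equal(assign_terminal(1:2, 2L), c("N", "C"))
  expect_equal(assign_terminal(1:5, 5L),
               c("N", "N", "middle", "C", "C"))
})

test_that("Asn classification flags the conserved 9th-site N", {
  # one repeat starting at 5; Asn at 5+8 is the consensus position 9
  seq <- paste0("AAAAA", "LSDLNLSNNSLSGPIP", strrep("A", 20))
  motifs <- data.frame(lrr_index = 1L, start = 5L)
  sites <- classify_asn_sites(seq, motifs, seq_id = "t")
  nine <- sites[sites$pos == 13L, ]
  expect_true(nine$conserved9)
  expect_equal(nine$side, "internal")
  # Asn outside all spans has no repeat mapping
  far <- classify_asn_sites(paste0(seq, "NGS"), motifs, "t")
  out <- far[far$pos == nchar(seq), ]
  expect_true(out$canonical)
  expect_true(is.na(out$lrr_index) && is.na(out$side))

  # synthetic planted sequons are recovered with their truth coordinates
  plants <- data.frame(lrr = c(2L, 4L), pos_in_lrr = c(5L, 10L))
  spec <- synthetic_spec(n_sequences = 4, lrr_count_range = c(6L, 6L),
                         noise_conserved = 0, noise_variable = 0,
                         island_prob = 0, sequon_plants = plants, seed = 61)
  corpus <- generate_corpus(spec)
  for (id in names(corpus$sequences)) {
    truth <- corpus$truth[corpus$truth$seq_id == id, ]
    motifs <- data.frame(lrr_index = truth$ordinal, start = truth$start)
    sites <- classify_asn_sites(corpus$sequences[[id]], motifs, id)
    planted <- corpus$sequons[corpus$sequons$seq_id == id, ]
    got <- sites[sites$pos %in% planted$pos, ]
    expect_true(all(got$canonical))
    expect_equal(got$pos_in_lrr, planted$pos_in_lrr)
    expect_equal(got$lrr_index, planted$lrr)
  }
})

test_that("ectodomain profiles satisfy the density identities", {
  dummy <- paste0(strrep("A", 490), "NGSNGTNPSX")  # 500 residues
  motifs <- data.frame(lrr_index = 1:5, start = seq(0, 96, by = 24))
  prof <- profile_ecd(dummy, motifs, seq_id = "p")
  expect_equal(prof$ecd_length, 500L)
  expect_equal(prof$lrr_density, 1.0)  # 5 per 500 aa
  expect_equal(prof$n_plus_count, prof$nxs_count + prof$nxt_count)
  expect_equal(prof$n_plus_density, 100 * prof$n_plus_count / 500)
  expect_equal(prof$nxs_count, 1L)
  expect_equal(prof$nxt_count, 1L)  # NPS blocked by the x != P rule

  none <- profile_ecd(strrep("A", 100),
                      data.frame(lrr_index = integer(0), start = integer(0)))
  expect_equal(none$lrr_density, 0)
  expect_equal(none$n_plus_density, 0)

  # density linearity: pooled counts over pooled length
  p1 <- profile_ecd(strrep("A", 100), motifs[1:2, ], seq_id = "a")
  p2 <- profile_ecd(strrep("A", 300), motifs[1:4, ], seq_id = "b")
  pooled <- 100 * (p1$n_lrrs + p2$n_lrrs) / (p1$ecd_length + p2$ecd_length)
  expect_equal(pooled, 100 * 6 / 400)

  expect_error(profile_ecd("", motifs), "empty")
})

test_that("position histograms conserve counts and split by side", {
  plants <- data.frame(lrr = c(1L, 3L), pos_in_lrr = c(5L, 10L))
  # Asn-free filler so the only sequons are the planted ones
  filler <- stats::setNames(rep(0, 20), AA)
  filler[c("A", "D", "E", "F", "G", "K", "L")] <- 1 / 7
  spec <- synthetic_spec(n_sequences = 6, lrr_count_range = c(5L, 5L),
                         noise_conserved = 0, noise_variable = 0,
                         island_prob = 0, sequon_plants = plants,
                         filler = filler, seed = 71)
  corpus <- generate_corpus(spec)
  sites <- do.call(rbind, lapply(names(corpus$sequences), function(id) {
    truth <- corpus$truth[corpus$truth$seq_id == id, ]
    classify_asn_sites(corpus$sequences[[id]],
                       data.frame(lrr_index = truth$ordinal,
                                  start = truth$start), id)
  }))
  h <- position_histogram(sites, "N+")
  expect_equal(nrow(h), 24L)
  # sequons planted only at in-repeat positions 5 and 10
  expect_equal(which(h$count > 0), c(5L, 10L))
  expect_equal(h$side[c(5, 10)], c("internal", "lateral"))
  expect_equal(sum(h$fraction), 1)
  expect_equal(sum(h$count),
               sum(sites$canonical & !is.na(sites$pos_in_lrr)))

  # N- histogram drops the conserved 9th-site Asn
  hm <- position_histogram(sites, "N-")
  expect_equal(hm$count[9], 0L)

  empty <- position_histogram(sites[0, ], "N+")
  expect_true(all(empty$count == 0))
  expect_true(all(empty$fraction == 0))
})

test_that("accessibility window means skip out-of-range offsets", {
  seq <- "NGSAAAAAAANGT"  # sites at 0 and 10
  motifs <- data.frame(lrr_index = 1L, start = 0L)
  sites <- classify_asn_sites(seq, motifs, "t")
  # constant track: every defined mean is the constant
  tracks <- list(t = rep(50, nchar(seq)))
  am <- accessibility_window_means(tracks, sites)
  expect_true(all(am$mean_acc[am$n > 0] == 50))

  # hand-computed means for a ramp track: the site at pos 0 (pos_in_lrr 1,
  # internal face) only covers offsets 0..+5; the site at pos 10
  # (pos_in_lrr 11, lateral face) covers the full window
  tracks <- list(t = as.numeric(1:13))
  am <- accessibility_window_means(tracks, sites)
  internal_np <- am[am$side == "internal" & am$class == "N+", ]
  lateral_np <- am[am$side == "lateral" & am$class == "N+", ]
  # internal site at pos 0: offsets -5..-1 skipped, not zero-filled
  expect_equal(internal_np$n[internal_np$offset == -1], 0L)
  expect_true(is.na(internal_np$mean_acc[internal_np$offset == -1]))
  expect_equal(internal_np$mean_acc[internal_np$offset == 0], 1)
  expect_equal(internal_np$mean_acc[internal_np$offset == 5], 6)
  # lateral site at pos 10: offset -1 -> track[10] = 10, offset +2 ->
  # track[13] = 13
  expect_equal(lateral_np$mean_acc[lateral_np$offset == -1], 10)
  expect_equal(lateral_np$n[lateral_np$offset == -1], 1L)
  expect_equal(lateral_np$mean_acc[lateral_np$offset == 2], 13)

  # missing track: warning and skip
  sites2 <- sites
  sites2$seq_id <- "missing"
  expect_warning(am2 <- accessibility_window_means(tracks, sites2),
                 "no accessibility track")
  expect_true(all(am2$n == 0L))
})

test_that("accessibility TSV reader enforces full-length tracks", {
  seqs <- seq_records(c(a = "LSDLNLSNNSLSGPIP"))
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(seq_id = "a", pos = 1:16, acc_value = seq(5, 80, by = 5))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- read_accessibility_tsv(path, seqs)
  expect_equal(tr$a, seq(5, 80, by = 5))

  write.table(tab[-3, ], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_accessibility_tsv(path, seqs), "every residue")
})

test_that("logo profiles report frequencies and information content", {
  # identical segments: zero entropy, log2(20) bits everywhere
  p <- logo_profile(rep("LSDLN", 4))
  expect_equal(p$info, rep(log2(20), 5))
  expect_equal(unname(p$freq[1, "L"]), 1)

  # uniform site: zero information
  p2 <- logo_profile(AA)  # 20 single-letter segments, one of each residue
  expect_equal(p2$info[1], 0)

  # counting oracle on hand-written 9-mers with a gap
  segs <- c("LSDLNLSSN", "LSDLNLSSN", "LRDLNLSSN", "L-DLNLSSN", "LTDLNLSSN")
  p3 <- logo_profile(segs)
  expect_equal(unname(p3$freq[2, "S"]), 2 / 4)  # gap excluded from site 2
  expect_equal(unname(p3$freq[2, "R"]), 1 / 4)
  expect_equal(unname(p3$freq[1, "L"]), 1)
  expect_true(all(abs(rowSums(p3$freq) - 1) < 1e-12))

  expect_error(logo_profile(c("AAA", "AAAA")), "same length")
})

test_that("group summaries normalise percentages within species", {
  prof <- function(id, grp, sp, n_lrrs = 10L) {
    data.frame(seq_id = id, ecd_length = 500L, n_lrrs = n_lrrs,
               lrr_density = n_lrrs / 5, n_plus_count = 4L,
               n_plus_density = 0.8, nxs_count = 2L, nxt_count = 2L,
               group = grp, species = sp)
  }
  profiles <- rbind(prof("a", "SG_i", "ARATH", 5L),
                    prof("b", "SG_i", "ARATH", 7L),
                    prof("c", "SG_xi", "ARATH", 22L),
                    prof("d", "SG_xi", "MAIZE", 20L))
  g <- group_summaries(profiles)
  arath <- g[g$species == "ARATH", ]
  expect_equal(sum(arath$pct_of_species), 100)
  expect_equal(g$n_sequences[g$group == "SG_i"], 2L)
  expect_equal(g$mean_n_lrrs[g$group == "SG_i"], 6)
  expect_equal(g$pct_of_species[g$species == "MAIZE"], 100)

  single <- group_summaries(prof("z", "SG_ii", "SOLTU"))
  expect_equal(single$n_sequences, 1L)
  expect_equal(single$pct_of_species, 100)

  # absent metadata falls into one bucket
  nometa <- prof("q", NA_character_, NA_character_)
  gn <- group_summaries(nometa)
  expect_equal(gn$group, "ungrouped")
})
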