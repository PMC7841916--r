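---
title: "Predicting plant LRR motifs with a trainable position-specific scoring matrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting plant LRR motifs with a trainable position-specific scoring matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrrscan)
```

## The problem

The extracellular domains (ECDs) of plant leucine-rich-repeat receptor-like
kinases (LRR-RLKs) are built from tandem LRR units of roughly 20–29
residues. Each unit opens with a plant-specific 16-residue highly conserved
segment (HCS) of the form `LxxLxLxxNxL(s/t)GxIP`: hydrophobic anchors at
positions 1, 4, 6 and 11, an invariant asparagine at position 9, a
serine-or-threonine toggle at 12, and glycine/isoleucine/proline at 13, 15
and 16. The first nine positions (`LxxLxLxxN`) line the inner face of the
LRR superhelix — the ligand-binding surface — positions 10–13 (`xLs/tG`)
form the plant-specific second beta strand on the lateral face, and the
remainder faces outward. Generic repeat detectors (HMM- or
alignment-based) miss the more divergent of these units; a
position-specific scoring matrix (PSSM) trained specifically on plant HCS
segments does substantially better. `lrrscan` implements such a detector
as a trainable library plus CLI, together with the ectodomain annotation
that makes the predictions useful: canonical N-glycosylation sequons,
superhelix side and terminal mapping, densities, residue logos and grouped
summaries.

## The model

Training input is a set of aligned 16-mers (one per curated repeat). With
$c_{ia}$ the count of residue $a$ at position $i$ over $n$ segments,
the Laplace-smoothed position probability matrix is

$$p_{ia} = \frac{c_{ia} + \alpha}{n + 20\alpha}, \qquad \alpha = 1
\text{ by default},$$

which keeps every entry strictly positive for any training set (the
zero-probability problem never arises). Scores are log-odds in bits
against a background distribution $b_a$:

$$w_{ia} = \log_2 \frac{p_{ia}}{b_a}, \qquad
S(\text{window}) = \sum_{i=1}^{16} w_{i,\,x_i},$$

with the unknown residue `X` contributing zero so fragmentary sequences
stay scannable. Every 16-residue window of an ECD is scored; windows at or
above a threshold become candidates; and the final call is the
*non-overlapping candidate group with the highest total score*, computed
exactly by weighted-interval-scheduling dynamic programming (two windows
conflict when their starts differ by less than 16). Ties break towards
more motifs, then the leftmost start tuple, so output is deterministic
across platforms. Each kept window is materialized as a repeat spanning
`[start, start + 24)`, truncated at the sequence end.

Two details are deliberately open in the published method and are fixed
here as package policy:

* **Background.** No background distribution is disclosed by the method
  this package re-implements; log-odds scoring needs one. Default:
  Laplace-smoothed residue frequencies of the training corpus itself,
  with a uniform 1/20 fallback when no corpus is given. Note the
  degenerate case: a background estimated from a single segment need not
  leave that segment as the matrix's top-scoring window; pass a uniform
  background (empty corpus) when that property matters.
* **Threshold.** No score cutoff is published either. Default: the 1st
  percentile (R type-7 order statistic) of the training segments' own
  scores, so ~99% of curated repeats would be re-detected by
  construction. This has a corollary worth stating plainly: *exact*
  recovery of every training window requires the percentile-0 cutoff (the
  training-score minimum), because the 1st percentile excludes ~1% of its
  own calibration set by definition. The package exposes
  `threshold_percentile` and absolute overrides; the zero-noise
  exact-recovery checks in the test suite use percentile 0 for exactly
  this reason.

## Two-round training

Round 1 trains from curated segments. Round 2 (`bootstrap_round()`)
predicts repeats on an expansion corpus, accepts segments scoring at or
above an acceptance threshold, applies plain-file include/exclude
overrides — the automatable, testable stand-in for manual verification —
and retrains on the *union* of round-1 and accepted segments. Union (not
replacement) is the conservative reading of "adjusting" the matrix: it
never discards curated data. Segment sets are multisets; duplicates carry
weight in the counts, so merging concatenates rather than deduplicates.
An expansion that yields nothing new reproduces the input matrix
bit-for-bit after serialization.

## Annotation layer

* **Sequons.** A canonical N-glycosylation site is Asn-x-Ser/Thr with
  x ≠ Pro (`N+`); all other asparagines are `N−`. Sequons that would run
  past the sequence end cannot complete and are never emitted.
* **Repeat mapping.** A residue belongs to a repeat when
  `start ≤ pos < start + 24` — half-open, so `pos_in_lrr` is always in
  1..24. When 24-residue spans of adjacent repeats overlap (spacing
  under 24), the repeat with the largest qualifying start wins, keeping
  `pos_in_lrr` small and side assignment meaningful.
* **Sides.** Positions 1–9 internal, 10–13 lateral, 14–24 external — a
  total partition.
* **Conserved ninth site.** The invariant Asn at HCS position 9 is
  flagged `conserved9`; `N−` statistics exclude it, as it otherwise
  swamps the non-canonical counts.
* **Terminals.** The published analysis never defines N/middle/C
  cutoffs; this package uses index terciles (first ⌈n/3⌉ repeats N, last
  ⌈n/3⌉ C, remainder middle; with fewer than three repeats, first → N,
  last → C).
* **Accessibility windows.** Mean solvent-accessibility (ACCpro20-style
  0–100 tracks, consumed, never computed) at offsets −5..+5 from each
  Asn, grouped by side × N+/N−. Offsets outside the sequence are
  skipped, not zero-filled, so means are over observed residues only.
* **Logos.** Per-site residue frequencies and information content
  $\log_2 20 - H$ in bits; gap characters are excluded from frequencies.
* **Densities.** Repeats and N+ per 100 ECD residues; grouped summaries
  normalise percentages within species.

## The synthetic generator

`synthetic_spec()` states a world and `generate_corpus()` emits it with a
full ground-truth table: tandem units whose HCS follows the consensus
template with substitution noise 0.02 at fixed positions and 0.10 at
variable ones, inter-start spacings of 21–29 residues (16 + a 5–13
residue tail), island insertions of 30–70 residues at probability 0.05
per junction, terminal caps of 10–60 residues, and optionally planted
sequons at stated in-repeat positions. Variable positions draw from a
plant-flavoured filler mix (enriched S, N, L, D, K, E, T, G, F) rather
than uniform, so trained toy matrices have realistic information content;
the island probability is the one generator default the source material
leaves unstated, set once at 0.05 — islands are present but uncommon, as
in superhelix-forming receptor subgroups. What the generator does *not*
emulate: signal peptides, transmembrane helices and kinase domains (it
makes ectodomains only), degenerate terminal caps that real receptors
have and real predictors miss, and between-family sequence heterogeneity
unless you vary the filler yourself. A green recovery test therefore
establishes that the scanner recovers repeats of the stated consensus
family under stated noise — not performance on divergent natural
families. Note also that the filler emits asparagines, so corpora contain
*accidental* sequons beyond planted ones; tests that need only planted
sequons use an Asn-free filler.

## Evaluation

`match_reference()` reproduces the crystal-structure benchmark protocol:
curated structure-derived HCS starts are the reference; a predicted and a
reference repeat match when their 16-residue windows overlap by at least
8 residues (majority overlap — strict enough to forbid frame-slipped
double counting, loose enough to absorb curation offsets); matching is
greedy left-to-right, which is optimal for sorted non-overlapping lists
(verified against brute-force bipartite matching in the tests); accuracy
is matched over reference, and set averages are unweighted over proteins.
The published benchmark against ~20 crystallized receptors requires the
protein sequences and curated per-repeat starts, neither of which ships
with the package nor is derivable offline; the evaluator is therefore
exercised against synthetic structure-style references, and the report
emits both `n_matched` and `n_predicted` so either reading of published
"n (p%)" cells is checkable against real curation when the user supplies
it.

## Numerical choices and degenerate inputs

* Alphabet fixed alphabetically (`ACDEFGHIKLMNPQRSTVWY`) in all
  serialized matrices; matrix JSON round-trips value-exact well beyond 12
  significant digits (full-precision serialization).
* Empty training sets are valid through the matrix pipeline (Laplace
  gives the uniform PPM) but threshold calibration refuses them and
  instructs the caller to pass an absolute cutoff.
* Sequences shorter than 16 residues scan to an empty candidate list,
  not an error.
* File coordinates are 1-based inclusive; internal coordinates 0-based
  half-open; the converters are exact inverses.
* The run-config file format is JSON (the environment provides a JSON
  parser but no TOML parser; hand-rolling one was not warranted). Unknown
  keys are rejected.

## A worked run

```{r worked}
spec <- synthetic_spec(n_sequences = 20, seed = 42)
corpus <- generate_corpus(spec)
segs <- extract_hcs_segments(corpus$sequences, corpus$truth,
                             source_tag = "emitted")
m <- train_matrix(segs)
m
preds <- predict_lrrs(corpus$sequences, m)
head(preds, 3)
matched <- sum(vapply(names(corpus$sequences), function(id) {
  match_reference(preds$start[preds$seq_id == id],
                  corpus$truth$start[corpus$truth$seq_id == id])$n_matched
}, integer(1)))
c(recall = matched / nrow(corpus$truth),
  precision = matched / nrow(preds))
```

## Known limitations

* Divergent N- and C-terminal repeats that deviate far from the HCS
  consensus score below any sensible threshold and are missed — the
  known failure mode of this family of detectors; the override files
  exist so curation can put them back.
* The published score scale is not reproducible (background and log base
  undisclosed); motif *calls* are the comparable output, not raw scores.
* `N+` here is the literal sequon rule; no glycosylation probability
  model is implied.
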