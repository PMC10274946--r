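---
title: "Detecting programmed ribosomal frameshifts from cellular properties"
author: "prfscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting programmed ribosomal frameshifts from cellular properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfscan)
```

## The model

A programmed ribosomal frameshift (PRF) is a regulated translation event:
at a slippery sequence the ribosome, with its E- and P-sites occupied and
the A-site empty, slips one nucleotide backward (−1) or forward (+1) and
continues in the new frame, bypassing the original stop codon. `prfscan`
treats PRF detection as site classification. For a pair of consecutive
same-strand genes in different frames, a shift inside the stop-free
overlap window could fuse them into one product; every in-frame codon
boundary in that window whose upstream heptamer matches a slippery-motif
class is a candidate site, described by eleven properties and classified
as −1, 0 or +1 by gradient-boosted trees.

The window is bounded on its 5' side by the first base after the nearest
stop codon upstream of the downstream gene's start *in that gene's
frame* (a shift before that stop could not produce the downstream
product) and on its 3' side by the last base of the first in-frame stop
at or after the upstream gene's end *in the upstream gene's frame* (a
shift after termination is impossible). For an intact gene that 3' bound
is its own stop codon; for the pseudo-pair obtained by splitting an
annotated joined gene, fragment 1 does not end at a stop, and the bound
is the fused gene's +0 stop found by scanning forward — the same scan
that defines the feature N below.

### Coordinates and strands

All coordinates are 1-based inclusive, the shared convention of GenBank
and IRanges; no 0-based representation exists anywhere in the package,
so there is no conversion point to get wrong. Reverse-strand gene pairs
are analyzed in "oriented space" — the reverse complement read 5'→3' —
and mapped back only for reporting.

### Slippery motifs

A motif class is a run pattern read 5'→3' (runs of one repeated
nucleotide, adjacent runs of different nucleotides), anchored so the
pattern's 3' end abuts the empty A-site codon. Eight backward classes
(six [6], threethree [3,3], fivetwo [5,2], twofive [2,5], twofour [2,4],
threetwotwo [3,2,2], five [5], twoonefour [2,1,4]) and two forward
classes (four [4], three [3]) are catalogued, with integer ids 0–9 used
as the MOTIF feature (the bijection is arbitrary for tree models and
recorded in `motifCatalog()`). Matching semantics: interior and 3' runs
are exact (the base 5' of the run must differ), the 5'-most run is
maximal (surplus identical bases are ignored, so seven A's still match
*six*), and any N blocks the match. Classes that are special cases of
others are resolved by precedence — the class with the lower probability
of occurring by chance wins; concretely the catalog is ordered by
descending run-length sum with *six* ahead of its sum-6 peers. Under
these semantics the classic subset pairs (six/threethree, twofive/
twofour, four/three) never co-match ambiguously, which the test suite
verifies against an independent regular-expression oracle on all 4^7
heptamers. We require only *adjacent* runs to differ in three-run
patterns; demanding all-distinct runs would be a stricter reading the
naming rule does not force.

Candidates are only emitted in the direction the region's frame geometry
implies ((frame_B − frame_A) mod 3 = 2 → −1, = 1 → +1): a backward motif
cannot fuse a pair whose frames are +1 apart, and DIR is the direction
of the (hypothetical) shift, not of the motif table row. Forward
candidates must additionally pass the codon-rarity gate A1 > A0: a
forward slip is promoted by a hungry (rare) codon waiting in the A-site
next to a well-supplied +1 codon.

### The eleven properties

| feature | meaning | range |
|---|---|---|
| DIR | shift direction implied by frame geometry | −1, +1 |
| RBS1 | Prodigal-style SD bin at the P-site | 0–27 |
| RBS2 | RAST-style SD frequency score at the P-site | 0.0–6.3 |
| MOTIF | motif class id | 0–9 |
| A0 | genome-wide usage of the +0 A-site codon | 0–1 |
| A1 | usage of the ±1-shifted A-site codon | 0–1 |
| LF50/LF100 | normalized fold energy, 50/100 bp window, hairpin slot | 0–1 |
| HK50/HK100 | same windows, pseudoknot-capable slot | 0–1 |
| N | nt from the A-site codon start to the +0 stop | 0–∞ |

Codon usage counts every in-frame codon of every annotated CDS (joined
features over their fragment-concatenated frame), stop codons included —
being one-per-gene they behave as informative rare codons. A1 is the
codon occupying the A-site position in the shifted frame (the codon at
p ± 1 for a shift at p); the alternative convention — the next codon
translated after the shift — differs only by a fixed 3-nt displacement
and was not adopted.

N is measured from the first base of the A-site codon to the first base
of the +0 in-frame stop. This reproduces the stop-adjacent geometry of
polyprotein shift sites (a site one codon group upstream of its stop
measures N = 15) and discriminates plausible sites near the in-frame
stop from chance motifs far upstream.

### Ribosome-binding-site scores

Both SD scorers search spacers of 3–15 nt measured from the motif's 3'
end to the first base of the P-site codon (a 20-nt upstream window) and
are pure functions of that window; the spacer convention follows the
start-codon usage of the originals, transplanted to the P-site. The
28-bin table crosses seven motif tiers (GG, GGxGG, GGA/GAG/AGG,
AGGA/GGAG/GAGG, AGGAG/GGAGG, one-mismatch AGGxGG/AGxAGG hexamers,
AGGAGG) with four spacer ranges (5–10 optimal, then 3–4, 11–12, 13–15),
ranked so that a stronger motif at the same spacer never scores a lower
bin; the weakest cell (GG at 13–15 nt) is bin 0, the no-motif value, and
AGGAGG at 5–10 nt is bin 27. The frequency table holds 191 SD-like
motifs × 10 spacer classes; because the original web service's internal
table is not distributable, the package ships a synthetic anti-SD
neighborhood model (all hexamers within Hamming distance 2 of AGGAGG,
pentamers within distance 1 of AGGAG/GGAGG, and five tetramer
substrings of AAGGAGGT, with frequencies decaying by mismatch count and
spacer suitability; `inst/extdata/rbs_sd_frequencies_synthetic.tsv`).
The derived score is log2(frequency/background) clipped to [0, 6.3].

### Downstream structure

The LF (hairpin) and HK (pseudoknot-capable) feature slots are filled
through a pluggable backend contract: `fold(window, backend)` must be
deterministic and return an energy ≤ 0. The built-in default for both
slots is a Nussinov-style nested-structure dynamic program with
stacking-aware weights: G:C −3, A:U −2, G:U −1, minimum hairpin loop 3,
where a pair contributes its weight only when its inward neighbor is
also paired and each helix pays a +4 initiation penalty. The two
refinements matter: scoring every pair independently lets essentially
every 50-bp window of natural composition reach |MFE| ≈ 35–50, which
saturates the normalization below at 1.0 and destroys the feature;
counting only stacked pairs and charging initiation keeps random windows
near 0.4–0.55 normalized while planted stems score 0.7–1.0. An adapter
for ViennaRNA's RNAfold is provided (`backend = "vienna"`) and used when
the executable is on the PATH; dedicated pseudoknot folders can be
plugged in the same way, so with the default configuration the HK
columns duplicate the LF columns and simply cost the trees nothing.

Windows of 50 and 100 bp start immediately after the three A-site bases
(offset 3 from the motif); windows truncated by the contig edge are
folded and normalized at their actual length. The normalization is
clamp(|MFE| / length / GC, 0, 1), with GC as a fraction (0–1; dividing
by percent would collapse the documented 0–1 range) and value 0 when
GC = 0.

### Classifier

xgboost histogram trees approximate a histogram gradient-boosting
classifier at library defaults: 100 rounds, learning rate 0.1,
loss-guided growth to 31 leaves, L2 regularization 1.0, no early
stopping, one thread — so training and prediction are deterministic
functions of the data. Labels {−1, 0, +1} come from annotated joins:
candidates within 10 bp of the annotated fragment boundary, in the
join's direction, are positive; everything else (including every
candidate of a non-joined pair) is 0. Class imbalance is left to the
trees, matching the default-parameters stance; a candidate's score is
max(P(−1), P(+1)), the class is the arg-max (no probability threshold —
a threshold option would only re-trade recall for precision the trees
already trade internally), and per overlap region only the
highest-scoring candidate with a non-zero class is reported.

### Genome grouping for validation

Leave-one-group-out validation needs groups that respect sequence
identity. `sketchGenome()` computes a bottom-400 MinHash sketch of
canonical 16-mers under a fixed splitmix64 hash (fixed seed: sketches
are reproducible artifacts, not random draws), `mashDistance()` the
usual −(1/k)·ln(2j/(1+j)) estimate, and `clusterGenomes()` single-links
at distance ≤ 0.05 (≈95% identity) — the common dereplication practice;
no p-value filtering is applied before linkage. True positives at
validation require a prediction on an annotated joined pair within 10 bp
of the annotated shift.

## The synthetic-data generator

`makePRFGenome()` builds genomes the pipeline can be tested against
end-to-end: background sequence at a target GC, plain genes drawn from a
Dirichlet-perturbed codon table (so the A1 > A0 gate can be exercised
both ways), engineered overlapping gene pairs that supply negative
candidate sites, and optionally one planted shift cassette — slippery
motif 3'-anchored at a codon boundary, AGGAGG at a configurable spacer
(≥ 6 nt), a 9-bp GC-rich hairpin at offset 3 past the +0 stop, the +0
stop at a configurable N (a multiple of 3), and a joined CDS annotation
with separation 0 (backward) or 1 (forward). Fixed cassette parts are
chosen to be stop-free in the constrained frames (AGGAGG, the C-rich
fillers and the hairpin contain no stop triplet in any frame); free
bases are sampled and repaired until the +0 frame is stop-free up to the
planted stop and the shifted frame up to the gene end. Output is
deterministic per seed, and the test suite proves generator–scanner
closure: every planted site across all ten motif classes, both strands
and a range of N values is recovered as a labeled candidate.

`simulateCorpus()` (defaults: 60 genomes — 40 backward, 10 forward, 10
without a shift — in 5 groups) gives groups distinct codon-usage tables,
GC levels (0.45–0.65), preferred motif pools and N levels (9–36 nt), and
concentrates SD-less shift sites in one group (45% of its plants). The
group signatures create the real phenomenon the validation levels are
meant to expose: a model trained without a whole group lacks evidence
for that group's idiosyncrasies (above all its SD-less sites), so
genome-level leave-one-out recall exceeds group-level recall. Every pool
shares the canonical heptamer class so no group's motif vocabulary is
entirely novel. What the generator does *not* emulate — shared ancestry
at the sequence level, annotation errors, non-standard genetic codes,
motif-position nucleotide biases, pseudoknots — bounds what passing
tests show about real genomes: they certify the machinery (parsing,
geometry, features, training, bookkeeping), not field accuracy on real
phage corpora.

## Numerical and degenerate-input choices

* Joined features: exactly two fragments with |separation| ≤ 10 bp are
  frameshifts (both constants are `prfConfig()` settings); two fragments
  abutting the ends of a circular genome are origin wraps; everything
  else — more fragments, larger separations, same-frame fragment pairs
  (no direction can be assigned) — is "other".
* Shift direction is always derived from frame geometry, which agrees
  with the separation-0/backward, separation-1/forward convention
  whenever the annotation is a genuine frameshift and stays defined for
  the rarer 2–7 nt separations.
* Genes wholly contained in another gene are skipped for pairing;
  intervening opposite-strand genes do not break same-strand adjacency.
  A pair is accepted whenever its stop-free window reaches into the
  upstream gene — no minimum physical overlap of the annotations is
  required.
* Candidate windows shorter than a motif (contig edge) simply fail to
  match; A-site codons running off the contig are dropped.
* `fold()` on an empty window is an error; windows entirely off the
  contig score 0 with a warning.
* Training refuses single-class labels and non-finite features (naming
  the offending row); model files carry the feature-column order, motif
  table and a schema version, and refuse to load on mismatch.
* Problem sizes in the tests — 60-genome corpora, 5 seeds, 1000
  enumeration windows ≤ 14 nt, 20 MinHash trials at 5 kb — were chosen
  as the smallest sizes at which the checked contrasts are stable.

## Limitations

The shipped RBS frequency table is a synthetic stand-in with the right
shape and range, not field-derived frequencies; the baseline folder is a
didactic nested-structure model, not a thermodynamic one (plug in
RNAfold for realistic hairpin energies; no pseudoknot backend is
bundled); stop-adjacent forward motifs (CUU*/UCC*), G:U-aware positional
constraints and tRNA-pool "hungry codon" adjustments are known candidate
improvements that are deliberately out of scope. Accuracy figures
reported by the test suite describe synthetic corpora only.
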