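# prfscan

Detection and classification of programmed ribosomal frameshift (PRF)
sites in annotated prokaryotic and viral genomes.

## The problem

During translation a ribosome can stall on a *slippery sequence* and slip
one nucleotide backward (−1) or forward (+1), so that translation
continues in an alternate reading frame past the original stop codon and
produces a fusion protein. In GenBank annotations such genes appear as
CDS features with compound `join(a..b,c..d)` locations spanning two
frames — the tail assembly chaperone of tailed phages is the classic
case. No sequence-homology method finds these sites; what distinguishes
them are *cellular properties* of the site itself: the slippery motif, a
Shine-Dalgarno-like element upstream of the P-site that can pair with the
ribosome's anti-SD sequence, stable RNA secondary structure just
downstream, the relative abundance of the codon waiting in the A-site
versus the codon it would shift onto, and the distance to the in-frame
stop.

`prfscan` turns this into a supervised learning problem:

1. **Labels** come from annotated `join` features: exactly two fragments
   within 10 bp of each other mark a frameshift (fragments at the ends of
   a circular genome are origin wraps; anything else — inteins, introns,
   errors — is discarded). Each joined gene is split into a pseudo
   gene-pair, and every consecutive same-strand pair in different frames
   with a stop-free overlap window is searched for candidate sites.
2. **Candidates** are matches of ten slippery-motif classes (eight
   backward: six, threethree, fivetwo, twofive, twofour, threetwotwo,
   five, twoonefour; two forward: four, three) anchored so the motif's 3'
   end abuts the empty A-site codon, with forward candidates gated on the
   shifted codon being more abundant than the waiting one (A1 > A0).
3. **Features** are the eleven properties
   `DIR, RBS1, RBS2, MOTIF, A0, A1, LF50, LF100, HK50, HK100, N`:
   direction, a Prodigal-style 28-bin SD score and a RAST-style SD
   frequency score at the P-site, the motif class, the A-site codon
   usages, four normalized minimum-free-energy values
   (`clamp(|MFE|/len/GC, 0, 1)` over 50 and 100 bp windows starting 3 nt
   past the motif, under two folding backends), and the distance N (nt)
   from the A-site codon to the +0 in-frame stop.
4. **Classification** is a three-class gradient-boosted tree model
   ({−1, 0, +1}; L2 regularization 1.0, no early stopping, single
   thread — fully deterministic). Per overlap region only the
   highest-scoring candidate whose predicted class is non-zero is
   reported.

Leakage-controlled validation uses leave-one-group-out splits, with
groups supplied externally or computed internally by MinHash sketching
(k = 16, sketch size 400) and single-linkage clustering at Mash distance
0.05 (≈95% identity).

## Worked example

```r
library(prfscan)

## a synthetic genome with one planted backward shift (threethree motif,
## SD element at 6 nt, downstream hairpin, N = 15)
fx <- makePRFGenome(7, prf = list(motif = "threethree", direction = -1L,
                                  N = 15L, sdSpacer = 6L, strand = 1L))
fx$genome
#> GenomeRecord: synth000007 (2660 bp, linear)
#>   8 CDS feature(s); 1 joined

prep <- prepareGenome(fx$genome)
prep$features[prep$features$label != 0,
              c("aSitePos", "motif", "DIR", "RBS1", "RBS2", "A0", "A1",
                "LF50", "N", "label")]
#>   aSitePos      motif DIR RBS1 RBS2         A0         A1 LF50  N label
#> 1     2186 threethree  -1   27  6.3 0.01700155 0.03554869  0.8 15    -1
```

The planted site is recovered as a candidate: the A-site codon starts at
2186, the heptamer window immediately 5' of it matches the `threethree`
class, the planted AGGAGG lands in the top Prodigal bin (27) and at the
RAST score ceiling (6.3), the planted hairpin drives the normalized
50 bp fold energy to 0.8, and the +0 stop is 15 nt downstream. Training on a
corpus of such genomes and predicting held-out genomes is one call each:

```r
corpus <- simulateCorpus(seed = 1)          # 60 genomes in 5 groups
preps  <- lapply(corpus$genomes, prepareGenome)
v <- validateCorpus(corpus$genomes, corpus$groups, preps = preps,
                    level = "GROUP")
v$confusion
#>  TP  FP  TN  FN
#>  42   4 167   8
round(c(recall = v$recall, precision = v$precision), 2)
#>    recall precision
#>      0.84      0.91
```

A thin command-line wrapper ships at `inst/scripts/prfscan`
(`fixtures`, `train`, `predict`, `validate` subcommands).

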