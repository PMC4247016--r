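---
title: "srnascape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srnascape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the scientific models behind each `srnascape`
stage, the parameters that matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and
the numerical decisions taken where the design was genuinely open.

# Reads, weights and coverage

An aligned small-RNA read carries a multiplicity — the number of
genomic locations it matches. Coverage can be computed from unique
matches only (each multiplicity-1 read counts 1) or from all reads
with each read's contribution reweighted by `1/multiplicity`, so that
the total coverage mass equals the sum of `weight × length` over
reads regardless of repeat content. Reweighted mode is the default
for region-level summaries and is always used for periodicity (repeat
regions are exactly where multimappers concentrate, and dropping them
would erase the signal being sought); unique mode is available
everywhere for sensitivity checks.

Reads outside the library's size selection (default 18–36 nt) are
flagged on loading rather than dropped, and excluded downstream by
default. All internal coordinates are 1-based closed `GRanges`
intervals — the native convention of the R/Bioconductor interval
stack this package is built on; BED input/output is shifted at the
boundary, and GFF coordinates round-trip unchanged.

# sRNA-producing loci and the two distribution archetypes

Reads are clustered by single linkage: two reads join the same locus
when connected by a chain of reads with pairwise genomic gaps below
`max_gap` (default 100 bp, measured between nearest read ends), and a
locus must collect at least `min_reads` (default 10). These two
values define what "sRNA-producing locus" means and are deliberately
permissive; all downstream stringency lives in the classification and
filtering steps.

Each locus is classified by two statistics:

* `strand_fraction` — fraction of member reads on the majority
  strand;
* `localization` — fraction of member 5' ends within ±2 nt of the
  modal 5' end.

A locus is a `PILE` when `strand_fraction >= S` and
`localization >= L` (defaults `S = 0.9`, `L = 0.8`), else
`DISTRIBUTED`. Piles are the signature of precise processing from a
defined precursor (tRFs, snRNA fragments, miRNA-like products);
distributed loci — both strands, overlapping staggered reads — are
the signature of siRNA-like populations over TEs and methylated
genes. `S` and `L` are package defaults chosen to demand near-perfect
strand purity while tolerating a few nucleotides of 5'-end wobble;
they are exposed as arguments because no community-standard values
exist. Note a locus harbouring *two* distinct piles (e.g. an 85 nt
region with 24- and 25-nt fragments whose 5' modes sit 12 nt apart)
classifies as `DISTRIBUTED` under this locus-level definition even
though each fragment individually is pile-like; fragment-level
classification is intentionally out of scope.

Candidate processed-sRNA loci are `PILE` loci passing: dominant
fragment length in 19–29 nt; the `S`/`L` thresholds; a complexity
test on the dominant fragment sequence (Shannon entropy >= 1.5
bits/nt and no single overlapping dinucleotide making up >= 60% —
a DUST-like proxy rejecting homopolymeric and simple-repeat
artifacts); and a degradation proxy rejecting loci inside annotated
structural RNAs that lack a localized 5'-end mode (non-localized
coverage of an abundant rRNA/snoRNA is its decay ladder, not a
processed product). Candidates are typed by annotation overlap:
tRNA-associated, known-ncRNA, or intergenic-novel. Merging across
libraries takes the interval union and records per-locus library
support.

# Genomic categories and length profiles

Category accounting supports two semantics. `partition` assigns each
read to exactly one category by priority (default tRNA > other ncRNA
> repeat > gene > intergenic, any-overlap, strand-ignored), so counts
sum to the aligned total. `overlap` counts a read under every
annotation row it touches, which is the semantics of per-annotation
summary tables where rows need not partition the total. Length
histograms run over the 18–36 nt support.

# tRNA-derived fragment classes

A tRNA gene model carries arm sub-coordinates (acceptor stem 3' span,
D loop, anticodon loop, T loop) and its mature 3' terminus.
Fragments are placed strand-aware in tRNA-relative coordinates and
classified:

| class | length | anchor |
|---|---|---|
| `3p_short` | 17–22 nt | 3' end within 3 nt of the mature terminus |
| `3p_long` | 30–36 nt | 3'-anchored |
| `5p_long` | 30–36 nt | 5'-anchored |
| `half_tRNA` | — | 5'-anchored, 3' end *inside* the anticodon loop |
| `dloop_anticodon` | 17–22 nt | overlaps D or anticodon loop, not 3'-anchored |

"Around 19 nt" is operationalized as the closed interval [17, 22] and
"30–35 nt" widened to [30, 36]; the anchor slack is 3 nt. All bounds
are arguments. Precedence when several rules match is most-specific
first: `half_tRNA` > `3p_*` > `5p_long` > `dloop_anticodon`. The
half-tRNA rule uses no slack on the anticodon loop: a long 5' tRF by
definition ends *before* the loop, a half ends *in* it (the cleavage
site) — with slack the two classes would be inseparable. CCA status
is read from the fragment sequence, not the genome, because the
trinucleotide is added post-transcriptionally and need not be
templated; it applies only to 3'-anchored classes.

# TE coverage, expression and methylation statistics

Region-level sRNA abundance uses RPKM,
`count × 10^9 / (length × total aligned)`, with reweighted counts by
default. Methylation level is the proportion of overlapping probes
called methylated; a probe-free region is undefined (`NA`), never
zero. RPKM bins are low < 5, middle 5–10, high > 10, with both
boundaries assigned to the middle bin so the bins are exhaustive
(strict inequalities on both sides would leave the boundary values
unclassified). Lowly-expressed regions are those at or below the 15th
percentile of the expression distribution (type-7 quantile).

The association battery: a one-sided Mann–Whitney U test of sRNA
coverage in low/none- versus expressed regions (alternative:
coverage greater in the low group), delegated to `wilcox.test()`,
which computes the exact distribution for small tie-free samples and
a tie-corrected normal approximation otherwise; Spearman and Pearson
correlations of methylation level against RPKM; and a pairwise
Spearman matrix across library coverage vectors. Groups under 3
regions report `NA` with a warning. TE region sets are filtered to
length > 50 nt (annotation fragments below that carry no usable
coverage signal); family-level summaries conventionally restrict
further (e.g. > 300 bp).

# Periodicity by sliding-window Fourier analysis

Windows of 1000 bp at 100 bp increments are transformed after mean
subtraction (removing the DC component; the transform is otherwise on
raw coverage). The main period search is restricted to a 50–500 nt
band: below ~50 nt lies read-length-scale structure, and
DC-adjacent bins would otherwise dominate any window with a coverage
trend. The per-window coefficient is the peak magnitude divided by
the sum of non-DC half-spectrum magnitudes — scale-free in [0, 1] and
equal to 1 for a pure sinusoid. Windows whose coefficient exceeds 75%
of the maximal coefficient *over the whole scanned set* (one global
pass, not per chromosome) carry a significant period.

Two numerical choices matter here:

* **Between-bin periods.** A 180 nt spacing in a 1000 nt window falls
  at 5.56 cycles — between Fourier bins. The bin-level argmax loses
  peak magnitude to spectral leakage exactly there, while an on-bin
  harmonic (90 nt = 11.1 cycles, near bin 11) does not, so naive bin
  extraction systematically reports the half-period. The default
  (`refine = TRUE`) therefore compares candidate band-local maxima by
  their refined spectral peaks — a 16× zero-padded FFT (the DTFT on a
  1/16-bin grid) with parabolic interpolation around each peak,
  interpolating only at strict local maxima so the shift is bounded
  by half a padded bin. `refine = FALSE` gives the plain `window/k`
  bin period.
* **Harmonic preference.** When a sub-harmonic at half the peak
  frequency (frequency ratio >= 1.7) reaches within 5% of the peak
  magnitude, the longer period is reported and the window flagged
  harmonic; pulse-train coverage genuinely contains both.

Region calls: every run of `min_significant` (default 3) consecutive
significant windows fitting within `span` (default 5000 bp)
contributes its whole genomic span; overlapping spans merge into
maximal regions reporting window count, mean main period, and whether
the mean falls in the 175–225 nt reference band. Overlap reports
against highly methylated regions (HMRs) give the fraction of
periodic regions touching an HMR and the fraction of HMRs overlapped
by sRNA loci, including coverage over more than 75% of their length.
HMR interval sets are consumed as input; when only probe calls are
available the pipeline derives a working set by merging methylated
probes within 200 bp and keeping runs of at least 5 probes.

Degenerate inputs: an all-zero window has no period (`NA`) and
coefficient 0; a constant window is zero after detrending and gets
coefficient 0. Tracks shorter than one window yield an empty scan.

# Hairpin evaluation

A candidate locus is extended by 50 nt on each side (clipped at
chromosome ends with a warning), extracted strand-aware, and folded.
The folding backend is pluggable: ViennaRNA `RNAfold` at 24 °C — the
growth temperature of the mesophilic marine organisms this analysis
targets, rather than the 37 °C default — when the executable is
available, else a bundled weighted Nussinov base-pair maximization
(pair weights GC = 3, AU = 2, GU = 1, minimum hairpin loop 3 nt).
The fallback is explicitly non-thermodynamic: its "MFE" is minus the
total pair weight, a pseudo-energy suitable wherever only the rank
ordering of structure stability matters (tests, empirical nulls).
The weighted score, rather than a plain pair count, keeps the null
energy distribution fine-grained enough that the strictly-less
empirical p-value below is not distorted by ties.

The empirical MFE p-value draws `n` (default 1000) random genomic
regions of the candidate's length — uniform over positions, strand
with probability 1/2, no overlap constraint — folds them with the
same backend, and reports `p = #{MFE_random < m} / n`, significant
below 5%. A stable candidate (very negative `m`) leaves few random
regions below it, so small p means more stable than random. Under
the null, p is uniform up to the 1/n grid; the test suite verifies
this by a Kolmogorov–Smirnov check over seeded trials.

Mature fragments are the up-to-6 most read-supported distinct
(start, end, strand) fragments, ties broken leftmost-start then
shortest. The star is inferred as the base-pairing partner span of
the mature shifted 2 nt toward its 3' end (standard duplex geometry),
unless an observed star is supplied. Each duplex end is checked for a
3' extension of exactly 2 nt beyond its partner's paired region —
the Dicer signature. Verdicts: `canonical_miRNA` (significant
hairpin, stem-located mature, 2-nt 3' overhangs on both ends),
`miRNA_like` (significant hairpin with mature and star but overhangs
on at most one side — a configuration compatible with
Dicer-independent processing), `rejected` otherwise. A mature with
under half its positions paired is loop-located and yields no star.

# The synthetic-data generator

`synth_config()` fixes a landscape whose defaults mirror the
populations the pipeline targets: three single-sequence piles
(depth 2000); an 85 nt intergenic locus of overlapping 24/25 nt
fragments with a central plateau (depth 5000); a U2-snRNA-style
226 nt region with a deep 3' pile of 26,000 reads and a shallow 5'
pile of 1,200; four tRNA genes emitting 10,000 tRF reads from a
class mixture (45% 3' short, 15% each D-loop/anticodon, 3' long and
5' long, 10% half) with genome-templated CCA and a 95% CCA retention
rate on 3' short fragments; twenty TE regions (Copia, PiggyBac,
Blackbeard families, 800–3500 nt) of which 25% are methylated and
silenced, covered on both strands by 25–30 nt reads at 1.5 reads/nt
(expressed TEs get 0.04 reads/nt) with the first base U with
probability 0.6; two 5000 nt highly methylated regions with read
piles every 180 nt (positional jitter SD 5 nt, Poisson pile depth
30); eight genes (two methylated, carrying TE-style coverage) with
log-normal expression for the expressed ones and near-zero for the
silenced ones; 5% of methylated-Copia reads duplicated across the
two copies at multiplicity 2; and a uniform degradation background
(0.002 reads/nt, geometric length mix). Reads are distributed over
five condition labels uniformly. One seed determines the entire
bundle byte-for-byte.

What the generator does *not* emulate — and what passing recovery
tests therefore cannot show about real data: sequencing error and
adapter artifacts; realistic genome composition (i.i.d. uniform
bases at GC 0.48, so low-complexity regions arise only where
planted); transcription-coupled read-depth structure; partial or
nested TE copies and families with internal homology beyond the one
duplicated pair; condition-dependent expression differences between
libraries; and CCA chemistry beyond a fixed retention rate. The
generator establishes that the algorithms recover what they are
defined to recover; it cannot establish robustness to the noise
structure of a real sequencing run.

# Problem sizes and runtime choices

The test suite validates the clustering against a brute-force
single-linkage oracle on 1000 random read sets of up to 50 reads;
the FFT against an O(n²) DFT oracle on windows up to 1024 nt; period
recovery on 90/180/200 nt plantings over 20 seeds each; tRF recovery
on the full 10,000-read default; the empirical-MFE null over 200
seeded trials of 200 permutations with the fallback folder; and full
pipeline determinism on the default bundle (~65,000 reads over a
2 × 80 kb genome). These sizes keep the whole suite in the
single-digit-minute range on one core while leaving every recovery
criterion statistically meaningful; all of them scale up through the
same APIs.

# Known limitations

* Locus-level PILE/DISTRIBUTED classification cannot separate two
  co-located piles from distributed coverage (see above); a
  fragment-level classifier would.
* The degradation filter is a proxy keyed to annotated structural
  RNAs; unannotated abundant transcripts can still leak degradation
  piles into the candidate set.
* Significance in the periodicity scan is relative (75% of the
  maximal coefficient in the run), so a scan containing one
  extremely periodic window suppresses weaker but real periodic
  regions; an absolute or null-calibrated threshold would decouple
  calls across the genome.
* Periodic regions merge through chains of significant windows, so a
  strongly periodic region flanked by step-edge windows (TE
  boundaries produce low-frequency significance at the band edge)
  can absorb them and shift its mean period; the in-band flag is the
  robust read-out.
* The star inference assumes a clean stem; large internal loops or
  multi-branch structures between mature and star make the 2-nt
  overhang geometry approximate.
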