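---
title: "Locating and quantifying zinc transcriptional regulatory elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating and quantifying zinc transcriptional regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ztre)
library(dplyr)
```

## The biology in one paragraph

Cells repress a suite of genes when zinc is plentiful. In human cells this
repression runs through the ZTRE — the *zinc transcriptional regulatory
element* — a degenerate, near-palindromic DNA element bound by the
KRAB-zinc-finger protein ZNF658. The element consists of two short
conserved arms,

```
C-[A/C]-C-[T/A/G]-C-C-[T/C]   ...N(0-50)...   [G/A]-G-[A/T/C]-G-[T/G]-G
```

whose 3' arm is approximately the reverse complement of the 5' arm,
separated by an unconstrained spacer of 0 to 50 nucleotides. ZTREs cluster
strikingly in the ribosomal RNA precursor, linking zinc homeostasis to
ribosome biogenesis — the most zinc-demanding transcriptional program in
the cell. This package implements the computational side of that analysis:
element scanning and per-kilobase density in anchored windows, C2H2
zinc-finger annotation of the binding protein, the arithmetic of its
peptide-mass-fingerprint identification, and the qPCR and microarray
statistics used to quantify zinc-responsive expression.

## Promoter coordinates without a zero

All regulatory coordinates here follow molecular-biology convention: +1 is
the transcription start site, −1 immediately precedes it, and *there is no
position 0*. `interval_length()`, `promoter_to_offset()` and
`offset_to_promoter()` implement this arithmetic exactly. The convention is
not cosmetic — it is the only numbering under which the documented SLC30A5
promoter features are mutually consistent: the printed −156..+46 probe is
202 nt, the −124..−75 competitor oligonucleotide is 50 bp, and the
−91..−84 deletion removes 8 bases:

```{r}
slc30a5_features()
```

(The probe region is sometimes loosely called "212 bp"; the printed
sequence, the element coordinates and the competitor length all agree with
202 under the no-zero convention, so 202 is what the package uses.)

## The gapped-motif scanner

`ztre_motif()` compiles the consensus above into a `gapped_motif`: two
ordered lists of residue sets plus a spacer range. `scan_motif()` reports
every `(start, gap, strand)` occurrence; reverse-strand hits are found by
scanning the forward text with the reverse-complemented motif
(`motif_reverse_complement()`, an involution), so all coordinates are
forward-text. Design points:

* **N handling.** `N` in the text never satisfies a half-site residue set
  (masked sequence cannot create an arm), but the spacer is unconstrained
  by the consensus, so `N` inside the spacer does not block a match.
  Matching is case-insensitive.
* **Footprints.** Because the element is a near-palindrome, most genuine
  sites match on both strands over the same interval. `dedupe_footprints()`
  collapses matches to unique `(start, end)` intervals, unioning strands;
  the footprint count is the element "copy count". For a fixed interval
  the spacer length is determined by the interval width
  (`end − start + 1 = 13 + gap`), so the canonical parse only breaks
  strand ties, preferring `+`.
* **Overlaps.** Footprints with *different* intervals are all counted,
  even when they overlap — two elements 20 bp apart legitimately admit a
  third, composite footprint (the left arm of one pairing with the right
  arm of the other across the spacer range). No merging rule is imposed.
* **Spacer classes.** `classify_gap()` splits spacers at 30: shorter than
  30 bases is `"short"`, 30–50 is `"long"` — the two classes drawn in
  element maps.

The worked example is bundled: the 202-nt SLC30A5 probe contains exactly
one footprint at promoter −91..−76 (spacer 3, both strands), and deleting
the element's 5' side (−91..−84) destroys it:

```{r}
fp <- slc30a5_probe() |> scan_motif() |> dedupe_footprints()
fp
offset_to_promoter(c(fp$start, fp$end), slc30a5_window_start())
nrow(scan_motif(slc30a5_probe_deletion()))
```

The scanner is validated against a brute-force oracle (exhaustive
enumeration of every start, gap and strand, written independently of the
scanner) on a thousand random sequences in the test suite.

## Windows, mapped regions and densities

Anchors are TSSs or 5' ends of processed rRNAs. `extract_windows()` takes
±`flank` (default 1000 bp, the ±1 kb convention) around each anchor,
clipping at sequence ends rather than erroring — rDNA repeat units are
short relative to the flanks, and the achieved window length is what
enters the density denominator. `build_mapped_regions()` merges
overlapping windows into disjoint intervals (via IRanges), mirroring maps
in which unmapped sequence is collapsed; `count_footprints()` counts
footprints *fully contained* in a mapped interval (a partially extracted
element is not a validated copy; overlap counting is available via
`rule = "any"`). `density_per_kb()` and `density_report()` then give
per-group densities — e.g. 10 elements in 14 kb of mapped rRNA-precursor
sequence is 0.71/kb, against 0.15/kb for ribosomal-protein genes and
0.35/kb for their nearest neighbors (ratios below one-quarter and
one-half). "Nearest adjacent neighbor" is measured TSS-to-TSS
(`nearest_neighbor()`), ties broken toward the smaller coordinate.

## C2H2 zinc-finger annotation

`scan_zinc_fingers()` detects the classical Cys2-His2 finger by exact
spacing, C-X2-C-X12-H-X3-H: a 21-residue window with coordinating
residues at positions 1, 4, 17 and 21. Spacing is fixed by default (the
pattern's spacers are configurable but carry no length tolerance), and
candidate windows are consumed greedily left to right so annotated
fingers never overlap — tandem finger arrays tile. Two documented
non-canonical configurations are admitted when `allow_variants = TRUE`:
H in place of the first C ("H-C-H2") and R in place of the last H
("C2-H-R"). The "HisCys-His2" description of such first fingers is
ambiguous between H-at-position-1 and an H-C pair in the first two
coordinating slots; the package implements the minimal relaxation
(position 1 may be H, everything else canonical) and keeps it behind the
variant flag. Disabling variants can only decrease the finger count.

## Peptide-mass-fingerprint arithmetic

`digest()` performs in-silico trypsin digestion: cleavage after K or R
except before P (the Keil rule, switchable — standard trypsin specificity,
stated explicitly because gel protocols rarely spell it out). Zero missed
cleavages is the default, reading "the fragments generated by trypsin" as
complete digestion; `missed_cleavages = m` adds every concatenation of up
to `m + 1` adjacent fragments. Masses are monoisotopic residue sums plus
water (18.010565 Da); peaks are compared as singly protonated [M+H]⁺ ions
(+1.007276 Da), as MALDI fingerprinting reports them over its scanned
900–4000 Da window. `match_peaks()` applies an inclusive ppm tolerance
(default 50 ppm) and gives each peak its best match (smallest |ppm|, ties
toward the smaller fragment start); `pmf_coverage()` reports the union of
matched spans. No fixed cysteine modification is applied by default (no
alkylation step in the source protocol); carbamidomethyl is available via
`residue_masses(fixed_mods = c(C = 57.02146))`.

## Expression statistics

**ΔΔCt.** `ddct()` implements relative quantification with 100%
amplification efficiency assumed throughout (no standard-curve
efficiencies are modeled): per sample ΔCt against a reference gene, per
condition ΔΔCt against a calibrator condition, relative level
`2^(−ΔΔCt)`; the calibrator is exactly 1 by construction and the result
is invariant to per-sample Ct offsets. `abundance_ratio_from_ct()` adds
the dilution-corrected abundance ratio
`dilution × 2^(Ct_low − Ct_high)` used when one species is so abundant
that its template must be diluted before measurement. (Note the published
18S:45S example: a ΔCt of 6.54 with a 20-fold dilution gives ≈1.9 × 10³
under this arithmetic, not the ≈1.3 × 10³ quoted alongside it; the
function implements the stated arithmetic.)

**Rank product.** `rank_product()` ranks genes by fold change within each
treatment-vs-control comparison and takes the geometric mean of ranks;
up- and down-regulation are two one-sided analyses (which is what
produces separate up/down tables). Significance is a permutation-based
estimated false-positive proportion (pfp): expected null exceedance count
divided by the gene's rank. Three null generators are provided, and the
choice matters:

* `"uniform"` (default): each comparison's null ranks are an independent
  uniform permutation — the classical rank-product null, and exactly the
  distribution enumerated by `"exact"`.
* `"exact"`: full enumeration of all `(G!)^K` rank configurations, for
  tiny instances; used in the tests as the reference the Monte-Carlo
  estimate must converge to.
* `"within_probe"`: shuffle each probe's values across its samples and
  recompute. This preserves the correlation structure of the comparisons
  but is *contaminated* by genes with real effects (a shuffle reproduces
  the group split with probability ~1/20 at 3+3 samples), which floors
  the attainable pfp when many genes are differential; it is kept as an
  option, not the default.

Comparisons are **paired** by default (replicate *i* vs replicate *i*,
the original formulation): each sample then enters exactly one
comparison, so per-gene fold changes are independent across comparisons
under the null — the assumption the uniform/exact null encodes. The
`"all_pairs"` alternative (every treatment vs every control replicate)
gains power by reusing samples, but the reuse correlates ranks across
comparisons and makes the independent null anticonservative; if you use
`all_pairs`, pair it with the `within_probe` null and expect conservative
pfp values under heavy contamination.

`apply_expression_filters()` applies the reported filter cascade in
order: probes must pass detection (p < 0.01) first, then change by
strictly more than 1.2-fold on the linear scale in either direction, then
be significant by directional pfp; results are split up/down and sorted
by fold magnitude. Fold changes are ratios of group means on the linear
scale; declare log2 input with `scale = "log2"`.

## The synthetic-data generator

Every stage is testable offline because `sim_*()` generators plant known
truth and return manifests:

* `sim_dna_with_ztres()` / `sim_anchor_panel()` plant concrete element
  instances (each degenerate position sampled from its set) at known
  positions, gaps and strands. The background is **rejection-scrubbed**:
  after planting, the sequence is rescanned and any accidental footprint
  is rerandomized away (only planted half-site arms are immutable — a
  planted element's spacer is unconstrained, so it may be resampled,
  which is what makes scrubbing always terminate). Recovery assertions
  are therefore exact, not probabilistic. A plant with spacer 51 is
  emitted but flagged invalid: a negative control the scanner must not
  report.
* `sim_protein_with_fingers()` embeds 21-residue finger instances
  (canonical or either variant) in a scrubbed background with a
  controllable K/R fraction, so digestion tests have predictable fragment
  counts.
* `sim_peak_list()` jitters selected in-range [M+H]⁺ values by
  Normal(0, 10 ppm) and places decoys at least 3× the matching tolerance
  from every theoretical mass, so a correct matcher has zero false
  negatives and zero decoy hits.
* `sim_ct_table()` encodes true folds as −log2(fold) Ct shifts; with zero
  noise, `ddct()` recovery is exact.
* `sim_expression_matrix()` draws per-gene log2 baselines from
  Normal(8, 1), adds ±log2(fold) knockdown effects for planted genes and
  Normal(0, 0.15) replicate noise (typical of well-detected bead-array
  probes after variance-stabilizing normalization), then returns linear
  intensities, detection p-values and a truth manifest. The study-like
  defaults are two groups of 3 samples and >1.2-fold planted effects.

All generators consume an explicit integer seed and are byte-identical
under a fixed seed. What they do *not* emulate: repeat structure, CpG
islands and base composition biases of real genomes; probe-level
cross-hybridization and array spatial artifacts; isotopic envelopes and
adducts in MALDI spectra. Passing tests therefore demonstrate the
*arithmetic and inferential* correctness of each stage, not robustness to
every artifact of real data.

## Numerical and degenerate-input choices

* Spacer class boundary is exactly 30 (29 → short, 30 → long); gaps
  outside [0, 50] are errors, not silently reclassified.
* ppm tolerance is inclusive (`|error| ≤ tol`); the mass-range filter
  applies to the theoretical [M+H]⁺, not the observed peak.
* `compare_density()` flags a zero reference density with `NA` rather
  than erroring mid-report.
* Empty inputs return empty, correctly typed tibbles (`scan_motif` on an
  empty match set, `dedupe_footprints(empty)`, `pmf_coverage(no matches)`
  is 0/0.0) — errors are reserved for contract violations (position 0,
  overlapping plants, empty sequences, unknown residues with their
  position named).
* Monte-Carlo sizes in the shipped tests are chosen for a laptop-scale
  run: 1000 random 300-nt sequences for scanner-vs-oracle equivalence,
  300–400-gene matrices with 250 permutations for calibration and
  recovery, a 100-window panel for density calibration; the full suite
  runs in about a minute.

## Accession-dependent checks

Checks that need real sequences (the 1,059-residue ZNF658 translation
with its 21 fingers and 60 tryptic fragments; the rDNA repeat with 10
element copies in the ±1 kb windows) are opt-in: place
`znf658_protein.fasta`, `rdna_repeat.fasta` and `rdna_anchors.tsv` in a
directory and set `ZTRE_DATA_DIR` to it before running the tests. Whether
the documented "60 fragments" counts all digestion products or only those
inside the scanned 900–4000 Da range is untestable without the original
peak list; the test asserts the literal (all-fragments) reading.

## Known limitations

* The scanner is a consensus matcher by design: no position-weight-matrix
  scoring, no background models, no genome-scale indexing.
* Rank-product power at exactly 3 replicates per group is modest under
  the calibrated paired design; 1.5-fold effects are recovered in the
  clear majority at n = 3 and completely from n = 4 (the anticonservative
  alternatives recover all at n = 3 at the cost of null calibration).
* KRAB-domain detection, BLASTP alignment and Mascot/Mowse probability
  scoring are out of scope; the package stops at the arithmetic that can
  be specified exactly.
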