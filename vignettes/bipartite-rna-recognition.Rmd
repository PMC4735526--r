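---
title: "Methods: bipartite (A/U)AA recognition analysis for STAR proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bipartite (A/U)AA recognition analysis for STAR proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starbind)
```

# The model

STAR-family proteins such as T-STAR (SLM-2) and Sam68 are obligate
homodimers: the QUA1 region forms a helix-turn-helix dimerization
module, and in T-STAR the KH domain and the C-terminal half of the
QUA1-KH linker contribute a second, larger dimer interface.  Each KH
domain accommodates about four single-stranded nucleotides in its
hydrophobic groove and specifically reads an (A/U)AA trinucleotide,
giving the per-domain consensus N(A/U)AAN.  Because the two RNA-binding
grooves of the dimer face away from each other, a single dimer can bind
one RNA molecule at both grooves only if that RNA presents two (A/U)AA
cores far enough apart to loop between them — more than 15 intervening
nucleotides.  That defines the bipartite site
(A/U)AA–N~>15~–(A/U)AA, and it makes three quantitative predictions
that this package turns into computations:

* CLIP tags from such a protein should be enriched in A/U-rich k-mers
  relative to composition-matched genomic background, and tags should
  preferentially contain **two** cores at a spacing compatible with the
  dimer (roughly 15–30 nt), not just one.
* Affinity measured by fluorescence polarization should jump when a
  two-core RNA's linker crosses the geometric threshold (additivity /
  avidity), and not before.
* The crystal structures should show a dimer whose two bound RNAs
  cannot be one short contiguous chain: large buried dimer interface,
  conserved geometry across crystal forms, and a long distance between
  the 3' end of one bound RNA and the 5' end of the other.

# Conventions

All sequence coordinates are 0-based, half-open, and all sequences are
normalized to the uppercase RNA alphabet at ingest (CLIP tags map to a
DNA genome, but every motif in this field is written as RNA).  Windows
or motif positions containing `N` are skipped, never counted.

# K-mer enrichment

`count_kmers()` counts overlapping windows; a tag of length L
contributes `max(0, L − k + 1)` windows minus any window containing
`N`.  `enrich_kmers()` builds, per k-mer, the 2×2 table of occurrence
vs non-occurrence windows in CLIP vs control and applies the 1-df
Pearson chi-squared test without continuity correction; the enrichment
ratio is the ratio of per-window occurrence frequencies.

Several details here are genuinely open choices and are implemented as
documented, configurable decisions:

* **Counting unit.** "Frequency of occurrence" can be read per window
  or per tag; the window-level 2×2 table is the simplest consistent
  reading and is what the test statistic assumes.  Overlapping windows
  of one tag are not independent, so the chi-squared calibration is
  approximate; on null simulations (two sets from the same generator,
  2000 tags) the observed fraction of p < 0.05 hexamers is checked to
  stay near the nominal level (the test suite asserts 0.02–0.09).
* **Multiplicity.** Raw p-values against `alpha = 0.05` by default,
  matching the convention of reporting "top N motifs, all p < 0.05"; a
  Bonferroni option exists (`correction = "bonferroni"`) but is off by
  default.
* **Ranking.** "Top" is not uniquely defined by p-values at these
  sample sizes (hundreds of k-mers reach p ≈ 0).  The package ranks by
  descending enrichment ratio, ties by ascending p, then k-mer.  A
  consequence worth knowing: with a +0.5/4-cell pseudocount (applied
  only when a cell is zero, and only to the ratio — the test always
  uses raw counts), rare k-mers can top the ranking by ratio while the
  bulk of the selected list carries the embedded motif; the logo stage
  consumes the whole top list, which is robust to this.
* **Logo anchoring.** Tags containing a top k-mer are anchored at the
  leftmost occurrence (earliest-ranked k-mer on positional ties) and
  base counts accumulate over `[-flank, k + flank)`; flank columns that
  fall off a tag contribute nothing, so only fully covered columns sum
  to the number of contributing tags.

# Bipartite spacing

`scan_cores()` reports every (possibly overlapping) `[AU]AA` match.
Separation between two cores is counted as intervening nucleotides
between the upstream **footprint** — core + 1 nt 3' flank, 4 nt total,
truncated at the sequence end — and the downstream core start.  The
footprint encodes the ~4-nt occupancy of a KH groove, and under this
convention the `UAAA-C_n-UAAA` linker ladder tracks n closely: maximum
separations 6, 11, 16, 21, 26, 31 for n = 5…30, strictly increasing.

`find_bipartite_sites()` uses `min_separation = 16` (strictly more
than 15 intervening nucleotides) and a default ceiling of 30 nt, the
spacing window where in vivo tags concentrate.  The C15 construct sits
exactly at the boundary (its trailing AAA core reaches separation 16),
so unambiguous contrasts — C5 vs C25, (UAAA)×4 vs (UAAA)×8 — are used
wherever a binary has-site call is asserted; the thresholds are
arguments, not constants.  `(UAAA)×4` (16 nt) has maximum separation 9:
no site.  `(UAAA)×8` (32 nt) reaches 25: site.

`spacing_distribution()` histograms the per-tag **maximum** separation;
tags with fewer than two cores stay in the denominator, so normalized
counts are per scanned tag and the CLIP and control curves are directly
comparable.  Negative separations (overlapping cores only) clamp to the
0 bin; values above `max_distance` fall in one overflow bin at
`max_distance + 1`.  The exact distance convention in published
spacing plots (start-to-start vs intervening) is not standardized;
footprint length and the binning ceiling are parameters so either
reading can be reproduced.

Overlapping cores are all reported, deliberately: poly(A) tracts
legitimately contain many registered sites, and pair enumeration
handles the redundancy.

# The synthetic-data generator

`generate_tags()` emulates what a CLIP tag set from a bipartite-binding
protein looks like at the sequence level: i.i.d. background at
mouse-like base composition (A 0.29, C 0.21, G 0.21, U 0.29 —
configurable; the real control is genomic sequence whose exact
composition varies), fixed 40-nt tags by default, and for a chosen
fraction of tags two copies of a motif (default UAAA) written **over**
the background at a spacing drawn uniformly from 20–30 nt.  Overwriting
rather than inserting keeps lengths exact, so `generate_control()` can
length-match.  One global seed derives a substream per tag, making
output bit-reproducible and independent of generation order.  The
number of control sequences is a parameter (the matched-control design
fixes lengths, not counts).

What the generator does **not** emulate: crosslink-induced deletions
and truncations, genomic repeat structure and local composition
heterogeneity, transcript-level coverage biases, and any RNA secondary
structure.  Passing tests on synthetic data therefore demonstrate that
the statistics recover planted signal under the stated noise model —
not that real CLIP libraries are free of artefacts these features can
cause.

Simulation sizes used throughout the tests (2000 tags of 40 nt,
500–2000 per property check, 200 titration replicates) are chosen so
every law-of-large-numbers band is comfortably stable across seeds
while the whole suite stays interactive.

# FP binding curves

`predict_signal()` implements two isotherms: hyperbolic
(free ≈ total protein) and the exact mass-action **quadratic** model
with probe depletion, `bound fraction =
((K_d + R + P) − sqrt((K_d + R + P)² − 4RP)) / (2R)` at probe
concentration R.  The quadratic model is the default because the
tightest constants measured for these proteins (~1 µM) are only ~5× the
0.2 µM probe, where the hyperbolic approximation biases K~d~ upward;
the quadratic model converges to the hyperbolic one as R → 0 (verified
to 1e-4).

`fit_kd()` runs Levenberg–Marquardt least squares over
(K~d~, f_free, f_bound) with data-driven initialization (end signals;
K~d~ from the concentration nearest the midpoint signal) and tight
convergence tolerances so noiseless data is recovered to machine
precision.  Degenerate inputs are flagged rather than fitted: constant
signals, or a fitted amplitude below three residual standard
deviations, set `unfittable`; a K~d~ outside
[min positive concentration/10, 10 × max concentration] is marked
unreliable.  No Hill term is offered: the additivity question is
addressed as a K~d~ **ratio across constructs**
(`additivity_ratio()` = K~d,ref~/K~d,long~), not as cooperativity
within one curve.  The default simulated design mirrors the standard
plate: two-fold serial dilution from 200 µM (15 points) plus zero.
Measured dissociation constants from the linker-ladder experiments are
treated as printed inputs to the ratio, never as fitting targets — they
are experimental numbers this package cannot recompute.

# Structural comparisons

`read_pdb()` (via bio3d) applies fixed, bit-reproducible policies:
model 1 only, altloc blank/'A', waters excluded.  `superpose_kabsch()`
is an SVD-based Kabsch superposition constrained to a proper rotation;
atoms are matched by paired chain, residue number + insertion code and
atom name, using only the intersection (crystallographically disordered
residues — e.g. missing linker stretches — drop out with a reported
count).  For dimers both chain pairings are tried and the smaller RMSD
kept (`backbone_rmsd()`), since the assignment of the two protomers is
arbitrary.  The test suite checks the implementation against an
independent quaternion (Horn) oracle to 1e-9 and against bio3d's
reference RMSD.

`sasa()` is a Shrake–Rupley implementation on a deterministic
golden-spiral lattice (default 960 points, probe 1.4 Å) with an
explicit radius table (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å); an
element without a radius is an error, never a silent default, because
buried-area numbers are only comparable under a declared
parameterization.  Published interface areas rarely state the software
and radii used, so buried-area comparisons should carry a ±10% band.
`interface_area()` is the standard
`(SASA(A) + SASA(B) − SASA(AB)) / 2` per monomer;
`rna_end_distance()` measures 3'-O3' to 5'-terminus (P, falling back to
O5', then C5') in both orderings.

The acceptance checks against the deposited structures (5EMO interface
area, 5EMO-vs-5ELT backbone RMSD, RNA end spans in 5ELT/5EMO) run when
the PDB files are present under `inst/extdata/pdb/`; the package does
not bundle the coordinate files, so those three tests require a
one-time download.

# Pipeline

`run_clip_analysis()` executes ingest → enrichment → top motifs → logo
counts → spacing → bipartite calls from one config (R object or flat
YAML), writing one TSV per stage plus a JSON report whose summary
numbers are, by construction, recomputable from the stage TSVs (the
test suite audits this).  The analysis stages are deterministic;
identical config and inputs give byte-identical TSVs, and the report
stores MD5 checksums.  The seed matters only when the config's inputs
were themselves generated.

# Known limitations

* The chi-squared window model ignores within-tag correlation of
  overlapping windows; calibration is checked empirically but the
  p-values are approximate.
* The spacing statistic uses only the per-tag maximum separation;
  multi-site tags contribute one count.
* The SASA radius table covers C/N/O/S/P; structures with hydrogens,
  ions or modified residues need a user-supplied table.
* FP fitting assumes a single-site isotherm per curve; avidity shows up
  only across constructs, as designed.
* The generator's i.i.d. background understates the sequence
  complexity of real genomic controls; enrichment ratios on real data
  will be noisier than on synthetic data.
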