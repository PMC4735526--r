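# starbind

Analysis toolkit for the bipartite RNA recognition model of STAR-family
RNA-binding proteins (T-STAR/SLM-2 and Sam68).

## The scientific problem

T-STAR and Sam68 homodimerize through their STAR region (QUA1 + KH +
QUA2).  Each KH domain reads a short **(A/U)AA core** — the consensus
binding site is `N(A/U)AAN` — and a single dimer can engage one RNA
molecule at two cores only when they are separated by **more than 15
intervening nucleotides**, defining a bipartite
`(A/U)AA–N>15–(A/U)AA` site.  This geometry has three measurable
signatures, and this package computes all of them:

1. **CLIP k-mer enrichment.** Hexamers over-represented in CLIP tags
   versus length-matched random genomic controls.  For each k-mer the
   2×2 window table (occurrence vs non-occurrence windows, CLIP vs
   control) is scored with a 1-df Pearson chi-squared test (no
   continuity correction),
   `X² = N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))`, and an enrichment ratio
   `(a/n₁)/(c/n₂)`.  The top motifs (default 15, ranked by ratio, then
   p) anchor a position count matrix for sequence logos.
2. **Spacing analysis.** Per tag, the maximum separation between two
   (A/U)AA cores — intervening nucleotides between the upstream core's
   4-nt footprint and the downstream core start — with normalized
   CLIP-vs-control distributions and bipartite site calls.
3. **Binding energetics.** Fluorescence-polarization titrations fitted
   with either the hyperbolic isotherm
   `f = f_free + (f_bound − f_free)·P/(K_d + P)` or the exact
   ligand-depletion (quadratic) isotherm, and **additivity ratios**
   `K_d(ref)/K_d(long)` across poly-C linker ladders
   (`UAAA-C_n-UAAA`), where a ratio ≫ 1 signals simultaneous two-site
   engagement by the dimer.
4. **Structural quantities.** Kabsch superposition backbone RMSD,
   Shrake–Rupley SASA, per-monomer buried interface area, and RNA
   end-to-end distances from PDB files (deposited T-STAR structures:
   5EL3, 5ELR, 5ELS, 5ELT, 5EMO).

A seeded synthetic-data module generates CLIP-like tag sets with
embedded motif pairs at controlled spacing, matched controls, and
simulated titrations with known ground truth, so every stage is
testable without downloads.

All sequence coordinates are 0-based, half-open; sequences are stored
in the RNA alphabet.

## Worked example

```r
library(starbind)

tags <- generate_tags(tag_generator_spec(2000, embed_fraction = 0.5, seed = 1))
ctrl <- generate_control(nchar(tags$seq), seed = 2)
write_fasta(tags, "tags.fa"); write_fasta(ctrl, "control.fa")

cfg <- pipeline_config("tags.fa", "control.fa", out_dir = "clip_out", seed = 1)
rep <- run_clip_analysis(cfg, quiet = TRUE)
print(rep)
#> analysis_report: 2000 tags vs 2000 controls
#>   significant k-mers: 175; top: GGCGCC UAAAAG UAAAUC GUAAAU CUAAAC
#>   bipartite-site fraction: clip 0.575, control 0.178

ti <- generate_fp_titration(titration_spec(true_kd = 6.7, noise_sd = 3, seed = 4))
fit_kd(ti)
#> kd_fit (quadratic): Kd = 6.26 uM (se 0.35), range 51-199, rsd 2.6

additivity_ratio(6.7, 1.4)   # C15 vs C25 linker: ~4.8-fold affinity gain
#> [1] 4.785714
```

Half the simulated tags carry an embedded UAAA pair spaced 20–30 nt
apart, and the report reflects it: the selected top hexamers are
dominated by (A/U)AA-core motifs, and the fraction of tags with a
bipartite site is ~3× the matched control's.  The fitted K_d recovers
the simulated 6.7 µM within noise, and the additivity ratio computed
from the measured linker-ladder constants quantifies the affinity gain
when the linker becomes long enough for both KH domains to bind.

A thin CLI wraps the same functions
(`inst/exec/star-bipartite run --config cfg.yaml`, plus `kmer`,
`bipartite` and `fit-kd` subcommands).

## Package layout

- `R/` — tag sets and FASTA I/O, synthetic-data generators, k-mer
  enrichment, bipartite spacing, FP fitting, structure comparison,
  pipeline driver.
- `tests/testthat/` — unit, property and acceptance tests with
  independent brute-force oracles.
- `vignettes/bipartite-rna-recognition.Rmd` — the methods vignette:
  models, parameter choices, numerical decisions, limitations.
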