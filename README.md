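# zfmut

Domain-aware analysis of somatic mutations in C2H2 zinc-finger (ZF)
transcription factors, with structural metrics for ZF-DNA complexes.

## The problem

CTCF, an 11-zinc-finger chromatin architectural protein, is a
haploinsufficient tumour suppressor that is recurrently mutated across
cancers. Making sense of its mutation catalogue requires domain-aware
statistics: are missense mutations enriched in the DNA-binding ZF domain
relative to its length? Do inactivating (nonsense + frameshift) mutations
exceed the 20% threshold of the tumour-suppressor "20/20 rule"? Which
helix positions (−6…+6) within the fingers are hit — the Zn²⁺-coordinating
Cys/His anchors, the key base-contacting positions −1/+2/+3/+6, the
invariant +4 Leu/Met, or the inter-finger linkers? And at the structural
level: how do individual mutations change protein-DNA contacts, finger
centroid positions and backbone dynamics?

`zfmut` implements this pipeline for anyone analysing ZF-protein mutation
catalogues and ZF-DNA structures: parsing and classification of HGVS
variants, observed/expected (O/E) domain enrichment with per-domain
chi-square tests, positional grammar and sequence-logo information
content, transition/transversion and impact-score statistics, protein-DNA
contact enumeration with per-finger bond tallies and wild-type/mutant bond
diffs, centroid shifts, folding free-energy (ΔΔG) classification, and
Kabsch-superposition RMSD/RMSF trajectory metrics with paired Wilcoxon
tests.

## The core quantities

- **O/E enrichment**: for domain *d* of length `len_d` in a protein of
  length `L`, with `n` missense mutations in total, the expected count is
  `E_d = n·len_d/L` and the ratio `O_d/E_d` is tested per domain with a
  2-cell goodness-of-fit chi-square (df = 1, no continuity correction).
- **20/20 rule**: fraction of somatic mutations that are nonsense or
  frameshift; strictly above 0.20 supports tumour-suppressor
  classification.
- **Ts/Tv**: transitions (purine↔purine, pyrimidine↔pyrimidine) over
  transversions among single-nucleotide substitutions.
- **Logo information content**: `IC = log2(20) − H` bits per alignment
  column (ceiling `log2 20 ≈ 4.32` for an invariant column).
- **Contacts**: hydrogen-bond / electrostatic / hydrophobic / cation-π
  protein-DNA contacts under configurable geometric criteria, tallied per
  finger; `ΔΔG > 0.5` kcal/mol classifies as destabilising.
- **RMSD/RMSF**: per-frame RMSD after optimal (Kabsch) superposition and
  per-residue fluctuation about the iterated mean structure.

A seeded synthetic-data module (`synth_catalog()`, `synth_architecture()`,
`synth_structure_pair()`, `synth_trajectory()`) generates every input with
known planted truth, so the full pipeline runs offline and every statistic
is validated by recovery tests.

## Worked example

```r
library(zfmut)
arch <- ctcf_architecture()   # 11 fingers, N/Z/C = 1-265 / 266-578 / 579-727

# a study-like somatic catalogue: ZF-domain enrichment, 40% inactivating,
# Ts/Tv 1.19 planted
records <- synth_catalog(catalog_spec(
  arch, n = 2000, origin = "somatic",
  multipliers = c(N = 0.63, Z = 1.47, C = 0.65),
  class_mix = c(missense = 0.46, nonsense = 0.21, frameshift = 0.19,
                splice = 0.05, synonymous = 0.05, other = 0.04),
  tstv = 1.19, seed = 1))

domain_enrichment(records, arch)
#>   domain length observed expected  oe_ratio chi_square      p_value
#> 1      N    265      218 335.3508 0.6500656   64.61970 9.084259e-16
#> 2      Z    313      577 396.0935 1.4567266  145.09234 2.050089e-33
#> 3      C    149      125 188.5557 0.6629341   26.94487 2.093426e-07
```

The ZF domain shows O/E ≈ 1.46 (planted 1.47): missense mutations are
~1.5× enriched in the DNA-binding domain relative to its share of the
protein, while both termini are depleted, each with a tiny per-domain
chi-square p-value.

```r
twenty_twenty(records)[c("fraction", "exceeds_rule")]
#> $fraction
#> [1] 0.4
#> $exceeds_rule
#> [1] TRUE

tstv_ratio(records)$ratio
#> [1] 1.201835

map_residue(arch, c(309, 339, 377, 420))
#>   residue_pos domain zf_index helix                 class
#> 1         309      Z        2     4 conserved_hydrophobic
#> 2         339      Z        3     6               key_dna
#> 3         377      Z       NA    NA              inter_zf
#> 4         420      Z        6     2               key_dna
```

40% of records are inactivating (exceeding the 20/20 rule), the Ts/Tv
estimate recovers the planted 1.19 within sampling error, and the residue
mapper places the canonical CTCF mutation sites: L309 at the invariant
hydrophobic +4 of ZF2, R339 at the key base-contacting +6 of ZF3, R377 in
the ZF4/ZF5 linker, G420 at +2 of ZF6.

```r
classify_stability(c(12.05, 6.87, 5.00, 5.64, 1.91))
#>     ddg         label
#> 1 12.05 destabilising
#> ...                      # all five exceed the +0.5 kcal/mol threshold
```

`run_pipeline(run_config("out/"))` writes the whole report bundle
(figure-shaped TSVs plus `summary.json`); `inst/scripts/zfmut.R` is a thin
command-line wrapper around it. See `vignettes/zfmut-methods.Rmd` for the
full methods description.

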