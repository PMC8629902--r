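---
title: "Methods: zinc-finger mutation statistics and ZF-DNA structural metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zinc-finger mutation statistics and ZF-DNA structural metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfmut)
```

## Scope and model

`zfmut` analyses somatic mutation catalogues of tandem C2H2 zinc-finger
(ZF) transcription factors — CTCF, an 11-finger chromatin architectural
protein and haploinsufficient tumour suppressor, is the motivating case —
and complements the catalogue statistics with structural metrics of ZF-DNA
complexes and their dynamics. The package covers four layers:

1. **Catalogue statistics.** HGVS `p.`/`c.` parsing, variant
   classification, recurrence, composition, transition/transversion (Ts/Tv)
   ratios, the 20/20 tumour-suppressor rule, and impact-score comparisons.
2. **Domain grammar and enrichment.** C2H2/C2HC motif detection, the
   DNA-binding helix coordinate system (−6…+6), observed/expected (O/E)
   domain enrichment and positional mutation frequencies, and sequence-logo
   information content in bits.
3. **Structure metrics.** Protein-DNA contact enumeration from PDB
   coordinates, per-finger bond tallies and wild-type/mutant bond diffs,
   ZF-DNA centroid shifts, and threshold classification of folding
   free-energy changes (ΔΔG).
4. **Trajectory metrics.** Kabsch superposition, RMSD time series,
   per-residue RMSF profiles, and paired nonparametric comparison.

A synthetic-data module generates every input the pipeline consumes, so all
stages run and are testable without network access.

## The zinc-finger grammar

Fingers are detected with the motif `C-x(2,4)-C-x(12)-H-x(3,5)-H` (the
C-terminal finger of CTCF is C2HC: the final histidine is a cysteine).
Overlapping candidates are resolved greedily left-to-right with the
shortest spacers; under this motif ties cannot occur. The DNA-binding helix
is numbered −6…−1, +1…+6 (no position 0) over the 12 residues immediately
N-terminal to the first coordinating histidine, so the +6 residue directly
precedes that histidine. Positions −1, +2, +3 and +6 are the key
base-contacting coordinates and +4 carries the invariant hydrophobic
Leu/Met; the remaining Z-domain residues are intra-finger "other" or
inter-finger linker.

The shipped CTCF architecture (`ctcf_architecture()`, config in
`inst/extdata/ctcf_zf_architecture.yaml`) encodes per-finger Cys/His
anchors chosen to reproduce the canonical CTCF residue assignments exactly:
L309 at ZF2 +4, R339 at ZF3 +6, K365 at ZF4 +3, G420 at ZF6 +2, R377 in
the ZF4/ZF5 linker, and H284 as a ZF1 coordinating histidine — these five
mappings are asserted in the test suite. Domain boundaries are N = 1–265,
Z = 266–578, C = 579–727. Boundaries are a config choice with no single
published value; `domain_enrichment_sensitivity()` quantifies how O/E
ratios move as the Z boundaries shift (±10 residues changes the Z-domain
O/E by only a few percent on length-proportional catalogues).

The package does not bundle the real CTCF amino-acid sequence. Operations
that need a sequence (motif detection round trips, alignments, logos) use
`ctcf_synthetic_sequence()`, a clearly labelled synthetic 727-residue
stand-in that carries the architecture's anchors, the invariant +4 Leu/Met
and the canonical residues above over a random Cys/His-free background —
by construction it reproduces the real anchor geometry, while its
non-anchor columns are random. Logo stack heights on this sequence are
therefore illustrative; only the anchored columns (and the analytic IC
ceiling) are scientifically meaningful.

## Catalogue statistics

**Classification.** Every record receives exactly one class from
missense, nonsense, frameshift, synonymous, splice, inframe_indel, other.
"Inactivating" for the 20/20 rule means nonsense + frameshift; splice
variants are excluded by default and can be included with a flag
(`include_splice`), since usage in the field varies. The rule is exceeded
when the inactivating fraction is strictly greater than 0.20.

**Ts/Tv.** Only single-nucleotide substitutions with parseable `c.`
notation enter the ratio; indels, duplications, intronic changes and
records without cDNA notation are excluded and counted separately rather
than erroring. The somatic-vs-SNP comparison is a 2×2 chi-square of
independence without Yates continuity correction (available by flag), so
the statistic equals the textbook Σ(O−E)²/E — a property the tests verify
against a hand-computed oracle on random tables.

**Impact scores.** Scores are consumed (never computed) and compared with
a two-sided Mann-Whitney U test: exact when the smaller group has ≤ 8
observations and no ties, otherwise the normal approximation with tie
correction. The U statistic is cross-checked in tests against brute-force
enumeration of pairwise wins.

## Enrichment

Expected counts are length-proportional: `E_d = n · len_d / L`. Per-domain
significance is a 2-cell goodness-of-fit chi-square (inside vs outside the
domain, df = 1, no continuity correction), two-sided. Raw p-values are
reported, matching common practice for three domains; a Bonferroni flag is
left to the caller via `p.adjust`. Per-finger frequencies use, by default,
mutations assigned to any finger as the denominator (inter-ZF excluded),
with `denominator = "zdomain"` as the alternative since either convention
is defensible. `recover_enrichment()` estimates per-domain rate
multipliers relative to a baseline domain with a percentile bootstrap over
records (default 200 resamples, 95% level).

## Sequence logos

Column information content is `IC = log2(20) − H` with
`H = −Σ p log2 p`, so an invariant column reaches `log2(20) ≈ 4.32` bits.
The WebLogo small-sample adjustment `e_n = (1/ln 2)·19/(2n)` is available
behind a flag and off by default: with n = 11 fingers it subtracts ≈ 1.25
bits from every column, which distorts the familiar ceiling more than it
corrects bias at this scale. Letter heights are frequency × IC, so stack
heights equal the column IC.

## Structure metrics

Contact criteria default to: hydrogen bond — N/O donor-acceptor heavy-atom
distance ≤ 3.5 Å, with a D-H···A angle ≥ 120° enforced only when the
structure contains hydrogens (crystal structures typically do not);
electrostatic — protein cationic nitrogen (Lys NZ, Arg NE/NH1/NH2, His
ND1/NE2) to DNA phosphate oxygen ≤ 4.0 Å; hydrophobic — apolar carbon pair
≤ 4.5 Å (name-based typing; backbone carbonyl and Cα carbons and the Arg
guanidinium carbon are excluded on the protein side, sugar/methyl carbons
count on the DNA side); cation-π — cationic atom to base-ring centroid
≤ 6.0 Å. All cutoffs are configurable via `contact_params()`. When an atom
pair satisfies several categories the precedence is hydrogen_bond >
electrostatic > hydrophobic; cation-π uses ring centroids and never shares
an atom-pair key. Because published bond counts depend on proprietary
interaction criteria, absolute counts from other software are not
reproduction targets here — the package's counts are internally consistent
(tally totals conserve, diffs are antisymmetric, contact sets are
invariant under rigid transforms) and the neighbour search is verified
against a naive all-pairs oracle.

Per-finger tallies assign inter-finger linker residues to the nearest
finger by sequence distance (ties to the N-terminal finger) and also
report them separately, since linker residues such as CTCF R377 affect
both flanking fingers. Centroid distances are mass-weighted heavy-atom
centroids; net shift is `d(variant) − d(reference)`, positive away from
the DNA. ΔΔG values (mutant minus wild type folding free energy) are
inputs; the classification is destabilising above +0.5 kcal/mol,
stabilising below −0.5, neutral between.

## Trajectory metrics

The backbone selection is N, CA, C, O. Superposition is the closed-form
Kabsch solution with a reflection guard (proper rotation, det = +1); the
test suite checks its optimality against a brute-force search over a 10°
rotation grid. RMSD series superpose each frame independently onto the
reference over the selection. RMSF fits all frames to an iterated mean
structure (two passes), because the choice of fitting reference is
otherwise underdetermined; per-residue RMSF is the root mean squared
deviation of the residue's selected atoms about their time means. For
isotropic Gaussian noise of standard deviation σ per coordinate the
expected RMSF is σ√3, which the generator-recovery tests confirm within
5% at 2000 frames. Paired series are compared with the two-sided Wilcoxon
signed-rank test: zero differences dropped, exact null for ≤ 25 non-zero
differences without ties, otherwise the normal approximation with tie
correction (no continuity correction); an all-zero difference vector is
degenerate and reported as p = 1. Quartiles everywhere use the
linear-interpolation convention (R type 7).

## What the synthetic generators emulate — and what they do not

`synth_catalog()` draws residue positions with per-domain rate multipliers
(optionally reshaped by position-class or per-finger weights), apportions
variant classes exactly to the planted mix (largest-remainder), plants the
Ts/Tv ratio as the transition probability `r/(1+r)`, and draws impact
scores from a normal clipped to [0, 1]. Clipping means the observed mean
of a group planted at mean 0.80, SD 0.35 is ≈ 0.74 — the generator
parameters are the published summary moments, and the clipped consequence
is reported as computed rather than re-tuned. Default study-emulation
conditions (used by the pipeline and the acceptance script) are: somatic
multipliers (N, Z, C) = (0.63, 1.47, 0.65) and SNP multipliers
(1.27, 0.48, 1.63) — the reported O/E pattern of the motivating study —
class mix 46/21/19/5/5/4% (missense/nonsense/frameshift/splice/
synonymous/other, i.e. 40% inactivating), somatic Ts/Tv 1.19 vs SNP 2.24,
and impact-score moments 0.80 ± 0.35 vs 0.49 ± 0.44.

What the generators do **not** emulate: trinucleotide mutational
signatures or per-residue mutability (positions are exchangeable within a
domain), linkage between class and position, realistic force fields
(trajectories are reference + i.i.d. Gaussian noise, optionally wrapped in
random rigid motions), or genuine molecular interactions (planted contacts
sit on an artificial lattice sized so that exactly the planted pairs
satisfy the criteria). Passing tests therefore demonstrate that the
statistics are implemented correctly and recover planted truth — not that
real catalogues or real MD trajectories satisfy these models.

## Numerical choices and degenerate inputs

- Chi-square tests never apply continuity corrections unless asked.
- A Ts/Tv ratio with zero transversions is undefined: counts are returned
  with `ratio = NA` and a warning, not an error.
- `superpose()` warns on near-collinear geometry and requires ≥ 3 points.
- Motif detection is deterministic; the greedy scan restarts after each
  accepted motif so fingers never overlap.
- Helix windows that would reach past the second cysteine are truncated
  with a warning rather than silently renumbered.
- All generators are pure functions of (spec, seed); a single integer seed
  drives one documented PRNG stream per generator.

## Problem sizes

The test suite and acceptance script use catalogue sizes of 2000–4000
records (large enough that the planted O/E ratios are recovered within a
few percent), 100 bootstrap/CI replicates for coverage checks, 2000-frame
trajectories for the σ√3 recovery, and 1000 replicates for the type-I
error simulations — sizes chosen so every sampling-based check has
comfortable statistical margin.

## Worked example

```{r example}
arch <- ctcf_architecture()
records <- synth_catalog(catalog_spec(
  arch, n = 2000, origin = "somatic",
  multipliers = c(N = 0.63, Z = 1.47, C = 0.65),
  class_mix = c(missense = 0.46, nonsense = 0.21, frameshift = 0.19,
                splice = 0.05, synonymous = 0.05, other = 0.04),
  tstv = 1.19, seed = 1))
domain_enrichment(records, arch)
twenty_twenty(records)[c("fraction", "exceeds_rule")]
tstv_ratio(records)$ratio
map_residue(arch, c(309, 339, 377, 420))
```

## Known limitations

- The CTCF sequence is synthetic (anchors real, background random); logo
  columns other than the anchored ones carry no biological signal.
- Atom typing for contacts is name-based and covers standard residues
  only; modified bases or non-standard residues are dropped with a note.
- The multi-model PDB reader expects a consistent roster and makes no
  attempt to align differing rosters.
- Absolute contact counts, ΔΔG magnitudes and MD-derived curves from
  other software are out of scope as comparison targets; only metric
  definitions, internal consistency and planted-truth recovery are
  guaranteed.
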