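---
title: "Self-consistency refolding metrics: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-consistency refolding metrics: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refoldr)
```

## The evaluation problem

De novo protein design pipelines screen candidates by *self-consistency*:
a designed sequence is folded by a structure predictor and the model is
compared against the intended target. Two metrics dominate this screen —
the predictor's own confidence (mean pLDDT, 0–100) and the C-alpha RMSD
between model and target after optimal rigid superposition (scRMSD, Å) —
combined into a binary *designability* verdict,

$$\text{designable} \iff \overline{\text{pLDDT}} \ge 70
  \;\wedge\; \text{scRMSD} \le 2.0\,\text{Å},$$

with both comparisons inclusive. `refoldr` implements the metrics, the
verdicts, the experiment designs built on them (mutagenesis panels, MSA
masking, threshold optimization against experimental outcomes,
length/secondary-structure summaries), and a synthetic-data module that
stands in for the GPU folding models so every stage runs at desk scale.

## Superposition and the corrected scRMSD

`kabsch_superpose()` solves the orthogonal Procrustes problem by SVD of the
cross-covariance of the centered coordinate sets; a negative determinant is
corrected by flipping the smallest singular vector, so the transform is
always a proper rotation (proteins are chiral; a reflection could silently
"match" a mirror topology). `rmsd_mean` is the classical root-mean-square
of the per-residue deviations, never the arithmetic mean of distances;
`rmsd_median` is the plain median of those distances. Both are reported
over *all* residues, whatever subset defined the fit.

Full-length predicted models (AlphaFold Database entries in particular)
often include flexible terminal regions absent from the deposited
experimental construct. Such tails adopt a different conformation in every
folding run, and because the Kabsch fit minimizes a global least-squares
cost, a 20-residue divergent tail on a 100-residue protein does not merely
add 20 large deviations — it *tilts the whole fit*, inflating core
deviations as well. `corrected_scrmsd()` addresses this with a single
reject-and-refit cycle:

1. fit all residues; compute deviations $d_i$;
2. outliers: $d_i > \mathrm{median}(d) + 1.5 \cdot \mathrm{MAD}(d)$, with
   the *unscaled* MAD ($\mathrm{median}|d - \mathrm{median}(d)|$, no
   1.4826 consistency factor) and a strict inequality;
3. refit on non-outliers;
4. report the median (default) or mean deviation of the full structure
   under the refit transform.

Outlier residues deliberately re-enter the reported aggregate: the
statistic describes the whole chain, and the median is what makes it
robust to the re-exposed tail deviations. This is why the corrected
*median* rescues tailed designs while the corrected *mean* does not (see
the README benchmark table).

`iterative_outlier_superpose()` repeats the cycle until the outlier set is
stable or `max_iter` is reached; with `max_iter = 1` it is definitionally
the single-pass correction.

Numerical choices worth recording:

* **Outlier threshold floor.** The comparison uses
  $d_i > \mathrm{median} + 1.5\,\mathrm{MAD} + 10^{-9}$ Å. The floor makes
  a constant deviation profile (MAD ≈ 0 up to floating noise, as for two
  identical structures) flag nothing, while a zero-MAD *split* — an exact
  majority at 0 Å and a divergent minority, which arises on the second
  iteration of the iterative variant once the core fits exactly — still
  flags the minority. Without the floor the iterative variant oscillates
  on precisely the structures it exists for.
* **Degenerate fits.** Fewer than 3 surviving residues trigger a fallback
  to the plain fit with a `fallback` flag and a warning; collinear fit
  points are an error.
* **Tie-breaking** never arises in the fit itself (SVD is deterministic up
  to sign conventions handled explicitly).

## Designability analytics

`is_designable()` is inclusive at both boundaries. `select_best_design()`
implements best-of-N selection by minimal naive scRMSD with first-position
tie-breaking, so permuting candidates never changes the selected value.
`length_binned_summary()` uses half-open bins of 25 residues by default —
fine enough to resolve the designability-versus-length decay, coarse
enough to keep per-bin counts stable; it is configurable.
`uniform_length_subset()` draws the same number of records from every
equal-width length bin (the minimum available), giving an exactly flat
length distribution for class-balanced comparisons; it errors on an empty
bin rather than silently producing a skewed subset.
`truncate_to_reference()` uses exact, unique substring matching by
default; a mismatch-tolerant sliding window is available but off, because
exact matching is verifiable and predicted-model sequences are exact by
construction. Eligibility for truncation comparisons uses the strict
window 5 < Δlength < 50.

## Mutagenesis panels

`mutate_sequence()` draws $k = \mathrm{round}(f L)$ distinct positions
(at least 1 when $f > 0$) and substitutes each with one of the 19 *other*
standard residues. Excluding the parent residue makes the realized
mutation load exactly $k$, so sequence identity to the parent is exactly
$1 - k/L$ and the panel's nominal fractions are not diluted by silent
re-draws. Per-replicate seeds derive from a stable string hash of
(master seed, parent id, fraction, replicate), so panels are
bit-reproducible without storing seeds. The canonical layout — 50 parents,
fractions 0.10–0.60 in steps of 0.10, 64 replicates — contains exactly
19,200 sequences.

## MSA masking and Neff

`mask_columns()` replaces homolog characters with `X` at the given query
columns; the query row is preserved by default because structure
predictors require row 1 to spell the exact input sequence (`mask_query =
TRUE` is available where the masked query itself is wanted). Masking is
idempotent and never mutates its input.

`sequence_weights()` assigns each row weight $1/n_i$, where $n_i$ counts
rows (including row $i$) with pairwise identity ≥ 0.8 over mutually
non-gap columns; `median_neff()` sums weights over non-gap rows per
position and takes the median across positions. The 0.8 threshold is the
convention associated with the weighting scheme's source and is
configurable; the query is included in both the weighting and the sums so
a single-sequence alignment has Neff 1 rather than 0, and N identical
rows also give exactly 1.

## Secondary structure

`assign_secondary_structure()` is a simplified 3-state
(helix/strand/coil) assigner: amide hydrogens are placed on N, 1.01 Å
anti-parallel to the preceding C=O (standard practice for H-less files);
a backbone hydrogen bond is declared when the Kabsch–Sander electrostatic
energy $0.084 \cdot 332 (1/d_{ON} + 1/d_{CH} - 1/d_{OH} - 1/d_{CN})$
falls below −0.5 kcal/mol; two consecutive i→i+4 turns make a helix
(minimum run 4, no isolated H), parallel/antiparallel bridge patterns with
|i−j| ≥ 3 make strands, everything else is coil. The 8-state alphabet is
collapsed as G/I/T/S → C and B → E, matching the helix/strand/coil
summaries the analyses need. Chains are split at C-alpha breaks (> 4.5 Å)
before assignment. On real structures this simplified assigner can differ
from full DSSP implementations by a few percent in composition; all
package tests therefore rely on geometric constructions (ideal helices,
lone extended chains) with unambiguous assignments.

## Oracle-performance statistics

`roc_auc()` uses the average-rank Mann–Whitney form: exact half-credit
for ties, exact complement symmetry
($\mathrm{AUC}(y) + \mathrm{AUC}(1-y) = 1$), invariance under monotone
score transforms, and no dependence on sort order. scRMSD enters with
`higher_is_better = FALSE`. `threshold_grid_sweep()` evaluates the
designability predicate as a classifier over pLDDT 50–100 (step 5) ×
scRMSD 0–5 Å (step 0.5) by default — 121 cells; precision is defined as 0
(and the cell flagged) when nothing is predicted positive, F1 as 0 when
precision + recall is 0, so grid corners are well-defined.
`select_optimum()` breaks criterion ties by the most stringent
thresholds, highest pLDDT first, then lowest scRMSD — the confidence bar
is treated as the stricter axis. `fisher_exact_2x2()` sums hypergeometric
point probabilities ≤ that of the observed table (relative tie tolerance
$10^{-12}$). `matched_subset_by_length()` uses a per-bin integer
multiplier $k$ of the case counts, so the control histogram is exactly
proportional to the cases'; fractional global ratios are rounded down
rather than approximated.

## The synthetic-data module

The generator produces every input the pipeline consumes, with the
statistical structure the analyses assume:

* **Backbones** (`make_ideal_backbone`) are built atom by atom (N, CA, C,
  O) from ideal bond geometry and per-state dihedrals (helix −57/−47,
  strand −119/113, coil from a broad seeded distribution), giving CA–CA
  spacings of ~3.8 Å and helices that close the loop with the
  secondary-structure assigner.
* **Compactness.** A chain whose coil dihedrals are drawn independently
  behaves like a stiff polymer: an 80-residue "domain" comes out with a
  radius of gyration near 30 Å (a folded 80-mer has ~12 Å) and 20-residue
  tails reach 27–43 Å (disordered-segment scaling predicts ~11–16 Å).
  Those rod-like objects are not what either a folded core or a floppy
  terminus looks like, and they exaggerate the lever arm of tail motions
  beyond anything the correction is meant to handle. `make_target`
  therefore steers coil dihedrals greedily — candidates are drawn from the
  same coil distribution and the one whose next C-alpha lands closest to
  the running centroid is kept — which restores domain-like extent while
  keeping every bond length and angle ideal. The default core layout
  repeats H10/C5/E5/C5, typical element and loop lengths for small
  globular domains.
* **Predictions** (`simulate_prediction`) displace every residue with
  isotropic Gaussian noise (default σ = 0.5 Å per coordinate, i.e. an
  expected plain scRMSD of √3·σ ≈ 0.87 Å on a tail-free core) and re-pose
  the tails: `hinge` rotates each tail rigidly about its junction by 90°
  around a random axis (an ordered terminus captured in a different
  conformation), `walk` rebuilds it as a 3.8 Å-step random walk (a
  disordered terminus). Confidence is Gaussian per region (core mean 90,
  tail mean 40, sd 3, clipped to [0, 100]) — low-confidence tails, like
  real predictors produce, without modelling the confidence mechanism
  itself. Tail disorder is modelled as conformational divergence, not as
  missing density, because that is the mechanism that inflates scRMSD.
* **MSAs** (`simulate_msa`) apply Binomial(L, divergence) substitutions
  and Binomial(L, gap rate) gaps per row; **outcomes**
  (`simulate_outcomes`) are Bernoulli draws from
  $\mathrm{logit}^{-1}(\alpha + \beta_p \cdot \text{pLDDT} + \beta_s
  \cdot \text{scRMSD})$.

Every generator is bit-reproducible from its seed; a prediction seed can
be varied independently of the target to draw replicate "folding runs".

What passing tests on these data do and do not show: they validate the
*metrics and procedures* — that the correction recovers a planted core
agreement, that AUCs recover planted effects, that counts and weights are
exact. They do not certify behaviour on real folding-model outputs, whose
error modes (confidence miscalibration, register shifts, compact wrong
folds) the generator deliberately does not emulate.

## Problem sizes and defaults

The test-suite and acceptance constructions use the canonical study
conditions: 200 tailed pairs (80-residue core, σ = 0.5 Å, 20-residue tail
hinged 90°, core pLDDT ≈ 90) for the rescue and truncation comparisons;
19,200 sequences for the panel-count check; 100 random 10-point instances
against a quaternion-parameterized numerical optimizer (tolerance
10⁻⁶ Å); 1000 small instances against brute-force AUC pair counting;
every 2×2 table with margins ≤ 10 against exhaustive hypergeometric
enumeration. These sizes keep the full suite under a minute of compute
while leaving the statistical assertions comfortably powered.

## Known limitations

* The PDB reader handles ATOM records of single-conformer, single-chain
  selections; mmCIF, multi-model NMR files and ligands are out of scope.
* The 3-state assigner approximates DSSP; π/3₁₀ helices and PP-II are
  collapsed into coil by design.
* `uniform_length_subset()` implements the exact k-per-bin rule; it does
  not attempt to maximize the subset size under a flatness constraint, so
  published subset sizes built with other maximization rules will not be
  reproduced exactly.
* The outcome simulator is a logistic model on two metrics; real
  experimental success depends on covariates (expression system,
  solubility chemistry) the pipeline does not see.
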