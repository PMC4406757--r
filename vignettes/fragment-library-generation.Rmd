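---
title: "Fragment library generation: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment library generation: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fragment-assembly predictors build protein models by splicing together
short backbone fragments taken from experimentally solved structures.
The fragment library — for every target position, a set of candidate
fragments — is therefore a hard ceiling on model quality: a region whose
true local conformation appears nowhere in the library cannot be
modelled correctly regardless of sampling effort. This package
implements a library generation pipeline whose distinguishing ideas are
(i) variable fragment lengths (6–20 residues) rather than a fixed
nine-mer, (ii) a combination of random and exhaustive candidate
generation, (iii) treating fragment windows differently according to
their predominant *predicted* secondary structure, (iv) ranking by a
predicted torsion-angle score, and (v) strict exclusion of homologs so
that measured precision and coverage reflect a genuine *de novo*
scenario.

## Data model

A template chain is reduced to aligned per-residue views: sequence,
3-state secondary structure (DSSP-reduced when available, otherwise a
torsion-window fallback), a Ramachandran-region string, backbone
torsions, and Cα coordinates. Chain breaks — gaps in residue numbering
or residues lacking complete N/Cα/C atoms — split a chain into
segments, and no fragment window ever spans a segment boundary. Windows
containing non-standard residues (mapped to `X`) are likewise never
extracted.

Positions and windows are 1-based everywhere (R's native convention): a
fragment at position *N* of length *L* covers target residues
*N..N+L−1*, and a position is "modelable" when at least a length-6
window fits.

## The three scores

* **Ramachandran-specific sequence score.** Each fragment residue is
  labelled by one of seven Ramachandran-plot regions, and the
  target/fragment amino-acid pair is scored by a 20×20 log-odds table
  specific to that region, summed over the window. The exact region
  boundaries used by the original environment-specific matrices are not
  published; the package ships a rectangular-box region map
  (`inst/extdata/rama_regions.txt`: core-helical, broad-helical,
  core-strand, broad-strand, polyproline-II, left-handed-helical,
  other) that fully covers the torus, is documented, and is
  user-replaceable — all scoring is parameterized by it. Points on a
  shared box boundary go to the lowest region index, which makes the
  classification deterministic. Because trained environment matrices
  are likewise not published, the default matrix set is seven copies of
  BLOSUM62 (half-bit units); `build_env_matrices()` implements the
  BLOSUM-style construction from environment-labelled columns for users
  with their own training alignments.
* **Secondary-structure score.** +2 per matching letter, −2 per
  mismatch, between the target window's predicted 3-state SS and the
  fragment's assigned SS.
* **Torsion-angle score.** Sum of absolute φ and ψ deviations between
  the target's predicted and the fragment's actual torsions. Deviations
  are *circular* (min(|d|, 360−|d|)): a −179°/+179° pair is physically
  2° apart, and a linear difference would mis-rank such fragments.
  Undefined fragment torsions at segment termini contribute 0, which
  avoids penalizing every fragment's termini identically yet
  arbitrarily.

**Cross-length comparability.** Raw score sums favour short fragments
under the torsion score and long fragments under the SS score, so
ranking a mixed-length pool by raw sums is not meaningful. All three
scores are therefore also exposed per residue (score/L), and ranking
across lengths uses per-residue scores by default; raw-sum ranking
remains available (`per_residue = FALSE`) for strict replication of a
fixed convention.

## Pipeline parameters

| parameter | default | meaning |
|---|---|---|
| `n_random` | 5000 | random draws scored per position |
| `len_range` | 6–20 | fragment length range (residues) |
| `top_k` | 1000 | exhaustive fragments kept per position |
| `lib20_size` | 20 | fragments kept after torsion ranking |
| `pool_size` | 500 | torsion-ranked pool searched by enrichment |
| `enrich_rmsd` | 0.5 Å | strict (<) RMSD threshold for enrichment |
| `threading_cap` | 20 | threading fragments kept per position |
| `homolog_prob` | 99.5% | threading probability flagging a homolog |

The exhaustive stage ranks by the combined per-residue
(sequence + SS) score with equal weights; the source method states the
two components without weights, and equal weighting is the minimal
assumption (weights are configurable through the matrices' scale).

**Per-class acceptance cutoffs.** Random-stage candidates are kept only
if both per-residue scores meet the cutoff for the window's SS class
(majority-α / majority-β / majority-loop / other, by strict majority of
predicted letters; an exact half is "other"). The shipped defaults —
α: (rama ≥ −2, ss ≥ 2), β: (−2, 1), loop: (−2, −1), other: (−2, 1) —
were produced by one `calibrate_cutoffs()` run on three synthetic
mixed-SS training targets (zero-noise predictions, native + 8 decoys,
1000 draws/position, cutoff grids −2..2, good-fragment cutoff 1.0 Å,
coverage floor 0.99): for each class, the cutoff pair maximizing
precision subject to retaining ≥ 99% of the achievable coverage. In
the synthetic conditions the SS score carries most of the signal (the
default sequence matrices are conformation-agnostic), and loop windows
get the most lenient cutoff, consistent with their higher
conformational variability. Published numeric cutoffs for real data do
not exist; users working with real structures should recalibrate on
their own training targets.

**Enrichment pool.** The method description is ambiguous about whether
enrichment searches the 500 top-torsion fragments or the whole merged
library; both are implemented (`enrich_pool = "pool"` (default) or
`"lib3000"`). Fragments of different lengths are compared over their
shared target span, requiring at least 4 overlapping residues — a
shorter overlap makes superposition RMSD nearly meaningless.

**Threading.** Hits at or above the homolog threshold are discarded
outright; surviving hits contribute every nine-residue window of every
gapless aligned block (a gap splits blocks, since a gapped window has no
well-defined backbone correspondence). Fragments are ranked by hit
score, capped at 20 per position, and majority-α positions are emptied
as a post-processing step (threading fragments help β/loop/mixed
positions but degrade helical ones). The order convert → rank/cap →
α-filter follows the description of the α-removal as post-processing.

## Geometry

RMSD is computed over Cα atoms only after optimal superposition
(Kabsch, via SVD with a determinant correction so only proper rotations
are used). Cα-only is the standard convention for fragment quality at
the 0.5–1.5 Å cutoffs involved; whether the original evaluation used
Cα or full backbone is unstated. Torsions follow the standard dihedral
definitions with angles in (−180°, 180°]; the first φ and last ψ of
each segment are undefined.

## The synthetic-fixture generator

`make_ideal_chain()` realizes an H/E/C string as an idealized backbone:
canonical torsions (helix −57/−47, strand −139/135), loop torsions
sampled from a documented permitted set that avoids the helical and
strand Ramachandran regions (so SS classes stay separable), fixed bond
lengths/angles (N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å, ω = 180°) via
the standard internal-to-Cartesian construction. `make_predictions()`
emits PSIPRED-ss2-style and torsion-table files with configurable SS
flip rate and wrapped Gaussian torsion noise; `make_threading_hits()`
emits a valid hit list; `make_fixture_case()` bundles the package's
standard study condition — a 60-residue helix/loop/strand target with
its native planted among 10 decoy templates and zero-noise predictions.

What the fixtures do *not* emulate: real side chains and packing,
irregular secondary structure, correlated prediction errors, sequence–
structure covariation (decoy sequences are random), crystallographic
disorder. Passing tests therefore demonstrate that the pipeline's
mechanics — scoring, filtering, ranking, exclusion rules, determinism —
behave exactly as specified, not that the shipped score parameters are
well-calibrated for real proteins. Idealized geometry also makes decoy
helices mutually identical, so enrichment adds far more fragments per
position in fixtures than the handful per position expected on real
data.

## Numerical choices and degenerate inputs

* All tie-breaks are lexicographic (score, template id, start, length)
  and sampling is driven by a single seed, so identical inputs and
  config give byte-identical library files.
* Random draws are taken with replacement; duplicates collapse at the
  merge stage.
* Near the C-terminus, candidate lengths are truncated so that every
  modelable position receives fragments.
* Fragments whose native window contains missing residues are
  *unevaluable*: excluded from both the precision numerator and
  denominator (with a count reported), never silently scored 0.
  "Good" is strict (`RMSD < cutoff`).
* Colinear backbone geometry yields undefined torsions with a warning,
  never an error; undefined regions use a neutral scoring table.
* Entries without a resolution (synthetic chains) count as 0 Å for the
  resolution filter; greedy identity culling processes chains best
  resolution first so the better-resolved member of an over-identical
  pair survives.

## Problem sizes

The test-suite and the acceptance script run the full default
parameters (5000 draws and top-1000 per position) on the 60-residue
standard case with 10 decoy templates, plus reduced configurations
(hundreds of draws, 3–6 templates) for the many per-stage property
checks; the exhaustive-vs-brute-force equivalence uses a two-template,
≤ 30-residue database where complete enumeration is cheap. These sizes
were chosen so each check isolates one contract of the pipeline while
the whole suite stays desk-scale.

## Known limitations

* The shipped region map and substitution matrices are documented
  stand-ins for unpublished originals; absolute score values are not
  comparable to the original implementation, though every structural
  rule, threshold and count of the pipeline is.
* Exhaustive extraction materializes all candidate scores per length;
  for genuinely large template databases a streaming implementation
  would be needed.
* No mmCIF support beyond what the PDB reader provides; DSSP itself is
  consumed (as a string), not re-implemented.
* Model generation (fragment assembly, decoy scoring) is out of scope:
  the package produces and evaluates libraries.
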