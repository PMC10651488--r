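---
title: "Tissue-scale forces at the implant interface and FBR gene signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-scale forces at the implant interface and FBR gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbrmech)
```

# The scientific problem

The foreign-body response (FBR) encapsulates implanted devices in fibrotic
scar tissue. Mice — the standard preclinical model — mount a far milder FBR
than humans even for chemically identical implants. One candidate
explanation is mechanical: the forces that surrounding tissue exerts on an
implant grow with body size (allometric scaling), so a human implant sits in
a mechanical environment orders of magnitude harsher than the same disc in a
mouse. `fbrmech` provides the computational side of testing that hypothesis:

1. a linear-elastic finite-element model of a layered tissue bed
   (muscle/bone, fat, skin) around a disc implant, under horizontal static
   or vibratory loading, reporting the interface stress `Sx`;
2. a two-group negative-binomial differential-expression pipeline for
   targeted biomarker panels, producing ordered top-k gene signatures (the
   severe "Baker-IV" versus mild "Baker-I" capsular-contracture contrast);
3. a single-cell workflow that scores those signatures across cell clusters
   and tabulates cluster composition by experimental condition;
4. seeded generators for all three input classes, so every stage is testable
   offline.

# The mechanical model

## Geometry and mesh

A domain is a square-footprint stack of tissue layers with a cylindrical
disc implant embedded in one host layer, vertically centred. The bottom face
of the lowest (muscle/bone) layer is fixed; the load acts along the
horizontal x axis. A structured grid is laid over the block — x/y subdivided
at the target edge length, z subdivided within each layer and conforming to
the implant's top and bottom faces — and each hexahedral cell is split into
6 tetrahedra around a fixed corner diagonal. Because the same split is used
in every cell, shared faces conform and the mesh is fully deterministic.
The disc's curved boundary is voxel-approximated (a cell belongs to the
implant when its centre is inside the disc); the region-volume error shrinks
with the edge length and is below 5% at the shipped resolutions, which the
test suite checks.

We use one element family (linear tetrahedra) for tissue *and* implant
rather than hexahedra for the implant: with linear elasticity at converged
resolution the interface stress is insensitive to this choice, and the
mandatory convergence check (`mesh_convergence_check()`) guards it.
"Tie" bonding between implant and tissue is realized by shared nodes on the
conforming mesh — perfect bonding, no contact mechanics.

## Solver

Small-strain isotropic linear elasticity with constant-strain tetrahedra and
exact one-point integration. The global sparse stiffness is assembled from
the per-element blocks `V·BᵀCB`; Dirichlet rows are eliminated and the
reduced SPD system is solved by sparse Cholesky with Jacobi equilibration
and iterative refinement. Equilibration matters: a titanium implant in fat
is a ~3·10⁷ stiffness contrast, where a plain factorization leaves a
relative residual near 1e-5. Convergence is certified by the normwise
backward error ‖r‖/(‖K‖‖u‖+‖f‖) ≤ 1e-8 — the measure that remains
meaningful under extreme conditioning (a raw ‖r‖/‖f‖ criterion is
unattainable in double precision for such contrasts, while the backward
error reaches ~1e-16).

Verification follows the standard FEM canon, all in the test suite: patch
tests (uniform stress states exact to 1e-10), an independent
quadrature-based element oracle, dense brute-force agreement below 300 DOF,
and load-linearity.

## Loads, units, reporting

* `vibration_body_force(a)` = `a · 9.8` N/kg. The gravitational constant is
  fixed at 9.8 m/s² exactly, so a 1.38 g amplitude is 13.524 ≈ 13.5 N/kg.
* Vibration is treated quasi-statically for headline numbers: the peak force
  `m·a·g` (implant + motor mass) is applied as a static horizontal load. An
  undamped harmonic solve `(K − ω²M)u = F` with lumped mass is available as
  an explicit optional mode (`harmonic_steady_state()`); it reduces to the
  static solution at 0 Hz. No damping model is included, so response at the
  driving frequency should be read qualitatively. The quasi-static treatment
  deliberately omits dynamic amplification; the vibrating-implant interface
  stress it reports is the peak-force equivalent, which for a ~2.3 g loaded
  mass is of the same order as the static murine model, far below what a
  resonant or damped-dynamic analysis might produce.
* Geometry is in mm, moduli in Pa, converted to SI internally; displacements
  are metres, stresses Pa, summaries kPa.
* The interface summary takes per-element `Sx` over tissue elements touching
  interface nodes and reports the tensile extremum, the compressive extremum
  (negative), and their absolute maximum. "Maximal stress" is the absolute
  extremum — a reporting rule we fix explicitly because element- versus
  node-sampling and sign conventions are otherwise ambiguous.

## Preset configurations and their provenance

Four shipped YAML presets describe the study conditions: `mouse_standard`,
`mouse_msi` (same disc with a 0.9 g coin motor, 1.38 g / 203 Hz),
`human_breast` and `human_titanium` (identical except the implant material
record). The implant disc is 15.5 mm diameter × 6.7 mm height for the mouse
models. Tissue layer thicknesses and moduli are literature-scale values
(skin O(100 kPa), fat O(1–10 kPa), lumped muscle/bone O(100 kPa)), and the
static species loads are resting-tension magnitudes of order 1e-2 N (mouse)
and 1e2 N (human); each file documents its provenance in comments, every
value is overridable, and none is fitted to any output of this package. The
human/mouse load ratio (~5·10³ at a ~3·10³-fold body-mass ratio) is
consistent with a near-linear allometric scaling of tissue force;
`allometric_force_scale()` exposes the exponent (default 2/3, force ∝
load-bearing cross-section) as an explicit modelling choice because the
allometric literature gives no single canonical value.

With these configurations the models place the murine static interface
stress at ~0.2 kPa and the human models at ~16–20 kPa, a ~90-fold species
gap, with silicone and titanium human variants within ~20% of each other —
the implant's own stiffness matters far less than the species' load scale.
These numbers are recomputed from scratch by `scripts/acceptance.R`.

## Default problem sizes

The shipped edge lengths (1 mm mouse, 5 mm human) give ~48k and ~92k
tetrahedra, solving in seconds to under a minute each; the suite's property
checks run on coarser toys. These resolutions sit past the knee of the
convergence curve for the interface extremum (successive-refinement change
below ~10%); `run_stress()` accepts an `edge_lengths` sweep to reproduce the
convergence report for any configuration.

# The panel differential-expression model

Targeted panels (a ~2,500-gene inflammation/fibrosis biomarker assay, two
groups of 10 samples) are modelled as negative-binomial counts with
variance μ + φμ².

* **Size factors** (`normalize_library_sizes()`): per sample, the trimmed
  mean (25% per tail) of log ratios against the geometric-mean reference
  profile, centred to geometric mean 1; `log(factor)` is the model offset.
* **Dispersion** (`estimate_dispersion()`): per-gene method-of-moments,
  floored at 0, shrunk toward the common (median) value with weight
  `prior_df/(prior_df + n − 2)`, `prior_df = 10`. Simulation shows the
  estimator centred on the truth at panel sample sizes (tests assert the
  Poisson limit and φ = 0.4 recovery).
* **Test** (`nb_two_group_test()`): per-gene NB likelihood-ratio test of one
  shared mean versus one mean per group, dispersion held fixed, referred to
  chi-square(1). This is a fully specified stand-in for edgeR's exact test —
  same model family, reproducible from this description alone; edgeR itself
  serves as an independent cross-check in the test suite, not as the
  implementation.
* **Calibration**: with estimated dispersions and offsets the raw LRT is
  mildly anticonservative in the far tail (a known small-sample effect; the
  field-standard exact test shows a similar, smaller shift on identical
  simulations). We therefore rescale the statistics so their median over
  expressed genes matches the chi-square(1) median — a genomic-control-style
  empirical-null correction, monotone (ranking unchanged), robust while well
  under half the genes are DE, and skipped for panels under 200 expressed
  genes where the median is unstable. After calibration the null type-I
  error at α = 0.05 and the realized FDR of BH at q < 0.05 both sit at their
  nominal levels in the acceptance checks.
* **Multiplicity**: `bh_adjust()` implements the Benjamini–Hochberg step-up
  rule directly and is tested against a brute-force application of the
  definition and against `p.adjust`.
* **Signatures** (`rank_and_signature()`): eligibility is direction of the
  fitted log2 fold change plus unadjusted p < 0.05 (matching how the
  source contrast was reported; q-values are carried alongside), ranked by
  ascending p with ties broken by descending |log2FC| then gene id — a
  deterministic total order. Top-100 and top-25 lists in both directions are
  what `run_de()` writes.

Conventions for degenerate cases: all-zero genes get p = 1 and log2FC = 0; a
pseudo-fraction 0.5/mean(factor) enters both group means so boundary fold
changes are finite.

# The single-cell model

The workflow mirrors the standard droplet scRNA-seq recipe: cells with at
least 200 detected genes (inclusive) and a mitochondrial count fraction
strictly below 10% are kept; counts are scaled to 10,000 per cell and
ln(1+x)-transformed; the mitochondrial fraction is regressed out per gene
(OLS; residuals standardized, zero-variance genes set to 0); PCA scores over
the first 15 components (SVD, signs fixed by making each component's
largest-magnitude loading positive) feed clustering; one-vs-rest markers are
genes passing a natural-log fold-change threshold of 0.25 on de-logged
means, scored by ROC AUC (Mann–Whitney rank statistic, midranks on ties);
signature scores are per-cell arithmetic means of log-normalized expression
over the mapped signature genes; composition tables are row-normalized
cluster-by-condition fractions.

Two deliberate substitutions, both documented as such: graph-based Louvain
clustering is replaced by seeded k-means on the PC embedding (fully
specified, deterministic given the seed, sufficient for planted-structure
recovery — cluster counts of real analyses are *not* reproducible this way
and are out of scope), and mouse–human ortholog mapping defaults to
case-insensitive symbol matching with an explicit two-column table override,
because no single canonical mapping exists. The score is computed on
log-normalized (pre-regression) values — "mean expression" read plainly —
with the regressed matrix available for anyone who prefers the scaled-data
reading.

# The synthetic-data generators

`simulate_panel_counts()` draws NB counts (log-normal baseline means across
~4 decades, log-normal(0, 0.2) library factors) and plants
`round(frac_de·n_genes)` genes at a chosen log2 fold change;
`simulate_umi_matrix()` draws sparse NB UMI counts for several populations
(shared log-normal base profile with population jitter), a mitochondrial
gene block with per-cell fractions from a configurable interval, log-normal
library sizes, and one designated population whose signature genes are
multiplicatively uplifted and which is preferentially sampled from the "MSI"
condition (0.75 versus 0.35). Signature rows are identical across
populations apart from the uplift, and non-signature mass is equalized, so
a zero uplift is an exact null for the signature score. Both generators are
pure functions of (parameters, seed) — bitwise-reproducible, RNG state
restored afterwards.

What they deliberately do not emulate: doublets, ambient RNA, batch
chemistry, gene–gene correlation beyond the population structure, and the
unpublished empirical depth/dispersion profile of the commercial panel
(defaults are stated placeholders). Tests passing on these fixtures
demonstrate the pipeline's statistical machinery, not performance on real
tissue libraries.

# Reproducibility and numerical choices

* Every stochastic entry point takes an explicit seed; `run_*` functions
  write their fully resolved config (with the seed) next to their outputs
  and reject unknown config keys.
* Integer data round-trip bit-identically through every writer/reader pair
  (CSV panel, Matrix Market UMI trio, gene lists).
* Tie-breaks are total orders everywhere a ranking is exposed.
* Degenerate inputs error loudly and specifically: zero-thickness layers, ν
  ≥ 0.5, implants that do not fit, edge lengths that cannot resolve a layer
  (naming the layer), empty post-QC matrices, all-zero samples, p-values
  outside [0, 1], singular or unconstrained systems.

# Known limitations

* Linear elasticity only: no hyperelasticity, contact, friction, damping or
  transient dynamics; vibrating loads are quasi-static peaks, so any
  resonant amplification of the real vibrating implant is not captured —
  the reported vibrating-implant stress is a lower bound of that family of
  models.
* Preset tissue parameters are literature-scale configuration inputs, not
  fitted quantities; absolute stress values inherit their uncertainty, while
  the species *hierarchy* (the package's main mechanical claim) is driven by
  the configured load scales and is robust to it.
* The DE stand-in reproduces the model family and decision rules of the
  panel analysis, not byte-level output of any external tool's pipeline.
* k-means on PCs recovers planted structure; it is not a substitute for
  graph clustering when the number or shape of real subpopulations matters.
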