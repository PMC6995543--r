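---
title: "Early-stage structural codes, fuzzy-oil-drop compliance, and the tetrapeptide screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early-stage structural codes, fuzzy-oil-drop compliance, and the tetrapeptide screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earlyfold)
```

## The model

`earlyfold` connects two stages of a protein folding model.

**Early stage.** The conformation of the early folding intermediate is
assumed to be decided by backbone preferences alone. Geometrically, the
"relaxed" backbone states — those whose pentapeptide radius of curvature
*R* follows the idealised quadratic trend of ln *R* against the aperture
angle *V* between adjacent peptide-bond planes — arrange themselves along
an **elliptical path** on the Ramachandran map. Any observed (φ, ψ) pair is
projected onto that path (nearest point in the Euclidean degree metric),
yielding an "elliptical" pair (φₑ, ψₑ) and a parametric angle *t* ∈
[0, 360), measured clockwise from an anchor point in the lower-right
quadrant. The distribution of *t* over a large domain set is multimodal;
its seven local maxima define the structural alphabet A–G via the integer
interval table

| code | from | to |
|------|------|----|
| A | 0 | 50 |
| B | 51 | 85 |
| C | 86 | 110 |
| D | 111 | 150 |
| E | 151 | 193 |
| F | 194 | 225 |
| G | 226 | 359 |

(inclusive integer bounds partitioning 0..359; a real-valued *t* is binned
by `floor(t)`, so intervals are half-open `[from, to+1)` in real *t*).
Helical conformations fall in C.

**Late stage.** The fuzzy-oil-drop (FOD) model posits that a folded
globular domain buries hydrophobicity like a spherical micelle: the
*theoretical* density *T* is a centric 3D Gaussian evaluated at the
residues' effective positions, the *observed* density *O* aggregates
intrinsic hydrophobicities over pairwise contacts, and the *uniform*
reference *R* is 1/N. With Kullback–Leibler divergences,

$$\mathrm{RD} = \frac{D(O\|T)}{D(O\|T) + D(O\|R)},$$

a domain with RD < 0.5 is *compliant* (closer to the idealised core than
to featureless uniformity). Originally noncompliant domains are *trimmed*:
the residue with the largest |Tᵢ − Oᵢ| is removed and both distributions
are recomputed until RD drops below the threshold; removed residues are
labelled noncompliant, retained ones compliant. Maximal runs of at least 4
equal labels define the fragments that enter the window corpora.

**Screen.** A 4-residue window slides along each encoded chain, emitting
(sequence 4-mer, code 4-mer) pairs into two contingency tables — logical
size 20⁴ = 160,000 sequence columns by 7⁴ = 2,401 code rows — one for
compliant, one for noncompliant fragments. The smaller-total table is
scaled up by the size ratio of the two sets. For a fixed sequence (column
mode) or fixed code 4-mer (row mode) the Pearson correlation *r* between
the two count vectors is tested with the large-sample statistic
z = r√(n−2)/√(1−r²) against 1.96 (two-sided α = 0.05). Sequences with a
significantly *negative* r adopt systematically different early-stage
forms in core-compliant versus noncompliant contexts.

## Parameters that matter

| parameter | default | units | notes |
|-----------|---------|-------|-------|
| RD threshold | 0.5 | — | compliance cutoff; classification is monotone in it |
| minimum run length | 4 | residues | status runs admitted to the window corpora |
| window length | 4 | residues | fixed; defines the 160,000 × 2,401 table |
| α / critical value | 0.05 / 1.96 | — | two-sided large-sample cutoff (`round(qnorm(0.975), 2)`) |
| contact cutoff *c* | 9 | Å | reach of the observed-hydrophobicity kernel |
| Gaussian σ (per axis) | max\|coord\|/3 | Å | three-sigma rule after principal-axis alignment |
| smoothing window | 5 | bins | circular moving average before maxima finding |
| code table | Table above | deg of *t* | replaceable via `code_interval_table(entries)` |

The intrinsic hydrophobicity scale is a required configuration point with
a packaged default (`"kd_normalized"`, the Kyte–Doolittle index min–max
scaled to [0, 1]) documented as a stand-in: FOD results depend only on
relative hydrophobicities, and all tests use the synthetic `"rank"` scale
(0, 1/19, …, 1 over the alphabetically ordered amino acids) so that no
conclusion depends on a published scale.

## The default ellipse

The exact parametric constants of the original elliptical path are not
published, so the package never hard-codes them. Instead the default is
**derived at first use** by `derive_ellipse()` from a seeded synthetic
calibration corpus (`calibration_corpus()`): 36 chains of 40 residues
whose torsions are drawn from basins placed *on* a designed reference path
(center (−40, 30), semi-axes (134, 73)°, tilt −40°) chosen so that the
path crosses the α-helical and β basins and its rightmost point — the
t = 0 anchor — lies in the lower-right quadrant. The derivation mirrors
the real procedure end to end: pentapeptide curvature radii and aperture
angles are pooled, the quadratic ln R–V trend is fitted, windows within the
residual band are kept, and a direct least-squares conic (constrained to
an ellipse) is fitted to their (φ, ψ). On the calibration corpus this
recovers the designed path to a fraction of a degree, and the helical
basin encodes as C. Real-data analyses should derive their own spec from
their own corpus with `derive_ellipse()`.

## Numerical choices

- **Projection** onto the ellipse minimises Euclidean distance in degrees
  on the unwrapped (−180, 180] square (the path is interior to it; inputs
  are wrapped first). The minimiser runs Newton iterations from a 2°
  coarse scan plus 8 evenly spaced starts, tolerance ~1e−13; ties (the
  exact center) break to the smaller *t*. Projections agree with a
  0.001°-resolution dense scan to < 1e−3°.
- **Curvature radius of five CA atoms**: the five points are projected
  onto their best-fit plane (orthogonal to the smallest-variance principal
  axis) followed by a least-squares (Kåsa) circle fit. This recipe is
  exact for points on a circle, recovers the cylinder radius of low-pitch
  helical fragments to < 1%, and returns the `+Inf` sentinel for collinear
  traces. The best-fit-plane choice (rather than any other principal axis)
  is what makes the circle case exact.
- **Aperture angle**: the unsigned angle between consecutive peptide-plane
  normals (each plane spanned by CAᵢ, Cᵢ, Nᵢ₊₁), in [0, 180]; the sign of
  the inter-plane dihedral carries no information here.
- **KL convention**: 0·log(0/q) = 0; divergences are reported in bits, but
  RD is invariant to the base (asserted to 1e−12 in the tests).
- **Trimming tie-break**: the lowest residue index wins at equal
  |T − O| — a determinism requirement. The difference is taken in absolute
  value (`trim_metric`), and both O and T (including the Gaussian
  parameters) are recomputed on the retained subset at every iteration so
  each step is a well-formed FOD evaluation.
- **Observed-hydrophobicity kernel**: the sigmoid contact polynomial
  g(x) = 1 − (7x² − 9x⁴ + 5x⁶ − x⁸)/2 for x = r/c ≤ 1, with the self-term
  included (g(0) = 1). Kernel and cutoff are configuration points.
- **Effective positions** use CA atoms: the package operates on
  backbone-only structures (N, CA, C), where a side-chain centroid is not
  computable.
- **Scaled counts stay real-valued**: re-rounding after the size-ratio
  scaling would break the invariance of Pearson r (and hence of every
  screen verdict) under the scale factor, which the tests assert.
- **Cells entering a correlation**: all 2,401 (column mode) or 160,000
  (row mode) canonical cells including zeros, so that *n* is fixed and the
  1.96 normal cutoff applies; a `cells = "joint_nonzero"` option restricts
  to jointly occupied cells for sensitivity analyses. No multiple-testing
  correction is applied by default, matching the plain α = 0.05 screen.
- **Incomplete residues** (missing N, CA or C) are kept in the structure
  but skipped by every geometry operation; dihedrals, windows and
  effective positions all treat them as undefined.

## What the synthetic generators emulate

- `sample_torsions()` + `build_backbone()`: i.i.d. draws from Gaussian
  Ramachandran basins (wrapped), rebuilt into backbones from ideal bond
  lengths (N–CA 1.458, CA–C 1.525, C–N 1.329 Å) and angles with trans
  peptide bonds. `compute_dihedrals()` recovers the inputs to ≪ 1e−4°,
  which cross-validates both modules.
- `make_fod_case()`: a compact isotropic Gaussian CA cloud (σ = 7 Å,
  n = 60 by default — protein-like density for a small domain) whose amino
  acids are rank-matched to distance from the centroid (compliant),
  anti-matched (anti) or random. At these defaults the two classes fall on
  the correct side of RD = 0.5 in 100% of 50 seeds each.
- `plant_polar_core()`: replaces the k = 12 innermost residues of a
  compliant case with the least hydrophobic letter; this reliably pushes
  RD above 0.5 and the trimming classifier removes (essentially only)
  the planted positions.
- `make_planted_corpus()`: per-tetrapeptide code-profiles drawn from a
  symmetric Dirichlet over the 2,401 code states; null sequences share one
  profile between classes (positive correlation), signal sequences get a
  rank-reversed profile in the noncompliant class, making the population
  correlation strongly negative by construction. Defaults (50 null + 3
  signal sequences, 6,000 multinomial windows per sequence per class) keep
  the count correlation clearly past the n = 2,401 significance boundary
  (|r| ≈ 0.04) after sampling attenuation.

What these generators do **not** emulate: real side chains and their
packing, chain connectivity constraints in the FOD clouds, experimental
artifacts (occupancy, B-factors), sequence composition biases, and the
genuine redundancy structure of a curated domain database. Passing tests
therefore demonstrate the correctness and statistical calibration of the
machinery, not any biological claim about real proteins; the real-data
analogue of the negative-tetrapeptide report requires a full nonredundant
domain corpus, which is out of scope here.

## Problem sizes used by the test-suite

The suite exercises the statistical claims at sizes chosen to make the
checks sharp yet quick: 100 random chains for the build→measure torsion
round trip, 50 seeds per class for FOD separation at n = 60, and 10
seeded corpora (53 sequences × 2 × 6,000 windows each) for the screen's
sensitivity/false-positive assessment. The same sizes are recomputed from
scratch by `scripts/acceptance.R`.

## Known limitations

- The packaged default ellipse is a synthetic calibration product; results
  on real data should use a corpus-derived spec.
- The packaged hydrophobicity default is a normalized stand-in; the FOD
  literature uses several scales and the choice is exposed as
  configuration.
- `read_structure()` handles standard PDB ATOM records (altloc ''/'A',
  insertion codes, common nonstandard residues mapped to parents, others
  to X); mmCIF and database clients are out of scope.
- Trimming labels depend on the chosen trim metric (absolute difference)
  and on recomputing the Gaussian on the retained subset; both are
  documented configuration-level decisions rather than uniquely determined
  by the model.
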