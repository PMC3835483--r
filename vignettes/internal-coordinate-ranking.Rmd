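---
title: "Ranking internal degrees of freedom by eigenvalue-weighted PCA"
author: "icpca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking internal degrees of freedom by eigenvalue-weighted PCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icpca)
```

## The question the package answers

A conformational ensemble — a few hundred snapshots of one molecule from a
molecular-dynamics run or any other sampler — fluctuates in some internal
degrees of freedom far more than in others. Which bonds, bond angles and
torsions carry the thermodynamically relevant motion? And when the same
molecule is simulated under several force-field parameterisations, which of
those soft degrees of freedom are identified independently of the
parameterisation?

`icpca` answers this with internal-coordinate PCA. Internal coordinates are
defined on the molecular graph alone: every bonded pair (a bond length),
every unordered neighbour pair around a central atom (a bond angle,
$\sum_a \binom{\deg a}{2}$ of them), and every proper torsion a–b–c–d around
a central bond b–c. For all-atom cholesterol
(3β-hydroxy-cholest-5-ene, C~27~H~46~O, 74 atoms) this gives exactly 77
bonds, 157 angles and 259 dihedrals — counts the package's built-in fixture
reproduces and its tests pin down. Enumeration is purely graph-based: no
distance thresholds, so the counts cannot drift with geometry.

## The ranking statistic

Each feature kind is measured frame by frame into its own matrix (frames ×
features; Å for bonds, degrees for angles and torsions), so units within a
matrix are homogeneous. After centering, the sample covariance
(denominator $n-1$) is eigendecomposed into eigenvalues
$\lambda_1 \ge \lambda_2 \ge \dots$ and orthonormal loadings $c_{ij}$
(feature $i$ on PC $j$). Two selection rules, both exposed as parameters:

* **PC subset** $J$: the smallest prefix of PCs whose cumulative explained
  variance reaches the threshold (default 0.90). Top eigenvalues of such
  ensembles are often only marginally separated, so a single "top PC" would
  be unstable; a 90% subset is not.
* **Score and top set**: every feature gets
  $S_i = \sum_{j \in J} \lambda_j \, |c_{ij}|$, an eigenvalue-weighted sum
  of absolute loadings, and the top $\lceil 0.10 \times n \rceil$ features
  by $S_i$ form the reported set (default fraction 0.10; the ceiling
  guarantees a non-empty set for any feature count — 8 of 77 bonds, 16 of
  157 angles, 26 of 259 dihedrals).

Absolute loadings make $S_i$ invariant to the arbitrary sign of
eigenvectors; a deterministic sign convention (largest-magnitude entry of
each PC positive) plus index-ascending tie-breaks make the whole ranking
reproducible across platforms. Covariance — not correlation — PCA is the
default because the statistic deliberately weights by fluctuation
magnitude; standardising columns would erase exactly the signal being
ranked. A correlation option exists for exploration.

When several ensembles are ranked over the same feature set,
`compare_rankings()` reports, per feature, which ensembles placed it in
their top set and with what multiplicity. A feature flagged by several
independently parameterised force fields is a parameterisation-independent
soft degree of freedom; the tests check that, for random independent
rankings, multiplicities match the hypergeometric null.

## Circular handling of torsions

Torsions live on a circle, and a column fluctuating around ±180° would show
huge spurious variance if treated linearly. Before centering, each dihedral
column is re-wrapped about its circular mean $\mu$ (direction of the mean
resultant vector) into $(\mu-180°, \mu+180°]$. For a column like
{179°, −179°} this gives {179°, 181°}, centered {−1°, +1°}, sample variance
2 deg² — the branch cut is gone. Columns whose mean resultant length falls
below 0.1 (near-uniform circular spread) are flagged unreliable: for them no
wrap can linearise the geometry and the linear variance is not meaningful.

Degenerate torsions (three collinear defining atoms) are masked per cell,
not raised as errors — one pathological frame must not abort a 250-frame
analysis. Masked cells are imputed with the column's circular mean before
PCA and the imputation is reported; a column degenerate in *every* frame is
an error, since it carries no information at all.

## Mean and representative structures

`superpose()` solves the mass-weighted rigid-body fit (Kabsch, SVD
formulation) with the rotation determinant forced positive: a reflection
can lower the RMSD of a chiral molecule like a sterol, and such a fit would
be meaningless. All atoms, hydrogens included, enter with their masses.
`mean_structure()` fits every frame onto an arbitrarily chosen reference
frame, averages, then re-fits each original frame onto that mean; the frame
with minimum RMSD from the mean is the representative. The single pass
matches the procedure the pipeline emulates; because an arbitrary reference
can bias the mean slightly, an iterative mode (re-fit to the current mean
until it moves < 1e−6 Å) is provided and agrees closely on
well-behaved ensembles. Tests verify the implementation against Horn's
closed-form quaternion solution, an algorithmically independent route.

## The membrane ESP map

For membrane-embedded cholesterol the package maps an electrostatic
potential onto a molecular dot surface with a two-domain continuum picture:
the hydroxyl group and ring positions 2–4 (plus their bonded hydrogens —
10 atoms on the fixture) face the polar head-group region, modelled with a
methanol-like dielectric (ε = 32.6); everything else faces the hydrophobic
core, cyclohexane-like (ε = 2.02). Both constants, the polar seed set and
the hydrogen rule are configurable.

The potential at surface point $p$ tagged with region $R$ is a region-wise
screened Coulomb sum,
$$\phi(p) = \frac{k_C}{\varepsilon_R} \sum_i \frac{q_i}{|p - r_i|},$$
reported in $k_BT/q_{el}$ at 300 K (the temperature of the simulation
protocols this emulates) and clamped to ±5 kT/e for display. With
$k_C = 14.3996$ eV·Å/e² and $k_BT(300\,\mathrm{K}) = 0.025852$ eV, a +1 e
charge seen from 10 Å through ε = 2 gives 27.85 kT/e — the worked value the
tests assert. This is a deliberately transparent stand-in, **not** a
Poisson or boundary-element solver: there is no reaction field and the
dielectric boundary is sharp at the atom tag. Signs and locations of
positive/negative patches are comparable across charge sets; absolute
magnitudes are indicative only. One consequence worth knowing: with a
strongly screened head group, the most negative surface point of a
hydroxyl-polarised charge set sits on a weakly-screened *core* atom on the
hydroxyl side rather than on the oxygen sphere itself; under a uniform
dielectric it sits on the oxygen, as intuition expects.

The dot surface is a Fibonacci lattice per atom at `vdW radius × scale`
(default scale 1.1, "slightly increased" radii; Bondi-style built-in
table), with points buried inside any other atom's scaled sphere removed.
Sampling density (default 5 points/Å² for analysis, lower in the demo
scripts) trades accuracy of surface statistics against runtime linearly.

## Energy summaries

`summarize_energy()` reduces per-frame energy tables to the two headline
ratios: the kinetic vs potential fraction of the total and the
bond/angle/dihedral shares of the bonded sum. Fractions are computed per
frame and then averaged; the denominator is $|E_{kin}| + |E_{pot}|$, which
is robust when a frame's net total approaches zero (frames with
non-positive totals are flagged, and an all-flagged table errors). Two
force-field conventions are encoded explicitly: a Urey–Bradley column (the
auxiliary 1,3-distance term some parameterisations add) is folded into the
angle share before shares are formed, and a missing bond column — the
signature of constraining all bond lengths during dynamics — yields a zero
bond share with an explicit "absent" flag rather than a silent zero. The
"bonded sum" reading of the three-term denominator is a deliberate choice:
bond, angle and dihedral terms are bonded energies, and shares of their sum
are the only scale-free comparison available when nonbonded columns are not
reported.

## What the synthetic generators emulate

No trajectories ship with the package, so generators stand in for them,
with defaults chosen once to mirror the study conditions the pipeline
emulates:

* `generate_feature_matrix()` — 250 frames (one 5 ns sampling at one frame
  per 20 ps) of independent Gaussians: a designated hot subset at
  `sd_hot = 20`, the rest at `sd_cold = 1` (variance ratio 400). This is
  the caricature of a measured internal-coordinate matrix: a few soft
  degrees of freedom over a stiff background. It deliberately omits
  frame-to-frame autocorrelation, inter-feature coupling and anharmonicity;
  recovery results on it show the ranking machinery is correct, not that
  any particular molecule's soft modes are identifiable.
* `generate_chain_ensemble()` — the Cartesian end-to-end check: an
  unbranched chain (bonds 1.53 Å, angles 111°, trans backbone) rebuilt
  frame by frame from internal coordinates, with one torsion oscillating
  sinusoidally (default ±60°) plus 2° Gaussian jitter on all torsions.
  Measurement must return exactly the torsions the builder used (round-trip
  ≤ 1e−6°), and the oscillating torsion must come out top-ranked.
  Sequential placement is restricted to unbranched chains on purpose; a
  full branched Z-matrix rebuild adds nothing to what the test exercises.
* `generate_charges()` and `generate_energy_table()` — minimal patterns
  (neutral, dipole, hydroxyl-polarised; Gaussian energy series about stated
  means) whose analytic consequences the ESP and energy tests assert.

Every generator requires an explicit seed and is a pure function of its
arguments; the same seed gives bit-identical output.

## Numerical choices and degenerate inputs

* Eigenvalues clipped at zero (symmetric eigensolver noise can produce
  −1e−17); the 90% cutoff uses a 1e−12 slack so an exact boundary (ten
  equal eigenvalues, nine needed) is not missed to rounding.
* An all-constant matrix has zero total variance; PC selection refuses it
  ("no variance") rather than returning an arbitrary subset.
* Angles are clamped into [−1, 1] before `acos`; torsion formulas use the
  atan2 form, returning values in (−180°, 180°] with −180° mapped to +180°.
* Collinearity threshold for torsion degeneracy: cross-product norm below
  1e−10.
* Surface points exactly on a neighbouring sphere (the coincident-atom
  limit) are kept; only strictly buried points are removed.
* All file formats are plain text; coordinates are Å everywhere with no
  unit auto-detection, and atom indices are 1-based in every file and
  report.

## Problem sizes in the shipped tests and scripts

The test-suite and the demonstration scripts run the full machinery at
sizes a laptop handles in seconds: 250-frame ensembles, 77–259 features,
100-replicate recovery runs, dot surfaces of 1–3 points/Å². These sizes are
the package's own choice of demonstration scale; nothing in the method
depends on them, and all operations scale as ordinary dense linear algebra
(`O(n_features^3)` for the eigendecomposition).

## Known limitations

* The ESP model is a screened-Coulomb stand-in; do not read magnitudes
  quantitatively near the dielectric boundary.
* The ranking is linear PCA: strongly bimodal torsions (e.g. a two-state
  rotamer) are ranked by their linearised variance, which understates or
  overstates their importance depending on the wrap; the unreliable-column
  flag marks the worst cases but does not fix them.
* Mean structures of highly flexible ensembles can be unphysical (averaged
  Cartesians); the representative frame, not the mean, is the object to
  inspect.
* No significance testing is attached to cross-ensemble overlap beyond the
  hypergeometric diagnostic.
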