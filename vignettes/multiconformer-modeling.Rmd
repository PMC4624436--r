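---
title: "Multiconformer model building: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiconformer model building: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(altconf)
```

This vignette records the model underlying **altconf**, the assumptions it
makes, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the underlying procedure left genuine freedom.

## The model

A crystallographic map is an occupancy-weighted average of discrete
conformations. altconf models each residue as one to `floor(1/t)`
conformers with occupancies `w_i`, chosen to minimize the real-space
residual

$$\min_w \Big\lVert \rho^o - \sum_i w_i \rho_i^c \Big\rVert^2
\quad \text{s.t.} \quad w_i \in \{0\} \cup [t, 1],\; \textstyle\sum_i w_i \le 1,$$

over voxels within a resolution-dependent radius
$r(d) = 0.7 + (d-0.6)/3$ Å for $d < 3$ Å (and $d/2$ beyond) of the
candidate sidechain (Cβ and beyond) and carbonyl-O atoms. The threshold
$t$ plays two roles: it suppresses arbitrarily small occupancies that would
model noise, and together with the unit-sum bound it caps the number of
selected conformers at $\lfloor 1/t \rfloor$. The two constraints combine
into a mixed-integer quadratic program (MIQP) with indicator variables
$z_i \in \{0,1\}$, $t z_i \le w_i \le z_i$.

The candidate pool couples backbone and sidechain freedom:

* **Ellipsoid-guided displacement.** The density-weighted second-moment
  tensor of the positive residual density around the guide atom (Cβ, or the
  backbone O for glycine — the O atom is both electron-rich and furthest
  from the Cα–Cα axis, so it carries the clearest signature of backbone
  heterogeneity) supplies three axes. The guide atom is pushed along
  $\pm \texttt{mc\_ampl}\cdot\sqrt{\lambda_j}\,\hat e_j$, with a uniform
  random addition of up to `jitter`$\cdot\sqrt{\lambda_j}$.
* **Nullspace inverse kinematics.** The 7-residue fragment centered on the
  residue is deformed in the 10 interior φ/ψ dihedrals. Each step solves
  the guide-atom move inside the nullspace of the 9-row anchor Jacobian
  (N, CA, C of the last fragment residue; the first residue sits upstream
  of every free dihedral), followed by a Gauss–Newton correction of the
  second-order anchor drift. Steps that fail to decrease the guide-target
  distance are backtracked, so the distance is non-increasing per
  iteration; anchors move less than 0.01 Å on every accepted candidate.
* **Peptide flips.** Outside helices and strands, the peptide k→k+1 is
  additionally replaced by each of four stereotyped flip geometries mapped
  into the peptide's local frame (x along Cα1→Cα2, y the Gram–Schmidt
  complement of Cα1→O1) by a rigid homogeneous transform. The transform
  moves the flanking Cα atoms slightly (all four geometries carry in-plane
  Cα translations > 0.2 Å), which strains the two junction bonds; a
  six-degree-of-freedom rigid-body relaxation of the peptide unit restores
  the junction bond lengths while staying close to the transformed pose.
  Flip first, then displacement + IK, gives the 5 × 7 = 35 candidate
  backbones per flip-eligible residue.
* **Sidechains.** Small residues (Asn, Asp, Cys, Ile, Leu, Pro, Ser, Thr,
  Val) sample every rotamer with χ offsets over a 40° window in 10° steps
  (the full Cartesian product across χ angles). Large residues (Arg, Glu,
  Gln, His, Lys, Met, Phe, Trp, Tyr) are built one χ level at a time over a
  50° window in 4.5° steps (12 offsets per level), with occupancy selection
  between levels keeping at most `floor(1/t)` survivors — the wider window
  protects conformations that are initially suboptimal but enable better
  fits for later χ angles.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `mc_ampl` | 0.1 / 0.2 / 0.3 (sweep) | mainchain displacement scale, unitless multiplier of √λ |
| `jitter` | 0.05 | uniform random addition to the scale |
| fragment length | 7 residues | IK closure fragment, truncated at chain ends |
| `t` | 0.25 for d < 1.8 Å, 1/3 beyond | minimum conformer occupancy |
| merge tolerance | 0.15 Å all-atom RMSD | conformers closer than this are indistinguishable at typical coordinate precision |
| relabel schedule | 10 000 proposals × 10 trials | downhill Monte-Carlo label swaps |
| grid spacing | d/4 | map sampling used for synthesis and fitting |

The resolution schedule for `t` is a declared default of this
implementation: the threshold is resolution-dependent in principle, but no
canonical values exist, so 0.25 (up to four conformers) at high resolution
and 1/3 (up to three) at lower resolution were fixed once, before any
benchmarking, and are user-overridable.

## Numerical choices

* **Density model.** Atoms contribute 4-Gaussian element form factors plus
  the constant term (folded in as a fifth Gaussian), with the isotropic
  Debye–Waller factor entering as `b_k + B` in each Gaussian width. A width
  floor of 0.1 Å² guards the constant term at B → 0. Contributions are
  truncated beyond 3 + r(d) Å. The lone-atom density integrates to the
  element's electron count within 2% at d/4 sampling.
* **QP/MIQP.** The convex pre-fit (threshold relaxed to 0) is solved by
  Lawson–Hanson active-set NNLS; when the unit-sum constraint is active,
  its Lagrange multiplier is located by bisection, each trial being another
  NNLS solve — exact for this strictly convex problem, and confirmed
  against an independent dual-method QP solver in the tests. The MIQP is
  solved by enumerating every support of size ≤ `floor(1/t)` among the
  pre-fit survivors (truncated to the 30 largest with a warning) and
  solving each small box/simplex-constrained least-squares subproblem by
  complete active-set enumeration, with an interior-point shortcut when the
  unconstrained minimizer is feasible. Ties break toward fewer conformers,
  then lexicographic candidate order, so results are deterministic.
* **Fragment synchronization.** Consecutive backbone multiconformers are
  recombined over the Cartesian product $C_f = \prod_i C_i$ of their
  per-residue conformers, each combined conformation carrying one
  occupancy for all its atoms. Above 1024 combinations a divide-and-conquer
  split at the residue boundary nearest the midpoint fits segments first
  and recombines their survivors.
* **IK parameterization.** ω is held trans; the Jacobian uses analytic
  axis-cross-product columns; the nullspace comes from an SVD with a 1e-8
  relative singular-value cutoff.
* **Degenerate inputs.** Residues with an empty fitting mask, no
  candidates, or a failed selection fall back to the input conformation at
  occupancy 1 and are flagged `degraded` in the report. An all-nonpositive
  density sphere yields an isotropic fallback tensor with a warning.

## The synthetic-data generator

`generate_synthetic_dataset()` emulates the standard validation protocol:
anisotropic B-factors are collapsed to isotropic, every B is inflated by
10 Å² per Å of resolution lost relative to the model's native resolution
(mimicking the general rise of B with resolution), the model is placed in a
comfortably enclosing P1 box, density is computed and band-limited at 1/d,
and zero-mean complex Gaussian noise is added to the structure-factor grid.
"10% noise in complex space" is interpreted as σ = 0.1 × the mean amplitude
over all non-DC structure factors inside the resolution cutoff; a
per-reflection proportional mode (σ_h = 0.1|F_h|) is available behind the
`noise_mode` flag, and the choice is recorded in the returned metadata. A
flat-mask bulk-solvent contribution (k_sol = 0.4, b_sol = 45) is
implemented but disabled by default, because the fragment-scale boxes used
by the benchmark contain no meaningful solvent region.

What the generator does **not** emulate: experimental phase error,
reciprocal-space refinement bias, solvent disorder, lattice disorder, or
model-incompleteness effects. Passing the synthetic benchmark therefore
demonstrates that the sampling reaches the planted conformations and the
MIQP recovers their occupancies under band-limiting and map noise — not
that every experimentally hidden conformation will be found in real maps.

## The benchmark

The fragment-scale benchmark grafts each of the four stereotyped flip
geometries into an idealized 11-residue host loop (irregular φ/ψ so flips
are not suppressed; glycine at the flip's second position, matching the
observed enrichment; one serine to exercise rotamer evaluation) at 70/30
occupancies for the "tweaked down" cluster and 50/50 for the others, across
resolutions 0.9–2.0 Å in 0.1 Å steps — 48 cases. Each case is refit from
the single-conformer major state at mainchain amplitudes 0.1, 0.2 and 0.3,
and a case counts as a success when the flip is recovered at any amplitude,
mirroring how an end user would run a small amplitude sweep and choose
among the models. Truth conformers are generated through the same flip
transform used by the sampler, so the planted state is reachable — the
benchmark isolates selection fidelity from sampling coverage. A four-residue
window around the flip is refit per case, which keeps the 48-case sweep
around ten minutes on one CPU; false-positive rates are reported both per
fitted flip and per evaluated residue, since the aggregation weighting is
not canonical.

Because per-resolution success rates rest on only 4 cases each, the
resolution trend is asserted on half-sweep means (0.9–1.4 Å vs 1.5–2.0 Å)
rather than point-by-point monotonicity.

## Design decisions in brief

* **Omit-map emulation.** Rather than zero-occupancy refinement, the
  fitting target is the observed map minus the calculated density of all
  atoms *not* being rebuilt; this preserves the residual signal the
  selection step needs without a refinement engine. Likewise the
  anisotropic-refinement ellipsoid is replaced by the density second-moment
  tensor.
* **Secondary-structure suppression** of flips uses φ/ψ windows with a
  3-residue run-length filter — the requirement is only that flips not be
  attempted in helices and sheets.
* **Flip centroid geometries.** The four shipped centroids
  (`inst/extdata/flip_centroids_synthetic.txt`) are synthetic stand-ins
  constructed from an ideal trans peptide to satisfy every published
  geometric property of the empirically clustered centroids: rotation
  classes ≈180°, ≈180°, +120°, −120° about the Cα–Cα axis, in-plane
  flanking-Cα translations > 0.2 Å (up to ~0.9 Å for "tweaked down"), and
  detectability by the flip criteria (carbonyls anti, rotation ≥ 90°,
  flanking Cα reconverged < 1.5 Å). Empirical centroid coordinates can be
  dropped in via `load_flip_centroids(path)` without code changes.
* **Flip rotation angle** is defined as the signed angle of O1 about the
  mean Cα→Cα axis after aligning the flanking-Cα midpoints — symmetric in
  its two arguments, which the detector's tests assert.
* **Relabeling** uses heavy atoms only, standard element vdW radii, a 6 Å
  cutoff, and excludes pairs within three bonds; blank-altloc (shared)
  atoms interact with every labeled conformer exactly once.
* **Multiconformer input** is collapsed to its highest-occupancy conformer
  (with a warning) before fitting, since fitting starts from a
  single-conformer model.
* **Proline** is sampled with its library rotamers but χ offsets restricted
  to {−10, 0, +10}° to respect ring closure.
* **Hierarchical survivors** per level are capped at `floor(1/t)`, matching
  the selection cardinality.

## Known limitations

* Output peptide geometry at fragment junctions can be slightly distorted
  (the flip relaxation preserves bond lengths, not angles); a downstream
  refinement engine is expected to regularize final models.
* Space groups other than P1, reciprocal-space refinement, R-factor
  computation, hydrogen placement, and solvent picking are out of scope.
* The exact MIQP enumerator assumes the pre-fit prunes to ≲30 candidates;
  pathological candidate sets with hundreds of near-collinear survivors
  would be truncated (with a warning) rather than solved exactly.
* Reproducing test-set recoveries on deposited crystal structures requires
  user-supplied experimental data and an external refinement engine; only
  the synthetic route is bundled.
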