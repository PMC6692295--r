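---
title: "Models and methods behind filadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind filadyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`filadyn` studies helical pilin filaments at Cα resolution: how a fiber
built from one protomer bends and twists, how ensembles of refined models
differ, how assembly changes per-residue dynamics (¹⁵N relaxation) and
solvent accessibility (HDX-MS). This vignette records the models, the
tunable parameters, the numerical choices, and what the synthetic world
does and does not establish. It states no empirical result that the test
suite does not itself compute.

## Helical assembly

A filament is generated from a protomer by repeated application of a screw
operator: subunit $k$ (0-based) is the protomer rotated by $k\cdot$twist
about $+Z$ and translated by $k\cdot$rise along $+Z$. Conventions we fixed
(the field uses both):

* the filament axis is $+Z$;
* positive twist is counter-clockwise viewed from $+Z$ looking down, and a
  1-start helix with positive twist and positive rise is *right-handed*.

The default synthetic parameters are rise 10 Å and twist 85°/subunit, so
that a 30-subunit fiber is roughly 30 nm long. These are configuration
values, not constants; the refined symmetry of any particular
reconstruction should be supplied by the user.
`consecutive_interface_rmsd()` confirms a construction is exactly
symmetric (every consecutive dimer superposes on the first with RMSD
$<10^{-8}$ Å) and localizes any broken interface.

## Anisotropic network model

Cα atoms closer than a cutoff (default 15 Å) are joined by springs of
uniform constant $\gamma$ (default 1). The Hessian super-element for a
connected pair is $H_{ij} = -(\gamma/d_{ij}^2)\, r_{ij} r_{ij}^{\top}$ and
diagonal blocks enforce translational invariance, so a connected,
non-collinear network has exactly six zero-frequency rigid-body modes.
Because only relative fluctuations are ever compared, $k_BT/\gamma$ is set
to 1 and all mean square fluctuations (MSF,
$\sum_k \lambda_k^{-1}\lvert u_{k,i}\rvert^2$) are in relative units.

Numerical choices:

* **Eigensolver.** Below 1200 coordinates, a dense symmetric
  eigendecomposition; above, shift-invert Lanczos — sparse Cholesky of
  $H + \sigma I$ with $\sigma = 10^{-7}\lambda_{\max}$ (Gershgorin bound)
  and ARPACK on the inverse operator. The test suite checks the two routes
  agree to $10^{-8}$ relative on mid-sized networks. ARPACK's start vector
  is drawn under a fixed local seed so eigenvectors are bit-reproducible.
* **Trivial-mode tolerance.** $\lambda < 10^{-8}\lambda_{\max}$ is
  trivial. This is robust for compact networks; for deliberately floppy
  chains (under-constrained mechanisms) near-zero *mechanism* modes can
  fall below any fixed tolerance — the synthetic fixtures are therefore
  compact by construction.
* **Mode sign** is arbitrary; all comparisons use $|$overlap$|$ and
  squared amplitudes.

### Mode classification

A mode $u$ is labeled by its normalized overlap with analytic deformation
fields built from the coordinates: twist (rotation about $+Z$ with angle
linear in $z$), stretch (axial displacement linear in $z$) and a
four-dimensional bend subspace (transverse displacement along $x$ or $y$
with half- and full-period cosine profiles in $z$, combined in
quadrature). The label is the argmax; below an overlap of 0.5 the mode is
`other`. Two refinements proved necessary in practice and are part of the
design:

* **Rigid-body deflation.** The six rigid-body components are projected
  out of every reference field before normalization. Normal modes are
  exactly orthogonal to rigid motions, so any rigid component left in a
  reference field deflates overlaps for reasons unrelated to mode
  character (a linear twist profile, for instance, contains a large
  uniform-rotation component).
* **Bend profile symmetry.** The first free–free bending mode of an
  elastic rod is *symmetric* about the center (ends and center move in
  opposite transverse directions, two nodes), which is orthogonal to a
  half-cosine (tilt-like, antisymmetric) profile. A half-cosine reference
  alone therefore misses the lowest bend pair entirely; the bend subspace
  includes both profiles so that long-filament bends and tilt-like slice
  bends are both captured. The twist and stretch references keep the
  linear profile: after deflation it is numerically almost parallel
  (overlap 0.99) to the fundamental torsion shape $\cos(\pi s)$.

### Local (slice) analysis

`local_nma()` selects all atoms whose $z$ lies within a margin (default
15 Å) of the central subunit's own $z$-range, mirroring how local
mobility of a lattice position is probed without paying for the whole
fiber. Cutting chains with a flat box leaves small dangling fragments
(a few atoms of a head whose subunit lies mostly outside the box); being
nearly free bodies, they contribute spurious near-zero modes. Subunits
contributing less than 25 % of their atoms (configurable) are therefore
excluded before the Hessian is built. With this hygiene the slice
reproduces the expected short-object mechanics: torsion below bending,
the reverse of the long-fiber ordering.

### Fluctuation-difference regions

Per-position two-sample *t*-tests (Welch by default; the pooled-variance
variant is a flag) between two ensembles of MSF profiles. A position
qualifies when $p < 0.001$ and the absolute difference of means exceeds
$\sigma$, the per-position standard deviation of MSF averaged over
positions and both ensembles (the pooled interpretation; per-ensemble
averaging is an open alternative, and the computed threshold is attached
to the result so the choice is auditable). Maximal runs of at least
$L = 3$ qualifying positions are reported with sign. The identical
machinery with a fixed 0.5 Å effect threshold serves the ensemble ΔRMSD
comparison.

## Ensemble RMSD comparison

Superposition is standard least squares (SVD with determinant
correction). An ensemble profile superposes each model independently onto
the reference over a selection (default: residues 27–130, the window over
which a truncated construct and a full-length model share coordinates) and
records per-residue Cα distances; with `reference = "mean"` the reference
is the coordinate average after two superposition iterations (converges
to $<10^{-3}$ Å on all fixtures). "Average pairwise RMSD" is interpreted
as model-vs-reference averaging; true all-vs-all pairing is available as
`ensemble_pairwise_rmsd()`. When a localized coordinate offset is being
tested for, the superposition selection should exclude the suspect region,
otherwise the fit absorbs part of a coherent displacement — the acceptance
test superposes on the unbiased core for exactly this reason. Whether
profile error bands are across models or positions was unstated upstream;
across models is implemented.

## Model-free relaxation analysis

The spectral density of an N–H vector on an anisotropically tumbling
molecule is the five-term Woessner form
$$J(\omega) = \tfrac25 \sum_{k=1}^5 A_k\!\left[\frac{S^2\tau_k}{1+(\omega\tau_k)^2}
 + \frac{(1-S^2)\tau_k'}{1+(\omega\tau_k')^2}\right],\qquad
 \tau_k'^{-1} = \tau_k^{-1} + \tau_e^{-1},$$
with correlation times and amplitudes determined by the tensor
$(D_x \le D_y \le D_z)$ and the N–H direction cosines in the tensor frame;
$\sum_k A_k = 1$ identically. The amplitude expressions contain
$(D_i - D_{iso})/\sqrt{D_{iso}^2 - L^2}$, which is $0/0$ for an exactly
spherical tensor; relative anisotropy below $10^{-12}$ therefore falls
back to the closed-form isotropic limit $\tau_m = 1/(6D_{iso})$, and the
tests check the two branches agree to machine precision across
orientations. Axially symmetric tensors take the general branch (the
$\tau_3/\tau_4$ degeneracy resolves correctly; verified against the
textbook three-term axial form).

Rates use the standard reduced equations at one field (default 14.1 T)
with conventional constants ($\gamma_H = 2.6752\times10^8$,
$\gamma_N = -2.7126\times10^7$ rad s⁻¹ T⁻¹, $r_{NH} = 1.02$ Å,
$\Delta\sigma = -160$ ppm) — none of these are data-dependent, they are
config defaults so results are reproducible bit for bit.

**Fitting.** Per residue, models m1 (S²), m2 (S², τₑ), m3 (S², R_ex) and
m4 (all three) are fit to the (T1, T2, NOE) triple by error-weighted least
squares: bounded multi-start `nlminb` over a fixed 5×5 start grid, with
τₑ expressed in nanoseconds inside the optimizer (in seconds the parameter
is $10^{10}$-fold smaller than its siblings and line searches stall).
Selection walks the ladder m1 → {m2, m3} → m4 and accepts a more complex
model only when (a) the simpler model shows lack of fit (χ²
goodness-of-fit rejected at 10 %) and (b) the χ² drop exceeds
$\chi^2_{1-\alpha}(\Delta p)$ with $\alpha = 0.20$. With three observables
the classical extra-sum-of-squares F-test has at most one denominator
degree of freedom and essentially no power, and measurement errors are
known, so the likelihood-ratio (χ²-difference) form is the statistically
appropriate one; this is the package's documented reading of an "F-test
ladder". Two-timescale models (m5) are out of scope.

**Tensor estimation** uses rigid residues only (NOE > 0.65 and T2 within
one standard deviation of the 10 %-trimmed mean — a common convention,
configurable, since the upstream filter is unpublished), minimizing the
χ² of observed vs predicted T1/T2 ratios over $(D_x, D_y, D_z)$ (log
scale) and three Euler angles, from a fixed orientation multi-start with
an isotropic warm start. T1/T2 is used because it is insensitive to S² at
fixed tumbling; S² = 0.9, τₑ = 0, R_ex = 0 are held during the fit.

Chemical shift perturbations use the weighted average
$\sqrt{\Delta\delta_H^2 + (0.159\,\Delta\delta_N)^2}$.

## HDX-MS

Per-peptide uptake is modeled as independent first-order exchange of the
peptide's exchangeable amides (all residues except the first and internal
prolines; a "first two" convention is available), scaled by the deuterium
fraction of the labeling mix (buffer/(sample+buffer); 55 µL into 15 µL
gives 78.6 %). No back-exchange correction is applied anywhere, and
relative fractional uptake divides by the theoretical maximum, flagging
(not altering) values above 1.05. The first time point is 0.16 min as
printed (≈10 s).

The two-state comparison fits, per peptide, the fixed-effects linear
model `uptake ~ state * factor(time)` on replicate-level data and Wald
tests (i) the state main effect — a magnitude difference — and (ii) the
state:time interaction — a kinetics difference. The reference tool's
exact mixed model is unpublished; this fixed-effects stand-in reproduces
its decision structure (two p-values per peptide, threshold 0.01) and is
documented as such. The Wald statistic is referred to its finite-sample F
distribution rather than χ²: with triplicates the χ² form is
anticonservative enough to break type-I control at the 1 % level.
P-values are Benjamini–Hochberg adjusted across peptides separately per
test; a peptide is significant if either adjusted p-value is below α.
Classification uses the maximum |ΔRFU| over time among significant
peptides: major > 10 %, minor 5–10 %. Residues inherit the most severe
class among significant covering peptides — an aggregation rule this
package fixes explicitly, since mapping peptides onto residues is
otherwise ambiguous.

## The synthetic world

Every analysis input is generated, deterministically given a seed (RNG
state is saved and restored around every generator):

* **Protomer** (`make_protomer`): an ideal α-helix for residues 1–54
  (rise 1.5 Å/residue, radius 2.3 Å, 100°/residue) parallel to the
  eventual filament axis but offset 6 Å from it, and a compact solenoidal
  stand-in head (radius 8 Å, height 24 Å) centered 22 Å from the axis.
  The head geometry was chosen once so the assembled fiber has pilus-like
  mechanics: diameter ≈ 60 Å (matching real T2SS pseudopili), a buried
  helical core, and a head belt whose inter-subunit coupling is strong
  enough to suppress spurious localized end modes yet soft enough
  torsionally that the collective twist sits below them — the mode
  ordering (bend pair, then twist, amplified at the fiber ends; twist
  lowest for a slice) that elastic-rod mechanics predicts at this aspect
  ratio. A thin hollow head shell at smaller radius instead produces
  end-subunit rocking modes between the bend pair and the twist; that
  geometry was rejected as a poor stand-in for a packed globular domain.
* **Ensembles** (`make_ensemble`): i.i.d. Gaussian per-coordinate noise
  around one model. The upstream perturbation (short MD to diversify
  refinement starts) served only to create spread; matched-RMSD Gaussian
  noise preserves that statistical role. Expected Cα RMSD to the original
  is $\sigma\sqrt3$.
* **Relaxation data** (`make_relaxation_dataset`): forward-modeled
  (T1, T2, NOE) multiplied by $(1+\epsilon)$,
  $\epsilon \sim N(0, f^2)$ with $f$ the fractional noise (default 2 %),
  and quoted errors $f\times$value. N–H vectors come from the protomer
  (a 20° cone around the local chain normal) or can be supplied, e.g.
  uniformly on the sphere for tensor-recovery studies.
* **HDX tables** (`make_hdx_tables` / `make_peptide_map` /
  `default_hdx_truth`): log-uniform per-residue base rates
  (0.05–2 min⁻¹), a slowed region (default ÷20) emulating burial on
  assembly, overlapping peptides of length 5–15 with 100 % coverage and
  ≥1 exchangeable amide each, triplicates at the seven-point time course
  with Gaussian noise (0.05 Da) truncated at zero.

**What a green test establishes — and what it does not.** The synthetic
world has exact helical symmetry, homogeneous springs, Gaussian noise and
a geometrically idealized protomer. Green acceptance tests establish that
the *algorithms* are correct and that the stated statistical criteria
behave as designed (power at the stated effects, type-I control under the
null). They do not establish that any particular experimental fiber has
these mode orderings or uptake patterns, and they cannot reproduce the
upstream study's numeric endpoints (refined-model RMSDs, the fitted
diffusion tensor, per-residue S²/R_ex, real region boundaries), which
depend on unreleased maps and raw spectra.

## Degenerate inputs and tie-breaks

* Bend modes of a symmetric fiber come as near-degenerate pairs; any
  rotation within the pair is a valid eigenbasis, which is why
  classification uses a bend *subspace* and tests compare subspaces, not
  individual vectors.
* Duplicate altlocs keep the first with a warning; insertion codes are
  rejected (not needed for this package's inputs).
* A disconnected elastic network is an error listing component sizes, not
  a silent near-singular solve.
* Identical state tables in the HDX comparison give a state effect of
  exactly zero (p = 1 or undefined when residual variance is zero; NA
  p-values are treated as not significant).

## Known limitations

Cα-only networks (no all-atom or Gaussian-network variants); single-field
relaxation data; no extended (two-timescale) model-free; no multi-start
helices or axial curvature; HDX peptide identification, centroiding and
intrinsic-rate chemistry are out of scope. The CLI is a thin Rscript
wrapper, not a compiled executable.
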