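---
title: "Cortical-column orientation models and MEG source inversion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical-column orientation models and MEG source inversion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

MEG source inversion is usually constrained to a cortical surface mesh, with
each dipole's orientation fixed perpendicular to the local surface — a proxy
for the orientation of cortical columns, whose aligned pyramidal cells
generate the measurable field. Two modeling choices hide inside that
sentence: *which* surface supplies the source locations (pial, white matter,
or both), and *how* the per-vertex orientation is estimated. `megorient`
implements five orientation estimators over paired pial/white surfaces,
a forward/simulation/inversion pipeline to measure how much those choices
matter, and random-effects family-level model comparison to rank them.

# Surfaces and correspondence-preserving decimation

The central data structure is a `surface_pair`: a pial and a white-matter
triangle mesh with identical vertex counts and one identical face list, so
vertex *i* on one surface corresponds anatomically to vertex *i* on the
other. Source inversion works on a decimated version (`decimate_pair()`,
default factor 10). Decimation is greedy edge collapse in which the removed
vertex snaps onto an existing neighbor — vertices are *removed, never
moved*, so decimated coordinates are a bit-exact subset of the originals and
the pial/white correspondence survives; the surviving pial edge structure is
copied to the white mesh. Collapses are prioritized by the symmetric quadric
(point-to-plane) error of standard surface simplifiers, which preserves
shape far better than naive shortest-edge collapse; collapses that would
break the manifold topology, duplicate faces, or flip face normals are
skipped, and all tie-breaks are index-based, so the procedure is
deterministic with no RNG.

Even so, a factor-10 vertex-subset decimation visibly distorts the surviving
faces: on a sphere fixture the decimated-mesh vertex normals deviate from
the radial direction by ~2° on average and up to ~6–10° at the worst vertex.
That bias is not an artifact to engineer away — it is precisely the weakness
of the "downsampled surface normals" estimator that motivates the other
four methods, and the test suite asserts it as a property (mean-level
agreement for the downsampled-normal field, per-vertex agreement for the
estimators that consult the original mesh).

# The five orientation estimators

For a decimated vertex *i* with original-mesh counterpart *r(i)*:

- **Downsampled surface normals** — mean of the unit normals of the faces
  adjacent to *i* in the decimated mesh, renormalized. The common default;
  inherits the decimation bias above.
- **Cortical patch statistics** — mean of the original-mesh vertex normals
  over the 1-ring neighbors of *r(i)*, excluding *r(i)* itself (the
  exclusive reading of "vertices adjacent to"; including the center moves
  results by under 2° on our fixtures).
- **Original surface normals** — the original-mesh vertex normal at *r(i)*.
- **Link vectors** — the unit vector from pial vertex *i* to white vertex
  *i*; a direct geometric stand-in for the cortical column. The white-surface
  field is the exact negation (180° everywhere), which the inversion — being
  covariance-based — cannot distinguish.
- **Variational vector field** — minimizes
  $E(v) = \sum_i [\alpha(1 - v_i \cdot n_i^{pial}) + \alpha(1 - v_i \cdot n_i^{white}) + \beta \sum_{j \in N(i)} (1 - v_i \cdot v_j)]$
  over unit vectors on the *original* mesh by projected gradient descent
  (renormalize after each step, backtracking step halving from 0.1, defaults
  $\alpha = 1$, $\beta = 0.5$, `tol = 1e-8`, `max_iter = 1000`), then samples
  the retained vertices. The functional is this package's concrete choice
  for the two stated pressures — normality to both surfaces and mutual
  parallelism; with $\beta = 0$ it has the closed-form solution
  $v_i \propto n_i^{pial} + n_i^{white}$, which the tests verify. The
  descent is initialized from the *negated* link vectors: the inward link
  direction is exactly antiparallel to both surface normals, a stationary
  saddle of $E$ from which a gradient method cannot escape, and the sign is
  pure bookkeeping for the inversion.

Angular differences use `atan2(||v1 × v2||, v1 · v2)` (stable near 0° and
180°); fields can optionally be folded to [0°, 90°] in reports, off by
default. Perturbed candidate models are built with `rotate_field_on_cone()`:
each vector is rotated by a fixed angle onto a random point of its cone,
azimuths independent and uniform under a recorded seed.

# Forward model

The conductor is the analytic current-dipole-in-a-homogeneous-sphere model,
with the sphere center fitted to the pial vertices by least squares. At the
geometry of the synthetic fixtures (near-spherical anatomy) this coincides
with realistic single-shell models; users with real anatomy can supply an
external gain matrix through the `lead_field` container. Two exact
properties anchor the implementation in the tests: a radial dipole produces
no external field, and the radial component of the external field equals
that of the primary current alone (volume currents contribute none), which
serves as an independent Biot–Savart oracle. Units are fixed throughout:
positions mm, moments nA·m, fields fT. Sensors are point magnetometers or
axial gradiometers (field difference across a baseline along the sensitive
axis). Co-registration error is modeled as one rigid transform of the sensor
array — translation of stated magnitude in a random direction composed with
a rotation about a random axis through the fiducial centroid — the exact
equivalent of perturbing fiducial coils and re-registering; the transform is
re-drawn per simulated source location, seeded.

# Simulation

A patch source is separable in space and time: a geodesic Gaussian weight
profile (FWHM 5 mm, σ = FWHM/2.355, truncated at 3σ; geodesics are
edge-path distances, adequate at these scales and deterministic) times a
Gaussian pulse centered in the epoch ("width" 25 ms read as FWHM, peak
10 nA·m). Per-trial Gaussian white noise is scaled so that the mean over
channels of the per-channel RMS amplitude ratio, in dB, equals the target
per-trial SNR; `measure_snr()` closes the round trip to within 0.1 dB at
every level from −50 to 0 dB. Noise is added per trial and averaged
afterwards, mirroring acquisition. Same seed, bit-identical dataset.

# Inversion and free energy

`reduce_data()` trial-averages the epoch, extracts a 100 ms window (25
samples at 250 Hz) centered on the event of interest, and keeps the top 4
temporal SVD modes; the spatial dimension stays at full channel rank (the
synthetic helmet has no reference channel to project out). The empirical
Bayesian beamformer prior is the printed per-source variance
$\Gamma(i) = [L_i^T (YY^T)^{-1} L_i + \lambda]^{-1} / (L_i^T L_i)$ with
$\lambda = 0$; because the reduced data are low-rank, the pipeline inverts
$YY^T$ by a tolerance-based pseudoinverse (the strict singular-matrix error
remains the standalone default of `ebb_prior()`). A geodesic Gaussian
coherence kernel (FWHM 5 mm, row-normalized) spreads the diagonal prior into
$Q = G\,\mathrm{diag}(\Gamma)\,G^T$.

Two covariance components — sensor noise $Q_\epsilon = I$ and source term
$L Q L^T$ — are mixed by ReML with log-scale hyperparameters, Fisher
scoring with step halving, weak Gaussian hyperpriors (mean −32, precision
$10^{-8} I$), and unit-trace internal scaling for conditioning. Two
conventions needed pinning:

- **The data covariance** is the pooled per-trial covariance of the
  window data projected through the common temporal modes, normalized per
  sample. Using the trial average alone leaves a rank-4 covariance whose
  271 empty directions no noise component can fit, and model comparison
  degenerates into noise-direction chasing.
- **The effective sample count** in the free energy is the number of
  temporal modes (4), not trials × modes: the trials are repeated
  measurements of one evoked response, not independent draws of the model
  covariance. Counting them as independent makes the evidence so sharp that
  even a −50 dB per-trial signal separates all candidate models by tens of
  nats, which contradicts the low-SNR indistinguishability the method is
  known to exhibit. The parameter-recovery test (true mixture 2·I + 3·LQLᵀ
  recovered within 10%) pins the per-sample normalization.

The free energy splits as accuracy − complexity, with accuracy
$-\tfrac{N}{2}\mathrm{tr}(C_Y C^{-1}) - \tfrac{N}{2}\log|C| - \tfrac{N_c N}{2}\log 2\pi$
and, by default, complexity equal to the full Gaussian KL divergence between
the hyperparameter posterior and prior — non-negative by construction, so
the decomposition identity and the complexity sign are invariants. A
`free_energy_convention = "printed"` switch exposes the two-term
$\tfrac12(\hat\lambda-\upsilon)^T\Pi(\hat\lambda-\upsilon) + \tfrac12\log|\Sigma_\lambda \Pi|$
form for comparison; model *differences* are essentially unaffected because
the extra terms vary only weakly across candidate models. $\hat J = Q L^T
(Q_\epsilon + L Q L^T)^{-1} Y$ with the fitted scalings folded in; the peak
vertex maximizes temporal-mode power with index-ordered tie-breaking.

# Model comparison

ΔF against a reference model approximates a log Bayes factor; the
significance convention is |ΔF| > 3 (strictly), i.e. odds of about
exp(3) ≈ 20:1. Family-level inference aggregates member evidence by
log-sum-exp minus log family size (uniform within-family prior, the cited
convention), then samples the hierarchical Dirichlet-multinomial
random-effects model by Gibbs (default 10⁵ draws after 10³ burn-in,
concentration α₀ = 1 per family, seeded). The exceedance probability of a
family is the fraction of posterior draws in which its frequency is the
largest; EPs sum to 1 by construction. For two families a deterministic
quadrature of the exact posterior serves as an independent oracle (agreement
within 0.01 in the tests).

# Synthetic study conditions

The fixtures emulate the recording that the simulations are calibrated to:
a 275-channel axial-gradiometer helmet (Fibonacci coverage of the upper 2/3
sphere cap at 110 mm radius, 50 mm baseline, radial axes), 250 Hz, 251
samples. Anatomy is an icosphere of radius 70 mm (subdivision 4, 2562
vertices) radially displaced by a band-limited random spherical-harmonic
field — defaults RMS 3 mm, maximum degree 8, chosen so the link-vector field
deviates from radial by ~10–20°, enough for folding to matter while keeping
the spherical conductor appropriate — with the white surface 2.5 mm inward
along smoothed normals. A zero-fold-amplitude call yields concentric
spheres, the analytic limit in which all five estimators agree and the tests
verify it.

Two experiments mirror the study design at desk scale: an SNR sweep
(−50…0 dB, zero co-registration error) and a co-registration sweep
(0 mm/0° … 10 mm/10° at 0 dB), each simulating link-vector patches at
random pial vertices and inverting with the link-vector reference model plus
nine models rotated 7°–63° in 7° steps. Desk-scale sizes are 20 locations
and 128 trials on ~256 decimated sources (the full-scale 100/515 values are
plain arguments); with these sizes the full acceptance pipeline runs in
about nine minutes on one core. All randomness fans out from one master
seed via stable string hashing (`derive_seed()`).

# What the synthetic conditions do and do not show

The generator reproduces the *mechanics* of the study — correspondence-
preserving decimation, estimator disagreement under folding, SNR-dependent
distinguishability — but not real cortical geometry. Three consequences are
worth stating plainly:

- Decimated vertex spacing is ~14 mm, so a 5 mm-FWHM patch is effectively a
  single vertex and the coherence prior is nearly diagonal. On a ~3 mm
  real-cortex mesh both are genuinely spatial.
- At 0 dB the evidence resolves orientation-field differences well below
  1°, so only estimators with essentially identical fields earn equal
  evidence; on the sphere fixture the residual decimation bias separates the
  single-surface estimators by tens of nats even though their fields agree
  to ~2°.
- Under large co-registration error (≥ 6 mm/6°) the sparse source grid
  cannot absorb the apparent rigid displacement by relocating sources, and
  rotated-orientation models sometimes compensate the misalignment instead —
  so the co-registration experiment's differentiability threshold degrades
  with error level here, more than it would on a dense cortical mesh. The
  experiment is reported as measured.

# Numerical choices and degenerate inputs

Unit-vector checks at 1e-9; degenerate faces and isolated vertices are
errors naming the offending index; exactly-cancelling vertex normals are
errors; a purely radial patch (invisible to MEG in a spherical conductor)
aborts the simulation with advice to pick another vertex; a decimation
target below 4 vertices is an error, and a stalled decimation (no valid
collapses within ±10% of target) is reported rather than silently accepted.
ReML failure to improve under 12 step-halvings terminates the ascent at the
best-found point; non-convergence of the variational descent is a warning
recorded in provenance, with the current field returned.

# Limitations

No realistic head models (BEM/FEM), no EEG, no oscillatory or multi-patch
simulations, no curved-column (multi-segment) orientation models, and no
alternative inversion schemes — the scope is the orientation/location model
comparison pipeline around the empirical Bayesian beamformer.
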