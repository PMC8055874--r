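---
title: "Image-driven modeling of glioma response to chemoradiation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-driven modeling of glioma response to chemoradiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The modeling problem

High-grade gliomas are infiltrative tumors whose response to concurrent
radiotherapy (RT) and chemotherapy (CT) varies widely across patients.
`gliomaRx` personalizes a family of biologically based tumor growth and
response models from a patient's own longitudinal MRI: diffusion-weighted
imaging supplies a voxelwise cellularity estimate, contrast-enhanced
T1-weighted imaging delimits the enhancing tumor and supplies a perfusion
surrogate, and T2-FLAIR delimits the non-enhancing clinical tumor volume.
Calibrated per patient, the models forecast the spatial distribution of
tumor at future visits.

## Imaging-to-model mappings

The tumor cell volume fraction is estimated from the apparent diffusion
coefficient as

phi(x, t) = (ADC_w − ADC(x, t)) / (ADC_w − ADC_min),

clamped to [0, 1] (an ADC above free water would otherwise produce a
negative fraction). `adc_w` defaults to 3.0e-3 mm^2/s (free water at body
temperature; the literature the mapping descends from cites a reference
rather than a number, so the value is configurable). `adc_min` is the
minimum ADC attributed to maximally packed tissue; whether it should be
per-patient, per-visit, or global is not prescribed anywhere, so the package
default is a fixed configurable value and a per-patient minimum can be
passed explicitly.

Inside the enhancing tumor volume the mapping above initializes the
cellularity; inside the non-enhancing clinical tumor volume a fixed fraction
of 0.16 is assigned (an optional mode replaces the fixed rim value with a
linear decay from the enhancing interface to a configurable periphery
value). Both species of the two-species model therefore start on disjoint
supports. The enhancement ratio ER = T1_post / T1_pre, clamped to [1, 2],
acts as the perfusion surrogate for treatment-efficacy coupling.

# The model family

Forty models arise from crossing

* two base models — a single-species reaction–diffusion equation for phi_T,
  and a two-species system for the enhancing (phi_E) and non-enhancing
  (phi_N) fractions with competitive logistic growth
  `k_pE phi_E (1 − (phi_E + beta_NE phi_N)/theta_E)` and
  `k_pN phi_N (1 − (phi_N + beta_EN phi_E)/theta_N)`;
* ten RT/CT efficacy coupling combinations of four approaches C1–C4
  (C1: efficacy decreases with occupancy phi/theta; C2: SF = SF_min +
  ((1−SF_min)/0.5)(1/ER − 0.5); C3: SF = SF_min + ((1−SF_min)/0.5)(1 − ER/2);
  C4: uniform SF_min). Combinations 1–3 vary RT only, 4–6 vary CT only,
  7–10 apply the same approach to both;
* two proliferation parameterizations — one global rate, or a voxelwise
  rate field on the baseline tumor region.

Note a small analytic point: because 1/ER is convex, C2 lies at or below C3
everywhere on ER in [1, 2] with equality at the endpoints — the reciprocal
coupling treats moderately perfused voxels more aggressively.

Treatment is instantaneous: on each scheduled therapy day,
phi_post = phi_pre · SF_RT · SF_CT voxelwise (both species in the two-species
model). RT and CT efficacies are independent; no synergy term is modeled.
The standard-of-care schedule builder produces 2 Gy weekday fractions for six
weeks (60 Gy), daily concurrent temozolomide across the RT window, and
5-days-per-28-day-cycle adjuvant temozolomide (six cycles by default).

## Mechanical coupling

Tumor expansion is resisted by tissue stress. Each simulation step solves
quasi-static linear elasticity,
`div(G grad u) + grad[G/(1−2 nu)](div u) − lambda2 grad(phi) = 0`,
with literature shear moduli (white 2.7 kPa, gray 3.1 kPa), nu = 0.45 and
lambda2 = 1, and dampens diffusion by the von Mises stress:
`D = D0 exp(−lambda1 sigma_vm)`. Neither the boundary condition nor CSF
mechanics is prescribed by the framework's sources, so the package assumes a
rigid skull (u = 0 outside the brain mask) and gives CSF a small positive
shear modulus (0.1 kPa) to keep the system well posed; both are
configurable.

# Numerical implementation

* **Discretization.** The simulation grid is the imaging grid — isotropic
  in-plane, thick slices, no refinement. Diffusion uses conservative
  flux-form central differences with harmonic face averaging; faces adjoining
  CSF or non-brain voxels carry zero diffusivity, which enforces the no-flux
  boundary and exact mass conservation (verified to ~1e-16 per step).
* **Time stepping.** Explicit forward Euler with
  `dt = min(dt_max, 0.45/(D_max sum(1/h_i^2)))`; `dt_max` defaults to 1 day
  so treatment events resolve to the day. After each step fractions are
  clamped to [0, theta] to guard logistic overshoot. When a dataset will be
  recalibrated, the generator and the calibration should pin the same
  explicit `dt`: letting dt float with the current parameter vector makes the
  step count a discontinuous function of the parameters and corrupts
  finite-difference Jacobians.
* **Elasticity solver.** The operator is assembled once per geometry as a
  symmetric positive definite sparse system (second-order central
  differences; skew-symmetric coupling blocks) and factored by sparse
  Cholesky; every subsequent solve is a pair of triangular solves with
  machine-precision residuals (~1e-15, tighter than any iterative tolerance
  we would set). A `mechanics_stride` re-solves the elasticity every k steps;
  trajectories with stride 5–10 differ from stride 1 by ~1e-4 in volume
  fraction at phantom scale, and the large calibration experiments use
  stride 5–10 for tractability.
* **Treatment efficiency.** For phi-independent couplings (C2–C4) the SF
  fields depend only on the current ER segment and are cached; values at
  phi = 0 voxels are irrelevant because the update is multiplicative.

# Calibration

Free parameters (per-tissue diffusion coefficients, proliferation rate(s),
the enhancing carrying capacity, lambda1, and the two SF minima — theta_N is
fixed at 0.16, beta_NE = 4, beta_EN = 1) are estimated by
Levenberg–Marquardt least squares against the measured cellularity maps.
The baseline visit is always the initial condition; residuals are taken only
at later visits. Scenario 1 calibrates to all follow-ups, scenario 2 to the
1-month visit, scenario 3 to the 1- and 3-month visits, with remaining
visits forecast.

Two residual-design choices deserve notice:

* **Measured total map.** By default (`total_from = "adc"`) the measured
  total cellularity is the ADC mapping applied brain-wide, which on the
  phantom is exactly consistent with the generating model (the ADC is
  synthesized from total cellularity everywhere). The mask-based piecewise
  map (ADC mapping inside the enhancing mask, 0.16 in the non-enhancing
  mask, zero elsewhere) is available as `total_from = "masks"` and is the
  choice one would use on clinical data, where ADC is only trusted inside
  the tumor.
* **Species attribution.** `species_term = TRUE` adds residuals comparing
  simulated phi_E with the measured map on the enhancing mask. This encodes
  the assumption that all cellularity inside the enhancing region belongs to
  the enhancing species; once the non-enhancing species has diffused into
  that region the assumption is violated by the model itself, which shifts
  the SSE minimum away from the generating parameters on phantoms. The
  parameter-recovery experiments therefore run with `species_term = FALSE`
  (totals only), where the minimum is exactly at the truth; species
  parameters remain identifiable through the disjoint initial supports and
  the distinct dynamics.

**Optimizer.** Bounded Levenberg–Marquardt runs in two stages. Stage 1 is a
box-constrained descent (`minpack.lm`); its start is kept strictly inside
the box because a parameter on a bound has a clamped finite-difference
Jacobian column and never moves. Stage 2 restarts from the stage-1 optimum
in a scaled-logistic reparameterization where the bounds are asymptotes;
this frees parameters parked on bounds and lets the optimizer crawl along
weakly identified ridges, most notably the near-collinearity between the
diffusion coefficients and lambda1 (damping rescales D by
exp(−lambda1 sigma_vm), and sigma_vm is small, ~0.05 kPa at phantom scale,
so only the spatial/temporal texture of the stress field separates the two).
The refinement is kept only if it lowers the SSE: started directly from a
distant initial guess the transform is prone to the degenerate
"annihilate-the-tumor" local minimum (kill everything with a very small
surviving fraction; the gradient with respect to every other parameter then
vanishes). Default bounds: D in [0, 1] mm^2/day (recovery experiments use
[0, 0.4] so a pinned dt of 0.5–1 day remains inside the stability region for
every admissible parameter vector), k_p in [0, 0.5] /day, theta in [0.5, 1],
lambda1 in [0, 10] /kPa, SF_min in [0.01, 1]. Stopping: relative SSE change
1e-10, step tolerance 1e-8, 50 + 50 iterations.

**Identifiability at desk scale.** With two follow-up visits (scenario 1)
and no noise, the calibration recovers every generating parameter of the
two-species model exactly (the SSE minimum sits at the truth by
construction; see the phantom section). With 3% ADC noise, proliferation
rates, carrying capacity and the surviving-fraction minima stay within a
few percent, tissue-wise diffusion within ~15-20%, while lambda1 is
noise-dominated (its whole effect on D is a few percent, below the noise
floor) — the overall median error across parameters and replicates is ~8%
at the 32 x 32 x 4 scale. A single 30-day follow-up (scenario 2) is much
weaker: the invasion front moves by roughly one voxel, so the non-enhancing
diffusion coefficients, the carrying capacity, and lambda1 are essentially
unconstrained even though the forecast of the next visit remains accurate.
Expect the same pattern, attenuated, on clinical-resolution data.

**Model selection.** For each candidate the Gaussian-SSE Akaike information
criterion `AIC = n ln(SSE/n) + 2 (k + 1)` (the +1 counts the residual
variance; AICc is a switch) is computed over the calibration residuals, and
the family is ranked by mean AIC across patients, ties broken by parameter
count. Cross-model comparisons use totals-only residuals so every model
sees the same n, and every candidate gets the same Levenberg-Marquardt
iteration budget, chosen large enough that each model reaches (the vicinity
of) its own SSE floor — an under-converged comparison systematically favors
the models with fewer parameters regardless of their adequacy.

# The digital phantom

No patient imaging is distributed with the framework this package
implements, so a generator synthesizes virtual patients with the structure
the pipeline assumes: an ellipsoidal brain (CSF core, gray-matter shell,
white interior) on a 64 x 64 x 8 grid at 1 x 1 x 5 mm; an off-center tumor
with a truncated-quadratic enhancing core (peak fraction 0.8) and a uniform
0.16 rim; visits at 0, 30, 90, 150 days; chemoradiation starting the day
after baseline. ADC is synthesized by inverting the cellularity mapping on
total cellularity (multiplicative Gaussian noise, default s.d. 3%,
approximating Rician noise at moderate SNR); T1 intensities realize a
radially decreasing ER profile (2 at the core to 1 at the rim edge, 2%
intensity noise); masks are thresholded at 0.05 from the noiseless fields.
The enhancing profile is truncated at the mask threshold so that the
baseline masks reproduce the generating initial state exactly.

Ground-truth parameters were chosen once for realism and identifiability
before any recovery experiment was run: D_E = (0.1, 0.05) and
D_N = (0.2, 0.1) mm^2/day in (white, gray) — the non-enhancing component
more invasive; k_pE = 0.05, k_pN = 0.08 /day; theta_E = 0.9;
lambda1 = 5 /kPa (at phantom stress scales this produces ~20% peak damping;
a smaller value would be too weak to estimate); per-event SF minima 0.97
(RT) and 0.99 (CT) — with ~30 RT and ~100 CT events, per-event surviving
fractions far below 1 annihilate the tumor outright, whereas values near 1
produce the partial-response-then-infiltrative-progression course these
models are meant to describe.

What the phantom does **not** emulate: MR physics (coil profiles, Rician
tails, bias fields), anatomy (real tissue geometry, ventricles, sulci),
registration error, segmentation variability, or model misspecification —
the data are generated by a member of the model family itself. Passing
recovery and selection tests therefore demonstrates that the inverse
machinery is correct and well conditioned at imaging scale, not that the
models are adequate for clinical data.

# Problem sizes used by the test suite

The packaged experiments are sized for a single CPU: parameter recovery
runs on the 64 x 64 x 8 phantom with baseline + 1- and 3-month visits
(scenario 1, noiseless, pinned dt = 0.5 day, mechanics stride 20, D bounded
by 0.4 mm^2/day, initial guess twice the generating values clipped into the
bounds); the
noise-robustness and model-selection experiments run on a 32 x 32 x 4
phantom with visits at 0, 30, 90 days — the noise experiment as five
scenario-1 recalibrations at 3% ADC noise, the selection experiment over a
reduced eight-member family ({single, two-species} x combinations
{2, 4, 8, 10} x global proliferation) across five noise seeds with equal
per-model optimization budgets. The methods are identical at every scale;
only grid size, visit count, and iteration caps change.

# Known limitations

* Explicit Euler ties the step to the stability bound; very large diffusion
  bounds inflate run time quadratically with resolution.
* lambda1 is weakly identified whenever the stress field is small or nearly
  proportional to the tumor profile; expect slow ridge convergence and wide
  uncertainty on clinical-quality data.
* The field proliferation mode calibrates a coarse lattice (configurable
  cell size) rather than every voxel; voxels invaded later inherit the
  nearest calibrated rate.
* ER is frozen at the most recent measured visit during simulation — the
  models do not evolve vasculature.
* AIC is computed in its Gaussian-SSE form; residual correlation between
  neighboring voxels is ignored, as is conventional in this literature.
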