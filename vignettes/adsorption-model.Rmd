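---
title: "Modelling nonspecific rAAV adsorption from capsid and surface descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nonspecific rAAV adsorption from capsid and surface descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CapsidAdsorb)
```

## The model

Nonspecific adsorption of rAAV particles onto solid surfaces is treated
as a linear function of physicochemical descriptors of both partners.
The response is the adsorption ratio

$$A\,(\%) = 100 \cdot \frac{\text{titer}_{\text{before}} -
\text{titer}_{\text{after}}}{\text{titer}_{\text{before}}},$$

clamped below at 0% (a negative ratio can only arise from titer
measurement error, so it carries no information about adsorption). The
final model is

$$A = \beta_0 + \beta_1\theta + \beta_2\zeta_{\text{pos}} +
\beta_3\zeta_{\text{neg}} + \beta_4 S_{\text{hydrophobic}} +
\beta_5 S_{\text{hydrophilic}},$$

with $\theta$ the surface contact angle (degrees; hydrophobicity),
$\zeta_{\text{pos}}/\zeta_{\text{neg}}$ the sign-split surface zeta
potential (mV), and $S$ the capsid outer side-chain SASA sums
(Å²) by residue category. Fitting is ordinary least squares with an
intercept; inference uses $t = \beta/\mathrm{se}$ with $n - k - 1$
degrees of freedom. Two nested reductions are kept as named variants —
S1 $\{\theta, \zeta\}$ and S2 $\{\theta, \zeta_{\text{pos}},
\zeta_{\text{neg}}\}$ — because the sign split and the SASA block are the
two scientifically meaningful increments: on any panel where S1's
columns are linear combinations of S2's, $R^2$ is non-decreasing across
S1 → S2 → final, and the test suite asserts this on every simulated
panel.

**Why split the zeta potential.** rAAV capsids are negatively charged
near neutral pH, yet they adsorb both to positively charged surfaces
(global attraction) and to negatively charged ones — behaviour consistent
with localized positive patches on the capsid. A single signed
$\zeta$ forces one slope for both regimes; splitting into
$\zeta_{\text{pos}}$ and $\zeta_{\text{neg}}$ (at most one nonzero per
surface) lets attraction and patch-mediated adsorption carry separate
coefficients. The default *magnitude* encoding stores
$|\zeta|$ in $\zeta_{\text{neg}}$ for negative surfaces; a *signed*
encoding is available as a switch. The two encodings span the same model
space — identical fits and $R^2$, with $\beta_3$ flipping sign — so every
report records which encoding produced its coefficients.

**Standardized coefficients.** To compare drivers across units, all
variables (including the response) are z-scored and the model refit;
equivalently $\beta^{\text{std}}_j = \beta_j \cdot
\mathrm{sd}(x_j)/\mathrm{sd}(y)$. Both routes are implemented and agree
to $10^{-10}$ in the tests; the rescaling identity is what
`standardizedCoefficients()` reports.

## Capsid outer-surface SASA

The SASA descriptor chain answers: *how much hydrophobic and how much
charged side-chain surface does one VP expose on the particle exterior?*

1. **Assembly expansion.** The deposited asymmetric unit is replicated
   by the biological-assembly transforms (REMARK 350 BIOMT, or a
   plain-text transform file for synthetic structures). The capsid
   center is the centroid of the full expanded particle, not of any
   subset — "capsid center" means the particle.
2. **Neighborhood.** SASA of one VP alone would overcount surface buried
   at subunit interfaces, so the reference copy (default: the deposited
   orientation, copy 0) is evaluated together with every copy having a
   heavy atom within a contact cutoff (default 6 Å) of it.
3. **Shrake–Rupley SASA.** Each atom is inflated by the probe radius
   (default 1.4 Å, a water probe) and covered with a deterministic
   golden-spiral point set (default 960 points/atom); a point is
   accessible when outside all neighboring inflated spheres. Van der
   Waals radii are the Bondi element values; hydrogens are absent from
   crystal structures, so the heavy-atom convention applies throughout.
4. **Outer-shell filter and category sums.** Side-chain atoms (heavy
   atoms other than N, CA, C, O, OXT — glycine contributes nothing) of
   the reference copy lying *strictly* farther than the radial threshold
   (default 105 Å, appropriate for the ~26 nm AAV capsid) from the
   capsid center are summed into hydrophobic / acidic / basic
   categories. SER, THR, ASN, GLN, HIS and any non-standard residue are
   unclassified and contribute to no category. Acidic and basic sums are
   strongly correlated across serotypes; when their Pearson $|r|$
   exceeds a threshold (default 0.9) the merge into the single
   hydrophilic variable is reported as justified — the merged variable
   is used by the final model either way, with a message when the
   correlation is weak.

SASA is computed on the **full neighborhood first** and filtered
afterwards, so atoms just inside the shell still occlude atoms outside
it. The alternative (filter before computing) would treat the outer
shell as if the capsid interior were vacuum; computing first matches the
purpose of the filter — selecting exposed atoms, not deleting the
structure beneath them.

### Numerical behaviour and tolerances

- The golden-spiral grid makes results a pure function of the inputs; at
  960 points an isolated sphere is reproduced to well under 0.5% and
  two-sphere cap configurations to under 1% (asserted against closed
  forms in the tests).
- Translation invariance is exact. Rotation re-samples the fixed point
  grid, so per-atom values move at the quadrature level (≲2% at 960
  points, much less in category sums); a claim of $10^{-6}$
  rotation invariance is unattainable for any finite fixed point set and
  is not made.
- Coincident atom centers with identical radii are rejected (the
  configuration is ill-posed for occlusion tests); the caller must
  deduplicate altloc records if they survive parsing.
- "More than the threshold" is strict: an atom at exactly 105 Å is
  excluded.

Absolute SASA values from this engine differ by a few percent from
reduced-surface methods (e.g. MSMS); the contract here is the
descriptor's role in the regression, where such a uniform rescaling is
absorbed by the coefficient.

## Colloidal conversions

Zeta potential from mobility uses the Smoluchowski limit
$\zeta = \mu\eta/(\varepsilon_0\varepsilon_r)$, appropriate when the
particle radius is large against the Debye length (true for ~26 nm
particles in ≥100 mM salt). Net charge uses the Einstein relation
$Q = \mu k_B T/(eD)$ with the measured diffusion coefficient supplying
the friction. This is deliberately the simplest defensible conversion:
no Henry or Ohshima correction is applied, and the operation is isolated
so a corrected variant could be swapped in. Solvent constants default to
water at 25 °C ($\eta = 8.9\times10^{-4}$ Pa·s,
$\varepsilon_r = 78.4$, $T = 298.15$ K) and live in
`solventDefaults()`, never inside the formulas.

## Assay statistics

The clamp is applied **per replicate ratio**, before averaging — the
ratio definition and the 0% rule are statements about a single
measurement. Clamping the mean instead would let a negative replicate
partially cancel positive ones; with the per-replicate rule a negative
replicate simply contributes 0. Replicate summaries use the sample
(n − 1) standard deviation, matching common statistical software.
Group comparisons use the two-tailed unpaired **pooled-variance**
Student's t-test (not Welch's), with stars at p < 0.05 / 0.01 / 0.001;
no multiple-testing correction is applied, since each comparison is
reported individually. Two identical constant groups are reported as
t = 0, p = 1 rather than as an error.

## The synthetic-data generator

`simulatePanel()` emulates a surfactant-free screening campaign:
4 pseudo-serotypes × 3 surfaces × 2 ionic-strength conditions = 24
conditions, triplicate observations. Its defaults are fixed once:

- **Surfaces**: contact angle 90° with ζ −85.9 mV (hydrophobic,
  negative), and two hydrophilic surfaces at 30° with ζ −61.7 mV and
  +37.2 mV — a panel spanning the hydrophobic/hydrophilic and
  negative/positive axes. Zeta at the two ionic conditions is the
  reference value attenuated by screening factors 0.29 and 0.17,
  representing double-layer compression at roughly 200 and 350 mM salt.
- **Generating coefficients** (`defaultBetaTrue()`): intercept 0.41,
  θ 0.32 %/deg, ζ_pos 2.47 %/mV, ζ_neg −0.42 %/mV, S_hydrophobic
  −2.587×10⁻⁴ %/Å², S_hydrophilic 8.661×10⁻⁵ %/Å², on the percent
  response scale — magnitudes shaped like published rAAV adsorption
  fits, labelled clearly as a simulation default rather than truth about
  any real serotype.
- **SASA windows**: hydrophobic 1.0–1.2×10⁵ Å² (nearly constant across
  serotypes, as observed for real capsids), hydrophilic 3.4–5.2×10⁵ Å²
  (the serotype-discriminating axis). The windows are chosen so the
  linear predictor stays inside the observable [0, 100]% window under
  the default surfaces: responses that clamp carry no gradient
  information, so a generator that clamps often would bias coefficient
  recovery. The generator reports its `clampFraction`, and tests keep it
  below 10%.
- **Noise**: i.i.d. Gaussian on the replicate ratio scale, default sd 2
  percentage points, motivated by typical replicate scatter in titer
  assays; replicate titers are back-computed from the ratios around a
  nominal pre-titer of 5.5×10¹⁰ vg/mL so titer-level code paths are
  exercised.
- Acidic/basic components are split near-evenly (fraction
  U(0.48, 0.52)) from the hydrophilic draw, making them strongly
  correlated across serotypes, as for real capsids.

Every generator is a pure function of its spec including the seed; the
caller's RNG stream is saved and restored.

`generateToyCapsid()` builds shells whose per-category outer SASA is
known **analytically**: pseudo-atoms are kept farther apart than
$2(r_{\text{vdW}} + r_{\text{probe}})$, so each atom's SASA is exactly
the isolated-sphere area and category sums are counts × area. Patches of
atoms sit on an outer shell (default 115 Å) and an inner shell (default
60 Å) to exercise the radial filter; copies are placed by rotations to
near-uniform directions with the first transform pinned to the identity.
What the toys do **not** emulate: real capsid packing density (real VPs
touch, toys do not — occlusion correctness is instead tested against
closed forms and monotonicity properties), backbone/side-chain mixtures,
and heteroatom chemistry.

## Problem sizes and design choices in the test suite

The suite runs in well under a minute on one CPU: SASA closed-form and
monotonicity checks use 5–8-atom clusters at 240–960 points; toy capsids
use 6–20 copies of 4–16 atoms; OLS is cross-checked against a
normal-equations oracle on 100 random designs; coefficient recovery uses
the 24-condition panel, with 95% CI coverage estimated over 500 seeded
replicates (accepted within ±4 points of nominal, the Monte-Carlo
resolution of that replicate count); the sampling-spread check compares
empirical coefficient standard deviations over 400 single-replicate
panels against the OLS formula within 10%.

## Known limitations

- The SASA engine is quadrature-based; absolute values differ from
  reduced-surface implementations by a few percent, and per-atom values
  are rotation-stable only to quadrature accuracy.
- The Smoluchowski and Einstein conversions ignore finite-κa and
  relaxation corrections.
- The adsorption model is linear with no interactions or regularization
  by design; it interpolates within the span of surfaces and serotypes
  it was fitted on, and extrapolation (e.g. to extreme pH, where surface
  charge itself shifts) is not covered.
- Validation $R^2$ is reported under both common definitions (squared
  Pearson correlation, and $1 - SS_{\text{res}}/SS_{\text{tot}}$)
  because "measured vs predicted" reports rarely state which was used;
  the default is the Pearson form.
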