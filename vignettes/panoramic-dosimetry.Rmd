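---
title: "Methods: dosimetry of paediatric panoramic radiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosimetry of paediatric panoramic radiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedpanodose)
```

## The problem

Dental panoramic radiography sweeps a narrow, vertically collimated X-ray
beam around the patient's head while the source and receptor rotate. For
paediatric patients the radiological risk per unit dose is higher than for
adults, so the *effective dose* of the examination — the ICRP-103
risk-weighted sum of organ equivalent doses,

$$E = \sum_T w_T H_T,$$

in sieverts — is the quantity of interest. This package implements, for the
head and neck of a 5-year-old, the two standard routes to $E$ and the
analysis that ranks the exposure factors determining it:

1. **Measurement route**: thermoluminescent dosimeter (TLD) chips embedded
   at 16 anatomic sites of an anthropomorphic phantom, processed through
   screening, background subtraction, calibration corrections and
   fraction-irradiated organ integration (`run_tld_pipeline()`).
2. **Simulation route**: Monte Carlo photon transport through a stylized
   voxel phantom with a rotating narrow-beam source
   (`run_simulation()`).
3. **Sensitivity analysis**: a one-factor-at-a-time (OFAT) sweep over the
   seven dose-determining factors, with simple linear regression of $E$ on
   each factor (`sensitivity_analysis()`).

For photons the radiation weighting factor is 1, so absorbed dose in µGy
and equivalent dose in µSv are numerically interchangeable; the package
stores absorbed doses in µGy and converts at the effective-dose boundary.

## The TLD processing chain

Each chip's reader output is processed as

$$D_\text{chip} = \frac{0.8 \cdot \text{raw}}{s_\text{chip}} - \bar{B},$$

where 0.8 corrects for the chips' gamma-energy calibration (LiF chips read
gamma energy about 1.25 times more sensitively than diagnostic X-rays),
$s$ is the per-chip sensitivity from a 5612.7 µGy calibration exposure,
and $\bar B$ is the mean of unexposed background chips corrected the same
way. Chips whose calibration reading deviates more than ±5% from the
sensitivity-scaled reference are screened out. Chips at one site are
averaged within each exposure repeat, and sites are averaged over the
(typically three) repeats.

Design choices where the measurement protocol is under-specified:

* **Stage order.** The gamma correction and sensitivity division are
  applied to exposed *and* background chips before subtraction. This makes
  the result exactly invariant to a constant offset on every raw signal,
  which is the behaviour one wants from a background estimate.
* **Negative net signals** (possible near background) are clamped to zero
  with a warning rather than propagated.
* **Chips per site** is data-driven, not hard-coded, so datasets of any
  layout run through the same code.

### From site doses to organ doses

Site doses are combined into tissue equivalent doses with the packaged
fraction-irradiated table (`tissue_table()`): each sub-region's dose is
the mean over its mapped sites and the tissue dose is
$\sum_i f_i D_i / \max(1, \sum_i f_i)$. The normalization handles the two
regimes the table contains: for bone marrow the sub-region fractions
(calvarium 11.6%, mandibular ramus 1.1%, cervical spine 2.7%) sum to
15.4% and the plain weighted sum applies; for the salivary gland each of
the three gland pairs is fully irradiated, so the printed fractions total
300% and the rule reduces to the mean over glands — the conventional
treatment in site dosimetry.

The **bone surface** dose is obtained from muscle-equivalent chip readings
via the bone/muscle mass energy-absorption coefficient ratio
(`meacr()`),

$$\mathrm{MEACR}(kVp) = -0.0618 \cdot \tfrac{2}{3} kVp + 6.9406,$$

an empirical linear fit valid for 40–120 kVp; outside that range the
function refuses to extrapolate. Two printed variants of this fit differ
in the sign of the slope; the negative form is the default because the
ratio must decrease as photon energy rises (the photoelectric advantage
of bone shrinks), and the positive "footnote" form is available as
`variant = "footnote"` for comparison. Similarly, the default bone rule
applies bone's own sub-region fractions (11.8/1.3/3.4%) before the MEACR
factor; `bone_rule = "marrow_times_meacr"` gives the literal
marrow-dose-times-ratio reading.

### Remainder tissues

ICRP-103 assigns the 14 remainder tissues one collective weight of 0.12 on
their mean dose. Four of them are measured here (extrathoracic airways,
lymph nodes, muscles, oral mucosa). Published site-dosimetry studies are
not explicit about the denominator, so both conventions are implemented:
`"mean_over_14"` (default: the ten unmeasured tissues count as
unirradiated) and `"mean_over_included"` (mean over the four measured
ones). The choice moves $E$ by a factor 14/4 on the remainder term, which
is precisely why both are exposed as options rather than silently fixed.

## The source model

The spectrum is a thin-target Kramers bremsstrahlung form, fluence
$\propto (kVp - E)/E$ per 1-keV bin, truncated at a 5 keV floor (photons
below are locally absorbed) and hardened by aluminum filtration using
packaged attenuation data:
$w_E \mapsto w_E e^{-\mu_\mathrm{Al}(E)\,t}$. Characteristic tungsten
lines and anode self-filtration are deliberately not modelled: the
spectrum serves dose *ratios* and factor *ordering*, not absolute
spectroscopy, and the monotone beam-hardening behaviour the sensitivity
analysis needs is preserved (tested over the full 57–72 kVp sweep range).

Photon histories are normalized to the configured dose-area product
(DAP, mGy·cm²): the packaged air mass energy-absorption coefficients give
the air kerma per source photon at the reference plane, and
`dap_to_history_weight()` scales histories so the configured DAP is
reproduced over the beam area. Organ doses are therefore exactly linear
in DAP (a tested invariant). The default DAP of 60 mGy·cm² is a
representative paediatric panoramic value chosen once from the published
range for such examinations; DAP is machine- and mode-specific and often
unpublished, so absolute doses from the simulator are conditional on this
input and scale linearly with it.

## Beam geometry

Machine geometry enters through seven factors: rotation angle (source arc,
default 240°), vertical angle (default −8°: source below the reference
plane, central ray tilting upward), focus-to-reference distance (FRD,
35 cm), beam width and height at the reference plane (0.20 × 10.00 cm),
filtration (2.8 mmAl) and tube voltage (66 kVp). Beam size can also be
derived from a collimator specification by similar triangles
(`beam_dimensions()`: height = CH·FRD/FCD). Note the printed collimator
values (3.78 cm, 0.09 cm, FCD 13.0 cm) give 10.18 × 0.24 cm at 35 cm
while machine documentation rounds to 10.00 × 0.20 cm; the package accepts
either an explicit beam size or a collimator spec and never reconciles the
two silently.

The source arc (`arc_positions()`) is centred behind the head — the
posterior side, matching panoramic practice, since the start angle is not
part of the machine specification — and sweeps symmetrically. Every
source lies exactly at FRD from the reference point $(0, -3, 47)$ cm (the
centre of the dental arch in the body frame: X left–right, Y
posterior–anterior, Z inferior–superior, origin at the whole-body centre),
and every central ray passes through it, both tested to $10^{-9}$ cm. The
default discretization is one source position per degree with equal
weights; halving the step changes the effective dose only within Monte
Carlo noise (checked at $5\times10^4$ histories).

## The Monte Carlo engine

`build_pediatric_phantom()` constructs a deterministic voxel phantom
(default 0.5 cm voxels) of the head and neck of a 19 kg / 109 cm
5-year-old from quadric shells and cylinders: brain inside a cranial
vault, a horseshoe mandible with mucosal lining, sublingual floor of
mouth, parotid and submandibular glands, cervical spine, oesophagus
segment, thyroid lobes, an extrathoracic-airway block, a fixed 0.4 cm
skin shell, and neck muscle/lymph tissue. Materials are air, soft tissue,
bone and brain-equivalent tissue with nominal densities; organ masses
follow from voxel counts and change by less than 15% when the voxel size
is halved (tested). Resolutions above 1 cm are refused because they
cannot resolve the thinnest organ (the sublingual gland).

Transport (`src/transport.cpp`) uses Woodcock (delta) tracking with the
per-energy majorant over materials — the standard choice for heterogeneous
voxel grids because it avoids ray–voxel boundary bookkeeping. Two
interactions are modelled: photoelectric absorption (full local
deposition) and incoherent Compton scattering with the Klein–Nishina
distribution, sampled by rejection on $\cos\theta$ (the bound
$f \le 2$ makes the rejection exact and simple at diagnostic energies).
The photoelectric probability is taken as the non-Compton remainder of
the total attenuation, which folds the small coherent (Rayleigh)
contribution into the absorbing channel; coherent scattering deflects
without depositing energy, so omitting it slightly shortens photon paths
but leaves dose ordering intact at these energies. Energy transferred at
an interaction is deposited in the interaction voxel (kerma
approximation; no electron transport — secondary electron ranges at
≤ 72 kVp are below the voxel size). Histories end below 5 keV or on grid
exit. Randomness comes from R's own generator, so `set.seed()` (or the
`seed` argument, which is recorded in every result) makes runs
bit-reproducible.

Attenuation data are compact transcriptions of the standard
photon-interaction compilations for aluminum, air, water, soft tissue and
cortical bone over 5–150 keV, interpolated log-log — adequate because the
coefficients are smooth power-law-like functions there.

### Whole-organ doses from a head/neck grid

The simulator tallies whole organs directly — no fraction-irradiated
table on this path. For organs wholly contained in the grid (brain,
thyroid, salivary glands, oral mucosa, extrathoracic airways) the tally
mass is the organ mass and nothing more is needed. Organs that extend
beyond the head and neck (bone marrow, bone, skin, muscle, oesophagus)
are represented only by their head/neck segment, so their whole-organ
dose is the deposited energy divided by the whole-organ mass, i.e. the
segment dose scaled by the head/neck share of the organ (15.4%, 16.5%,
5%, 5%, 10% respectively). This mirrors how whole-body simulation codes
report marrow or skin dose, and it keeps the downstream ICRP weighting
step identical for both routes. Bone marrow and bone surface both take
the tallied bone-region dose: deposition is computed in bone material
with bone cross-sections, so no MEACR conversion is applied on this
path (that ratio corrects muscle-equivalent *measurements*).

The per-organ standard error comes from the per-history deposition
variance and scales as $1/\sqrt{n}$ (tested over $10^3$–$10^5$ histories
on organs hit by most histories; for rarely-hit organs the SE estimate
itself is noisy at small $n$, which is a property of the estimator, not
of the transport).

## Sensitivity analysis

`build_design()` emits one configuration per (factor, level) of the
packaged six-level sweep table with all other factors at baseline.
Configurations identical to the baseline collapse into a single shared
baseline run; each factor's sweep contains the baseline value once, so
seven factors × six levels deduplicate to 36 runs. The filtration sweep's
top level (2.81 mmAl) and the baseline (2.8 mmAl) are two printed forms
of the same setting, so that field uses a 0.011 mmAl dedup tolerance;
all other fields use $10^{-9}$.

`ols()` fits $E$ on each factor's six levels by ordinary least squares
(`stats::lm`), reporting slope, intercept, $R^2$ and the classical
two-sided $t$ p-value with $n-2$ degrees of freedom; no multiple-testing
correction is applied across the seven factors. Degenerate inputs are
handled explicitly: a constant response returns slope 0 and $R^2 = 0$;
an exact line returns the smallest representable positive p-value so
p stays in $(0, 1]$; a constant design is an error.

Because raw regression coefficients carry each factor's units (µSv per
degree, per cm, per mmAl, per kVp), `sensitivity_report()` also reports a
*per-range impact* — coefficient × swept span — which is comparable
across factors, and ranks by its absolute value with ties broken by
factor name. Both views are kept because published tables typically
compare raw coefficients.

The engine is an independent implementation, not a re-creation of any
external simulator's phantom or arc kinematics, and the measured DAP of
the examined machine is not available; simulated *absolute* effective doses
are therefore engine- and DAP-conditional, and only directional/ordering
statements are comparable across engines. Accordingly the packaged tests
check internal consistency (each fitted sign equals the sign of the rank
correlation of its six points) rather than any published coefficient
table.

## The synthetic-data generator

`gen_chip_dataset()` emulates the measurement layout — 16 sites × 3 chips
× 3 repeats + 3 background chips — with
`raw = ((D_site + B)/0.8) \cdot s \cdot (1+\varepsilon)`:
background accumulates in the chip and is read through the same
sensitivity factor, noise is multiplicative Gaussian (TLD reader noise is
roughly proportional to signal; an additive model can be emulated by
scaling), and the ground-truth effective dose is computed by a literal,
separately-written weighted sum of the printed table — not by the
pipeline under test — so round-trip tests compare two independent code
paths. With zero noise the round trip is exact to $10^{-12}$ for any
sensitivity spread; with 5% noise the pipeline estimate is unbiased
(tested over 200 seeds). What the generator does *not* emulate: chip
fading/annealing, energy-response curves beyond the single 0.8 factor,
and spatial dose gradients within a site — so passing round-trip tests
validates the arithmetic chain, not the physical fidelity of TLD
measurement.

`gen_slab_scenario()` provides homogeneous slabs with the Beer–Lambert
closed form $e^{-\mu t}$ as transport oracle, and
`gen_linear_response()` seeded linear data for the regression stage
(slope recovery, unbiasedness, and the 5% type-I error rate of the slope
test are all checked).

## Problem sizes and test design

The test-suite and acceptance-script problem sizes are chosen to make
each statistical check decisive at desk scale: $10^5$ histories for slab
oracles (3 standard errors), $10^3$–$10^5$ for the $1/\sqrt n$ scaling,
$5\times10^4$ per run for geometric containment checks, 200 seeds for
generator calibrations, 2000 replicates for the type-I error band, and
$2\times10^4$ histories per configuration for the 36-run sweep. The
compiled kernel transports about $10^6$ histories per second on one core,
so the whole suite runs in well under a minute of transport time.

## Known limitations

* Stylized quadric anatomy, not CT-derived; organ doses are indicative,
  not patient-specific.
* Fixed rotation centre: the real machine's focal-trough kinematics move
  the pivot during the sweep, which spreads dose differently across the
  arch than a single crossing point does.
* No characteristic X-ray lines, no anode model, no coherent scattering,
  no electron transport.
* Absolute simulated doses are conditional on the DAP input; only the
  measurement route yields machine-calibrated absolute doses.
* The remainder-denominator and bone-rule conventions change $E$ by known
  factors; results should always be reported together with the
  conventions used (every result object carries them).
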