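---
title: "Models and methods behind npwrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind npwrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npwrap)
```

npwrap models how spherical gold nanoparticles (AuNPs, 5–60 nm) interact
with large unilamellar lipid vesicles (LUVs, ~179 nm), and reduces the
instrument readouts such experiments produce. This vignette documents the
models, the parameter choices that matter, the numerical decisions, and the
limits of what the synthetic-data tests demonstrate.

## Elastic wrapping theory

A membrane wraps a particle spontaneously when adhesion beats bending.
The two closed forms are

$$d_c = 2\sqrt{2k/|W|}, \qquad
  d_{c,\sigma} = 2\sqrt{2k/(|W|-\sigma)},$$

with bending modulus $k$ (J), adhesion strength $|W|$ (N/m) and tension
$\sigma$ (N/m). Below $d_c$ a particle adheres unwrapped (bending too
costly); between $d_c$ and $d_{c,\sigma}$ it is partially wrapped; above
$d_{c,\sigma}$ full wrapping is allowed. Assumptions: spherical rigid
particles, fluid membrane described by bending + tension only, no
electrostatic or entropic corrections.

Two choices were genuinely open:

* **Grouping of the tension radical.** The second critical diameter is
  implemented as $2\sqrt{2k/(|W|-\sigma)}$: this is the only grouping that
  is dimensionally consistent, recovers $d_c$ at $\sigma = 0$, and grows
  with $\sigma$ (diverging at $\sigma = |W|$, where tension fully offsets
  adhesion). It is fixed and will not be silently changed.
* **Default bending modulus.** `membrane_spec()` defaults to
  $k = 8.4\times10^{-20}$ J ≈ 20 $k_BT$ at 298 K, the canonical value for
  fluid phosphatidylcholine bilayers. With the bare-gold adhesion
  $|W| = 42$ mN/m this puts $d_c$ at 4 nm. $k$ is an explicit parameter,
  not a constant.

The curvature-corrected contact energy
$w(a) = -k_w + m/a - 2\kappa_{\mathrm{SLB}}/a^2$ takes the **wrap radius**
$a$ = nominal particle radius + `wrap_margin` (default 2 nm, half the 4 nm
bilayer): a sphere-plus-half-bilayer wrap is the geometrically consistent
reading. $k_w$, $m$ and $\kappa_{\mathrm{SLB}}$ are fitted,
surface-specific constants and ship without defaults; the *adhesion*
critical diameter returned by `adhesion_critical_diameter()` is twice the
larger root of $k_w a^2 - m a + 2\kappa_{\mathrm{SLB}} = 0$, i.e. a wrap
diameter (documented as such), and is 0 whenever the discriminant is
negative — the bare-gold case.

All lengths cross the interface in nm; conversion to SI happens once,
internally.

## The engulfment lockout model

The lockout criterion — engulfment stops when membrane tension reaches a
maximum — is implemented as an **isoperimetric area-strain surrogate**, and
this deserves prominence: the surrogate is *calibrated, not derived* from a
tension theory. Each engulfed particle removes wrap area
$\Delta A = 4\pi a^2$ and, in the default impermeable-volume mode, adds
$\Delta V = \tfrac{4}{3}\pi a^3$ to the enclosed volume. Feasibility of $n$
engulfments requires

$$(36\pi)^{1/3}\,(V_0 + n\,\Delta V)^{2/3}
  \le (1+\varepsilon_{\max})\,(A_0 - n\,\Delta A),$$

the left side being the minimal (spherical) area able to enclose the
volume. A spherical vesicle starts exactly on the bound, so the required
strain at $n=0$ is 0 to machine precision.

* `max_area_strain` defaults to $\varepsilon_{\max} = 0.0133$. The
  admissible window in which a 179 nm vesicle simultaneously holds exactly
  two 10 nm particles *and* has a 15 nm single-engulfment limit is
  (0.01303, 0.01358) — verified against a direct high-precision evaluation
  of the bound; 0.0133 sits mid-window and is physically sensible, ~1.3%
  areal strain being within the accepted lysis range of fluid PC bilayers.
* Impermeable volume is the default because engulfment is fast relative to
  osmotic equilibration; `water_permeable = TRUE` drops the volume
  increment for slow processes where water crosses the membrane, and can
  only increase capacity.
* `max_engulfable_diameter()` scans an integer nm grid, matching how such
  limits are quoted.

The surrogate ignores the bending-energy contribution to lockout and all
engulfment dynamics (including cooperative tube formation, which it cannot
represent).

## Dosimetry

Lipids per vesicle count both leaflets, the inner one offset by the
bilayer thickness $h$:
$N_\mathrm{tot} = 4\pi[(d/2)^2 + (d/2-h)^2]/a_\mathrm{lipid}$, with
$a_\mathrm{lipid} = 71$ Å² for DOPC/POPC (the "71 Å" often quoted for
these lipids is an area). The default molar mass is 773.1 g/mol, the mean
of DOPC (786.1) and POPC (760.1); per-lipid values are selectable.

`liposomes_per_ml()` exposes a **unit convention** because the standard
equation $N_\mathrm{lip} = M_\mathrm{lipid}\cdot N_A/(N_\mathrm{tot}\cdot
1000)$ is ambiguous in the unit of $M_\mathrm{lipid}$. With the molar
amount per millilitre (`convention = "published"`, the default) a
2.5 mg/mL, 179 nm preparation gives $7.18\times10^{9}$ liposomes/mL — the
convention under which the value is cross-validated by orthogonal particle
counting (multi-angle DLS $5.03\times10^9$/mL, calcein assay
$2.42\times10^9$/mL). The strict mol/L reading (`"dimensional"`) evaluates
exactly 1000-fold higher. Only ratios of surface areas enter the ITC
chained normalisation, where the convention cancels.

Vesicle lumens use $D - 2h$ (179 − 8 nm); total liposome surface area is
offered by two routes — number concentration × outer sphere area, or
lipids/mL × $a_\mathrm{lipid}/2$. The leaflet route equals the *mean* of
outer and inner leaflet areas, so the two differ by the fixed geometric
factor $(1 + ((D-2h)/D)^2)/2 \approx 0.956$ at 179/4 nm; both are exposed
because which area a normalisation "should" use is a reporting convention.

## ITC reduction

`integrate_thermogram()` splits the trace into per-injection windows
(first small injection at `delay`, then one per `interval`). The baseline
is a **per-window linear fit** through the 20 s before the injection and
the final 20 s of the window; the heat is the trapezoidal integral of
power minus baseline. This choice is testable: adding any affine function
of time changes recovered heats by well under 0.5%. Exothermic heats are
negative throughout; `normalize_enthalpy()` keeps the sign.

The first small (0.4 µL) injection is integrated but flagged `discard`
(standard practice); the enthalpy is referenced to the **first full
injection**, for which the injected vesicle area is orders of magnitude
below the gold area in the cell ("100% interaction"); the mean over all
full injections is reported alongside, since summary statistics across
injections are also common. $\Delta H = \Delta Q/SA_\mathrm{Au}$ is
reported in mJ/m² (the only unit consistent with an area normalisation),
and the chained form $(\Delta Q/SA_L)/(SA_\mathrm{Au}/SA_L)$ is carried as
an algebraic-identity check. The Gibbs relation
$\Delta G = \Delta H - T\Delta S$ is provided as a solver only; no entropy
is estimated.

**Noise floor.** The synthetic generator emits one-sided exponential
pulses (response time $\tau = 8$ s — only the integrated area matters
downstream) sampled at 0.05 s with additive white noise (default
0.02 µW sd) and optional linear drift. Under the window/baseline scheme
above, the integrated-noise sd is ≈ $26.7\,\mathrm{sd}\sqrt{dt}$ µJ
≈ 0.12 µJ at the defaults, so recovery of heats of a few µJ is accurate to
~1–2% in the median, but individual small heats (~2 µJ) carry ~6% noise-
induced sd — a floor set by the full-window integration itself, not by the
implementation. Tests therefore assert the median relative error (< 2%
over 100 seeded thermograms) and a tail bound (< 10% of heats off by more
than 5%), not a universal per-heat maximum.

## Fluorescence assays

Leakage is $100\,(F_\mathrm{sample}-F_\mathrm{control})/F_\mathrm{max}$
with the **raw** post-lysis maximum in the denominator, as the assay is
usually written up; `subtract_control_from_max = TRUE` gives the
alternative normalisation. Negative values are reported (with a warning),
not clipped.

Nile Red spectra are fit with a single Gaussian plus **constant** baseline
— the standard peak model for this probe — by Levenberg–Marquardt with
data-driven starts (argmax centre, half-maximum width). Degenerate inputs
(flat spectra) return a flagged non-converged fit with diagnostics rather
than an error. Shift classification defaults to a 1 nm noise threshold
for "no shift", configurable since what counts as within experimental
noise is instrument-dependent; a blue shift (negative) indicates reduced
environment polarity at the probe.

## DLS forward model and reductions

The field correlation of a mixture is
$g_1(\tau) = \sum_i w_i e^{-D_i q^2 \tau}$ with **Rayleigh** intensity
weights $w_i \propto N_i d_i^6$, $q = 4\pi n \sin(\theta/2)/\lambda$, and
Stokes–Einstein $D_i = k_BT/(3\pi\eta d_i)$; $g_2 = 1+\beta g_1^2$.
Defaults: 630 nm (as specified for the instrument, not the 632.8 nm HeNe
line), 173°, water at 25 °C ($\eta = 8.90\times10^{-4}$ Pa·s),
$\beta = 0.8$.

The $d^6$ weighting is a known **limitation**: 60–180 nm particles violate
the Rayleigh limit, and whether a given instrument's intensity-weighted
distributions apply Mie corrections is generally not knowable from a
methods section. The module's purpose is qualitative signal-dominance
reasoning — e.g. two equal-number 10/179 nm populations put
$179^6/(10^6+179^6) \approx 1 - 3\times10^{-8}$ of the intensity in the
vesicle mode, which is why binding shifts the whole signal to the vesicle
peak — not instrument emulation.

`cumulant_fit()` fits $\ln(g_2-1) = \ln\beta - 2\Gamma\tau + \mu_2\tau^2$
by least squares weighted by $(g_2-1)^2$ (undoing the log-transform's
noise amplification), on points above 3% of the intercept; PDI
$= \mu_2/\Gamma^2$. `population_shift_metric()` fits the *before* and
*after* correlograms jointly with a shared pair of decay rates and a free
slow-mode weight per curve (bounded in [0,1]); the metric is the change in
slow-mode intensity weight. The joint fit keeps the two-mode basis
identifiable even when one curve is effectively monoexponential.

## Synthetic data: what passing tests show

Every generator returns its ground truth as an attribute, so each
reduction has a parameter-recovery test: thermogram → heats (median < 2%),
spectrum → centre (< 0.5 nm at 1% noise), correlogram → diameter (< 2%
across 5–179 nm), leakage course → rate (< 5% at 1% noise), lognormal
sizes → median/GSD. Seeding is local (the caller's RNG state is restored),
and identical seeds give byte-identical CSVs.

The generators emulate additive Gaussian noise, linear drift, ideal pulse
shapes, single Gaussian peaks and ideal exponential decays. They do **not**
emulate correlated (1/f) instrument noise, injection-shape artefacts,
multiple scattering, number fluctuations at low counts, peak asymmetry, or
photobleaching. Passing recovery tests therefore demonstrates correctness
of the reductions under the stated noise model, not robustness to every
instrument pathology.

Problem sizes used by the test suite and demo pipeline — 100 thermograms
of 13 × 150 s windows at 0.05 s sampling, 200-point correlograms, 10⁴
lognormal draws — were chosen as the smallest sizes at which the
distributional claims above are statistically stable.

## Degenerate inputs and tie-breaks

* $\sigma \ge |W|$: $d_{c,\sigma} = \infty$ (never fully wrapped), not an
  error; $W = 0$ is an error ("no adhesion").
* Lockout: wraps exceeding the whole membrane give `required_strain = Inf`;
  `max_area_strain = 0` gives capacity 0 at every size (a sphere has no
  excess area).
* Classification boundaries are closed on the wrapped side
  ($d = d_c$ ⇒ partially wrapped; $d = d_{c,\sigma}$ ⇒ fully wrapped).
* Correlograms with $g_2-1 \le 0$ over more than half the range are
  rejected; flat spectra return flagged fits.

## Known limitations

Beyond those noted above: no free-energy minimisation of partially wrapped
shapes or penetration-depth prediction; no polydispersity or
multilamellarity corrections in dosimetry; no binding-isotherm fitting
(the ITC module reduces heats, it does not fit $K_d$); no regularised
(CONTIN-style) DLS inversion or multi-angle analysis; entropy enters only
through the algebraic Gibbs identity.
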