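---
title: "Methods: preclinical-to-clinical internal dosimetry with ludosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preclinical-to-clinical internal dosimetry with ludosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ludosim)
```

## The problem

A therapeutic radiopharmaceutical — here a ^177^Lu-labeled nanoparticle
injected into, or intravenously towards, a tumor — deposits radiation dose
wherever it resides. Before any clinical use one wants a first-order answer
to: *if this agent behaved in a human the way it behaves in a mouse, what
absorbed dose would each organ receive per MBq injected, and how much larger
is the tumor dose?* `ludosim` implements that chain from raw multi-animal
biodistribution tables to a per-organ dose report, tumor sphere self-dose
and tumor-to-organ dose ratios.

The chain is the classic MIRD formalism:

1. **Biodistribution** (`read_biodistribution`, `summarize_biodistribution`):
   %ID/g per organ, animal and timepoint, summarized to per-(organ, time)
   means.
2. **Extrapolation** (`extrapolate_table`): mouse concentration to human
   whole-organ uptake,
   $(\%IA/organ)_{human} = (\%ID/g)_{mouse}\cdot (kg_{TBW})_{mouse}\cdot
   g_{organ}/(kg_{TBW})_{human}$,
   with defaults 0.025 kg and 73 kg. The formula assumes concentration
   scales with relative organ mass — a deliberate first-order choice; no
   allometric alternatives are offered.
3. **Kinetics** (`fit_monoexponential`, `integrate_tac`): a
   mono-exponential fit per organ, integrated to the time-integrated
   activity $\tilde A$ (MBq·s per MBq injected — numerically $10^6$
   disintegrations per MBq).
4. **Dose** (`generate_s_matrix`, `organ_doses`, `sphere_dose`,
   `effective_dose`): $D(t)=\sum_s \tilde A(s)\, S(t\leftarrow s)$, the
   sphere model for the tumor, and an ICRP-60-weighted effective dose.

`run_dosimetry()` chains all of it.

## Radionuclide physics

`lu177_decay_data()` carries: half-life 6.65 d (159.6 h,
$\lambda_{phys}=4.343\times10^{-3}\,h^{-1}$), principal $\beta^-$ branch
0.497 MeV endpoint at 78%, 0.208 MeV $\gamma$ at 11%, mean $\beta$ range
670 µm. Doses need mean *emitted energies per decay*, split into
non-penetrating ($\Delta_{np}$: betas plus conversion/Auger electrons,
absorbed within millimetres) and penetrating ($\Delta_p$: photons):

* $\Delta_{np}$ defaults to **0.147 MeV/decay**, the published ^177^Lu
  value including conversion electrons. As an independent cross-check the
  package computes the mean of an allowed-shape, Coulomb-corrected beta
  spectrum per branch (`beta_mean_energy`); the branch-weighted result
  (≈0.138 MeV) sits a few percent below the shipped constant, the gap being
  exactly the conversion-electron contribution the spectrum model omits.
* $\Delta_p$ defaults to $0.208\times0.11=0.02288$ MeV/decay, i.e. only the
  listed gamma branch. The full photon spectrum of ^177^Lu is somewhat
  richer; since photons contribute ≲1% of organ dose under this package's
  models, the simpler constant is kept.

## Time–activity fitting choices

Biodistribution values are conventionally decay-corrected to injection
time; `decay_corrected = TRUE` (default) therefore treats the fitted slope
as *biological* clearance $\lambda_{bio}$ and integrates
$A_0 e^{-(\lambda_{bio}+\lambda_{phys})t}$. With `decay_corrected = FALSE`
the fitted slope is the effective constant directly.

Design choices that were genuinely open, and how they were settled:

* **Fit window.** The default `monoexp_from_peak` regresses
  $\log A$ on $t$ from the observed peak onward: uptake phases are not
  mono-exponential and would bias the terminal slope. When fewer than two
  positive points remain at or after the peak — a still-rising curve, or a
  terminal zero — the window widens to the whole positive series. This
  widening is what lets a monotonically rising organ (bone) be fitted at
  all and then clamped (below) rather than erroring.
* **Clamping.** A positive fitted slope (rising uptake) is clamped to
  $\lambda_{bio}=0$: the organ is assumed to retain activity and decay only
  physically, the slowest admissible — hence most dose-conservative —
  kinetics. An unclamped rising exponential would diverge under
  integration. The constrained zero-slope least-squares level is the
  geometric mean of the window.
* **Integration from $t=0$.** `ignore_pre_peak` (default) integrates the
  fitted exponential from zero using the back-extrapolated intercept
  $A_0$: $\tilde A = 3600\,(A_0/100)/\lambda_{eff}$. The alternative
  `trapezoid_pre_peak` integrates decay-weighted trapezoids from (0, 0)
  through the observed points up to the peak, plus the analytic tail. The
  default slightly overestimates the ramp-up period (conservative for
  normal organs) and is the simpler, fully analytic convention.
* **Unfittable organs.** A series with a single positive point (it happens:
  a late-timepoint organ measured as exactly 0) errors under strict
  settings; the pipeline default `on_insufficient = "fallback_physical"`
  instead assumes physical-decay-only kinetics from that observation and
  records the fallback in the per-organ provenance, so one degenerate row
  cannot abort a whole run.

Every $\tilde A$ obeys the closed-form bound
$\tilde A \le 3600/\lambda_{phys} \approx 8.29\times10^5$ MBq·s/MBq for
$A_0\le100$ %IA (all injected activity decaying with no clearance); the
test suite fuzzes this.

## The S-value model

Phantom S-value libraries of commercial dosimetry codes are licensed and
cannot be redistributed, so `generate_s_matrix()` builds the coefficients
from first principles:

* `local_np_only`: non-penetrating energy is absorbed where it is emitted,
  $S(o\leftarrow o)=\Delta_{np}/m_o$, all cross terms zero. For ^177^Lu
  (β self-dose dominated) this captures the leading term.
* `local_np_plus_uniform_photon` (package default): adds a uniform
  whole-body photon bath, $\Delta_p\cdot AF_{body}/TBW$ for every
  source–target pair, with $AF_{body}=0.3$ a configurable whole-body photon
  absorbed fraction. This is an order-of-magnitude photon term, not a
  phantom-geometry calculation; for this nuclide it shifts organ doses by
  well under 1%.

Blood activity is not a phantom organ: it is routed to a `total body`
remainder source whose non-penetrating energy is spread over the whole-body
mass. Urine is excreted activity and contributes no dose. The tumor's
non-penetrating self-dose is the sphere model's job, so the tumor is not an
S-matrix source; its photon cross-dose to organs (≈10⁻⁶ mSv/MBq under the
bath model here) is neglected.

Organ masses come from a bundled YAML of Cristy–Eckerman adult-male phantom
reference masses (`organ_mass_table()`, overridable per run). Absorbed dose
in mGy/MBq is reported numerically as mSv/MBq (radiation weighting factor 1
for β/γ).

The **tumor** is treated as a unit-density sphere of configurable mass
(default 0.5 g). Its uptake is extrapolated with the sphere mass as "organ
mass" — the interpretation under which whole-organ uptake, hence dose, is
on a physically sensible scale — and its self-dose is
$D=\tilde A\,(\Delta_{np}\phi_{np}+\Delta_p\phi_p)/m$ with an edge-loss
absorbed fraction $\phi_{np}=1-\tfrac34\,r_{range}/R_{sphere}$ (0.898 for
0.5 g with a 670 µm range; →1 for large masses) and a small constant photon
fraction $\phi_p=0.01$. Sphere doses are reported in mGy/MBq: no tissue
weighting factor applies to a sphere.

**Effective dose** uses ICRP-60 tissue weighting factors (the set used by
the era's dosimetry software). Weighted tissues without a measured dose
contribute zero with a warning; the 0.05 remainder weight is applied to the
mean of the unweighted measured organs — a simplification of the
mass-weighted remainder rule, acceptable at the accuracy of the generated
S model.

## What the synthetic generator emulates — and what it does not

`kinetic_scenario()` + `generate_biodistribution()` produce multi-animal
%ID/g tables from known ground truth: per organ
$A(t)=A_0e^{-\lambda_{bio}t}$, optionally
$A_0(1-e^{-k_{up}t})e^{-\lambda_{bio}t}$ for accreting organs, with
multiplicative log-normal noise of unit mean
($\sigma=\sqrt{\ln(1+CV^2)}$ — biodistribution data are positive and
right-skewed). Identical seeds give bitwise-identical tables and the
caller's RNG stream is left untouched.

`bundled_scenarios()` ships an `intratumoral_like` scenario (per-organ
parameters are log-least-squares fits to the published intratumoral means,
anchored to pass exactly through each 4 h mean; 4 animals; CV 0.3, the
magnitude of the published inter-animal SDs) and an `intravenous_like`
scenario (liver/spleen-dominant reticuloendothelial uptake, tumor kinetics
anchored to the published intravenous tumor values of 1.17 %ID/g at 24 h
and 0.59 at 48 h; other organ magnitudes are the package's own realistic
choices for intravenously injected gold nanoparticles).

Limits to keep in mind: a mono-exponential generator cannot reproduce
non-monotone measured rows (a tumor value that dips at 48 h and rebounds at
72 h) at every timepoint — the intratumoral scenario matches the published
table exactly at 4 h and in trend elsewhere. Passing recovery tests on
synthetic data therefore demonstrates correctness of the fitting and dose
arithmetic under the stated kinetic model and noise, not that real tissue
kinetics are mono-exponential, and no imaging, survival or toxicity
processes are simulated.

## Numerical conventions and degenerate inputs

* Hours internally; $\tilde A$ exposed in MBq·s per MBq (the 3600 appears
  once, at integration).
* Peak detection is the argmax of mean uptake, ties to the earlier
  timepoint (maximizing the fitted window).
* A literal 0.00 measurement is data, not missingness; it is dropped from
  log-space windows but kept in summaries.
* All-zero organ series integrate to $\tilde A=0$ without error.
* Per-animal ratio methods drop animals whose denominator organ is 0 and
  error only if none remain.
* $\phi_{np}$ is clamped into (0, 1]; the edge-loss expression is a
  first-order model valid for spheres much larger than the beta range.
* Dose ratios are computed at full precision and rounded only for display
  (1 decimal at ≥1, else 2), so a ratio like 3.55/0.00234 prints as
  1517.1.

## Problem sizes used in validation

The shipped validation suite runs the full pipeline on the packaged
64-cell (16 organs × 4 timepoints × 4 animals) intratumoral table;
checks integration against numerical quadrature on 1000 randomized fits;
verifies exact (≥6 significant digits) parameter recovery on noiseless
curves; and estimates stochastic recovery at the study's design point
(4 animals, 10% CV, 200 seeded replicates), requiring median absolute
relative bias below 15% for $\lambda_{bio}$ and 20% for $\tilde A$. These
sizes give stable medians while keeping the suite quick to run.

## Known limitations

* The generated S matrix has no organ-pair photon geometry; organ doses for
  photon-dominated situations (or nuclides) would need an imported S-value
  table (`read_s_matrix()` accepts one).
* One global mono-exponential per organ; no multi-compartment fits, no
  uncertainty propagation beyond the synthetic-replicate studies.
* The mouse-to-human formula is a relative-organ-mass extrapolation; species
  differences in clearance routes are not modeled.
* SPECT support is semi-quantification arithmetic only (cylinder factor,
  %ID/cc, correlation) — no reconstruction, attenuation or partial-volume
  handling.

## A worked run

```{r example}
tab <- read_biodistribution(intratumoral_fixture_path(),
                            route = "intratumoral")
report <- run_dosimetry(tab, s_model = "local_np_only")
report
format_ratio(dose_ratio(report, "brain"))
```
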