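---
title: "Subcellular dosimetry and radiobiology of Auger emitters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subcellular dosimetry and radiobiology of Auger emitters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldose)
```

`celldose` quantifies the absorbed dose delivered to the nucleus and the
cytoplasm of a cultured cell by an internalized Auger/conversion-electron
emitter, and connects those doses to radiobiological endpoints. This
vignette is the package's account of the science: the models, their
assumptions, the tunable parameters, and the choices made where the design
was genuinely open.

## 1. From counts to cumulated activity

A gamma counter reports counts per minute (cpm) for the surface-bound,
internalized and nuclear fractions of a cell sample. The conversion to
activity is

$$A \,[\mathrm{Bq}] = \frac{\mathrm{cpm}/60}{\varepsilon},$$

with detector efficiency $\varepsilon$ (default 0.54; the counting window
is taken as the 1-minute normalization implicit in cpm). The measurement
happens at the end of a $t = 24$ h incubation; the analysis assumes the
measured cellular activity was present from $t = 0$ and only decayed
physically (*instant-uptake model* — no uptake ramp, no biological
washout), so the initial activity is recovered by inverting the decay law,

$$A_0 = A(t)\, e^{\ln 2 \cdot t / T_p},$$

with $T_p = 6.02$ h for $^{99\mathrm{m}}$Tc. The number of decays over the
incubation interval $\Delta t$ (default 24 h, configurable) is the
time-integrated (cumulated) activity

$$\tilde A = \frac{T_p}{\ln 2} A_0 \left(1 - e^{-\ln 2 \cdot \Delta t / T_p}\right)
\quad [\mathrm{Bq\,s}],$$

where $1/\ln 2 = 1.44$ is the familiar mean-life factor; the package uses
$\ln 2$ internally and its tests tolerate the $\le 0.2\%$ difference
against the printed constants 0.693/1.44. $\tilde A$ is split between
nucleus and cytoplasm by the measured nuclear fraction $f$ of internalized
activity; the split conserves $\tilde A$ exactly. Surface-bound activity
is excluded from dose by design: Auger electrons emitted at the membrane
have sub-micron ranges and contribute negligibly to nuclear dose, and dose
from the culture medium is likewise out of scope.

Two modes are offered for how $f$ enters dose tables: the default pools
the per-compound mean nuclear fraction (the convention under which the
headline dose shares below follow directly from the mean fractions), and a
per-record mode uses each measurement's own fraction. Both are reported by
`dose_table()` via `nuclear_fraction_mode`.

## 2. MIRD cellular S-value dosimetry

With decays localized per compartment, absorbed doses follow the standard
bilinear S-value form

$$D_N = \tilde A_N S(N\!\leftarrow\!N) + \tilde A_{Cy} S(N\!\leftarrow\!Cy),
\qquad
D_{Cy} = \tilde A_N S(Cy\!\leftarrow\!N) + \tilde A_{Cy} S(Cy\!\leftarrow\!Cy).$$

The packaged $^{99\mathrm{m}}$Tc matrix (`s_value_tc99m()`, for a 2 µm
nucleus inside a 4 µm cell, electron emissions only — the β yield is
negligible and photons are not scored) is

```{r}
s_value_tc99m()
```

**Total-dose convention.** The "total cell dose" is defined as
$D_N + D_{Cy}$, the sum of the compartment doses. This is the convention
under which the nuclear dose share implied by a mean nuclear uptake
fraction of 0.45 is 84% (and 66% for a fraction of 0.22):

```{r}
100 * nuclear_dose_fraction_from_uptake(c(0.45, 0.22))
```

A physically motivated alternative — energy per total cell mass, i.e. the
mass-weighted mean of the compartment doses — is available via
`compartment_doses(..., total = "mass_weighted")`, but it is *not* the
default because the compartment-sum convention is the one that makes the
reported dose shares and the mean uptake fractions mutually consistent.
The share $D_N/(D_N+D_{Cy})$ itself is invariant under any rescaling of
the total cumulated activity, is strictly increasing in $f$ whenever
$S(N\!\leftarrow\!N) > S(N\!\leftarrow\!Cy)$, and is therefore the robust,
unit-free summary of subcellular targeting.

**Absolute dose scale.** S-values are per *cell*; gamma-counter counts are
per *sample* (often tens of thousands of cells). `dose_table()` therefore
accepts `cells_per_sample` (default 1) to normalize cumulated activity to
the average single cell. Absolute doses scale linearly with the measured
count magnitude and with $1/\texttt{cells\_per\_sample}$, and published
absolute dose tables additionally depend on normalization details that are
not recoverable from summary figures; the package validates dose *shares*,
which are immune to all of these scale factors.

## 3. The Monte Carlo transport engine

The MIRD S-values assume homogeneous sources. To model a DNA-bound
radionuclide more realistically, the engine places the source in a central
0.7 µm sphere — the condensed chromatin region — inside the 2 µm nucleus
and 4 µm cell (`cell_phantom()`, unit-density water; compartment masses
from sphere volumes). Homogeneous nucleus and cytoplasm-shell sources are
also provided, which is how the engine cross-validates against the MIRD
matrix.

**Transport model.** Electrons travel in a straight line from their
emission point, losing energy continuously at the stopping-power rate
(CSDA); deposits are split between nucleus and cytoplasm by exact
ray–sphere intersection; residual energy below the 10 eV transport floor
deposits locally; energy carried across the cell boundary is scored as
escaped. There is no angular scattering, no secondary-electron transport
and no photon scoring. The justification is the acceptance surface: what
is being computed is the *partition* of deposited energy between two
concentric compartments a micron or two across, which is dominated by
chord-length geometry. For sub-keV Auger electrons (ranges of nanometres)
transport detail is irrelevant — they deposit at the source; for the
~120 keV conversion electrons (CSDA range ~10² µm) the cell is a thin
slab and energy loss along the chord is all that matters. Path-length
straggling and lateral diffusion would redistribute a few percent of the
intermediate-energy deposit, which is far below the contrasts of interest
(dose shares of 84% vs 99%). Track-structure fidelity, strand-break
simulation and cross-section databases are explicitly out of scope.

**Stopping powers.** A packaged plain-text table gives the collision
stopping power of liquid water from 10 eV to 150 keV (ICRU/ESTAR values
at and above 1 keV; approximate dielectric-model values below), log-log
interpolated; the CSDA range is its cumulative inverse on a 4000-point
log grid, and energy-vs-residual-range is the interpolated inverse of
that. Deposits are computed as telescoping differences of the residual
energy at the boundary crossings, which makes per-history energy
conservation *exact* in floating point rather than accurate to
interpolation error. An empirical power-law range–energy model
(`range_energy_model()`, $R = aE^p$) provides a table-free fallback.

**Statistics.** `run_s_value_mc()` runs a fixed number of histories per
spectrum line (default $10^5$, which resolves the nuclear share to ≲0.1
percentage point and runs in seconds), weights line means by yield, and
reports standard errors from the history-level variance; the seed is
mandatory in the pipeline wrappers, and identical seeds give bitwise
identical results. Standard errors scale as $1/\sqrt{n}$, verified over a
history-doubling ladder.

**Spectra.** Any two-column (energy keV, yield/decay) text file is
accepted. The packaged `toy_spectrum("tc99m_like")` fixture is a
*documented approximation* of the $^{99\mathrm{m}}$Tc electron emissions —
grouped sub-keV Auger lines (~0.9 keV/decay), the 1.8–2.1 keV conversion
electrons of the almost fully converted 2.17 keV transition
(~1.6 keV/decay), K Auger electrons, and the 119.5–140 keV conversion
lines (~13.3 keV/decay) — totalling 15.9 keV/decay. It is emphatically
*not* the ICRP-107 dataset, which is not redistributable here; users doing
absolute S-value work should load the ICRP-107 electron lines with
`read_spectrum()`. With the fixture, the homogeneous-nucleus configuration
reproduces the published MIRD $S(N\!\leftarrow\!N)$ within ~2.5% (the test
suite asserts 10%, a bound chosen for a synthetic spectrum under CSDA
transport; the 3% figure quoted for full single-event Monte Carlo with
ICRP-107 data is treated as aspirational), and the central-chromatin
configuration puts >95% (in practice ~99%) of the intracellular dose in
the nucleus — the regime where DNA-intercalated Auger emitters operate.

## 4. Survival, IC50 and RBE

Clonogenic endpoints use the standard definitions: plating efficiency
$PE = \text{colonies}/\text{seeded} \times 100\%$ (colonies of ≥50 cells),
and survival fraction $SF = \text{colonies}/(\text{seeded} \times
PE_{\text{control}}/100)$, which makes the control's SF exactly 1.

Survival curves are modelled with the one-parameter exponential
(single-hit) model $SF = e^{-\kappa D}$. This interpretation of the
"linear model" is the only single-parameter form under which a
$\kappa$-only error analysis closes, and it makes both RBE endpoints exact
functions of the fitted slopes:

$$RBE_{0.5} = \frac{D_{\mathrm{ref}}(0.5)}{D_{\mathrm{test}}(0.5)} =
\frac{\kappa_{\mathrm{test}}}{\kappa_{\mathrm{ref}}}, \qquad
RBE_{2\mathrm{Gy}} = \frac{SF_{\mathrm{ref}}(2)}{SF_{\mathrm{test}}(2)} =
e^{2(\kappa_{\mathrm{test}} - \kappa_{\mathrm{ref}})}.$$

The fit is ordinary (optionally $1/\mathrm{se}^2$-weighted) least squares
on $\ln SF$ with no intercept; zero-SF points cannot enter a log fit and
are dropped with a warning rather than pseudo-counted. On noiseless
exponential data the fit recovers $\kappa$ exactly with zero residual; on
lognormal-noise synthetic data the estimator's bias is below 2% and its
reported standard error matches the replicate spread (calibration checks
run at 200–500 replicates of 6-dose curves, sizes chosen to pin the
calibration to a couple of percent while keeping the suite quick).
Survival is fitted against the *total cellular dose* ($D_N + D_{Cy}$) when
computing RBE, with the reference radiation entering as a user-supplied
`survival_fit()` (its slope is an input, not something this package
refits). RBE uncertainties use first-order (delta-method) propagation of
the two independent $\kappa$ errors; `rbe_sampling_se()` provides a
sampling-based check, and the two agree to a few percent at realistic
uncertainty levels.

IC₅₀ on the activity axis uses the same exponential form,
$SF = e^{-\lambda A}$, giving $IC_{50} = \ln 2/\lambda$; by default the
data must bracket $SF = 0.5$. γ-H2AX foci summaries report the mean ± SD
of foci per nucleus (warning below 200 nuclei) normalized to control both
subtractively and as a ratio, since "normalized to control" is used both
ways in practice; micronucleus yields are per 1000 binucleated cells,
optionally normalized to the control yield.

## 5. The synthetic-data generators

The generators reproduce the *statistical structure* the analysis assumes,
with defaults chosen to emulate the studied system:

* **Uptake** (`generate_uptake_table()`): internalized fraction
  $f(A) = f_{\max}/(1 + A/k_{\mathrm{sat}})$ — a saturable form chosen
  only to reproduce the observed decline of percent uptake with applied
  activity, with no mechanistic claim (passive diffusion is the likelier
  mechanism). Presets: compound C3 $f_{\max} = 0.08$,
  $k_{\mathrm{sat}} = 4.5$ MBq (8% → 3% over 7.4 kBq–7.4 MBq),
  surface:internal ratio 4, nuclear fraction $0.45 \pm 0.05$
  (truncated normal); compound C5 $f_{\max} = 0.24$,
  $k_{\mathrm{sat}} = 1.95$ MBq (24% → 5%), ratio 1.6, nuclear fraction
  $0.22 \pm 0.05$. Counts are Poisson over a 1-minute window at 54%
  efficiency. The 0.05 SD reflects the reported near-constancy of the
  nuclear fraction across activities.
* **Survival** (`generate_survival_data()`): $e^{-\kappa D}$ times
  mean-one lognormal noise (default CV 5%), control point (0, 1) always
  exact.

What the generators deliberately do **not** emulate: uptake kinetics over
time, biological clearance, cell-to-cell activity heterogeneity (the
average-cell MIRD picture only), dose-rate effects, and any coupling
between dose and assay noise beyond Poisson counting. Passing tests on
synthetic data therefore demonstrate that the *estimators and dose
arithmetic* are correct and calibrated under the stated model — not that
the model captures every feature of real uptake experiments.

## 6. Degenerate inputs, tie-breaks and edge policies

* Zero internalized counts give zero dose in both compartments regardless
  of surface counts; the nuclear dose share is undefined (NA) at zero
  total dose, and `nuclear_dose_share_mc()` errors rather than returning
  0/0.
* Sphere-boundary grazing rays: the nucleus interval is clipped to the
  forward ray and the cell chord, so tangent rays score zero nucleus path
  rather than a negative one.
* Electrons with range beyond the remaining path escape with their
  residual energy; an electron stopping *exactly* at a boundary deposits
  its sub-floor residue in the segment where it stopped.
* `s_value_matrix()` warns (not errors) when the short-range ordering
  $S_{NN} > S_{CyCy} > S_{NCy}$ fails, since long-range emitters
  legitimately violate it; reciprocity of the cross terms is recorded, not
  enforced.
* Activities parse with kBq/MBq/GBq suffixes; the canonical unit is Bq
  everywhere internally.

## 7. Known limitations

* Straight-ray CSDA transport has no lateral spread: point-dose profiles
  are not meaningful, only compartment partitions.
* The sub-keV stopping powers are approximate; quantities dominated by
  10–500 eV transport detail (e.g. nanodosimetric clustering) are outside
  the engine's validity.
* The instant-uptake assumption maximizes the cumulated activity; if real
  uptake ramps over the incubation, absolute doses are overestimated by up
  to ~40% (the ratio of the interval integrals), though shares are
  unaffected.
* The exponential survival model cannot represent shouldered survival
  curves; linear-quadratic fitting is a deliberate non-goal.
* The packaged Tc-99m-like spectrum is a fixture: absolute S-value claims
  should be based on user-supplied ICRP-107 emission data.
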