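---
title: "Quantifying opsin photopigment assays: models, parameters, and design choices"
author: "OpsinAssays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying opsin photopigment assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, message=FALSE}
library(OpsinAssays)
```

## The scientific problem

Nonvisual opsins such as the TMT-Opsins and Encephalopsin are G-protein
coupled receptors expressed in vertebrate brain neurons. Two assay
families establish that such proteins are functional photopigments and
that neurons expressing them are intrinsically photosensitive:

1. **Impedance-based (RTCA) light-response assays.** Cultured cells
   transfected with a candidate opsin grow on electrode plates; the
   dimensionless *cell index* (CI) tracks impedance and thereby GPCR
   activation. A light pulse evokes a transient CI excursion in wells
   expressing a functional pigment, but not in wells expressing a
   non-opsin GPCR, an untransfected culture, or a pigment whose
   chromophore-binding lysine has been mutated to alanine.
2. **Whole-cell patch-clamp screening.** Neurons recorded in isolated
   brain slices (2 min darkness, 1 min light, 2 min darkness) are
   classified as light-responsive when their membrane potential moves
   strongly during the light minute while staying stable in darkness.

The raw instrument exports behind these assays are generally not
deposited alongside publications, so this package pairs each analysis
with a seeded synthetic-data generator that reproduces the statistical
structure the analysis assumes. Every pipeline is therefore testable end
to end, and the generators double as explicit, executable statements of
what the analyses expect from real data.

## Impedance pipeline

The processing chain mirrors standard RTCA practice, with provenance
flags (`raw -> normalized -> corrected`) enforced at each step:

1. `normalizeCI()` divides each well by its CI at the last sample before
   light onset. Any common multiplicative gain cancels here; the pipeline
   is exactly equivariant under `ci * c` for `c > 0` (tested).
2. `baselineCorrect()` subtracts the pointwise mean of the plate's
   control wells (non-opsin GPCR / untransfected), removing shared
   drifts.
3. `relativeLightResponse()` integrates the corrected trace by the
   trapezoid rule over the light window and the immediately preceding,
   equally long dark window and reports the ratio.
4. `spectralPercentAUC()` expresses a color-light response as a
   percentage of the same well's preceding white-light response.
5. `kineticsSummary()` reports time-to-peak, peak amplitude, the
   fraction of the peak lost by a probe time after light-off
   (`probeDt`, default 300 s), and a log-linear decay-rate estimate.
6. `compareGroups()` runs the two-sided Mann–Whitney test with the
   conventional star labels.

Two conventions deserve comment because the underlying figure-level
descriptions leave them open:

* **The AUC ratio is computed on the corrected trace re-offset by +1.**
  A baseline-corrected non-responder hovers around zero, so its dark AUC
  is ~0 and a ratio would be ill-posed. Re-offsetting by +1 makes the
  dark AUC equal to the window length, so a flat non-responder scores
  exactly 1.0 and a responder scores 1 + (excess area)/(window length).
  This reproduces the depicted behaviour of the published quantification
  while keeping the statistic well defined; it is an interpretation, not
  a transcription.
* **%AUC uses the baseline-excess convention**,
  `100 * (r_color - 1) / (r_white - 1)`, so that a non-responder scores
  ~0% rather than ~100%, matching how mutant constructs plot near zero.

Windows are closed–open (`[a, b)` contains samples with `a <= t < b`);
argmax ties resolve to the earliest time; wells failing a degeneracy
guard (reference CI ≤ 0, dark AUC ≤ 0, white response at baseline) are
excluded *and reported*, never silently dropped.

### The kinetic simulator

`simulateImpedancePlate()` integrates, per pigment class, a two-state
receptor model with active fraction $R$ and desensitized fraction $D$:

$$R' = \alpha E (1 - R - D) - \beta R, \qquad
  D' = \delta R \cdot 1[\text{light on}] - \rho D,$$

with the normalized photoactivation drive $E$ from `effectiveDrive()`.
The well trace is then

$$CI(t) = C_0\, g_w\, \mathrm{drift}(t)\, (1 + g R(t) - d\cdot\mathrm{dip}(t))
          + \varepsilon(t),$$

with a lognormal well gain $g_w$, a shared linear plate drift, an
optional post-onset dip (the HEK-cell trace shape; `dip = 0` for the
Neuro-2A defaults), and i.i.d. Gaussian sampling noise. Integration is
fixed-step RK4 (deSolve) at a 1-s internal step resampled to the 15-s
instrument grid: the rates involved are far from stiff, and a fixed-step
method keeps simulated plates bit-reproducible for a given seed.

Default kinetic parameters (per second): the rhodopsin-like reference
uses $\alpha = 0.008$, $\beta = 0.010$, $\delta = 0.002$,
$\rho = 5\times10^{-4}$, chosen by a coarse parameter scan so that the
noiseless response to a saturating 12-min white pulse peaks ~3 min after
onset (the desensitization term is what makes the peak interior) and
relaxes with a ~100 s time constant after light-off. The fast-deactivating
class (`tmt_fast`, modelling group-2-like pigments) uses
$\beta = 0.020$; the slow class (`tmt_slow`, group 1/3-like) uses
$\beta = 0.003$; `enc_low_gain` couples at 0.3× the TMT gain;
`mutant_null` and `non_opsin_control` have zero drive by construction.
These defaults are calibrations that reproduce ordinal, qualitative
response features — they are not fitted estimates of any real pigment's
kinetics, and conclusions from simulations should be read ordinally
(faster/slower, larger/smaller), not quantitatively.

### Spectral model

Pigment absorption is a Gaussian template in log-wavelength with
half-bandwidth 0.08 log-units, peaking at 1 at $\lambda_{max}$, rather
than a full A1 visual-pigment nomogram. The simpler template reproduces
every spectral claim the analyses rest on — a blue-shifted pigment
prefers the blue (450 nm) over the green (528 nm) filter more strongly
than a 497-nm reference pigment, and any visible pigment is blind
($S < 10^{-6}$) to the 950-nm near-infrared control — while remaining
transparent; a nomogram can be slotted in through the `bw`/template hook
if absolute spectral work is ever needed. Filters are Gaussian bands
(sd 20 nm); white light is a flat 450–750 nm band. Fluxes default to the
printed instrument values (white $1.3\times10^{16}$, blue
$3.6\times10^{14}$, green $1.9\times10^{14}$, red $7.4\times10^{14}$,
halogen $2.53\times10^{16}$ photons cm⁻² s⁻¹). The drive normalization
(`referenceFlux()`) makes the default white pulse give $E = 1$ for the
497-nm reference pigment; whether the printed blue/green fluxes truly
equalize a 497-nm pigment's activation is treated as a configuration
property of the instrument calibration, not as a law the simulator must
enforce.

## Patch-clamp pipeline

`windowedDeltas()` implements the windowed membrane-potential statistic:
with the reference value $V_{ref}$ taken at the last sample before light
onset (time 0), each delta is the mean Vm over a 1-min window minus
$V_{ref}$, for the windows at $t = -1$ (last dark minute), $t = +1$
(light minute) and $t = +2$ (first post-light minute).
`cohortAnalysis()` adds the paired Student's t test between the $-1$ and
$+1$ deltas across a cohort.

`classifyResponsive()` labels a cell responsive when
$|\Delta(+1)| \ge 10\,\mathrm{mV}$ **and** $|\Delta(-1)| < 10$ mV. The
10 mV line is adopted from the empirical observation that dark-only
recordings never approach it; the dark-stability clause protects against
drifting cells. This operationalization is this package's own — the
original description identifies responsive cells descriptively rather
than by a stated threshold — so the threshold is an explicit
configuration value, not a reproduced algorithm.

Spikes, when present, are included in the window means (no spike
removal); a median-based summary can be substituted for robustness, and
the windowed-mean classification is tested to be unaffected by
stereotyped spiking at physiological rates (a 60 mV, 4 ms spike at 2 Hz
shifts a 1-min mean by ~0.5 mV).

### The cohort generator

`simulateEphysCohort()` draws each cell's resting potential from
$\mathcal N(-30.91, 5^2)$ mV. The −30.91 mV mean echoes the published
average for tectal interneurons; the printed ±2.3 mV is not labelled as
SD or SEM there, so the cross-cell SD is a free default (5 mV) and this
ambiguity is deliberately not resolved. Dark noise is an
Ornstein–Uhlenbeck process (exact AR(1) discretization, stationary
start) with reversion rate 0.05 s⁻¹ and stationary SD 0.6 mV; planted
responders add a saturating depolarization with amplitude drawn from
U(12, 35) mV, 2-s rise and 10-s post-light decay. The noise level and
rise time were fixed together by an error-budget calculation: the
windowed deltas of dark cells must stay far below 10 mV (observed
cohort maxima ~2 mV), while the weakest planted responder (12 mV) must
clear the threshold with its window mean, keeping label recovery exact.
Simulation runs at 1 kHz rather than the 10 kHz acquisition rate of the
instrument: 1-min window means are insensitive to this (tested: 10×
downsampling moves deltas by < 0.1 mV), and it keeps hundred-cohort test
sweeps desk-scale.

## Statistics

`mannWhitneyU()` and `pairedT()` are self-contained so that their exact
small-sample behaviour is verifiable by brute force within the package's
own test suite (base R's `wilcox.test`/`t.test` serve as independent
cross-checks there). The Mann–Whitney p value is exact — enumeration of
all group assignments — when the combined sample is ≤ 12 with no ties,
and a tie- and continuity-corrected normal approximation otherwise; the
crossover matches the point where enumeration stops being instant, and
the plate-scale comparisons (n = 12–136 wells) always use the
approximation. Both tests are two-sided. No multiple-testing correction
is applied anywhere, on purpose: the upstream analyses report raw
p values, and silently adding a correction would change their meaning.

One statistical caveat surfaced by the simulator is worth recording:
wells on the same plate share their control-well correction, so
*cross-plate* group comparisons inherit a plate-level random shift and
can reject far above nominal level even when nothing is happening.
Group comparisons should be made within plate (as in the
wild-type-vs-mutant and NIR designs), or with plate as a blocking
factor; the package's tests encode the within-plate designs.

## Sequence annotation

`annotateOpsin()` transfers bovine-rhodopsin numbering onto a query
opsin by global alignment (Gotoh affine-gap DP, BLOSUM62, gap open 10 /
extend 1) and reports the residues at the Schiff-base lysine position
(reference 296) and the two counterion candidates (113 and 181). The
traceback tie-break is deterministic: match/mismatch over gap-in-query
over gap-in-reference. The 348-residue bovine rhodopsin reference ships
in `inst/extdata` with its provenance note. Which counterion position is
functional in a given lineage is a biological interpretation the package
does not make; it reports identities only. C-terminal fingerprint motifs
are scanned (over the C-terminal third) only from user-supplied
patterns — the published fingerprints exist as figure panels, not as
printed sequence strings, so shipping hard-coded defaults would invent
data. `nearestReference()` ranks references by alignment score and is
labelled a heuristic; phylogenetic placement is out of scope.

## What the synthetic data do and do not show

The generators emulate: pigment-class-specific kinetics (fast/slow
deactivation, desensitization-driven interior peaks, low-gain class,
null mutants), HEK-style onset dips, shared plate drift with well-level
gain and noise, OU dark noise with stable windowed deltas, planted
depolarizations, and optional stereotyped spiking. They do **not**
emulate: biophysical phototransduction cascades, conductance-based
neuron models, irradiance–response saturation curves, access-resistance
artefacts, or plate edge effects. Passing tests therefore demonstrate
that the *quantification machinery* is correct and well-calibrated under
the stated assumptions — not that any particular biological effect size
would be recovered from real recordings.

## Problem sizes and reproducibility

The test suite runs cohorts of 14–28 cells at 1 kHz for 5 simulated
minutes, plates of up to 25 wells on the 15-s grid, 100-seed sweeps for
the label-recovery and null-calibration properties, and 5000 null
simulations for the type-I-error check of the Mann–Whitney
approximation. All stochastic stages take explicit integer seeds, and
identical seeds give bit-identical output (tested); every written result
carries a JSON sidecar with the seed and a hash of the configuration
that produced it.

```{r example}
layout <- data.frame(
  well  = c("A1", "A2", "A3", "B1"),
  class = c("rho_like", "tmt_fast", "mutant_null", "non_opsin_control"))
pe <- simulateImpedancePlate(layout, defaultPlateProtocol(), seed = 1)
res <- analyzeImpedancePlate(pe)
res$responses[, c("well", "construct", "ratio")]
```
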