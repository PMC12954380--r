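---
title: "Methods: midpoint potentials, tunneling geometry and bifurcation energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: midpoint potentials, tunneling geometry and bifurcation energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rieske)
```

## The scientific question

Anammox bacteria such as *Kuenenia stuttgartiensis* encode Rieske/cytochrome
*b* complexes that carry putative NAD(P) oxidoreductase subunits, suggesting
these complexes run electron bifurcation "in reverse" of the canonical Q
cycle: one electron from menaquinol oxidation goes downhill to a
high-potential acceptor via the Rieske [2Fe2S] cluster, paying for the other
electron's uphill trip to NAD(P)⁺. Deciding whether that proposal is
thermodynamically and structurally plausible needs three computations, which
are this package's three layers:

1. **Titration**: determine the Rieske cluster midpoint potential from
   thin-layer (OTTLE) spectro-titrations, with a defensible uncertainty.
2. **Geometry**: extract the cofactor inventory from structural models and
   ask whether electrons have a viable multi-step tunneling route from the
   membrane hemes to the flavin.
3. **Energetics**: close the redox-potential ledger of the proposed coupling.

A synthetic-data layer generates titration experiments and toy coordinate
files with known ground truth, so each layer is testable end to end without
any experimental download.

## The titration model

At a poised potential $E$ a one-electron couple with midpoint $E_m$ is
oxidized to the fraction $f_{ox}(E) = [1 + e^{-zF(E-E_m)/RT}]^{-1}$. The
band-averaged, normalized absorbance relative to the fully reduced reference
is fitted with the single-transition Nernstian function

$$Y = A - A_{red} = \frac{a}{e^{zF(E-E_m)/RT} + 1} + c$$

with $z$ fixed (default 1), $F = 96485.34$ J mol⁻¹ V⁻¹,
$R = 8.3145$ J mol⁻¹ K⁻¹ and $T = 293$ K, giving a thermal scale
$RT/F \approx 25.25$ mV and a 10%→90% transition width of
$2\ln 9 \cdot RT/F \approx 111$ mV. The amplitude $a$ is deliberately
unconstrained in sign: the fraction-reduced term decays with $E$, so a band
that *gains* absorbance on oxidation simply fits with $a < 0$. One
functional form thus covers oxidizing and reducing branches.

### Preprocessing choices

* **Baseline**: each spectrum has the mean of its 650–700 nm absorbance
  subtracted. This region is featureless for the FeS chromophore, and a
  per-spectrum constant subtraction makes the fitted $E_m$ exactly invariant
  to wavelength-independent offsets (a tested property).
* **Band extraction**: the analysis value is the arithmetic mean of
  absorbances with $465 \le \lambda \le 485$ nm, endpoints inclusive,
  membership tested on the recorded grid with no interpolation — the
  simplest reproducible rule.
* **Drift**: thin-layer cells lose optical path during a run (capillary
  forces, evaporation). When the first and last spectra were poised at the
  same potential, their band-value difference measures the accumulated
  drift, and a ramp *linear in acquisition index*, anchored at that pair, is
  subtracted. Index is used rather than wall-clock time because timestamps
  are not part of the data model and acquisition order is a faithful proxy.
  Note the physical drift is multiplicative (a path-length factor), so the
  additive ramp is a first-order correction; on simulated data with 5% total
  drift it changes the fitted midpoint by well under a millivolt — the
  correction mainly tidies the plotted plateaus.
* **Normalization**: "normalized" admits several readings (divide by the
  maximal change, by the fitted amplitude, ...). We min–max scale the trace
  onto [0, 1] after drift correction. $E_m$ is invariant under any affine
  rescaling of the response, so this choice standardizes amplitudes across
  replicates without being able to bias the headline number.
* **Branches**: oxidizing and reducing sweeps are fitted jointly by default
  (one equilibrium midpoint per protein); `fit_titration(branch =
  "separate")` fits them independently and reports the midpoint difference
  as hysteresis for diagnostics.

### The fitter

For fixed $E_m$ the model is linear in $(a, c)$, so the conditional optimum
has a closed form and the residual sum of squares becomes a smooth 1-D
function of $E_m$. `fit_nernst()` scans this profile on a 2 mV grid over the
sampled range widened by 200 mV, then refines by golden-section search. This
has no starting-value sensitivity — important because the bootstrap calls the
fitter thousands of times — and it matches an exhaustive 0.1 mV grid search
(and an independent Levenberg–Marquardt fit) in the test suite. A midpoint
landing outside the sampled potential range is flagged `extrapolated` rather
than silently returned.

### Bootstrap uncertainty

Triplicate runs are processed independently; per-acquisition means and
standard deviations across replicates summarize them. `bootstrap_em_sd()`
draws 1000 synthetic datasets from the means with Gaussian noise of SD
`sd_scale × sds` (default scale 3), refits each, and reports the SD of the
resulting midpoint distribution. Replicates whose refit fails are dropped
and counted, with a 10% ceiling beyond which the call errors — silent bias
is worse than a loud failure.

The ×3 inflation makes the estimate *deliberately conservative*: fitting
per-point means of $n$ replicates responds to noise reduced by $\sqrt{n}$,
while the bootstrap re-injects three times the per-point SD. The test suite
therefore checks calibration where it is statistically meaningful — at
`sd_scale = 1` the mean bootstrap SD tracks the run-to-run spread of fitted
midpoints within a factor of two — and checks the default for what it is:
roughly three times larger, always an over- rather than under-statement of
the uncertainty.

## What the simulator emulates — and what it does not

`simulate_titration()` builds each spectrum as the Nernstian mixture of
reduced and oxidized component spectra (Gaussian-band caricatures with
oxidized gains across 320–380 and 420–580 nm), multiplied by a linearly
shrinking path factor $1 - d\,i/(N-1)$, plus i.i.d. Gaussian noise on every
0.5 nm wavelength sample. Defaults mirror the emulated experiment: a −50 to
+550 mV (vs SHE) ladder in 20 mV steps with the first potential repeated at
the end (anchoring the drift correction), triplicates, 5% total drift, and
noise at 2% of the analysis-band contrast. Potentials are written to file on
the reference-electrode scale (Ag/AgCl, +280 mV vs SHE) so the reading
pipeline genuinely exercises the offset conversion.

Not emulated: electrochemical-cell physics (iR drop, double layers, slow
equilibration), wavelength-correlated noise, multi-transition chromophores,
and pH dependence of $E_m$. Passing the recovery tests therefore shows the
*pipeline* is unbiased under its own assumptions — clean one-electron data —
not that any particular instrument behaves this well.

Problem sizes in the routine checks were chosen to give stable Monte-Carlo
estimates at interactive runtimes: 50 simulated triplicate experiments
(seeds 1–50) for the recovery study, 20 random-truth draws for the
generator's own property test, and 150–1000 bootstrap replicates depending
on whether a spread is being compared or reported.

## Geometry: cofactors, edges, pathways

`parse_structure()` reads PDB files (first model only; alternate locations
resolved to the highest-occupancy conformer, ties to the first) and
`identify_cofactors()` groups heterogroup atoms into instances by chain,
residue number and residue code, mapped through a registry (`HEM`→heme_b,
`HEC`→heme_c, `FES`, `SF4`, `F3S`, `FAD`, `NAP`/`NDP`). The registry is
user-overridable on purpose: residue codes encode the depositor's heme-type
assignment, and predicted models frequently mislabel *b*- versus *c*-type
hemes, so curated reassignments must be injectable.

**Edge-to-edge distance** is the minimum over heavy-atom pairs of the two
groups — the standard electron-tunneling metric. Which atoms constitute the
"edge" is a genuine convention choice: by default all heavy atoms of the
heterogroup count, including heme propionates and the FAD/NADP tails.
An optional `mode = "conjugated"` restricts hemes to the porphyrin
macrocycle plus iron, FAD to the isoalloxazine ring system, and NADP to the
nicotinamide ring and amide (FeS clusters are their own conjugated core).
The conjugated mode follows the common Moser–Dutton practice of excluding
substituents; both modes are exposed so the two can be reported when they
disagree materially.

`build_transfer_graph()` connects cofactors within a 20 Å cutoff and
classifies each edge: *efficient* at ≤ 15 Å (compatible with fast
physiological transfer) and *possible* in (15, 20] Å (transfer conceivable
but slow). `find_path()` returns the **bottleneck-optimal** route — the path
minimizing its longest single step, since the longest tunneling step
dominates a chain's overall rate — with deterministic tie-breaking by fewer
steps, then lexicographic label order. A 19 Å shortcut therefore loses to a
detour of 14 Å hops. Disconnected endpoints yield an explicit
`disconnected` result, not an exception.

Full-complex structural models are deliberately not bundled. The
measurement used on such models — how closely the soluble multiheme
cytochrome hemes approach the membrane-embedded cofactors — is exposed as
`group_min_distance()` and exercised on constructed fixtures; users with
local copies of predicted or experimental complex models can run the same
call on them directly.

## Energetics bookkeeping

The bifurcation ledger is pure potential arithmetic, on purpose — no free
parameters, no proton-motive-force terms (those depend on membrane state
and are discussed qualitatively in the field; mixing them into the ledger
would suggest more precision than exists). With the tabulated couples
(menaquinone-7 −70 mV, NAD(P) −320 mV, nitrite/NO +380 mV):

* favorable branch: $+380 - (-70) = 450$ mV released per electron;
* uphill branch: $-70 - (-320) = 250$ mV required;
* net $+200$ mV → coupling feasible on standard potentials.

Two heme estimates follow from empirical trends across characterized
complexes: the Rieske cluster and positive-side heme $b_P$ potentials sit
approximately symmetrically around the quinone potential, so
$E_m(b_P) \approx 2E_m(Q) - E_m(\text{Rieske})$ (−475 mV for a 335 mV
Rieske), and the negative-side heme lies ~130 mV above $b_P$ (the offset is
a parameter, defaulting to 130, precisely because the trend is approximate).
With the measured Rieske midpoints of 303 and 335 mV these give $b_N$
estimates of −313 and −345 mV; the implementation reports exact arithmetic
and does not round to any previously published figure. Whether the
"symmetry" should use the two-electron quinone/quinol midpoint or a
semiquinone couple is unresolved in the field; the single pool value is
used.

## Numerical conventions and degenerate inputs

* Potentials in mV vs SHE throughout; "favorable" = positive
  acceptor-minus-donor difference. $\Delta G = -nF\Delta E$ for unit
  conversion.
* Distances in Å, no periodicity.
* A constant trace (no transition) and an analysis band or baseline window
  without samples are errors, not silent NAs; window/band endpoints are
  inclusive.
* Fits require ≥ 4 points spanning more than $2RT/zF$; fewer points cannot
  constrain three parameters and a narrower span cannot locate a midpoint.
* All stochastic code takes an integer seed and restores the caller's RNG
  state; fixed seeds give byte-identical simulation output files.

## Known limitations

* Single-transition fits only: overlapping multi-cofactor titrations need a
  sum of transitions, which is out of scope.
* The drift model is first-order; severe path-length loss with a strongly
  structured trace would leave a residual tilt.
* Tunneling feasibility is judged on distance thresholds alone; no rate
  model (driving-force and reorganization-energy dependence) is computed.
* Toy structure templates are geometric stand-ins with canonical atom
  names, adequate for distance logic but not for chemistry.
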