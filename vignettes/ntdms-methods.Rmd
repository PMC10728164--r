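---
title: "Methods: native top-down MS of metal-bound protein complexes"
author: "ntdms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: native top-down MS of metal-bound protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntdms)
```

## Scope and model

`ntdms` implements the inference chain of a native top-down mass
spectrometry (nTDMS) experiment on an intact, non-covalently assembled
protein complex, using the human cardiac troponin (cTn) heterotrimer —
troponin C (TnC, the Ca²⁺ sensor), cTnI, and cTnT — as its worked system.
The chain has four stages, each usable on its own:

1. **Proteoform mass combinatorics.** A proteoform is a chain plus covalent
   modifications (acetylation +42.01057 Da, phosphorylation +79.96633 Da,
   Met1 excision −131.04049 Da), a metal-adduct set, and an optional
   terminal truncation. Assemblies are strictly additive: a non-covalent
   complex has the exact sum of its subunit neutral masses. Candidate
   compositions are enumerated from per-subunit grammars (ranges of
   phosphorylation count, Ca occupancy, flags), or from explicit itemized
   variant lists when the observed species set is not a full Cartesian
   product.
2. **Isotope-envelope deconvolution.** Isotopically resolved spectra are
   centroided, isotope clusters are collected at the 1.00235/z spacing,
   the charge follows from that spacing, and a theoretical envelope is
   aligned to each cluster to read off the monoisotopic mass.
3. **Fragment-based metal localization.** CAD b/y fragment ions that retain
   a position-dependent number of adducts bracket each adduct between the
   last fragment without it and the first fragment with it; b- and
   y-derived brackets are intersected and trimmed to acidic residues.
4. **Ion-mobility CCS analysis.** Reduced mobilities convert to collision
   cross sections through the Mason–Schamps equation
   CCS = (3/16)·√(2π/(μ k_B T))·(z e)/(N₀ K₀), with μ = mM/(m+M) the
   reduced ion–gas mass; mobilograms are summarized into conformers.

A seeded synthetic-data module generates MS1 charge-envelope spectra,
CAD fragment spectra, and mobilograms with ground-truth sidecars, so that
every recovery claim in the test suite is scored against a known answer.

## Mass conventions

All masses derive from one internal isotope table (exact isotope masses and
abundances for H, C, N, O, P, S, Ca), so monoisotopic masses, average
masses, and isotope envelopes are mutually consistent. Reported masses are
monoisotopic by default; the average scale is available for cross-checks.
m/z arithmetic uses a proton mass of 1.007276 Da and neglects the electron
mass, which is far below the ppm scale of interest for intact proteins.

Two conventions exist for the mass of a divalent metal bound to a species
observed as a neutral: **charge displacement** (the bound Ca²⁺ displaces
two protons; Δm = 39.96259 − 2 × 1.007276 = +37.94804 Da per Ca), and
**neutral addition** (Δm = +39.96259 Da). Native electrospray of a folded,
acidic Ca-binding protein is conventionally modeled as charge-displacing,
so that is the default; the mode is a config switch and is recorded in
labels and outputs, because printed literature MWs rarely state which
convention they used and the two differ by ~2 Da per metal.

Residue coordinates use full UniProt numbering including Met1 everywhere.
Met1 excision, when enabled, changes mass only — never reported indices.
This is forced by consistency of published fragment indices on the
161-residue TnC chain (e.g. y₉₄ starting at residue 68, y₅₂ at 110). Only
terminal truncations are modeled (e.g. C-terminal Lys loss).

## Deconvolution: a SNAP-style surrogate

The vendor SNAP picker is proprietary, so the package defines an explicit
surrogate and documents each choice:

* **Centroiding**: local maxima refined by three-point parabolic
  interpolation; sub-ppm accurate on Gaussian peaks sampled at ≥4 points
  per σ.
* **Noise / S/N**: peak height over 1.4826 × MAD of the *lower half* of
  intensities in a ±5 m/z window. Using the lower half keeps dense
  envelope flanks from inflating the noise estimate (a plain window MAD
  misclassifies signal as noise on noiseless or high-density spectra).
  The thresholds default to the common vendor settings: quality factor
  0.4, S/N 3.0, intensity 500 counts.
* **Cluster walking**: expected isotopologue positions stay anchored to
  the seed's isotope grid rather than re-anchoring on each found peak.
  A wrong-charge walk then accumulates spacing error and terminates,
  instead of drifting peak-by-peak along a true cluster.
* **Envelope alignment**: the averagine average-residue model
  (C₄.₉₃₈₄H₇.₇₅₈₃N₁.₃₅₇₇O₁.₄₇₇₃S₀.₀₄₁₇ per 111.1254 Da, constants fixed
  in code) supplies the theoretical envelope for unknown compositions;
  exact elemental envelopes are used wherever a formula is derivable. The
  fit score is the normalized dot product between observed intensities and
  theoretical probabilities; the match tolerance is the smaller of 10 ppm
  and a quarter isotope spacing, because at high m/z a ppm window can
  otherwise exceed the isotope spacing and degenerate.
* **Quality factor**: fraction of theoretical peaks above 1% relative
  probability found within tolerance — a declared approximation of the
  vendor quantity, not a claim of equivalence.
* **Off-by-one resolution**: candidate monoisotopic masses one isotope
  apart are compared by fit score; a tie within 0.1% relative score
  resolves deterministically to the lower mass and flags the species. The
  window is deliberately narrow: for a smooth ~77 kDa envelope the score
  difference between the true and a ±1-isotope alignment is itself well
  under 1%, so a wider tie window would override a clear winner and bias
  all large-protein masses low by one isotope.

Isotope envelopes are computed by exact convolution of per-element
distributions on the integer neutron-offset grid (binary exponentiation
over atom counts, probability-weighted exact mass per bin, tails below
10⁻¹⁵ relative dropped). This reproduces centroided isotopologue peaks at
any protein size without enumerating isotopic fine structure, which the
instrument classes modeled here do not resolve.

## Localization: interval algebra and its assumptions

For the k-th adduct along the chain (ordinal by position), the b-series
bracket is (i₍prev₎+1 .. i₍curr₎), where b at index i₍prev₎ carries k−1
adducts and b at i₍curr₎ carries k; the y-series bracket maps into
ascending coordinates through the precursor's total adduct count. The raw
interval is the intersection; an empty intersection is a structured error
naming both intervals (it means the evidence is internally inconsistent).
Trimming clips the raw interval to its first and last D/E residue, the
side chains with the highest Ca²⁺ affinity at neutral pH; an interval
with no D/E is returned untrimmed and flagged rather than discarded.

Two caveats are explicit in the interface. First, when no single fragment
carries all adducts, the b- and y-ordinal bookkeeping can only be aligned
through the true total adduct count of the precursor, which is known from
the MS1 level; `localize_adducts(..., n_adducts = )` takes it explicitly
and defaults to the maximum observed fragment count. Second, the procedure
presumes position-faithful adduct retention through CAD; the synthetic
generator implements exactly that model (with an optional per-adduct loss
probability, default 0), so the localization property tests validate the
algebra, not gas-phase chemistry.

Ordinals are positional. Where a binding order differs from chain order
(for cardiac TnC: domain III, then IV, then II), that is metadata about
energetics, not coordinates, and is reported as such.

## Mobility and CCS

The Mason–Schamps conversion is evaluated in SI units and returned in Å².
Constants are fixed: k_B = 1.380649×10⁻²³ J/K, e = 1.602176634×10⁻¹⁹ C,
N₀ = 2.68678×10²⁵ m⁻³ (the standard-condition number density consistent
with the reduced-mobility convention — instantaneous gas density is
deliberately unsupported to avoid double normalization), N₂ gas mass
28.0134 Da. The drift temperature defaults to 305 K, a typical
trapped-ion-mobility drift region value; source gas temperatures do not
apply to the drift region. It is configurable and recorded in outputs.

Mobilogram summarization detects local maxima, filters by prominence
(default 5% of the maximum intensity), refines apexes parabolically,
partitions the trace at inter-apex minima, and integrates each conformer
trapezoidally; shares are area fractions and sum to 1. Two conformers
closer than the prominence threshold merge into one — a documented
limitation, not an error. CCS-vs-charge structure is fit by ordinary least
squares.

## Synthetic data: what it emulates, and what it does not

The MS1 generator places each species' theoretical envelope at every
charge of a discrete-Gaussian charge envelope (default support 18–21
centered at 19 for the intact complex, 6–8 centered at 7 for the TnC
monomer, matching the charge states such complexes take up under native
electrospray), with Gaussian peak shapes at a default FWHM resolving power
of 150,000 (isotopic resolution at intact-protein m/z), additive baseline
noise (default level 20 counts against a tallest peak of 5×10⁴) and a 5%
per-peak intensity CV for "moderate noise" runs. The standard TnC fixture
mixes the 0/1/2/3-Ca states at proportions 0.2/0.2/0.5/0.1 — the relative
occupancies such preparations show, with the doubly bound state dominant
and structural sites mostly saturated.

Emulated: isotopic structure, charge envelopes, envelope overlap,
abundance proportions, baseline and multiplicative noise, CAD bond
sampling at a stated per-bond efficiency, position-faithful adduct
retention, Gaussian mobility peaks. Not emulated: isotopic fine structure,
FTICR line shapes and phase effects, space charge, chemical noise,
adduct scrambling, detector saturation. Passing recovery tests therefore
demonstrates correctness of the inference chain under its stated model,
not robustness to every artifact of real spectra.

Every generator is a pure function of (config, seed) and emits a truth
record (species masses and proportions, cleaved bonds and adduct
positions, conformer CCS and weights) sufficient to score any recovery
with no other inputs.

## Numerical and design choices

* Envelope truncation at 0.9999 cumulative probability, renormalized.
* Candidate matching is best-match-wins at a per-context ppm tolerance
  (defaults: 2 ppm intact species, 16 ppm monomer isolation spectra,
  20 ppm fragments), with lexicographic label tie-break; ambiguity is
  never resolved by intensity.
* The ejection ledger computes `parent − Σ products` exactly and flags
  consistency at the active tolerance; no automatic redistribution of
  metals between parent and products is attempted.
* The landscape total counts distinct species per isolation level and sums
  levels; the same molecular species seen at two levels counts at each,
  which is how a complex-up experiment tallies its proteoform landscape.
* The four-composition intact-complex list and the three-composition
  ejected-cTnT list shipped in `ctn_level_grammars()` are figure-derived
  defaults (the sources itemize them in annotations, not text) and are
  replaceable per run. The cTnT level is an itemized variant list rather
  than a Cartesian grammar because the unmodified-but-truncated corner is
  not observed.
* The printed ejected-TnC MW of 18,520 Da is not exactly reproduced by any
  single combination of Met1 excision, acetylation, and 0–3 Ca in either
  adduct convention on the P63316 chain; `nearest_composition()` reports
  the closest candidate and its signed ppm error instead of forcing
  agreement. (The nearest interpretations sit on the average-mass scale
  with neutral Ca addition.)
* Whether printed complex-level MWs are monoisotopic or average is often
  unstated; both scales are first-class throughout so either reading can
  be tested.
* The roundtrip CCS fixture for the intact complex assumes z = 20 (the
  charge used in chelator-titration analyses); the assumption is recorded
  with the fixture.

## Problem sizes used in the shipped tests

Test and acceptance runs use: TnC-scale MS1 spectra (~0.5 M profile
points, 12 isotope clusters) deconvolved in a few seconds; a 10-seed
repetition for the quantification recovery; 200 randomized
localization cases; 1000-replicate regression bias checks; and
4-mobilogram titration series. These sizes give stable statistics for
every asserted tolerance while keeping a full run in tens of seconds.

## Known limitations

* Unresolved (non-isotopic) charge envelopes are out of scope; the
  deconvolver requires isotopic resolution.
* c/z fragment chemistry (electron-based activation) is not modeled; only
  b/y ions from CAD.
* Phosphosite probability scoring is not provided; phosphorylation enters
  as composition counts unless positions are given.
* CCS calibration against tune-mix references and structure-based
  theoretical CCS are out of scope; the mobility module consumes
  calibrated 1/K₀ values.
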