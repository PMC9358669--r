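---
title: "Detecting protein-ligand binding from post-column protein-infusion LC-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protein-ligand binding from post-column protein-infusion LC-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nativems)
```

## The experiment this package models

In a native-metabolomics screen, a crude extract is separated by
reversed-phase LC while a target protein (here modeled on
alpha-chymotrypsin, ~25.2 kDa) is infused post-column under non-denaturing
electrospray conditions. Whenever a ligand elutes that binds the protein,
part of the protein signal shifts from the apo form to a protein-ligand
complex whose neutral mass exceeds the apo mass by the ligand mass (times
the binding stoichiometry). A second injection of the same extract without
protein infusion yields a conventional LC-MS/MS metabolomics run in the low
m/z range. Binders are identified by pairing the two runs: a complex whose
deconvoluted mass shift equals a metabolite's neutral mass, at the same
retention time, is evidence of binding.

`nativems` implements the full data-analysis chain for this design:

1. **Charge-state deconvolution** of native MS1 scans into neutral-mass
   species (`deconvolve_scan()`, `deconvolve_run()`).
2. **Mass traces and feature finding** on the deconvoluted protein side and
   on the small-molecule m/z side (`build_mass_traces()`, `detect_peaks()`,
   `build_protein_features()`, `build_metabolite_features()`).
3. **Complex-to-ligand matching** by mass offset and retention time
   (`match_complexes()`).
4. **Molecular networking** of the metabolite MS/MS spectra with typed
   binding edges (`modified_cosine()`, `build_network()`).
5. **Binding quantification**: titration-ratio fits, dilution-series LOD
   summaries and 4PL IC50 fits (`fit_titration()`, `summarize_dilution()`,
   `fit_ic50()`).
6. **Synthetic data** with planted ground truth (`screen_scenario()`,
   `simulate_native_run()`, `simulate_metabolomics_run()`), so that every
   stage is testable without instrument data.

## Mass bookkeeping

All m/z arithmetic is positive-mode protonation with charge-carrier mass
1.00727646677 Da (`PROTON_MASS`), which folds the electron mass into the
convention: m/z = (M + z·p)/z. Ion formulas printed for protonated species
(e.g. `C61H88N9O15` for an [M+H]+ ion) carry the extra hydrogen;
`theoretical_mh()` therefore removes one H, takes the monoisotopic mass of
the neutral molecule, and adds the proton mass. Under this convention the
reference [M+H]+ values of the Ahp-cyclodepsipeptides used in the test
suite reproduce within 1 ppm, e.g.

```{r}
ppm_error(1186.6400, theoretical_mh("C61H88N9O15"))
```

## Charge-state deconvolution

The deconvolution is a deliberately simplified charge-series-consistency
algorithm rather than an isotope-resolved method: the synthetic fixtures are
centroided envelopes without isotopic structure, and everything downstream
consumes only neutral masses and intensities.

For an MS1 scan, every peak above the noise floor proposes one neutral-mass
hypothesis per charge in `charge_range` (default 5-25). Hypotheses agreeing
within the intra-series tolerance — `max(0.05 Da, peak_tol × mass)` with
`peak_tol` 10 ppm — are clustered; a cluster survives if backed by at least
`min_charge_support` (default 3) distinct charges with no gap larger than
`max_charge_gap` (default 1) in the supporting charge ladder. Peaks are then
committed greedily to clusters in order of decreasing summed intensity (ties
broken toward the lower mass, for reproducibility), each peak supporting at
most one species; the species mass is the intensity-weighted mean of its
per-charge masses. The contiguous-ladder default doubles as structural
harmonic rejection — the doubled-charge ladder of a 2M artifact has gaps of
two and never reaches the support threshold — and, in addition, a candidate
whose mass is within tolerance of 2x, 3x, 1/2 or 1/3 of an
already-accepted, stronger candidate sharing at least half of its peaks is
discarded as a harmonic.

**Noise floor.** The default floor is `min(3 × median(intensity),
max(intensity)/100)`. Three times the median is the usual cut for centroid
scans dominated by a noise carpet; the cap matters for sparse scans in which
every centroid is real signal (there the median *is* signal and 3x median
would discard the scan outright). An absolute `noise_floor` can always be
supplied.

Species are linked across scans into neutral-mass traces with a ±`window`
(default 5 Da) mass window — the deconvoluted analog of an extracted ion
chromatogram. Traces require `min_scans` (3) observations and tolerate
`max_gap` (2) missing scans. `extract_xic()` produces the deconvoluted XIC
for any mass window, and `detect_apo_depletion()` finds the negative peaks
that appear in the apo trace where binders elute (rolling-median baseline,
default dip threshold 30%).

## Feature finding

`detect_peaks()` smooths the trace with a 5-point moving average, cuts it
into segments at baseline crossings, and splits a segment at the valley
between two local maxima only when the valley drops by at least
`min_prominence` (default 0.5) relative to both apexes. A segment with no
prominent internal maximum becomes a single feature spanning the segment.
This plateau rule is intentional: the apoprotein is infused at constant
concentration, so its trace is a noisy plateau over the whole gradient and
must surface as one spanning feature (which is what `apo_autodetect()`
relies on), not as dozens of noise wiggles. Areas are trapezoidal integrals
of the raw trace; peaks narrower than `min_width` (0.05 min) or lower than
`min_height` are dropped. The smoothing width, prominence and minimum width
are engineering defaults in the spirit of common LC-MS feature finders,
which do not prescribe exact values.

Metabolite features are built by tolerance-linking MS1 centroids across
scans (10 ppm), running the same peak detector per m/z trace, and attaching
MS2 scans whose precursor lies within tolerance of the trace m/z and whose
retention time falls inside the peak boundaries. A feature's co-elution with
a protein feature is quantified as the Pearson correlation of the two
profiles interpolated onto their common retention-time grid
(`coelution_correlation()`); without overlap the correlation is undefined
and treated as zero by the matching stage.

## Matching complexes to ligands

`match_complexes()` emits a match for every protein feature P, metabolite
feature L and stoichiometry n ≤ `max_stoichiometry` (default 2) with

> |(P.mass − apo_mass) − n·neutral(L)| ≤ mass_tol and |ΔRT apex| ≤ rt_tol,

with defaults of 4 Da and 0.2 min. The metabolite neutral mass assumes
[M+H]+ (proton subtraction); other adducts are out of scope. The result is
exactly the brute-force enumeration over all pairs, and matches are ranked
by protein retention time and then absolute mass error. All qualifying
matches are kept (the 4 Da window is wide by design and several isobaric
ligands can co-elute); no one-to-one assignment is forced, and the table
ranking plus co-elution score is the deduplication tool. Matches with n ≥ 2
are flagged, since higher apparent stoichiometry can indicate nonspecific
binding rather than a second site.

The apo mass itself is a user parameter. The reference experiment quotes
both a nominal 25,234 Da and a deconvoluted 25,232.6 Da for chymotrypsin
without resolving average-versus-monoisotopic; the package does not try to
resolve this either — `apo_autodetect()` (highest-area protein feature
covering ≥80% of the gradient) is only a convenience, and an explicit
`apo_mass` always wins. With the 4 Da tolerance the 1.4 Da discrepancy is
immaterial.

## Molecular networking

`modified_cosine()` is the GNPS-style analog similarity: square-root
intensity transform, unit L2 normalization, and fragment pairs admitted
either at equal m/z or offset by the precursor mass difference (tolerance
0.02 Da). Pairing is greedy by decreasing intensity product with a
deterministic tie-break; an exact maximum-weight pairing is available via
`method = "exact"` for small spectra, and the test suite verifies the greedy
score stays within 5% of the exact optimum on spectra with ≤6 peaks.
Operands are put in canonical order first so the score is exactly symmetric.

`build_network()` keeps msms edges with score ≥ 0.7 and ≥ 6 matched
fragments, caps each node at its `top_k` (10) strongest edges (an edge must
make the cut at both endpoints), and adds one typed binding edge per complex
match, annotated with the mass shift and co-elution correlation. The 0.7 /
6 / 10 defaults mirror common feature-based molecular-networking settings;
the reference study does not print its networking parameters, so these are
configuration with documented defaults. Networks export to GraphML
(`write_graphml()`) for Cytoscape.

## Binding quantification

*Titration.* The bound/unbound ratio against ligand concentration is fitted
with the 1:1 hyperbolic saturation model ratio(c) = Rmax·c/(Kd + c), which
passes through the origin and rises monotonically. The underlying solver
model of the reference workflow is unstated; the hyperbola is the natural
1:1 choice, and the fitted Kd is labeled *apparent* because gas-phase
response factors of apo and complex are unknown.

*Dilution series.* `summarize_dilution()` scores a concentration as
detected when its area exceeds blank mean + 3 blank SD, reports the LOD as
the bracket between the largest undetected and smallest detected
concentration, and fits a linear calibration over the detected range.

*IC50.* `fit_ic50()` fits the four-parameter logistic y(c) = bottom +
(top − bottom)/(1 + (c/ic50)^hill) by unweighted least squares and reports
the curve midpoint (relative IC50), matching common practice in
dose-response software. Whether the reference fits constrained the bottom
to zero is unstated; the package fits a free bottom by default and offers
`constrain_bottom = TRUE`. All nonlinear fits use `minpack.lm` with three
deterministically perturbed initializations (best residual sum wins);
failures are returned as flagged results, and a response that does not
decrease with concentration is flagged `no_inhibition` instead of being
fitted. Standard errors come from the local curvature of the fit.

## The synthetic-data generator

`screen_scenario()` fixes the study conditions: apo mass 25,232.6 Da;
charge envelope over z = 6-11 with Gaussian charge abundance (mean 8.5,
sd 1.2); acquisition window m/z 2500-4000 (native run) and 300-2000
(metabolomics run); a 10-min gradient; Gaussian elution peaks with sigma
0.03 min; 30 planted binders (masses 700-1400 Da, apex complex/apo ratios
0.2-0.8, grouped into families of five sharing an MS/MS fragment ladder)
and 20 lighter decoys. Charge states of an envelope that fall outside the
acquisition window are simply not recorded — as on the instrument — and an
error lists the charges only when the entire envelope misses the window;
for a 25.2 kDa protein in the 2500-4000 window that leaves z = 7-10.

Total protein ion current is conserved per scan: intensity gained by
complex envelopes is taken from the apo envelope, which is what produces
the depletion dips in the apo XIC. The default noise model applies 5%
log-normal intensity noise and 2 ppm m/z jitter to every centroid and adds
a low-intensity noise carpet (150 random centroids per native scan). MS/MS
spectra of family members share a fragment ladder in which eight fragments
are common and four shift with the precursor, so modified-cosine networking
groups families into components; decoys get unique ladders.

The MS1 scan interval defaults to 0.02 min (a 1.2 s duty cycle), chosen so
that a sigma = 0.03 min elution peak is sampled by roughly seven to nine
scans — enough for the trace builder's three-scan minimum and for adjacent
analog peaks to resolve under the 5-point smoother. Data-dependent MS/MS
picks up to two precursors per duty cycle above an intensity threshold with
0.1 min dynamic exclusion.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: isotopic envelopes and charge-state fine
structure, adducts other than [M+H]+, chimeric MS/MS, retention-time drift
between the paired runs, detector saturation, and matrix-dependent
ionization suppression. Real deconvolution problems are harder than the
centroided envelopes simulated here; the deconvolution module is validated
as a round-trip property (random masses in 10-60 kDa recovered from their
envelopes within twice the intra-series tolerance), not against
isotope-resolved reference software.

## Reproducibility and problem sizes

Every stochastic element is seeded: scenario generation, noise, and fit
initializations are deterministic functions of the scenario or call seed,
and the pipeline (`run_screen()`) writes byte-identical tables when re-run
on the same inputs. The test suite exercises the default 30-binder screen
(501 MS1 scans per run) end-to-end both noiselessly (100% planted-match
recall required) and under the default noise model (≥90% recall required),
plus property suites of 100 random deconvolution round trips, 100 random
matching tables against a brute-force oracle, and 50 random 4PL recovery
draws; these sizes keep the full suite around a minute while giving the
properties reasonable statistical weight. For the stochastic IC50 recovery
claim the midpoint estimator's sampling error at the stated design (5%
noise, n = 3) is about 5%, so the claim is asserted on the median error
over a fixed panel of seeds rather than on a single lucky draw.

## Limitations

Cross-sample retention-time alignment, spectral-library identification,
ion-identity networking, covalent-adduct discovery and absolute binding
affinities from single-point ratios are all out of scope. The
`apo_autodetect()` heuristic assumes the apoprotein is the dominant
spanning feature and will refuse to guess when two candidates are
comparably abundant. Deconvoluted masses from the simplified algorithm are
only as accurate as the centroid m/z values; with real isotope-resolved
data a dedicated deconvolution engine should be used upstream and its
feature tables imported via `read_feature_csv()`.
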