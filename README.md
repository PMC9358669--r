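# nativems

Detecting protein–ligand binding directly from LC-MS data, for natural-product
and chemical-biology groups running **native metabolomics** screens: a crude
extract is separated by reversed-phase LC, a target protein (e.g.
alpha-chymotrypsin, ~25.2 kDa) is infused post-column under non-denaturing
ESI conditions, and binders reveal themselves as protein–ligand complex ions
mass-shifted from the apoprotein. A parallel LC-MS/MS injection of the same
extract provides the small-molecule features and fragmentation spectra needed
to say *which* metabolite is binding.

## The core method

For each MS1 scan of the native run, multiply protonated ions are collapsed to
neutral masses via the positive-mode relation

> m/z = (M + z·p) / z,  p = 1.00727646677 Da,

using a charge-series-consistency algorithm: (peak, z) hypotheses that agree
in M across enough contiguous charge states form a species, peaks are assigned
greedily to the strongest species, and harmonics are suppressed. Species are
linked across scans into neutral-mass traces, and chromatographic peaks on
those traces become *protein features*; the constantly infused apoprotein
shows up as a spanning feature whose chromatogram dips wherever a binder
elutes (apo depletion). On the metabolomics side, m/z traces yield *metabolite
features* with linked MS/MS scans.

The linking step declares a match between protein feature P and metabolite
feature L with stoichiometry n when

> |(M_P − M_apo) − n·(m/z_L − p)| ≤ 4 Da and |RT_P − RT_L| ≤ 0.2 min,

i.e. the complex mass shift equals n ligand neutral masses (assuming [M+H]+)
at the same retention time. Matched ligands are placed in a molecular network:
GNPS-style modified-cosine edges (fragments pairing at equal m/z or offset by
the precursor difference) group structural analogs, and typed *binding* edges
connect the protein node to its ligands. Binding is quantified by hyperbolic
titration fits (ratio = Rmax·c/(Kd+c)), dilution-series LOD bracketing, and
four-parameter logistic IC50 fits y = bottom + (top−bottom)/(1+(c/IC50)^hill).

A seeded synthetic-data generator emulates both acquisitions — charge
envelopes with conserved protein ion current, Gaussian elution, DDA MS/MS
with family-shared fragment ladders, planted ground truth — so the entire
pipeline is testable without instrument files. See the methods vignette
(`vignettes/native-metabolomics.Rmd`) for models, parameters and limitations.

## Worked example

Simulate a screen with two planted binders (a rivulariapeptolide-like 1185.63
Da peptide at 5.5 min and molassamide, 962.4749 Da, at 5.0 min) against
chymotrypsin, then run the full pipeline:

```r
library(nativems)

sc <- screen_scenario(
  apo_mass = 25232.6,
  binders = data.frame(id = c("riv1185", "molassamide"),
                       ligand_mass = c(1185.6327, 962.4749), mz = NA,
                       rt = c(5.5, 5.0), width = 0.03, ratio = c(0.5, 0.4),
                       stoichiometry = 1L, family = c("riv", "mol"),
                       apex_intensity = 2e5),
  decoys = default_decoys(3), seed = 1)

nat <- simulate_native_run(sc)
met <- simulate_metabolomics_run(sc)
res <- run_screen(pipeline_config(native_run = nat$run,
                                  metabolomics_run = met$run,
                                  apo_mass = 25232.6,
                                  out_dir = "screen_out", seed = 1))
res$matches[, c("delta_mass", "ligand_neutral_mass", "mass_error",
                "rt_diff", "coelution", "stoichiometry")]
#>   delta_mass ligand_neutral_mass  mass_error rt_diff coelution stoichiometry
#> 1    962.488             962.476  0.01193138       0  0.999180             1
#> 2   1185.630            1185.635 -0.00453099       0  0.996704             1
res$depletion
#>    rt     depth
#> 1 5.5 0.3299663
```

Both planted binders are recovered: the deconvoluted complex mass shifts
(`delta_mass`, 962.49 and 1185.63 Da) agree with the ligand neutral masses
within ~0.01 Da, the runs co-elute (r > 0.99), and the apo chromatogram
shows a 33% depletion dip at 5.5 min where the stronger binder elutes
(the 0.4-ratio binder's ~29% dip sits just under the 30% reporting
threshold). `screen_out/` contains the feature tables, the match table, the
GraphML network and a QC report.

Potency fitting on synthetic dose–response data at the potency of the most
active isolated peptide (IC50 = 13.17 nM):

```r
fit <- fit_ic50(simulate_dose_response(ic50 = 13.17, noise = 0.05, seed = 1))
fit
#> <ic50_fit> IC50 = 12.68 (hill 1.08, top 100.2, bottom 1.894)
round(fold_change(862.60, 24.65))   # bromination-driven potency gain
#> [1] 35
```

A thin command-line wrapper with subcommands `simulate`, `deconv`,
`features`, `match`, `network`, `fit-titration`, `fit-ic50` and `run` is
installed under `exec/nativems`.

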