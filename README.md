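# rhoiq

Binding selectivity analysis for RHO GTPase–IQGAP interactions.

IQGAP scaffold proteins associate with the GTP-loaded forms of CDC42 and
RAC-like RHO GTPases but not with RHOA-like, RND, RHOD or RIF paralogs,
even though all of them share nearly identical switch I/II regions (the
canonical effector interface, residues 29–42 and 62–68). The residues
that decide selectivity must therefore lie outside the switches. `rhoiq`
implements the computational pipeline behind that kind of study, for
biochemists and computational biologists who work with GTPase–effector
kinetics:

* **Stopped-flow kinetics** — mass-action simulation of association,
  displacement, competition, GAP and GEF experiments, single-exponential
  trace fitting, and inference of the rate constants. Under
  pseudo-first-order conditions the observed rate is
  `kobs = kon·[E]0 + koff`, so the slope of kobs against effector
  concentration gives the association rate constant kon, a displacement
  experiment gives the dissociation rate koff directly, and
  `Kd = koff/kon`. The estimator additionally corrects for effector
  depletion at finite receptor concentration (via the exact relaxation
  rate `kobs = kon·sqrt((R0+E0+Kd)² − 4·R0·E0)`) and for effector
  rebinding during displacement.
* **Hotspot discovery** — alignment positions conserved within IQGAP
  binders (consensus frequency ≥ 0.8), deviating in physicochemical
  class in nonbinders (fraction ≥ 0.6), outside the switch regions,
  grouped into sites within a 7-position window.
* **Sequence statistics** — G-domain net charge (+1 per K/R, −1 per
  D/E), charged-locus alignment reduction, pairwise global identity,
  residue-swap variant construction.
* **SEC stoichiometry** — partition coefficients
  `Kav = (Ve − V0)/(Vc − V0)`, calibration against log10 mass, apparent
  masses, and integer complex composition.
* **Structure** — heavy-atom distance interface mapping and hotspot
  proximity classification on PDB coordinates.
* **Synthetic data** — seeded generators for traces, labelled
  alignments, elution profiles and toy complexes, so everything runs and
  is tested offline.

## Worked example

Recover the rate constants of the tightest binder (RAC2-like fixture,
ground-truth Kd 27 nM) from seeded noisy synthetic traces, then run the
hotspot and charge analyses on the bundled 14-member G-domain panel:

```r
library(rhoiq)

est <- run_full_estimation("rac2", sigma = 0.02, seeds = 1:5)
cat(sprintf("kon  %.2f /uM/s\nkoff %.3f /s\nKd   %s (method: %s)\n",
            est$kon, est$koff, est$kd_formatted, est$koff_method))
#> kon  8.03 /uM/s
#> koff 0.213 /s
#> Kd   26.5 nM (method: displacement)
```

Five association traces (2–8 µM effector) and one displacement trace
per seed were simulated with 2% Gaussian noise and refitted; the
recovered Kd lands within 2% of the 27 nM ground truth, and
`koff_method` reports that the dissociation rate came from the
displacement experiment (authoritative for slow-dissociating
complexes).

```r
res <- find_hotspots(synthetic_rho_panel())
res$positions
#> [1] 25 26 45 52 74 85 88
lapply(res$sites, `[[`, "members")
#> [[1]] 25 26   [[2]] 45 52   [[3]] 74   [[4]] 85 88
```

The panel (5 binders, 9 nonbinders; three transcribed sequences plus
eleven documented synthetic stand-ins) yields four grouped sites at the
selectivity loci, all outside the switch regions.

```r
charge_table(core_sequences()[c("RAC1", "CDC42")],
             alignment = synthetic_rho_panel())
#>          id n_K n_R n_D n_E net_charge
#> RAC1   RAC1  13   7  12   9         -1
#> CDC42 CDC42  15   4  11  12         -4

infer_stoichiometry(228, 795 * (189.25 / 1657),
                    molecular_mass(core_sequences()$RAC1, gppnhp_mass()))
#> <Stoichiometry> 2:2, predicted 222.4 kDa (|error| 5.6)
```

The G-domain net charges are −1 (RAC1) and −4 (CDC42), and an observed
228 kDa SEC peak resolves to a 2:2 heterotetramer of the IQGAP
C-terminal fragment with nucleotide-loaded RAC1.

A thin command-line launcher (`inst/scripts/rhoiq`) exposes the same
functionality as subcommands (`netcharge`, `hotspots`, `simulate`,
`estimate`, `competition`, `sec`, `interface`, `make-fixtures`,
`reproduce`); run it without arguments for usage.

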