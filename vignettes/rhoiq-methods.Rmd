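---
title: "Methods: how rhoiq models RHO GTPase-IQGAP binding selectivity"
author: "rhoiq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how rhoiq models RHO GTPase-IQGAP binding selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhoiq)
```

## The scientific problem

IQGAP scaffold proteins bind the GTP-loaded (active) forms of some
RHO-family GTPases — CDC42 and the RAC-like paralogs — but not others
such as RHOA, the RND proteins, RHOD or RIF, even though all of these
share nearly identical switch I/II regions (residues 29–42 and 62–68 in
CDC42/RAC numbering), the canonical effector interface. Selectivity
must therefore be encoded by residues outside the switches. The
analytical route to that conclusion combines four kinds of computation,
each implemented here as a reusable, tested module:

1. stopped-flow kinetics: observed rates from single-exponential fits,
   kon/koff/Kd from concentration series and displacement experiments,
   and competition/GAP/GEF schemes simulated as mass-action systems;
2. discrimination of specificity-determining alignment positions
   (conserved in binders, deviating in nonbinders, outside the
   switches);
3. net-charge statistics of G-domains (electrostatic character);
4. size-exclusion chromatography (SEC) calibration arithmetic and
   integer stoichiometry inference, plus distance-based interface
   mapping on atomic coordinates.

A seeded synthetic-data module generates every input, so the entire
pipeline runs and is tested offline.

## Kinetic model and estimation protocol

All binding reactions are treated as mass-action schemes in µM and
seconds: association `R + E <-> RE` (`kon` in µM⁻¹s⁻¹, `koff` in s⁻¹,
`Kd = koff/kon`), two-ligand competition `R + E <-> RE`, `R + C <-> RC`
with mutually exclusive binding, displacement of a pre-formed complex
by an unlabelled scavenger, GAP-stimulated hydrolysis of the free (but
not effector-bound) GTPase, and GEF-catalysed nucleotide exchange.
Schemes are integrated with a stiff-capable solver (`deSolve::lsoda`,
rtol 1e-8, atol 1e-12) because rate constants span several orders of
magnitude; for plain association the exact analytic solution of the
reversible bimolecular rate equation is also available
(`association_closed_form()`) and the two agree to better than 1e-4,
which the test suite asserts.

The fluorescence readout is modelled as
`baseline + span * [RE]/R0` with additive iid Gaussian noise whose
standard deviation is given as a fraction of the span and is always
seeded. The instrument dead time (2 ms) is truncated from every trace.
Real stopped-flow data differ in ways we deliberately do not model:
photobleaching and lamp drift, mixing artefacts, and correlated noise.
Passing recovery tests therefore demonstrates correctness of the
estimation arithmetic, not robustness to every instrument pathology.

The default mixing concentrations are the study conditions: 0.2 µM
labelled GTPase mixed with 2 µM effector for the association screen,
2–8 µM effector for the kon series, 20 µM premixed competitor (10-fold
molar excess over effector) for competition, and 10 µM unlabelled
displacer for dissociation.

### From traces to rate constants

`run_full_estimation()` follows the classical protocol — fit each
association trace with a single exponential, regress kobs on effector
concentration, take koff from a displacement trace — and adds three
corrections that the protocol needs at finite receptor concentration:

* **Depletion-exact rate law.** With `R0 = 0.2` µM and `E0 = 2` µM the
  effector is only in 10-fold excess, and the straight line
  `kobs = kon*E0 + koff` is biased at the percent level. The exact
  relaxation rate of the reversible bimolecular scheme,
  `kobs = kon * sqrt((R0+E0+Kd)^2 - 4*R0*E0)`, is fitted instead (the
  ordinary least-squares slope/intercept are still reported).
* **Shape-bias calibration.** Even noiselessly, a single-exponential
  fit of the exact bimolecular curve returns a rate slightly different
  from the true relaxation rate. The estimator removes this by fitting
  the same single exponential to model-generated curves at the current
  parameter estimate (on the same time grid) and rescaling the observed
  rates by the resulting ratio, iterated three times.
* **Displacement rebinding and premix.** The displacement simulation
  premixes the complex equimolar (`E0 = R0`): a free-effector excess in
  the premix would superimpose a scavenging transient on the decay.
  Even then, the scavenger pool holds a small free-effector
  concentration at exchange equilibrium, which adds `kon*Efree` to the
  fitted decay rate; the estimator subtracts this term
  self-consistently. The capture transient (`t < 5/(kon*U0)`) is
  excluded from the fit window.

Displacement-derived koff is authoritative for slow-dissociating
complexes. When dissociation is fast compared to the scavenging rate
(`koff > 0.15 * kon * U0`, judged on the series estimate) the
displacement trace has no resolvable exponential phase, and the
series-derived koff is used instead — this is the regime of the weak
GRD-CDC42Q61L interaction and of the hotspot-swap variants. With these
choices, noiseless estimation reproduces every fixture entry's kon,
koff and Kd to well within 1%, and seeded noisy estimation (sigma 0.02,
five replicates) recovers the anchored Kd values within a few percent.

### Competition classes

Competition outcomes are summarised by the amplitude ratio
`rho = amplitude(with competitor)/amplitude(without)`, measured
model-free from first/last signal deciles so that fully suppressed
(flat) traces need no exponential fit. The class thresholds —
`rho >= 0.8` unaffected, `rho <= 0.1` complete suppression, otherwise
partial — are package conventions (the original comparison is
qualitative) and are always reported next to the raw ratio. The
three-class pattern is reproduced by construction-independent
competitor kinetics: a fast, tight competitor abolishes the signal; a
fast competitor of moderate affinity partially suppresses it; a slow
competitor of comparable affinity leaves it untouched even at 10-fold
excess — kinetics, not equilibrium affinity, decide the outcome on the
stopped-flow timescale.

## Ground-truth fixture table

`make_kinetics_fixture()` encodes the published anchors as exact
invariants: Kd(rac2) = 27 nM; Kd(rac1) = 34 x Kd(rac2), split as a
4.25-fold slower kon and 8-fold faster koff (the published 4x and 8x
round to 32, while the printed Kd ratio is 34; the Kd ratio is taken as
authoritative and the kon split adjusted to 4.25); Kd(cdc42) =
Kd(rac1)/3; Kd(grd_cdc42q61l) = 2.37 µM; the four RAC1 hotspot-swap
variants sit between 7- and 17-fold above Kd(rac1) with slower
association and faster dissociation. Absolute kon values are package
choices in the typical effector range (1–10 µM⁻¹s⁻¹) because the
underlying per-protein table is not public; each entry records this
provenance.

## Hotspot discovery

Positions are named in the numbering of a reference row (CDC42). For
every column with a reference residue the finder computes the binder
consensus and its frequency `f_b` (ties broken alphabetically for
deterministic reports) and the nonbinder deviation `d`, the fraction of
nonbinder rows whose residue falls in a different physicochemical class
(hydrophobic / polar / positive / negative; histidine counts polar,
gaps are their own class, never conserved and always deviating). A
column is a candidate when `f_b >= 0.8`, `d >= 0.6`, and the reference
position lies outside switch I/II. Candidates closer than 8 positions
(window 7) are grouped greedily into sites.

Class-level (rather than strict-residue) deviation is deliberate: a
locus where binders carry asparagine and nonbinders glutamate should
count as deviating, but binders split between serine and threonine
should not. The thresholds are conventions chosen once so that a
14-member panel with realistic variability yields the four documented
sites (25/26, 45/52, 74, 85/88); they are explicit `hotspot_config()`
parameters, surfaced in every result, and the suite verifies that
tightening them never adds positions.

### The bundled panel is partly synthetic

No sequence database is bundled or fetched. The package ships
hand-transcribed construct sequences for RAC1 (aa 1–179), CDC42
(aa 1–178) and RHOA (aa 1–181) that were cross-checked against
published residue landmarks (hotspot residues T25/N26/M45/N52/Q74/V85
and A88/S88; the RHOA wild types K27/D28/E47/E54/D76 of the five-residue
swap; the G-domain net charges −1 and −4) — they are transcriptions,
not downloads, and are labelled accordingly. The remaining eleven
panel rows (`*_SYN`) are synthetic stand-ins derived from those
backbones: nonbinders carry the RHOA-type residues at the seven
selectivity loci, the RAC2 stand-in carries its published
distinguishing residues (S48/Y90/D150), every derived row receives
seeded same-class substitutions as neutral variation, and a
discriminating column is planted inside switch I as a negative control
for the region exclusion. Analyses of this panel exercise the
algorithms end to end on realistic input; they do not substitute for
the database sequences, and the hotspot result on real alignments
should be reproduced by supplying an aligned FASTA to the `hotspots`
subcommand.

## Net charge and G-domains

`net_charge()` implements the simple electrostatic census: +1 per
lysine or arginine, −1 per aspartate or glutamate, everything else
(including histidine) neutral. The physiologically debatable choices
(no histidine, no termini, no pKa model) follow the published rule
exactly, because the statistic's purpose is cross-paralog comparison,
not absolute charge prediction. The G-domain is defined as the residues
aligning to CDC42 1–178 via the package alignment, which excludes the
hypervariable C-terminal tail; `charge_table()` can also use raw
construct ranges. For the bundled RAC1 and CDC42 constructs both
definitions give the same integers (−1 and −4).

## SEC arithmetic

The partition coefficient is `Kav = (Ve − V0)/(Vc − V0)` with V0 = 8 mL
and Vc = 24 mL by default; calibration is a least-squares line of Kav
against log10 mass, required to have negative slope. Peaks are local
maxima with three-point parabolic apex refinement on the 0.02-mL grid;
overlapping-peak deconvolution is out of scope. Stoichiometry inference
searches copy numbers a, b in 1..4 minimising the absolute mass error,
with ties broken toward fewer total copies then fewer copies of the
first component; both copy numbers start at one because the inference
is applied to peaks in which both components were detected on the gel.
The bundled calibration standards (13.7–669 kDa) are synthetic — the
actual column calibration of the original experiments is not public —
so tests assert the round-trip identity of the calibration line and the
integer composition, not absolute masses. A GppNHp nucleotide mass of
0.52 kDa is added to GTPase chain masses because the complexes are
nucleotide-bound; the observed 228 kDa then resolves to a 2:2
heterotetramer against the sequence-derived RAC1 mass and the IQGAP
C-terminal fragment mass scaled from the canonical full-length protein.

## Interface mapping

Interface analysis is purely geometric: a residue is interfacial iff
any of its heavy atoms (element ≠ H) lies within 4.5 Å of a heavy atom
of the partner group, with distances exactly at the cutoff included;
"proximal" means within 8 Å. Both cutoffs are explicit flags — the
original figures state no numbers — and the suite checks symmetry,
monotonicity in the cutoff, and exact agreement with an all-pairs
oracle. Alternate locations keep conformer A; insertion codes are
rejected rather than silently renumbered; author numbering is
preserved. Surface-area-based interface definitions and electrostatic
potential maps are out of scope.

## Problem sizes and determinism

The test suite and the acceptance script are sized for a single CPU:
traces of 200 points, four association concentrations plus one
displacement per estimation, five replicate seeds for noisy recovery,
1000 random instances for the stoichiometry oracle, 400 atoms for the
interface oracle, and a 14 x 178 alignment panel. Every stochastic step
takes an explicit integer seed and derives per-trace seeds from it;
re-runs are byte-identical, which the suite asserts.

## Known limitations

* The three transcribed sequences are corroborated by published
  landmarks but remain transcriptions; all other panel rows are
  synthetic, so panel-level results are demonstrations of the method,
  not biological claims about the paralogs they are named after.
* The IQGAP C-terminal fragment sequences are not included, so the
  published 72% fragment identity cannot be recomputed offline; the
  corresponding check fails by design until a user supplies the
  accession FASTA.
* Single-exponential fitting is the only trace model (as in the
  original protocol); multiphasic traces are out of scope.
* Competition classification thresholds and the contact/proximity
  cutoffs are package conventions, reported with every result.
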