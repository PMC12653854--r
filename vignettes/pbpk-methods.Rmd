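---
title: "PBPK modeling of clobazam, N-desmethylclobazam and stiripentol: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PBPK modeling of clobazam, N-desmethylclobazam and stiripentol: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model
structure, the parameters that matter, the numerical choices, what the
synthetic-data machinery does and does not emulate, and the known
limitations. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The problem

Dravet syndrome patients are commonly co-treated with clobazam (CLB)
and stiripentol (STP). CLB is demethylated by CYP3A4, CYP2C19 and
CYP2B6 (70/19/11% of its enzymatic clearance) to the active,
long-lived metabolite N-desmethylclobazam (N-CLB), which is eliminated
almost exclusively by CYP2C19. STP competitively inhibits several CYP
isoforms — most potently CYP2C19 (optimised ki 0.0139 uM, a 10-fold
reduction of the in vitro 0.139 uM, analogous to the established in
vitro/in vivo potency gap of fluvoxamine). Adding STP therefore leaves
CLB exposure nearly unchanged but multiplies N-CLB exposure several
fold in CYP2C19 extensive metabolizers (EM), while poor metabolizers
(PM) — who already run ~10-fold higher N-CLB — see a slight *decrease*
because their CYP2C19 cannot be inhibited further and STP's CYP3A4
inhibition reduces N-CLB formation. The package rebuilds this system
as a whole-body PBPK model, replicates the published pediatric
drug–drug interaction (DDI) studies, extrapolates to infants of six
months, and quantifies parametric sensitivity.

## Model structure

Each compound is described by a 15-state whole-body model: an oral
depot; twelve perfusion-limited tissues (adipose, bone, brain, gut,
heart, kidney, liver, lung, muscle, skin, spleen, pancreas); venous
and arterial blood. Two bookkeeping states track cumulative
elimination and metabolite formation. Up to three compounds are
integrated simultaneously (CLB + N-CLB + STP), coupled through (a) the
parent-to-metabolite formation flux, delivered mole-converted into the
metabolite's liver compartment, and (b) dynamic competitive
inhibition, in which each isoform's intrinsic clearance is multiplied
by $1 / (1 + \sum_i I_{u,i}/k_{i,i})$ evaluated at every solver step
from the current unbound liver concentration of each inhibitor
($I_u = f_{u,p} C_\mathrm{liver} / K_{p,\mathrm{liver}}$, i.e. the
unbound plasma-equivalent exposure in the liver, which transiently
exceeds systemic exposure during absorption through the portal vein).
A compound's own occupancy is excluded from the factor applied to its
own clearance: stiripentol's auto-inhibition is represented
empirically by its regimen-dependent clearance anchors, and modelling
it mechanistically as well would double-count the non-linearity.

Tissue partitioning uses the unified tissue-composition method for
neutrals and monoprotic bases: partitioning into tissue water (with
Henderson–Hasselbalch ionisation, plasma pH 7.4, intracellular pH
7.0), neutral lipid and phospholipid (log P-driven; the adipose
neutral-lipid term uses the vegetable-oil:water relationship
$\log D_{vo} = 1.115 \log P - 1.35$), and albumin-type binding scaled
from $1/f_{u,p}$ by tissue:plasma albumin ratios. CLB (pKa 6.65) falls
below the pKa-7 criterion and is treated in the weak-base/neutral
family; the strong-base acidic-phospholipid family is implemented but
unused by the built-in compounds. With the packaged composition
tables the method predicts Vss of 0.42 L/kg for STP unscaled (1.64
with its 4.2 Kp scalar) and 0.54 L/kg for CLB — the package's
reproduction of the published 0.45/1.74/0.56 L/kg. For N-CLB the
published table is ambiguous about whether its 1.04 L/kg prediction
is pre- or post-scalar; both are computable
(`compute_vss(predict_kp(x))` with or without `apply_kp_scalar`), and
the value is not used as a calibration target.

## Clearance anchoring

The models are calibrated middle-out, on whole-organ clearances
printed for each compound, never on per-pmol intrinsic clearances
(which depend on unpublished abundance conventions; the per-pmol
representation is available as `clint_per_pmol()` but is
informational).

* **CLB**: total hepatic plasma clearance 2 L/h, of which 1.4 L/h is
  the enzymatic, N-CLB-forming portion (split 70/19/11 across
  CYP3A4/2C19/2B6) and 0.6 L/h is an additional systemic clearance
  representing the minor 4-hydroxylation route — non-inhibitable, not
  metabolite-forming, acting on venous plasma, and scaled across ages
  with liver mass x MPPGL since it is hepatic metabolism in
  disguise. The enzymatic 1.4 L/h is converted to unbound intrinsic
  clearance by inverting the well-stirred liver model,
  $CL_{int,u} = Q_h CL_b / (f_{u,B}(Q_h - CL_b))$.
* **N-CLB and STP**: the printed anchors are *apparent oral plasma
  clearances*. For these the retrograde relation
  $CL_{int,u} = f_a \, CL_{po} / f_{u,p}$ is used. This is not a
  stylistic choice: STP's low-dose anchor of 70 L/h corresponds to
  121 L/h of blood clearance, above the ~90 L/h hepatic blood flow,
  where the well-stirred inverse has no solution — the first-pass
  term cancels in the oral relation, which also makes the model
  self-consistent (simulating the reference adult returns the
  anchored CL_po as its oral clearance).
* **STP non-linearity**: dose- and regimen-dependent anchors
  (adult single 300 mg → 70, 500/600 → 60, 1000/1200 → 35,
  2000 → 25 L/h; adult multiple 1200–1800 mg/day → 17, 3000 → 8;
  pediatric < 6 y → 14, ≥ 12 y → 8 L/h) selected by nearest anchor
  with no interpolation, fixed over a simulation. This mirrors the
  fitted-clearance representation rather than Michaelis–Menten
  kinetics, for which no in vitro parameters exist.

Anchors are always converted to intrinsic clearance *in the reference
adult* and then scaled to each individual. Anchoring inside a
pediatric body would be circular (the same pediatric anchor would
imply an adult oral clearance of ~67 L/h for the multiple-dose
regimen, contradicting the printed adult anchor of 17 L/h).

The individual scaling is multiplicative:
ontogeny fraction (isoform- and age-specific) x liver mass x MPPGL
relative to the adult x a log-normal abundance variability multiplier
(one per isoform per subject, shared across compounds so that a
subject's CYP2C19 affects both N-CLB elimination and the CLB 19%
pathway coherently) x the CYP2C19 phenotype multiplier. The
non-enzyme-assigned residual of STP clearance (24.5%) scales with
liver size only — no ontogeny, no inhibition. Renal clearances scale
with the GFR age fraction.

**Poor-metabolizer multiplier.** PMs carry a CYP2C19 multiplier of 0
(no functional enzyme), configurable in `population_spec()`. A small
positive floor looks harmless but is not: with any inhibitable
CYP2C19 residue, adding STP *increases* PM N-CLB exposure, whereas
the replicated clinical data (and the published simulations) show a
slight decrease (ratio ~0.9) driven by CYP3A4 inhibition of N-CLB
formation against a fixed renal elimination. Division guards, not a
numerical floor, handle the degenerate abundance.

## Physiology, ontogeny, population

The reference adult (81 kg male; hepatic blood flow 87 L/h; liver
1775 g; MPPGL 40 mg/g; meta-analysis CYP abundances; GFR 7.2 L/h) and
all age tables live in `inst/extdata/physiology.yaml` with per-value
source notes; a path override lets users substitute their own file.
Pediatric scaling: body weight from sex-specific WHO/CDC medians;
liver and brain volumes from organ-specific tables (ICRP/Johnson-type
values); remaining organ and blood volumes proportional to body
weight; flows with allometric cardiac output ($BW^{0.75}$); MPPGL and
GFR from their own tables; abundances by tabulated ontogeny curves
(linear interpolation) with CYP2C19 rising from 30% of adult at birth
to adult level by about two years. Supported age range 0.5–25 years;
outside it `scale_to_age()` errors rather than extrapolating.

Virtual populations draw age uniformly over the design range, sex by
the stated proportion, log-normal inter-individual variability with
default CVs of 30% on CYP abundances and ka and 15% on fu,p (the
study reports that variability exists but not its magnitudes; these
are typical mid-range values for hepatic enzymes and absorption), and
the CYP2C19 phenotype by the design frequency. Everything is a pure
function of the `PopulationSpec` seed. STP's absorption lag is
sampled per subject from U(0.5, 1) h, a uniform reading of the
published 0.5–1 h range.

## Trials and the DDI design

`run_ddi_study()` uses a within-subject two-arm design: each subject
is simulated once with the perpetrator added after the baseline phase
and once without it, with identical physiology, random effects and
victim dosing; troughs are read pre-dose at the same final study day
in both arms and dose-normalized to 1 mg/kg/day CLB. Sampling both
arms at the same day — rather than comparing end-of-phase-1 with
end-of-phase-2 — matters in PMs, whose N-CLB half-life of 2–3 weeks
means the phase-1 trough still sits ~7% below plateau at day 28; the
phase-difference design would measure ~1.0 instead of the true ~0.9
ratio. For the same reason the PM replication presets run 84-day
phases (the STICLO preset keeps its historical 1 + 2 months).

The three replication presets encode the published designs: STICLO
(ages 3–16, CLB 0.5 mg/kg/day, STP 25 mg/kg BID), the Japanese add-on
trial (ages 1–24, CLB 1 mg/kg/day, STP 25 mg/kg BID, with a
PM-stratified variant) and the retrospective Japanese cohort (STP
17.5 mg/kg BID). The STP clearance anchor is chosen by the study's
mean age (~9.5 y → 8 L/h for all three). The published STICLO text
says "up to 0.5 mg/kg/day" CLB while the summary table labels rows
"CLB 1 mg/kg QD"; dose-normalization reconciles them, and both doses
are expressible through the regimen objects.

`pediatric_extrapolation()` simulates fixed-age groups (default 0.5,
0.75, 1, 1.5, 2 years; 10 trials x 10 subjects, 1:1 sex) on CLB
0.5 mg/kg/day + STP 50 mg/kg/day BID with the under-six anchor of
14 L/h for three months, and summarises steady-state C_avg over the
final dosing interval against the therapeutic reference windows (CLB
0.03–0.3, toxic > 3 mg/L; N-CLB 0.3–3, toxic > 12 mg/L; STP effective
4–25 mg/L). All age groups share one seed (common random numbers), so
between-age contrasts are not diluted by sampling noise.

## Numerics

`deSolve::lsoda` with rtol 1e-6 and atol 1e-9 mg; the right-hand side
is compiled C (12-tissue, up to 3 compounds, 51 states). Doses are
state reinitialisations of the depot (events), shifted by the
absorption lag; only `fa x dose` enters the depot and the unabsorbed
remainder is carried in the mass-balance ledger, which closes to
< 1e-4 of the administered dose at every output time (asserted in the
suite). Output rows at event times hold the pre-event state. Trough
sampling uses explicit pre-dose time points. A full 84-day
three-compound pediatric subject integrates in ~0.5 s, which sets the
study sizes used in the tests: the replication presets run the
published 10 x 10 design, and the acceptance checks complete in a few
minutes.

Tie-breaks and degenerate inputs: T_max ties resolve to the earliest
time; terminal half-life requires >= 3 post-peak points with
r² >= 0.9 and is otherwise flagged NA; AUC uses linear-up/log-down
(log-trapezoid only on strictly descending positive segments);
zero-width dosing or empty regimens yield zero trajectories rather
than errors.

The Morris screen works on the unit-cube scale (so elementary effects
are comparable across parameters with different units), r = 20
trajectories on a p = 4 grid by default. Sobol indices use Saltelli
sampling with the centered first-order estimator and the Jansen
total-effect estimator plus bootstrap percentile intervals; the
centering matters — it cuts the Monte-Carlo error of S1 several-fold
at the default N = 1024. GSA outputs are AUC(0–24 h) and C_max of a
single dose in the reference adult with the whole-liver intrinsic
clearance held fixed: with CLint fixed, varying fu,p propagates to
hepatic clearance the way the well-stirred model dictates, and a
*truncated* AUC is the only exposure metric through which
distribution parameters (logP, Kp scalar) can act at all — the AUC to
infinity of a linear model is clearance-determined and would be
insensitive to them by construction.

Fitting minimises the sum of squared *log*-concentration residuals
(proportional-error assumption) with bounded L-BFGS-B and multistart;
fits are to mean profiles, matching how digitised mean data were fit
originally. An identifiability guard requires >= 3 observations per
free parameter.

## Synthetic data

The generator emulates the study's two input classes: digitised-style
mean concentration profiles (model truth in the reference adult plus
mean-unbiased multiplicative log-normal noise, default CV 15% — a
typical assay-plus-digitisation error) and steady-state pediatric
trough collections (population simulation plus assay noise, phenotype
labels attached). Ground truth is always stored alongside the noisy
values, and every dataset is exactly reproducible from its spec and
seed; `fixture_suite()` writes a standard pack with an MD5 manifest.
What the generator does *not* emulate: digitisation bias (systematic
misreading of axes), inter-study heterogeneity in formulations or
assays, dropout, or sparse opportunistic sampling patterns of real
retrospective data. Passing recovery tests therefore demonstrate that
the estimation machinery is consistent — not that the original
literature profiles would be recovered.

## Known limitations and honest misses

* **Infant absolute exposures.** With open-literature pediatric
  tables, an infant's hepatic capacity per kg is ~0.45–0.55 of the
  adult value, and the simulated six-month steady-state averages come
  out ~2-fold (STP) to ~3-fold (N-CLB) above the published values,
  which imply near-adult per-kg oral clearance at six months. The
  gap traces to the proprietary simulator's pediatric system
  parameters (liver mass x MPPGL x ontogeny products ~1.5–2x larger
  than the open sources packaged here support); the acceptance report
  computes and reports the values as simulated.
* **N-CLB age trend.** Under ~40-fold CYP2C19 inhibition by
  stiripentol, the growth of N-CLB formation with age and the growth
  of its (renal + inhibited hepatic) clearance cancel almost exactly,
  leaving the 6-month-to-2-year exposure profile flat within ~1%
  rather than rising. The published mechanism for the rise — CYP2C19
  maturation increasing conversion — cannot operate while that
  pathway is ~97% inhibited, so this discrepancy is structural, not a
  seed artifact.
* **Three-week accumulation.** The published clearance (1.09 L/h) and
  predicted volume (~0.9–1.1 L/kg) give N-CLB an accumulation
  half-life near two days, so simulated troughs are at plateau well
  before day 21; the literature's three-week time-to-steady-state
  would require a ~5-fold longer effective half-life than those
  parameters imply. Relatedly, without a time-dependent reduction of
  N-CLB clearance on chronic dosing the model under-predicts
  multiple-dose N-CLB exposure (adult steady-state
  metabolite:parent ratio ~1.3 versus 3–5 clinically).
* **CLB Morris #2 rank.** With ±30% ranges truncated to (0, 1] for
  fractions, fa's sweep is asymmetrically clipped (0.93 × 1.3 caps at
  1.0) while fu,p's is not, and their elementary-effect magnitudes
  tie (μ* 2.43 vs 2.46 at 150 trajectories; logP clearly first at
  5.0). At the default 20 trajectories the #2 rank between fa and
  fu,p flips with the seed, so the published strict ordering "logP
  then fa" is reproduced on some seeds only. The Sobol picture is
  unambiguous: logP, fu,p and fa are the three indices above the 0.1
  threshold for CLB AUC.
* No gut-wall metabolism (fu,gut is carried but inert), no
  transporters (P-gp/BCRP ki stored as metadata only), no
  enterohepatic recycling, no mechanism-based inhibition, no
  neonates (< 6 months), and perfusion-limited treatment of every
  tissue including brain.
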