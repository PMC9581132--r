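---
title: "In silico drug trials on populations of cardiac Purkinje models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico drug trials on populations of cardiac Purkinje models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(purkinjetrials)
```

## The problem

Drugs that block the hERG potassium channel (carrying IKr) prolong cardiac
repolarization and can trigger torsade de pointes (TdP), but hERG block
alone is a poor predictor: concomitant block of depolarizing channels
(Nav1.5, Cav1.2) can neutralize the risk. Preclinical screening therefore
combines multi-channel IC50 measurements with functional models — classically
isolated rabbit Purkinje fibers, increasingly simulations of human cardiac
cells. This package implements the full in-silico arm of such a screen on
cardiac Purkinje cells: a population of action-potential (AP) models with
varied ionic profiles, pore-block drug application from per-channel IC50s,
multi-rate pacing, AP-biomarker and early-afterdepolarization (EAD)
quantification, and binary TdP risk classification benchmarked against
CredibleMeds classes. A synthetic rabbit-fiber assay generator stands in for
wet-lab recordings so every downstream stage is testable.

## The cell model

Published human Purkinje models are distributed as large code artifacts, not
printed equation sets, so the package ships its own reduced model: a
Hodgkin–Huxley formulation of the twelve currents that dominate Purkinje
electrophysiology — INa, INaL, ICaL, ICaT, Ito, Isus, IKr, IKs, If, IK1,
INCX, INaK — with membrane capacitance normalized to 1 and intracellular
concentrations held fixed (INCX and INaK are static voltage-dependent
currents). Reversal potentials are effective constants chosen together with
the conductances; they parameterize driving forces in a model without ion
bookkeeping and are not thermodynamic predictions.

The parameterization was tuned once, against the human control biomarker
windows (mean ± 2 SD at 0.25, 1 and 3 Hz) that also drive population
calibration, to satisfy a behavioral contract that the test suite enforces:

* control APD90, APD50, dV/dtMax, APA and TOP inside their windows at all
  three rates;
* APD90 ordering slow > 1 Hz > 3 Hz. Rate adaptation comes from two
  carryover mechanisms: slow IKr deactivation (xr persists through short
  diastoles) and slow IKs kinetics (xs accumulates over beats at fast
  rates);
* a rate-dependent take-off potential via funny-current-driven diastolic
  depolarization (the membrane drifts from about −89 mV toward −84 mV over
  a multi-second diastole, saturating without spontaneous firing);
* dV/dtMax non-increasing under INa block; APD90 non-decreasing under IKr
  block;
* EADs at slow pacing under ≥ 90% IKr block in members with high ICaL/INaL
  and low IK1/INaK. The EAD mechanism is L-type window-current
  reactivation: the f gate inactivates slowly at plateau voltages and
  recovers quickly between −20 and −45 mV, so when repolarization is slow
  enough through that range the d·f window current turns net inward and
  regenerates a depolarizing deflection.

With a phenomenological model of this size, the contract — not any single
parameter value — is the specification; the tuned conductances are the
package's baseline and population scaling explores 50–200% around them.

## Numerical choices

The ODEs are stiff (gating time constants span 0.1 ms to 3 s), so
integration uses `deSolve::lsoda` with rtol 1e-6 and atol 1e-8, beat by
beat: one segment for the 1 ms stimulus pulse, one for the remainder of the
cycle. The solver is deterministic — identical inputs give bitwise-identical
states — and a non-finite state raises a classed error rather than
propagating NaNs.

The stimulus is a rectangular pulse of twice the diastolic threshold
(threshold found once per model by bisection to 1/2^14 resolution). At
twice threshold a 1 ms pulse necessarily overlaps phase 0, which affects the
maximal upstroke velocity: rather than excluding the pulse window from the
slope search (which would discard the true upstroke), `compute_biomarkers()`
subtracts the known stimulus current from voltage slopes inside the pulse —
exact on a unit-capacitance membrane. Biomarker beats are sampled at
0.05 ms: the upstroke lasts ≈ 0.3 ms, and coarser grids under-resolve
dV/dtMax enough to break its monotonicity under INa block.

APDx is measured from the earliest sample attaining the maximal slope to
the first later downward crossing of `peak − x% · APA`, linearly
interpolated; APA is referenced to the take-off potential, not the
diastolic minimum. The "end of potential" (EOP) is defined as the voltage
at the last sample of the beat window and recorded as an assumption in
output manifests.

Abnormality detection flags a positive voltage slope (> 0.01 V/s) occurring
later than 150 ms after stimulus onset: an EAD if the membrane is still
above −70 mV, a DAD otherwise. All three constants are configurable and
reported in trial manifests, since the experimental literature rarely
states them; the 150 ms window start excludes the upstroke and early
plateau. Diastolic If-driven drift is two orders of magnitude slower than
the slope threshold and is never flagged. Members that fail to repolarize
by the end of the last beat are counted as abnormal of kind EAD for
classification and logged distinctly.

## Population construction and calibration

An initial population samples the twelve maximal conductances independently
over 50–200% of baseline by Latin hypercube (`lhs::randomLHS`, seeded;
per-dimension stratification with exactly one draw per bin). Candidates are
paced to steady state at 1 Hz, their nine biomarkers computed on the last
beat, and retained only if all nine fall inside the calibration windows and
no abnormality appears in control at 1 Hz, the slow rate, or 3 Hz.
Calibration is a pure filter; the retained set is hashed, and trial
aggregation refuses to mix summaries from different population hashes.

The windows are a YAML config, never hard-coded. For APD50, APD90,
dV/dtMax, APA and TOP they are the human control mean ± 2 SD; APD10, APD25,
APD75 and EOP have no published human ranges, so their windows default to
the bundled model's baseline ± 50%. Because Purkinje APs have a deep
phase-1 notch, baseline APD10/APD25 are a few milliseconds (the notch dips
below the 10% and 25% repolarization levels), and these windows mainly
filter members with aberrant notch morphology.

Pacing scales are configurable: the study-scale protocol is 1000 candidates
with 1000 pre-pacing beats and 150 beats per condition; the bundled
reduced-scale profile (used in tests, the acceptance script and the
analysis drivers) uses 24–50 candidates, 40–100 pre-pacing beats and 25–30
condition beats. The model contains no slow concentration dynamics, so its
slowest time constants (~3 s) equilibrate within a few tens of beats and
the reduced profile sits on the same steady states; tests verify the
beat-150-vs-151 APD90 difference is below 1%.

## Drug block and trials

Drug effects use the conductance-scaling pore-block model with Hill
coefficient 1: residual = 1 / (1 + C/IC50). The bundled library carries the
14 reference compounds' IC50s for INa, ICaL, Ito and IKr, their tested
concentrations, pacing rates and CredibleMeds classes. Channels annotated
as unaffected ("no effect or IC50 far above tested concentrations") keep
residual 1 rather than a large finite IC50. Concentrations beyond the
tested list are allowed and flagged as extrapolation. One bundled list
departs from its source: the cisapride concentrations are printed as a
non-ascending sequence with a duplicate in the original table; the library
stores the ascending unique set (0.003, 0.01, 0.03 µM).

Trials start from each member's cached control steady state per frequency
(obtained by 150 — or at reduced scale 25 — beats at the target rate from
the 1 Hz steady state), pace with the block applied, assess abnormality on
the last beat (optionally any of the last k, off by default), and summarize
mean percent biomarker changes over normal members plus abnormality
incidence. By default a drug tested at 0.2 Hz is paced at the population's
cached slow control rate (0.25 Hz) unless the population was calibrated
with 0.2 Hz among its control frequencies; the two slow rates are
interchangeable for the EAD endpoint in this model.

## Risk metrics

Two classifiers: (i) risky if any member shows an abnormality at any
concentration at the drug's slow rate — "at least one model" is deliberate,
mirroring the sensitivity rationale of population-based screening; (ii)
risky if mean APD90 prolongation at 1 Hz exceeds 10% (strict inequality) at
any concentration. Both are monotone in added concentrations. Truth is the
CredibleMeds mapping (classes 1 and 2 risky, NC safe); accuracy is rounded
half-up to integer percent. Cross-arm consistency of mean percent changes
uses the three-level rule (same trend within 15 points = strong; same trend
beyond = qualitative; opposite trend = disagreement), with an exact zero
agreeing in trend with either sign and the 15-point boundary counting as
strong.

## The synthetic in-vitro generator

The generator emulates the statistical shape of the rabbit fiber assay, not
its biology: per-fiber control biomarkers are independent truncated normals
(APDs and APA positive, TOP in [−100, −60] mV) around the published rabbit
control means/SDs per rate; biomarkers without published rabbit statistics
(APD10/25/75, EOP) get synthetic defaults derived from the published ones.
Dose effects are Emax curves on the percent scale with multiplicative
fiber-level noise, and EAD flags are Bernoulli draws at the slow rate only.
Within-fiber correlation across biomarkers and cumulative-dosing carry-over
are not modeled. Passing pipeline tests on these data therefore
demonstrates correctness of the machinery (aggregation, classification,
consistency grading), not fidelity to rabbit electrophysiology.

## Limitations

The reduced model reproduces the calibrated behavioral contract, not the
full published human Purkinje dynamics: absolute drug-induced percent
changes are expected to differ from study-scale values (population size 530
and per-drug prolongation percentages are out of reach at desk scale), and
no calcium handling means no DAD generation from spontaneous calcium
release — DADs are detectable in traces but not produced by the bundled
model. Drug binding is conductance-scaling only: no state-dependent or
kinetic block, no temperature correction. Tissue-level propagation is out
of scope.
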