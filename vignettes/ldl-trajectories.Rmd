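---
title: "LDL-c target attainment and trajectory analysis from routine care data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LDL-c target attainment and trajectory analysis from routine care data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Lipid-lowering therapy is a cornerstone of secondary cardiovascular
prevention, yet in routine care many patients with established cardiovascular
disease (CVD) never reach their low-density lipoprotein cholesterol (LDL-c)
target. Electronic health records (EHRs) hold every LDL-c measurement a
hospital laboratory ever produced, so in principle they can answer, at the
population and the patient level: who is off target, does LDL-c improve over
follow-up, and what is associated with deterioration? `ldltraj` implements
that analysis as a reusable, tested pipeline over four routine EHR exports
(patients, laboratory results, diagnosis/billing events, prescriptions, plus
optional blood-pressure and smoking tables), together with a synthetic
generator with known ground truth so that every stage can be validated
without access to patient data.

## Measurement derivation and reliability

A lipid panel is assembled per patient-date from long-format laboratory rows.
When a direct LDL-c measurement is absent but total cholesterol (TC), HDL-c
and triglycerides (TG) are all present, LDL-c is derived by the Friedewald
formula in mmol/L units:

$$\mathrm{LDL} = \mathrm{TC} - \mathrm{HDL} - \mathrm{TG}/2.2 .$$

When both a direct value and a complete triplet exist on one date the direct
value wins; the derivation exists precisely for dates where LDL-c itself was
not measured, and a measured value is the better datum.

Two reliability rules mirror laboratory practice. Friedewald LDL-c is
unreliable at high triglycerides, so derived panels with TG above 8.0 mmol/L
are excluded. Very low LDL-c values (below 0.8 mmol/L) computed by the
formula are also unreliable; before the laboratory's remeasurement policy
took effect (default date 2017-01-24) *all* LDL-c was Friedewald-derived, so
low values before that date are excluded regardless of how the panel in hand
was sourced, while low values from the remeasurement era are kept. Each
excluded panel carries exactly one reason (the low-LDL rule takes precedence
when both apply), which makes the exclusion flowchart conservative: input
panels always equal retained plus excluded.

## Cohort definition and covariates

The analysis cohort is adult (≥ 18 years at measurement) patients with
established CVD — coronary heart disease, stroke, peripheral artery disease
or abdominal aortic aneurysm — identified from a configurable code map.
A measurement belongs to the CVD cohort when a qualifying event is dated no
later than seven days after it; the look-ahead keeps measurements taken as
part of pre-operative screening. This rule is deliberately monotone: once a
patient qualifies, every later measurement qualifies.

Per measurement the pipeline derives: diabetes (diagnosis code or
glucose-lowering prescription on/before the date), hypertension (nearest
blood pressure within ±7 days above 140/90 mmHg — read strictly, systolic
> 140 or diastolic > 90 — or any blood-pressure-lowering prescription
on/before the date), chronic kidney disease (code, dialysis, or any eGFR
below 60 mL/min/1.73m² within ±2 calendar days — the 48-hour window at the
day precision of the data), current smoking (most recent dated observation),
medication classes from ATC prefixes (A10 glucose-lowering, B01/B02A
antithrombotic, C10AA statins, other C10 lipid-lowering, C02–C09
blood-pressure-lowering), and the current statin converted to
atorvastatin-20 equivalents via an editable potency table (default anchors:
rosuvastatin 10, simvastatin 80/2 = 40, pravastatin 80, fluvastatin 80,
lovastatin 80 mg/day ≡ atorvastatin 20). Prescriptions count only when
registered on or before the measurement date: registration timing is the
weakest part of prescription data, and a no-look-ahead rule at least never
attributes future decisions to past measurements.

## States, trajectories and transition probabilities

Each measurement is categorized against the guideline target (default
2.5 mmol/L, strict inequality) into six ordinal states: on target, or off
target by `[0, 0.5)`, `[0.5, 1.0)`, `[1.0, 1.5)`, `[1.5, 2.0)` or
`[2.0, ∞)` mmol/L. Half-open bins keep the partition exhaustive and
reproduce one-decimal reporting conventions exactly.

Repeat measurements are linked into per-patient state sequences by follow-up
windows: short-term evaluation at 61–183 days (2–6 months at 30.44
days/month), long-term at 184–548 days (6–18 months), anything sooner or
later is *unrelated* to clinical evaluation of the previous measurement.
The shared six-month boundary belongs to the short-term window. Linking is
greedy forward chaining: the first measurement anchors the sequence, each
subsequent measurement is kept iff its gap from the last *retained*
measurement is short- or long-term, and unrelated measurements are
discarded. Greedy chaining is the only order-independent single-pass rule
consistent with excluding unrelated measurements, and it naturally produces
patients who are left with a single retained measurement (they contribute no
sequence and are counted).

Transition probabilities between states are estimated by pooling every
consecutive pair at every sequence position — the homogeneous Markov-chain
estimate — and normalizing rows with at least one pair. By default the
matrix is estimated on untruncated related sequences; a configuration switch
(`transitions_on_truncated`) estimates it on the truncated set instead,
since either reading of the source procedure is defensible.

For clustering, sequences are truncated at the nearest-rank 75th percentile
of sequence lengths (every sequence keeps its first *k* elements).
Dissimilarity is optimal matching (OM): the minimum total cost of editing
one state sequence into the other with substitutions and
insertions/deletions, computed by dynamic programming in C++. Defaults are
the conventional constant substitution cost 2.0 with indel 1.0; a
transition-rate (TRATE) variant derives costs as
$2 - P(i \to j) - P(j \to i)$. Sequences of unequal length are compared
directly through indels, without padding. Clustering is agglomerative with
Ward-type linkage (`stats::hclust(method = "ward.D2")`, the Ward criterion
on squared dissimilarities); OM dissimilarities are not Euclidean, which is
the standard caveat of Ward on sequence data and the reason a silhouette
report over candidate cluster counts is emitted. The number of clusters
defaults to 4 and is configurable — the method itself does not fix it.
Cluster labels are deterministic (numbered by size, descending). Cluster
membership is modelled one-vs-rest by binomial logistic regression on
patient covariates.

## Favorable and unfavorable change

Across each retained measurement pair, change is *favorable* when the next
measurement is on target (LDL-c decreasing to, or remaining on, target) and
*unfavorable* otherwise — an increase, a decrease still off target, or
stable off-target LDL-c. Read at the category level these three unfavorable
clauses are exactly the complement of "next state on target", which is how
the classifier is implemented and exhaustively tested over all 36 ordered
state pairs. Statin changes between the two measurements are categorized by
type and equivalent dose (same/higher/lower dose × same/different type);
pairs without a mapped statin at both ends are not evaluable and are counted
rather than forced into a category, and starts/stops are reported separately.
Deterioration is modelled by complete-case logistic regression on age, sex,
diabetes, hypertension, smoking, antithrombotic use, statin change
(reference: same dose, same type), measurement index and follow-up type
(reference: short-term), with Wald 95% intervals.

## The synthetic generator

`generate_cohort()` emulates the structure of the source data with known
ground truth:

* **Baseline off-target status** follows a logistic model on the latent
  covariates. Default log odds ratios: women log 1.48, diabetes log 0.69,
  hypertension log 0.87, smoking log 1.29, age per year log 0.99,
  repeated-measurements log 1.25, intercept 0 — jointly giving ≈ 51%
  off-target prevalence at first measurement. Off-target baselines draw
  their category from the off-target part of the initial state distribution
  (default 0.49, 0.18, 0.15, 0.09, 0.05, 0.04).
* **Trajectories** follow a six-state Markov chain whose default matrix is
  the package's routine-care persistence matrix (strongest diagonal 0.84 for
  on-target patients; rows renormalized from their two-decimal source to sum
  to one exactly). A prevalence-centered covariate tilt (default: women,
  log 1.44 on the unfavorable side) lowers the on-target transition
  probability for carriers while leaving marginal transitions at the
  configured matrix up to a Jensen gap well below sampling noise at the
  validation sizes.
* **Visit timing** mixes four interval components: too soon (7–60 d, weight
  0.10), short-term (61–183 d, 0.50), long-term (184–548 d, 0.34) and too
  late (549–1200 d, 0.06). Weights were calibrated once so that ≈ 24% of
  follow-up measurements are unrelated under the greedy linker — a too-late
  gap is absorbing (every later gap from the stale anchor also exceeds 18
  months), so the unrelated share exceeds the raw too-soon + too-late
  weight. 55% of patients have a single measurement; repeated patients have
  `2 + Poisson(2.77)` measurements (mean ≈ 4.8, 75th percentile 6, capped
  at 40).
* **Chain/linker agreement.** The latent chain advances exactly on the
  measurements the greedy linker retains (unrelated measurements repeat the
  anchor state), so the pipeline's transition estimate is unbiased for the
  configured matrix by construction, not approximately.
* **Covariate encoding is exact.** Every diabetic carries a diabetes code,
  every hypertensive a blood-pressure-lowering prescription predating the
  first measurement, every CKD patient a CKD code and low eGFR, smokers a
  dated smoking record, statin/antithrombotic users a prescription — and
  non-carriers none of these signals. Parameter recovery through the full
  pipeline is therefore a property of the pipeline, not of luck in covariate
  detection.
* **Panels.** Measurements before the remeasurement date are always
  Friedewald-derived (TC emitted as LDL + HDL + TG/2.2, so the derivation
  reproduces the latent LDL-c); later panels carry a direct LDL-c unless hit
  by the missing-direct fraction (default 0.35). LDL-c is sampled uniformly
  within the state's bin (top bin capped at 8.0 mmol/L; the on-target bin
  floored at 0.8 mmol/L so clean cohorts pass the reliability filter
  untouched) — any within-bin law is admissible for category-level analyses
  and uniform keeps bin membership exact.
* **Pathologies** are injected separately (`inject_pathologies()`) as tagged
  patients: pre-remeasure low-LDL panels, high-TG panels, under-18 patients
  and non-CVD patients, in exact numbers, so exclusion counts are exactly
  predictable.

`simulate_change_pairs()` is a pair-level simulator whose data-generating
model is *exactly* the deterioration logistic being fitted. This is
deliberate: a marginal logistic over pairs pooled across current states is
misspecified for any chain whose on-target transition probability varies by
state (odds ratios do not collapse over that mixture), so coefficient
*coverage* is validated on the pair simulator, while the full cohort
generator validates transition recovery, exclusion bookkeeping and the
baseline model end to end.

What the generator does **not** emulate: real coding systems (the code map
is synthetic), inter-covariate correlation beyond configured prevalences,
seasonality or calendar trends, within-bin LDL-c distributions, free-text
smoking records, and measurement times of day. Passing recovery tests
therefore demonstrates that the pipeline computes the intended quantities
correctly, not that those quantities are unbiased on any particular real
EHR.

## Numerical and degenerate-input choices

* Dates carry day precision; the eGFR "48-hour" window is ±2 calendar days.
* First measurement per patient: earliest date, ties broken by preferring a
  directly measured LDL-c over a derived one.
* Nearest-rank percentile for truncation (`ceiling(p/100 * n)`-th order
  statistic), so the cutoff is always an observed length.
* Transition rows with no observed pairs are reported as `NA`, never
  imputed; populated rows sum to 1 within 1e-9.
* Regressions are complete-case; non-convergence or an empty outcome class
  or reference level raises an error naming the problem rather than
  returning a silent fit. Clusters with fewer than 10 members are skipped
  with a warning.
* Cohorts where no patient has two related measurements are legitimate
  inputs: trajectory, clustering and change stages emit empty, labelled
  outputs with a notice while baseline stages complete.
* Generated lab values are emitted at ≤ 9 decimals so CSV round-trips are
  byte-stable; the Friedewald identity holds within 5e-10 after rounding,
  inside the package's 1e-9 invariant.

## Validation sizes

The shipped test suite validates transition recovery on 5,000 simulated
sequences (every matrix entry within three binomial standard errors of
truth), logistic coverage on 200 replicates of 10,000 patients/pairs (95%
Wald intervals cover the generating coefficient in at least 90% of
replicates), optimal matching against an exhaustive alignment oracle over
every pair of 3-state sequences up to length four, and exact conservation
of all exclusion counts under injected pathologies. `scripts/acceptance.R`
re-runs the headline estimates at the same sizes (the worst-state
persistence estimate accumulates at least 20,000 pairs originating in that
state before estimating).

## Limitations

Prescription registration dates are not prescription decisions; the
deterioration model's statin-change covariate inherits that ambiguity (the
package deliberately draws no causal conclusion from it). The CVD cohort is
only as good as the code map. Optimal-matching costs and the cluster count
are analysis choices, not estimates; the silhouette report aids but does not
automate the choice. The marginal deterioration model is descriptive — see
the generator section for why its coefficients are validated on the matched
pair-level simulator.
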