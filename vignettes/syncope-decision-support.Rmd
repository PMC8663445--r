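---
title: "Likelihood-ratio differential diagnosis and risk stratification for syncope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-ratio differential diagnosis and risk stratification for syncope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncopedx)
```

## The problem

Syncope — transient loss of consciousness from global cerebral
hypoperfusion — is common, usually benign, and occasionally the herald
of a fatal arrhythmia. The bedside question is twofold: *what caused
this episode* (differential diagnosis) and *how dangerous is it to send
this patient home* (risk stratification). `syncopedx` implements both
stages as a declarative rule engine: the clinical content is data (a
JSON knowledge base), the statistics are code, and the two can be
audited and evolved independently.

## The diagnostic model

Four candidate etiologies are modelled: vasovagal (reflex) syncope,
orthostatic syncope, cardiogenic syncope, and neurogenic loss of
consciousness (e.g. seizure — not true syncope, but the highest-risk
mimic that must not be missed). Each is a **separate binary logistic
model**. For etiology $e$ with pretest probability $p_{0e}$ and binary
findings $x_i \in \{\text{yes}, \text{no}, \text{unknown}\}$:

$$
\operatorname{logit}(p_e) \;=\;
\operatorname{logit}(p_{0e}) \;+\;
\sum_{i \,:\, x_i \neq \text{unknown}} \ln \mathrm{LHR}_{ie}(x_i),
$$

where $\mathrm{LHR}_{ie}$ is the finding's positive likelihood ratio
for a yes and its negative likelihood ratio for a no. This is the
classical sequential-Bayes identity: posttest odds equal pretest odds
times the product of the answered findings' likelihood ratios. The same
model can be written as an ordinary logistic regression with intercept
$\beta_0' = \operatorname{logit}(p_{0e}) + \sum_i \ln \mathrm{LHR}^-_{ie}$
and coefficients
$\beta_i = \ln(\mathrm{LHR}^+_{ie}/\mathrm{LHR}^-_{ie})$ on 0/1
indicators; both parameterizations are implemented and tested for
equality, which guards against sign and baseline errors in either.

Assumptions worth stating plainly:

* **Conditional independence of findings given the etiology.** Known to
  be optimistic (that is why collinear history items are consolidated
  into single questions in the knowledge base), but it is what makes
  literature-sourced univariate likelihood ratios usable without a
  fitted joint model.
* **Independent per-etiology models.** The four posteriors are *not*
  renormalized to sum to one. Each answers "how probable is this cause
  given the findings"; the differential is simply the descending sort.
  A test asserts the engine never renormalizes.
* **Unknown is uninformative.** An unanswered or explicitly unknown
  question contributes a likelihood factor of 1. The alternative —
  treating silence as "no" — would let an incomplete assessment
  actively argue against diagnoses; we chose graceful degradation
  toward the priors instead.

### Clinical overrides

Published likelihood ratios are sparse for orthostatic syncope and
essentially absent for neurogenic LOC. Rather than invent ratios, the
engine uses a rank override: each of these etiologies has two flagged
questions, and when *all* of an etiology's flagged questions are
answered yes, it is moved to the top of the differential with its
probability untouched (the output marks it `overridden` so the ranking
is never mistaken for a probabilistic statement). A *partial* yes
pattern does not reorder anything; it emits targeted question-specific
recommendations instead (volume loading for positive orthostatic
vitals, neurologic workup for focal deficits), composing cleanly with
the all-yes override. "At least one but not all" was chosen over
"exactly one" so that the two behaviours partition the non-empty answer
patterns.

### Tie-breaks

Among overridden etiologies, and among exactly equal probabilities, a
fixed risk-first precedence decides: neurogenic LOC, cardiogenic,
orthostatic, vasovagal. Rationale: when the evidence cannot separate
candidates, the more dangerous one should surface first. The order is a
knowledge-base field (`tie_break_order`) and is configurable.

## Parameters and defaults

* **Likelihood ratios** — the packaged knowledge base transcribes the
  published 20-question table: per-question LHR+/LHR− pairs for
  vasovagal and cardiogenic syncope (e.g. age ≤ 35: 7.29/0.30 for
  vasovagal, 0.13/3.24 for cardiogenic), with absent cells encoded as
  null. All dimensionless, all > 0.
* **Pretest probabilities** — the deployed values behind the published
  tool are not public. The packaged defaults take the midpoints of the
  published prevalence ranges for the two well-studied etiologies
  (cardiac 5–21% → 0.13, vasovagal 21–48% → 0.345) and round,
  deliberately conservative values for the rest (orthostatic 0.10,
  neurogenic LOC 0.05). These are surrogate values, marked as such, and
  everything downstream treats them as opaque configurable inputs.
* **CSS weights** — the risk-score point values come from the score's
  original publication (vasovagal predisposition −1, heart-disease
  history +1, SBP <90 or >180 mmHg +2, elevated troponin +2, abnormal
  QRS axis +1, QRS >120 ms +1, QTc >480 ms +2, diagnosis-vasovagal −2,
  diagnosis-cardiac +2), fully overridable in the knowledge base. The
  vasovagal-predisposition item is sourced from the trigger-context
  question (warm/crowded place, prolonged standing, fear, emotion,
  pain), the closest available assessment input; the mapping is
  configuration, not code.
* **Risk cut points** — low < 1, intermediate 1–3, high > 3. With
  integer totals "< 1" is implemented as ≤ 0, and both interval
  endpoints 1 and 3 are intermediate, per the printed interval. An
  exhaustive sweep over totals −5…10 pins the partition.
* **QRS duration** — the assessment question uses the 120 ms cutoff as
  printed in the question tables, and that single question feeds both
  the differential stage and the CSS item, accepting a known divergence
  from the score's original derivation cutoff.

## The synthetic-case generator

There is no public patient-level dataset for this tool, so the package
generates labeled vignettes directly from the knowledge base. For a
true etiology $e$, each question whose likelihood-ratio cell is
*orientation-consistent* ($\mathrm{LHR}^+ > 1 > \mathrm{LHR}^- > 0$) is
answered yes with the sensitivity obtained by inverting the pair:

$$
\text{spec} = \frac{\mathrm{LHR}^+ - 1}{\mathrm{LHR}^+ - \mathrm{LHR}^-},
\qquad
\text{sens} = \mathrm{LHR}^+ (1 - \text{spec}).
$$

Cells that are absent or not invertible (e.g. the vasovagal
heart-disease pair 0.072/1.82, which is oriented *against* the
etiology) fall back to a neutral yes-rate of 0.2 — a documented
constant chosen as a plausible background endorsement rate, not a
fitted quantity. Answers are conditionally independent given the
label; an `unknown_rate` masks answers to emulate partial assessments;
a single seed drives label draws and answers and is recorded in the
cohort output.

**What this emulates and what it does not.** The generator reproduces
exactly the statistical structure the engine assumes — independent
findings with the configured operating points — so it measures the
engine's *internal consistency* (can the method recover the label its
own knowledge implies?), not clinical accuracy. Real presentations
violate conditional independence, have correlated missingness, and a
different case mix; passing the cohort tests says nothing about
performance on real patients. On a 50/50 vasovagal-vs-cardiogenic
cohort (n = 1000, no unknowns) the engine ranks the true label first in
about 73–75% of cases; the ceiling is well below 1 because the
etiologies share overlapping findings and several informative cells are
non-invertible, so their answers carry engine evidence but are
generated at the neutral rate.

## The evaluation loop

Completed assessments can be appended to a local JSON Lines store whose
schema contains no identifier fields (anonymity by construction). Each
record is verified against a re-run of the engine before it is written,
so the store cannot silently hold results an updated knowledge base
would not reproduce. The **congruence report** computes, among records
where the clinician selected a diagnosis, the fraction whose selection
matches the engine's top rank — optionally restricted to selected
etiologies, mirroring how such feedback metrics are quoted for the
well-supported diagnoses. Records can be flagged hypothetical (test
entries) and are excluded from the metric by default; this is the
pragmatic answer to the unsolved problem of distinguishing genuine from
exploratory entries in an unauthenticated tool.

## Numerical choices

* Evidence accumulates in log space, summed in knowledge-base question
  order; permuting answer order is guaranteed to 1e-12, not bit-for-bit.
* The engine is property-tested against an independent brute-force
  oracle (sequential odds multiplication, never touching logs) over
  1000 randomly perturbed knowledge bases and answer sets, at 1e-10
  relative tolerance.
* The probability/log-odds identity `p = 1/(1+exp(-lo))` is asserted at
  1e-12 on every differential.
* Degenerate inputs: priors outside (0,1) and non-finite log-odds are
  domain errors; empty answer sets are valid and return the priors;
  zero eligible records yield an explicit empty congruence report.
* Problem sizes in the shipped tests — 1000 oracle trials, one
  n = 1000 cohort, one n = 10,000 marginal-rate check — were chosen as
  the smallest sizes at which binomial sampling error is clearly
  separated from the tested tolerances.

## Known limitations

* The conditional-independence assumption overstates evidence when
  correlated findings are all answered; the knowledge base mitigates
  this by consolidation, not the engine.
* Posteriors are per-model and not comparable as a probability
  distribution over causes; consumers who need normalized weights must
  renormalize downstream, knowingly.
* The packaged priors are surrogates; sites should configure local
  prevalences.
* The generator cannot certify clinical performance (see above); it
  exists to make rule changes testable.
* The override mechanism is deliberately blunt (all-yes), trading
  sensitivity for transparency: it never manufactures probability mass.
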