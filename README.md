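# syncopedx

Clinical decision support for transient loss of consciousness (TLOC) at
the point of care. Emergency-department clinicians evaluating a syncope
presentation must weigh dozens of history, exam, ECG, and laboratory
findings; `syncopedx` turns a 20-question bedside assessment into

1. a **ranked differential diagnosis** over four etiologies — vasovagal,
   orthostatic, cardiogenic, and neurogenic loss of consciousness — via
   likelihood-ratio accumulation on the log-odds scale,
2. a **risk stratification** with the Canadian Syncope Score (CSS), and
3. **disposition and testing recommendations** keyed to the diagnosis,
   the app-vs-clinician agreement, and the risk class.

It is aimed at clinical-informatics teams building or studying
decision-support rules: the entire clinical content (questions,
likelihood ratios, prevalences, score weights, recommendation texts)
lives in a declarative JSON knowledge base that can be swapped out
without touching code, and the package ships a synthetic-case generator
and an evaluation log so rule changes can be tested end to end without
patient data.

## The model

Each etiology *e* is modelled as an independent binary outcome. With
pretest probability (population prevalence) *p₀ₑ* and the answered
findings *i* having likelihood ratios LHR⁺ᵢₑ (finding present) and
LHR⁻ᵢₑ (finding absent), the posttest log-odds are

```
logit(p_e) = logit(p0_e) + Σ_i  ln LHR_ie ,   LHR_ie = LHR+_ie if yes,
                                              LHR-_ie if no
```

and the posttest probability is `p_e = 1 / (1 + exp(-logit(p_e)))` —
equivalently, posttest odds = pretest odds × ∏ LHR. Questions answered
*unknown* (or not asked) contribute a factor of 1, so a partial
assessment degrades gracefully toward the priors. Probabilities are
**not** renormalized across etiologies; the ranked list orders the raw
per-model posteriors.

Two etiologies (orthostatic, neurogenic LOC) lack reliable published
likelihood ratios. They are handled by *clinical overrides*: when every
override-flagged question for the etiology is answered yes, it is moved
to the top of the differential (probability unchanged); a partial yes
pattern instead triggers targeted question-specific recommendations
(e.g. volume loading for positive orthostatic vitals even under a
cardiogenic differential).

The CSS stage tallies signed integer points from seven assessment
answers plus two items derived from the working diagnosis (the user's
selection when present, the engine's top rank otherwise) and classifies
the total as low (<1), intermediate (1–3), or high (>3) risk, mapping to
discharge with outpatient workup, observation of 6 hours or less, or
longer observation/admission.

## Worked example

```r
library(syncopedx)
kb <- load_knowledge_base()   # packaged default knowledge base

case <- answer_set(
  age_le_35 = "no", heart_disease_history = "yes", chest_pain = "yes",
  exertion = "yes", trigger_context = "no", troponin_elevated = "yes",
  user_selected_ddx = "vasovagal")

assess(case, kb)
```

```
== Differential Diagnosis ==
Differential diagnosis (rank 1 = most likely):
 rank       etiology probability note
    1    cardiogenic      0.9867
    2    orthostatic      0.1000
    3 neurogenic_loc      0.0500
    4      vasovagal      0.0056
user selection discordant with the engine's top rank

== Risk Stratification ==
Canadian Syncope Score: total 1 -> intermediate risk
  diagnosis used: vasovagal (user)
...
== Recommendations ==
  primary [vasovagal]: Vasovagal syncope: reassure and educate on ...
  secondary [app cardiogenic vs user vasovagal]: The engine ranks
    cardiogenic highest while vasovagal was selected: high-risk cardiac
    features are present; ...
  disposition [intermediate risk]: Intermediate risk (score 1-3):
    short-term observation of 6 hours or less.
```

Reading the output: the cardiac findings (heart-disease history, chest
pain, exertional onset, elevated troponin, age over 35, no vasovagal
trigger) drive the cardiogenic posterior to 0.987 while collapsing
vasovagal to 0.006; orthostatic and neurogenic LOC keep their priors
because no answered question carries ratios for them. The clinician
selected vasovagal anyway, so the risk score uses that diagnosis (−2
points) against heart disease (+1) and troponin (+2), totalling 1 —
intermediate risk — and a *secondary* recommendation flags the
discordance.

Every fitted object has `tidy()`, `glance()` and `autoplot()` methods,
so results drop straight into dplyr/ggplot2 pipelines:

```r
assess(case, kb) |> tidy()           # per-etiology tibble
compute_differential(case, kb) |> autoplot()
```

## Command line

A thin wrapper over the same functions is installed at
`system.file("cli", "syncopedx", package = "syncopedx")`:

```
syncopedx assess --case case.json [--store log.jsonl] [--format json|table]
syncopedx batch DIR
syncopedx simulate --n 1000 --seed 7 --mix vasovagal=0.5,cardiogenic=0.5 --out cohort/
syncopedx report --store log.jsonl --restrict cardiogenic,vasovagal
syncopedx validate-kb my_kb.json
```

Exit codes: 0 success, 1 partial batch failure, 2 invalid input,
3 invalid knowledge base.

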