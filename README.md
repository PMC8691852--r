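# ppmsbound

Privacy-preserving periodical publication of spontaneous-reporting-system
(SRS) tables.

## The problem

Pharmacovigilance programmes (FAERS, the Yellow Card scheme, ...) publish
adverse-drug-event reports every quarter.  Reports carry quasi-identification
attributes (QIAs: Sex, Age, Weight) that are individually harmless but
jointly linkable, multivalued sensitive attributes (sets of adverse-reaction
codes), and a persistent `CaseID` that ties a case's follow-up reports
together across releases.  Generalizing each quarter in isolation
(k-anonymity style) is not enough: by comparing consecutive releases an
adversary can strike candidates out of an equivalence group —

* **B-/F-attack** — a candidate's rows in earlier/later releases do not
  cover the target's known QIA values;
* **L-attack** — the adversary knows the target is new, so candidates seen
  in earlier releases are excludable;
* **MD-attack** — the adversary knows the target stops medication, so
  candidates that reappear in the next release are excludable;
* **SS-attack** — every remaining candidate carries far more
  adverse-reaction codes than typical, which itself discloses that the
  target has substantial symptoms.

## The model

A release series satisfies **PPMS(k, θ, α)-bounding** when for every
equivalence group *G* and every admissible target:

* `|C − (B ∪ F ∪ L ∪ MD)| ≥ k` — at least *k* candidates survive every
  combination of exclusion attacks (*k-bounding*);
* every sensitive value `v` has frequency ≤ `θ_v` among the surviving
  candidates and in each adversary view of *G* (*θ-bounding*);
* the frequency of substantial-symptoms records (code count ≥ quarterly
  mean + SD) stays ≤ `α` (*α-bounding*).

The anonymizer grows each group greedily around a seed record, admitting the
candidate of least `ΔPRIL = ΔIL × PR(G ∪ t)` — the certainty-penalty
information-loss increment times the privacy risk
`PR = 1 + Σ_v σ_v/(η_v − σ_v + 1)`, with the per-value cap
`η_v = ⌊|GV1|·θ_v⌋` taken over the group's new-and-discontinuing view — until
the group holds `k` new-and-discontinuing members.  Substantial-symptoms
safety in all four adversary views is screened incrementally with
reserved-position counters, so it can be enforced before the views' final
sizes are known.  Old records are first widened to cover their earliest
published raw values, which blocks backward/forward exclusion of returning
cases.

The package also ships the adversary side: `audit_series()` replays all four
exclusion attacks against any release series and reports the Dangerous
Identity / Dangerous Sensitivity / Substantial-Symptoms Group ratios
(DIR/DSR/SSGR) plus the normalized information loss (NIL, mean certainty
penalty in [0, 1]).

## Worked example

The bundled three-quarter toy cohort (`toy_quarters()`) comes with two
published anonymizations: `toy_release_ktheta()` (the PPMS(3, 1/3) baseline)
and `toy_release_ktheta_alpha()` (full PPMS(3, 1/3, 1/4)).

```r
library(ppmsbound)

schema <- toy_schema()
raw    <- toy_quarters()

fit <- anonymize_series(raw, schema, k = 3, theta = 1/3, alpha = 1/4, seed = 1)
glance(fit)
#>   quarters records_in records_published n_groups n_suppressed mean_nil     k
#> 1        3         29                25        5            4    0.484     3

audit_series(raw, fit$releases, schema, k = 3, theta = 1/3, alpha = 1/4)
#> <ppms_audit>
#>   quarter n_groups   dir   dsr  ssgr   nil
#> 1       1        1     0     0     0 0.625
#> 2       2        2     0     0     0 0.558
#> 3       3        2     0     0     0 0.27
#>   pooled: DIR = 0.000, DSR = 0.000, SSGR = 0.000, mean NIL = 0.4842
```

Zero ratios mean no group can be pushed below `k` candidates, above any
value threshold, or above the substantial-symptoms share by any combination
of the four attacks.  Four records were suppressed because no group could
take them safely.  The baseline release, by contrast, is attackable:

```r
glance(audit_series(raw, toy_release_ktheta(), schema))
#>   n_groups  dir  dsr  ssgr   nil
#> 1        8 0.25 0.25 0.125 0.186
```

A quarter of its groups collapse under the discontinuation attack — one of
them to a single candidate, i.e. certain re-identification:

```r
C <- candidate_set(toy_release_ktheta()[[2]], list(Sex = "F", Age = 39), schema)
exc <- exclusions(toy_release_ktheta(), 2,
                  list(qia = list(Sex = "F", Age = 39),
                       is_new = TRUE, discontinues = TRUE),
                  C$CaseID, schema)
setdiff(C$CaseID, unlist(exc))
#> [1] 18
```

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/ppms.R simulate  --seed 1 --out sim/
Rscript inst/cli/ppms.R anonymize --quarters sim/raw_q1.csv,sim/raw_q2.csv,sim/raw_q3.csv \
                                  --k 3 --theta 0.3333 --alpha 0.25 --out rel/
Rscript inst/cli/ppms.R audit     --raw sim/raw_q1.csv,sim/raw_q2.csv,sim/raw_q3.csv \
                                  --release rel/release_q1.csv,rel/release_q2.csv,rel/release_q3.csv
```

## See also

The methods vignette (`vignettes/ppms-bounding.Rmd`) documents the model,
the incremental counters, the information-loss reconstruction, every tunable
parameter, and the generator's scope and limitations.
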