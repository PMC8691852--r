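---
title: "Anonymizing periodical SRS releases: model, algorithm and design notes"
author: "ppmsbound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anonymizing periodical SRS releases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppmsbound)
library(dplyr)
```

## The setting

Spontaneous-reporting systems publish adverse-drug-event tables
periodically.  Three features distinguish them from the static tables that
classical k-anonymity assumes:

1. **Identity persistence.** Follow-up reports of one case share a `CaseID`
   across quarterly releases, and consumers need that linkage, so it cannot
   be removed.
2. **Multivalued sensitive attributes.** A report carries a *set* of
   reaction codes, with a heavily skewed per-report count.
3. **Correlated releases.** Each release constrains the possible identities
   in the others, which is exactly what an adversary exploits.

`ppmsbound` implements an anonymization model for this setting together
with the adversary's side, so every release the package produces can be —
and in the tests is — attacked with the same machinery that motivated the
model.

## Threat model

The adversary knows a target individual's raw quasi-identifier values and
that the target appears in a given release.  Candidate records are the rows
of the covering equivalence group.  Four kinds of auxiliary knowledge allow
exclusions: rows of the same candidate in earlier releases that fail to
cover the known values (backward), the same over later releases (forward),
knowledge that the target is newly enrolled (latest: candidates seen before
are out), and knowledge that the target stops medication (discontinuation:
candidates that reappear next quarter are out).  A fifth attack needs no
exclusion at all: if the surviving candidates all carry far more reaction
codes than typical, the adversary learns that the target has substantial
symptoms.

Two conventions fix what "the adversary knows the QIA values" means for a
returning case.  We take it to be the case's *earliest published raw
values*: the published intervals of later quarters need not nest (and in
general cannot, or intervals would only ever grow), but they must all cover
the earliest raw tuple.  The anonymizer enforces exactly that via the
earliest-appearance cover (`ear_cover()`), and the auditor's
backward/forward checks test candidate rows against the same tuple.

## The guarantee

A release series satisfies PPMS(*k*, *θ*, *α*)-bounding when every group
*G*, under every admissible combination of the four exclusion attacks,
keeps (i) at least *k* surviving candidates, (ii) every sensitive value *v*
at frequency at most *θ~v~* among survivors and in each adversary view, and
(iii) substantial-symptoms records at frequency at most *α*.

The four *views* of a group are the member subsets a partially informed
adversary can delimit: new-and-discontinuing members (view 1), new members
(view 2), discontinuing members (view 3), all members (view 4).  View 1 is
contained in all others, so bounds enforced against view 1 hold everywhere;
this is what makes the construction-time screening below sound.

A record is *substantial-symptoms* (ss) in its quarter when, for any
sensitive attribute, its distinct-code count reaches the quarter's mean
plus standard deviation.  We use the population standard deviation (divide
by *N*): it is well defined for a single record and, on the bundled toy
quarter below, reproduces the intended ss set.  When every record has the
same count the deviation is zero and the rule literally marks everyone
substantial; we keep the literal rule (inventing an exception would change
the guarantee silently) and emit a warning.  Thresholds are computed per
quarter, since each release is audited on its own; a pooled variant would
be a straightforward extension but is not provided.

```{r ss-rule}
sr <- merge_super_records(toy_quarters()[[2]], toy_schema())
cls <- classify_ss(sr, toy_schema())
cls$CaseID[cls$is_ss]
attr(cls, "ss_rule")
```

## The algorithm

Per quarter: reports sharing a `CaseID` merge into one super-record (code
sets unioned, spans the min–max envelope); records are tagged new/old
against the publication history and discontinuing/continuing against the
next raw quarter; ss flags are computed; old records get the
earliest-appearance cover; then groups are built greedily and each group is
generalized to the minimal tuple covering its members.

**Greedy growth.** A group starts from a seed record and repeatedly admits
the candidate with the least `ΔPRIL = ΔIL × PR` until it holds *k*
new-and-discontinuing members.  `PR(G ∪ t) = 1 + Σ_v σ_v/(η_v − σ_v + 1)`
sums a per-value risk over the candidate's codes, where `σ_v` counts
members carrying *v* (a member counts once per value) and the cap
`η_v = ⌊|GV1|·θ_v⌋` is taken over view 1 — the smallest view — so a finite
risk implies every view's frequency stays within *θ~v~*.  While the group
is still being grown, view 1 is padded up to the *k* positions it is
guaranteed to reach (`η_v = ⌊max(|GV1|, k)·θ_v⌋`); without the padding an
empty group would cap every value at zero and no group could ever start.
At audit time the actual view sizes are used.

**Substantial-symptoms screening.** The final view sizes are unknown while
a group grows, so the α-bound is enforced through eight counters: `msavr[x]`
counts the ss-records in view *x* and `n[x]` is a conservative denominator
that starts at *k* (the reserved positions of the eventual *k*
new-and-discontinuing members, assumed non-ss) and grows only when an
ss-record is admitted beyond the reserved positions.  `msavr[x]/n[x]` upper
bounds the true ss-frequency of view *x* however the group is finished, so
admitting only candidates that keep all four ratios within α guarantees the
bound.  A consequence worth knowing: with `k = 3` and `α = 1/4`, a
new-and-discontinuing ss-record can never be admitted during growth (its
ratio would be 1/3) — it can only join in the leftover phase, where its
position is *not* reserved and the denominator grows with it
(`1/(k+1) = 1/4`).  The tests replay every formed group through the
reference counter rules and recount the views from scratch to confirm both
the equality of the counters and the bounding direction.

**Dissolution and retries.** When no admissible candidate remains before
the group is complete, the group dissolves.  First-time members rejoin the
pool and growth restarts from a fresh random seed; a record whose group
dissolves a second time retires to the leftover phase.  This terminates
(each dissolution either flags or retires a record) and avoids the
degenerate behaviour of ending all group creation at the first bad seed —
with α = 1/4 any ss seed would otherwise empty the quarter.

**Leftover phase.** Remaining records join the existing group of least
`ΔPRIL`, subject to the same finite-risk and α screens; a record no group
can take safely is suppressed, i.e. withheld from the release entirely —
publishing it would create a singleton group — and reported.

**Determinism.** The only randomness is the seed-record choice, driven by
the seed passed to `anonymize_series()`.  Ties in the admission score are
broken by smallest `CaseID`, ties in the farthest-seed distance likewise,
and leftover assignment prefers the earliest-formed group, so a run is a
pure function of (input, parameters, seed).

**Baseline mode.** `mode = "legacy"` emulates the predecessor scheme the
model improves on: groups need *k* *new* members (discontinuation is
ignored) and the α machinery is off.  Its outputs are the attackable
baseline used in the tests and the acceptance script.

## Information loss

The admission score needs an information-loss increment, and the audit
reports a release-level utility penalty.  Both use the normalized certainty
penalty (NCP) family, the standard choice for interval generalization: a
numeric cell costs its interval width divided by the attribute's domain
width; a categorical cell costs 0 when exact and 1 when suppressed.  A
group's loss is its member count times the penalty of its merged span, and
`ΔIL(G, t)` is the difference after adding the candidate — never negative,
and zero exactly when the candidate's own span is degenerate and inside the
group's.  NIL is the mean penalty over published cells, 0 for an
ungeneralized release and 1 for a fully suppressed one.  The exact loss
formulas are deliberately the package's own documented reconstruction: the
model is agnostic to the utility metric as long as `ΔIL ≥ 0`.

## Tunable parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `k` | Surviving candidates every group must keep | 3 | ≥ 1; groups need `k` new-and-discontinuing members |
| `theta` | Per-value frequency threshold(s) | 1/3 | scalar, or named per-code vector with a `.default` |
| `alpha` | Substantial-symptoms frequency threshold | 1/4 | in (0, 1] |
| `mode` | `"ppms"` or `"legacy"` | `"ppms"` | baseline disables the MD/SS machinery |
| `seed` | RNG seed for the seed-record choices | none | fixes the run completely |
| `terminal` | md convention for the last quarter | `"md"` | publisher side; conservative |
| `terminal_md` | may the auditor use MD in the last quarter | `FALSE` | no next release, no such knowledge |

Schema domains matter: the certainty penalty normalizes by the numeric
domain width, so Age intervals are measured against the configured
`[0, 100]` years by default.  The toy tables never state a domain; the
default is a conventional human age range and is configurable through
`qia_schema()`.

## Auditing definitions

A group is flagged *dangerous identity* (DIG) when some member,
instantiated as a worst-case target (earliest raw values known; "new"
knowledge when true; "discontinues" knowledge when true and a next release
exists), retains fewer than *k* candidates after all enabled exclusions.
It is *dangerous sensitivity* (DSG) when some value's frequency among some
target's surviving candidates exceeds its threshold.  It is a
*substantial-symptoms group* (SSG) when the group's own ss-record share
exceeds α; the per-view ss shares are additionally reported
(`max_view_ss_freq`) but do not drive the flag — the group-level share is
the metric's definition, and it is the one the bundled reference release
satisfies.  DIR, DSR and SSGR are the fractions of flagged groups.  Extra
knowledge can only shrink candidate sets, so the worst admissible mask per
target is the right one to audit (the tests check this anti-monotonicity).

```{r audit-toy}
aud <- audit_series(toy_quarters(), toy_release_ktheta_alpha(), toy_schema())
glance(aud)
```

## The synthetic cohort generator

`generate_cohort()` emulates exactly the structure the method depends on:
persistent cases entering at a constant rate (default 25 new cases per
quarter over 3 quarters, ≈ 30 reports a quarter), chain survival with
continuation probability 0.3 per quarter (a lapsed case never returns),
uniform ages over 18–85 with a per-quarter drift of at most one year
(exercising the earliest-appearance cover), a 40-code vocabulary, distinct
code counts of `1 + Geometric(0.5)` (mean 2, population SD √2, so the
mean-plus-SD rule captures the ≈ 12.5 % tail and ss-records genuinely
arise), and a 5 % chance of a duplicate report within a quarter
(exercising super-record merging).  These sizes keep a full
anonymize-and-audit round under a second, and the property tests run the
round across twenty seeds.

What the generator does *not* emulate, and what passing tests therefore do
not show: real code co-occurrence structure (reactions cluster by drug),
demographic skew, cases that skip a quarter and return (real forward
exclusions can then touch new-and-discontinuing members; under chain
survival they cannot), reporting-volume seasonality, and FAERS-scale
volumes.  Conclusions about absolute NIL levels or about runtime at scale
do not transfer; the zero DIR/DSR/SSGR property is a structural guarantee
of the construction and does transfer, which is why the tests check it
against the independent auditor rather than against the builder's own
counters.

## Numerical and degenerate-input choices

* Intervals are closed on both ends and emitted in ASCII (`[46-50]`); an
  en dash is accepted on input.  Raw numeric values are degenerate
  intervals, so one covering relation serves raw and generalized data.
* For a numeric attribute `*` denotes the full-domain interval (numeric
  attributes are generalized only by intervals); for a categorical one it
  denotes suppression.
* Counter ratios are compared with plain `<=`; the quantities are small
  rationals and the comparisons are exact in binary floating point for the
  thresholds of interest (1/4, 1/2, 1), while 1/3-type thresholds err on
  the safe side by strictness of `>`.
* A quarter whose record count cannot support a single group (for example
  `k` above the number of new-and-discontinuing records) publishes nothing:
  every record is suppressed and a warning is emitted.
* With lookahead absent (terminal quarter) the publisher marks every record
  discontinuing — the conservative choice, since it maximizes what view 1
  must contain — while the auditor by default grants the adversary no
  discontinuation knowledge there, since no next release exists for the
  knowledge to be about.

## Relaxing α and utility

Tightening α constrains admissions, so loss decreases on average as α is
relaxed from the binding regime.  Between two settings where the screen
almost never binds (for example α = 1/2 versus α = 1 at `k = 3`), runs
differ only through occasional tie-flips of the greedy heuristic and the
averaged difference sits at noise level with no guaranteed sign.  The
utility test therefore compares each relaxed setting against the tight
α = 1/4 baseline rather than asserting a monotone chain across
near-identical settings.

## Known limitations

* The grouping heuristic makes no optimality claim about information loss;
  it only guarantees the privacy bounds.
* Categorical attributes support exact values and full suppression only —
  no generalization hierarchies.
* Sensitive-value revisions across quarters are handled by set union at the
  super-record level; semantic update modelling is out of scope.
* One bundled reference row (case 18 of the full-model quarter-2 release)
  does not cover its raw age — preserved verbatim from its source; the
  auditor treats such a target as not locatable in that group.
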