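---
title: "Scoring, agreement and stability in CHNRI priority-setting surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, agreement and stability in CHNRI priority-setting surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chnri)
```

## The method

The Child Health and Nutrition Research Initiative (CHNRI) methodology
turns a long list of candidate research questions into a ranked
investment agenda.  A panel of invited experts scores every question
against a small set of judging criteria (in the merged three-criterion
variant: *answerability*, *usefulness* and *impact*), answering each
question x criterion query with one of four categories:

| answer | points |
|---|---|
| Yes | 1 |
| Undecided | 0.5 |
| No | 0 |
| Insufficiently informed | treated as missing input |

For one question $i$ and criterion $c$, the **criterion score** is

$$S_{ic} = 100 \cdot \frac{\sum_{e \in R_{ic}} x_{eic}}{|R_{ic}|},$$

where $R_{ic}$ is the set of experts who gave a substantive (non-missing)
answer and $x_{eic}$ the point value of expert $e$'s answer.  The
**Research Priority Score** is the weighted mean over criteria,

$$\mathrm{RPS}_i = \frac{\sum_c w_c S_{ic}}{\sum_c w_c},$$

with equal weights by default (most exercises omit the weighting stage,
judging the criteria equally important); `research_priority_score()`
accepts any non-negative weight vector.  Questions are ranked by
descending RPS.

The **Average Expert Agreement** summarises consensus versus
controversy.  For each of the question's $C$ criterion queries, take the
fraction of responding experts who gave the most frequent substantive
answer (the *modal fraction*), then average over the criteria:

$$\mathrm{AEA}_i = \frac{1}{C} \sum_{c=1}^{C}
  \frac{N(\text{most frequent answer to query } ic)}
       {N(\text{any substantive answer to query } ic)}.$$

With three substantive categories every modal fraction, and hence the
AEA, lies in $[1/3, 1]$; a value near 1 means the panel answered in near
unison, while values near the floor signal controversy.  The agreement
statistic is sometimes written with a fixed $1/9$ factor in exercises
whose questions carry more sub-queries; this package always averages
over the $C$ criterion queries actually present in the `survey_design`,
which is the only reading that yields one AEA per research question for
a three-criterion survey.

## Missing data and partial completion

Two kinds of "no score" occur in practice and are kept distinct in I/O:
an **explicit** *Insufficiently informed* answer, and an **absent
record** (an expert who stopped the survey early or skipped a query).
Both are excluded from the numerator *and* denominator of every score
and modal fraction — only substantive answers carry information — but
round-tripping a response CSV preserves the distinction, because
declining to judge and never seeing the query are different survey
facts.  Partial completers contribute to every cell they did answer;
this makes per-criterion responder counts vary across cells, which is
exactly the pattern visible in published score tables (denominators such
as 14/15, 15/16, 15/17 implied by scores of 93.3, 93.8, 88.2).

When some criterion scores are undefined, the RPS renormalises the
weights over the defined ones rather than treating the missing criterion
as zero.

## Numerical conventions

* **Full precision internally, rounding only at display.**  Ranking uses
  unrounded means: two questions printing as 82.9 and 82.8 can differ by
  0.03 in full precision, and published tables show that printed RPS
  values were themselves rounded from rounded inputs.  Rendered tables
  use one decimal for scores and RPS, two for AEA, with half-up rounding
  (`round_half_up()`), matching how such tables are printed; base R's
  half-to-even rounding would print 82.85 as 82.8.
* **Ties.**  Ranks are dense (1, 2, 3, ...).  Equal full-precision RPS is
  broken by higher AEA (a more agreed-on question ranks first), then by
  design order.  The published methodology does not state a tie rule;
  this one is deterministic and documented.  Modal ties inside a cell
  need no tie-break since only the maximal count enters the fraction.
* **Degenerate inputs.**  A cell with zero substantive responders has an
  undefined score and modal fraction; a question undefined under every
  criterion has undefined RPS and AEA and is excluded from ranking with
  rank `NA`.  Validation rejects unknown identifiers, duplicate
  (expert, question, criterion) records and unknown answer labels
  outright rather than coercing.

## Stability diagnostics

Panels in this kind of exercise are small — typically a couple of dozen
invitees with fewer respondents — so the ranking deserves an uncertainty
statement.  `bootstrap_ranks()` resamples **experts** with replacement
(the expert, not the individual answer, is the unit whose sampling drives
the uncertainty), recomputes all scores, agreement and ranks per
replicate, and reports per-question median ranks, central 95% rank
intervals and the probability of staying in the top *k*.  Global
concordance across replicates is summarised by Kendall's $W$ on the
replicate x question rank matrix; the mean pairwise Spearman correlation
follows as $(mW - 1)/(m - 1)$ for $m$ replicates, avoiding a quadratic
pairwise loop.

`aea_rps_association()` quantifies the usual observation that
higher-rated questions attract more agreement: an ordinary least-squares
fit of AEA on RPS, tested with a two-sided permutation test (AEA values
relabelled across questions).  With a few dozen bounded, non-Gaussian
observations the permutation reference is the primary inference; the
t-based p-value is reported alongside.  The permutation p uses the
add-one estimator $(1 + \#\{|b^\ast| \ge |b|\})/(1 + B)$ and so is never
exactly zero.  Defaults are 2000 bootstrap replicates and 9999
permutations; every randomised routine requires an explicit seed and is
reproducible given it.

## The synthetic panel generator

No raw per-expert response set is publicly deposited for exercises of
this kind, so validation rests on `generate_panel()`: each (expert,
question, criterion) cell is an independent draw from a four-category
probability vector $(p_{yes}, p_{no}, p_{und}, p_{miss})$, resolvable
globally, per theme or per cell (cascading override).  An optional
`consensus` parameter $\gamma$ sharpens each cell's substantive
distribution towards its mode, $(1-\gamma)p + \gamma\,\delta_{mode}$,
leaving missingness fixed — raising $\gamma$ provably raises expected
agreement, which the tests check as a monotonicity property.  Experts
stop early with probability `partial_completion_rate`, answering a
uniform proper prefix of the criterion-major query ordering (all
questions under one criterion, then the next), the order in which such
online surveys are administered.

`default_panel_spec()` fixes the generator to study-scale conditions:
25 invited experts, 18 responding, a stopping rate of 2/18 (so 16 of 18
complete in full, in expectation), 30 questions x 3 criteria, 8%
per-cell missingness, and a linear per-question enthusiasm gradient
($p_{yes}$ from 0.80 down to 0.37 with $p_{und}$ fixed at 0.20, scaled
by the non-missing mass).  The gradient makes expected RPS span roughly
47-90 — the spread reported by published exercises of this size — and
couples enthusiasm with consensus, reproducing the positive AEA-RPS
association such exercises observe.

Under this model the expected criterion score has the closed form
$100\,(p_{yes} + 0.5\,p_{und})/(p_{yes} + p_{no} + p_{und})$,
conditional on at least one responder (`expected_scores()`).  The
expected AEA has no simple closed form — it is the mean of the maximal
component of a trinomial divided by a random responder count — so
`expected_aea()` builds a Monte-Carlo reference by simulating each
cell's responder counts directly ($10^5$ replicates per cell by
default).  `recovery_experiment()` regenerates panels, re-runs the
pipeline and reports bias and spread of RPS and AEA against these
references; the validation suite runs it with 500 replicates at the
18-expert study scale, and checks the $1/\sqrt{10}$ shrinkage of RPS
spread when the panel grows from 18 to 180 experts on a 4-question
design.

**What the generator does *not* emulate:** correlated expert effects
(shared disciplinary leanings, herding), question-order or fatigue
effects beyond the prefix truncation, and any dependence between a
question's criteria within one expert.  Cells are fully independent.
Passing the recovery and property tests therefore demonstrates that the
pipeline's arithmetic and inference are correct under the stated
sampling model, not that real panels behave like that model; with
correlated experts the bootstrap intervals would, if anything, be
anti-conservative.

## What is validated against published numbers, and what cannot be

The published top-ten table of the wasting-stunting prioritisation
exercise (`wasting_stunting_top10()`) supplies real per-criterion score
triples.  Feeding them through `research_priority_score()` reproduces
the printed RPS at one decimal for nine of the ten rows and the printed
rank order 1-10 exactly.  The exception is the ninth row (81.3, 90.6,
76.7): its full-precision mean is 82.87 while the table prints 82.8,
which is only reachable by averaging the already-rounded printed scores
— evidence that the published RPS column was computed before rounding
but printed from rounded inputs in that row.  The package deliberately
does not reproduce that artefact.

The printed AEA column, the overall RPS minimum and AEA range endpoints,
and the regression p-value over all 30 questions all depend on the
unpublished per-expert responses and cannot be recomputed; they are
replaced in the test suite by exhaustive small-panel oracle equivalence,
parameter recovery at study scale, and property checks (bounds,
expert-permutation invariance, answer-upgrade monotonicity, seeded
determinism).

## A worked example

```{r example, eval = FALSE}
spec <- default_panel_spec(seed = 7)
panel <- generate_panel(spec)
completion_summary(panel, panel_size = 25)

scores <- score_all(panel)
agreement <- agreement_all(panel)
ranked <- rank_questions(scores, agreement)
render_ranking(ranked, agreement, top_k = 10, design = spec$design)

bootstrap_ranks(panel, n_replicates = 2000, seed = 7)
aea_rps_association(scores, agreement, n_permutations = 9999, seed = 7)
```

The same pipeline is available from the shell via
`inst/cli/chnri.R` (subcommands `score`, `agree`, `rank`, `stability`,
`simulate`, `report`, `run`), with exit code 0 on success, 2 for invalid
input and 3 for computation failures.

## Limitations

* The AEA is not chance-corrected; it is the methodology's own statistic,
  not a kappa-type coefficient, and its floor rises with fewer response
  categories.
* With weights, the renormalisation over defined criteria is a modelling
  choice; exercises that prefer to treat an unanswered criterion as
  disqualifying should filter such questions before ranking.
* The bootstrap treats experts as exchangeable; stratified or weighted
  panels would need a grouped resampling scheme, which is an extension
  point, not implemented.
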