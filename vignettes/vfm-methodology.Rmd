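---
title: "Value-for-money prioritization: model, elicitation and selection methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value-for-money prioritization: model, elicitation and selection methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfmchart)
```

## The decision problem

A funder with a fixed annual budget must choose which health technologies
(drugs, devices, procedures) to add to a publicly funded benefits list.
`vfmchart` supports that deliberation by comparing four variables per
technology, kept deliberately separate:

1. **Incremental benefits** to the population, aggregated across several
   benefit dimensions into a single additive score;
2. **Incremental total cost** to the health system, in millions of
   currency per annum (or as an NPV via `npv_cost()`);
3. **Quality of evidence**, an ordinal grade (poor / medium / high) that
   is *displayed*, never folded into the score;
4. **X-factors**, free-text strategic/legal/ethical flags that act as
   display highlights and as lock-in/lock-out constraints on selection.

Costs are intentionally *not* a dimension of the points system: mixing
cost into benefit scoring makes trade-off questions ambiguous, so cost
enters only as the second axis of the chart.  This separation is an
architectural constraint of the package, not a convenience.

## The additive points model

A points system assigns each benefit dimension $d$ an ordered set of
levels with non-negative values $v_{d,1} \le v_{d,2} \le \dots \le
v_{d,m_d}$, with $v_{d,1} = 0$.  A technology rated at level $l(t,d)$ on
each dimension scores

$$S_t \;=\; \sum_d v_{d,\,l(t,d)}.$$

Additivity is the model's key assumption: the value of improving one
dimension does not depend on the levels of the others.  That is what
makes two-dimension trade-off questions sufficient to identify the
values, and it is also the model's main limitation — interactions
(e.g. "lives saved matter more when quality of evidence is high") cannot
be expressed.

Choices made where the convention was open:

* Point values are stored as plain doubles and compared with an absolute
  tolerance of `1e-9`; the bundled schedule prints three decimals, and no
  finer tolerance is meaningful at that precision.
* The bottom-level-zero rule is enforced by `validate_points_system()`
  but can be relaxed (`require_zero_bottom = FALSE`) for imported
  systems with a non-zero floor.
* "Not yet known" is treated as the bottom level — the bundled schedule
  merges them in the level wording itself.
* Rating labels match case-insensitively after stripping all whitespace
  (`"> 500"` matches `">500"`), because technology tables are hand-edited
  CSVs and such differences occur even between the two bundled tables.
* `npv_cost()` uses end-of-period discounting; no convention was
  prescribed, and this is the most common default in cost calculations.
* `interpolate_mid_levels()` inserts arithmetic-mean "mid" levels to
  soften rating-boundary sensitivity; it never moves the original levels,
  so existing ratings keep their scores exactly.
* The bundled illustrative schedule's top values sum to 0.999; the
  near-1 total is treated as coincidence, not as a normalization rule.
* The bundled dimensions fold the number of patients affected into the
  level wording; how a rater should weigh magnitude against patient
  counts within a level is left to the rater.

## Eliciting point values from pairwise rankings

`ranking_state()` builds a pool containing, for every pair of distinct
dimensions, every pair of level *upgrades* — one on each dimension —
posed as a two-technology comparison in which one hypothetical is better
on one dimension and worse on the other (all remaining dimensions held
equal).  Dominated comparisons are never posed.  The pool size is
$\sum_{i<j} \binom{m_i}{2}\binom{m_j}{2}$; for the bundled 5/4/4/3/2
structure that is 247 questions.

Internally each question compares two *gains* $g_{d}(l, l') =
v_{d,l'} - v_{d,l}$.  The session maintains the weak and strict
transitive closures of the judged relation over all gains as boolean
reachability matrices, seeded with dominance: a gain whose level interval
contains another gain's interval (same dimension) is weakly at least as
large.  Each recorded verdict adds an edge and updates both closures
incrementally; a verdict that would create a strict cycle is rejected
with an `vfm_inconsistency` error naming the contradiction.  A question
is *resolved* when the closure already ranks its two gains (strictly
either way, or as tied).

`next_question()` defaults to a greedy ordering: ask the open question
whose answer implies the most other open questions, counting the worse
of its two possible strict answers (ties broken in canonical pool
order).  The published descriptions of comparable elicitation software
do not state an ordering, so this is the package's own choice; a
`"random"` ordering is provided for order-independence testing.  The
number of questions actually asked is always below the pool size
whenever implications can cross dimension pairs:

```{r asked-count, eval = FALSE}
st <- run_elicitation(table1_points_system(),
                      simulate_answers(table1_points_system()))
c(asked = st$asked, pool = nrow(st$pool))
```

On the bundled structure the greedy ordering asks roughly 70–80 of the
247 pool questions.  Interactive survey software for this class of
methods reports asking about 40 questions for a structure of this size;
that figure depends on unpublished implementation details, so it is
logged for comparison but never asserted.

Group elicitation is reduced to a single judgment stream (the
recommended mode of use is consensus answers, which arrive as one
stream), and "equal" is an allowed verdict — it is required for an exact
simulation oracle, and nothing in the method forbids ties.

### Deriving the schedule

Once the pool is fully resolved, `derive_point_values()` computes values
by linear programming: with one variable per non-bottom level plus a
slack $s$,

* every strict relation between gain classes must hold with margin
  $\ge s$ (only the covering edges of the class-level strict order are
  included — the rest are implied by transitivity and would only bloat
  the program);
* tied gains are constrained equal;
* values are non-decreasing within each dimension with bottom 0;
* top-level values sum to 1;
* $s$ is maximized.

The derivation mathematics of the original software are proprietary;
this maximum-minimum-slack formulation is the package's own, documented
substitute.  It guarantees *ordinal* recovery — the derived schedule
ranks every pool pair exactly as the judgments do — which is the
property the tests assert.  The numerical values themselves are the
most-separating representative of that ranking, not a unique truth.

The program is solved by a small internal two-phase dense simplex with
Bland's pivoting rule (`R/lp.R`).  These programs are heavily degenerate
(many exactly-binding constraints, exact ties), and Bland's rule gives
guaranteed finite termination and deterministic output — determinism is
what makes the derived values independent of the order in which
questions were answered, a property the test suite checks by comparing
randomized sessions.  If the session contains no strict judgment at all
(every answer "equal"), the slack objective is vacuous and the
constraints alone pin the schedule — e.g. with two-level dimensions all
top values come out equal.

## Frontier, selection and the knapsack benchmark

`build_vfm_points()` projects each technology to (benefit score, cost,
evidence, X-flag).  `pareto_frontier()` returns the non-dominated set:
no other point with cost no higher and benefit no lower, one inequality
strict.  Points with identical (cost, benefit) do not dominate each
other and are all retained — exact ties are not addressed by the
deliberation narrative, and silently dropping one would hide a real
candidate.  The implementation is a cost-sorted sweep, checked in the
tests against the quadratic brute-force definition on random portfolios.

`selection_state()` / `select_technologies()` implement the
deliberation loop: humans pick technologies round by round, the state
tracks spending against the budget (300 million is the demo default,
configurable) and writes an auditable JSON action log.  Overspending
requires an explicit `force = TRUE`.

`knapsack_optimal()` is the mechanical benchmark for what a pure
benefit-maximizer would select: an exact 0-1 knapsack by dynamic
programming.  Costs are held at two-decimal precision in millions and
scaled by 100 to integers, so the DP is exact with no floating-point
drift on the capacity axis.  Among benefit-optimal subsets it returns
the cheapest, then the lexicographically smallest id set, so results are
reproducible.  Evidence and X-factors never enter the objective; a
mandated technology is passed as `locked_in` (it consumes budget first),
a vetoed one as `locked_out`.  The benchmark deliberately does *not*
replace deliberation — X-factors of uncertain importance are exactly
what the DP cannot see.

`what_would_it_take()` answers the sensitivity question for a dominated
technology: the smallest set of single-dimension rating upgrades (never
cost reductions — the what-if concerns rating uncertainty) after which
the technology is non-dominated, searching upgrade combinations ordered
by count and then by score change.  `committee_shortlist()` implements
top-$k$ nomination tallying: strict majority on the board, the rest
question-marked.

## The chart

`render_svg()` emits an SVG 1.1 document whose structure mirrors the
data one-for-one: one `circle.bubble` per technology with bubble *area*
proportional to the evidence rank (1 : 2 : 3 — "proportional" is all the
convention specifies, so the linear-in-rank mapping is the package's
choice), fill color (or a grayscale-safe hatch) marking X-factors, a
`polyline.frontier` through the frontier, and two dashed
`line.quadrant-guide` rules.  The quadrant language ("top-left = good
value") implies thresholds that are nowhere defined, so the guides
default to the midpoint of the plotted cost and benefit ranges and can
be overridden absolutely.  Benefit is vertical, cost horizontal, origin
at (0, 0).  Because every visual element carries a class and data
attributes, the test suite checks charts by parsing them back rather
than by pixel inspection.  PNG export is not built in; the SVG is the
canonical artifact and rasterizes cleanly with any standard converter.

## The synthetic generator

`generate_synthetic()` produces portfolios for property tests and
demos.  Its defaults emulate the bundled 18-technology table: log-normal
annual costs with location `log(15)` and scale 1 (typical range roughly
2–120 million, matching the table's 3.11–124 spread — calibrated by
inspection, not fitted), per-dimension rating probabilities decreasing
as 1/rank (most technologies offer modest benefits on most dimensions),
evidence probabilities 0.10/0.25/0.65 (the bundled table is
high-evidence-heavy), and X-factor probability 0.25.
`random_points_system()` draws strictly increasing level values with
normalized top sum.  What the generator does **not** emulate: correlation
between cost and benefit, correlation between evidence and anything
else, realistic label text, or multi-year cost profiles.  Passing
property tests on synthetic portfolios therefore demonstrates
*algorithmic* correctness (frontier = brute force, knapsack = exhaustive
enumeration, elicitation recovery), not realism of any particular
decision.

## Test scales and numerical choices

The test suite exercises: frontier-vs-brute-force on 200 seeded random
portfolios of up to 50 technologies; knapsack-vs-enumeration on 50
portfolios of up to 12 (4096 subsets each); and full elicitation
recovery on 20 random hidden schedules with 3–5 dimensions of 2–5
levels.  These sizes keep the whole suite under a minute while covering
the combinatorial space densely.  Score comparisons use absolute
tolerance `1e-9`; the simulation oracle calls two profiles tied when
their score sums differ by at most `1e-9`; knapsack benefit comparisons
use the same tolerance on top of the exact integer cost axis.  Derived
schedules are written to YAML with 15 significant digits because the
default 7 was observed to break exact ties on round-trip.

## Known limitations

* Additive scoring cannot express interactions between dimensions.
* The derived point values are one representative of the elicited
  ranking; confidence intervals on values are out of scope.
* The knapsack benchmark ignores evidence and X-factors by design.
* Divisible funding (partial coverage) is not modeled: decisions are
  0-1.
* Only one judgment stream is supported; surveying many respondents and
  aggregating their preferences is out of scope.
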