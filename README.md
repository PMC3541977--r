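# vfmchart

Decision-support tools for **health technology prioritization under a
budget constraint**, built around the value-for-money (VfM) chart.  The
intended users are health-economics analysts and the committees they
support: bodies that must decide once a year which new drugs, devices and
services to add to a publicly funded benefits package when the requests
far exceed the budget.

The package compares four variables per candidate technology and keeps
them deliberately separate:

* **Incremental benefits** — an additive multi-criteria score.  Each
  benefit dimension $d$ (lives saved, life prolongation, quality-of-life
  gains, access equity, other social benefits) has ordered levels with
  point values $v_{d,1} = 0 \le v_{d,2} \le \dots \le v_{d,m_d}$, and a
  technology rated at level $l(t,d)$ on each dimension scores
  $S_t = \sum_d v_{d,\,l(t,d)}$.
* **Incremental total cost** — millions of currency per annum (or NPV).
  Never a scoring dimension; it is the chart's second axis.
* **Quality of evidence** — ordinal poor/medium/high, displayed as
  bubble size, never summed into the score.
* **X-factors** — residual strategic/legal/ethical flags, displayed as
  bubble color and usable as lock-in/lock-out constraints on selection.

On top of the scoring model the package provides:

* **Elicitation** of the point values from pairwise trade-off questions
  ("which hypothetical technology has higher priority?"), with
  transitivity and dominance used to skip every implied question, and a
  maximum-minimum-slack linear program that derives a schedule ranking
  every trade-off exactly as the answers did
  (`ranking_state()`, `next_question()`, `record_judgment()`,
  `derive_point_values()`).
* **Pareto frontier** identification over (benefit, cost)
  (`pareto_frontier()`), the budget-tracking selection loop with audit
  log (`selection_state()`, `select_technologies()`), an exact 0-1
  knapsack benchmark (`knapsack_optimal()`), rating-upgrade sensitivity
  analysis (`what_would_it_take()`) and committee top-ten shortlisting
  (`committee_shortlist()`).
* **SVG charts** with machine-checkable structure (`make_chart_spec()`,
  `render_svg()`).
* Bundled fixtures: an illustrative 5-dimension points system
  (`table1_points_system()`) and an 18-technology portfolio
  (`table2_technologies()`), plus a seeded synthetic generator
  (`generate_synthetic()`).
* A command-line interface (`vfm_cli()`; launcher in
  `inst/cli/vfm.R`) with subcommands
  `score | frontier | select | knapsack | whatif | elicit | shortlist | chart | synth`.

## Worked example

```r
library(vfmchart)

ps        <- table1_points_system()
portfolio <- table2_technologies()
points    <- build_vfm_points(portfolio, ps)
head(points[order(-points$benefit), ], 6)
#>  tech_id benefit   cost evidence x_flag
#>       t1   0.891   5.29     high   TRUE
#>       t2   0.439   4.60     high  FALSE
#>       t3   0.436 124.00     high  FALSE
#>       t4   0.424   5.45     poor   TRUE
#>       t5   0.412  26.47     high  FALSE
#>       t6   0.390   4.83     high  FALSE
```

t1 scores 0.891 of a possible 0.999 (`max_score(ps)`) and costs only
5.29 million — the obvious first pick.  The frontier of the full
portfolio is the set of technologies no rival beats on both axes:

```r
pareto_frontier(points)
#> [1] "t16" "t14" "t2"  "t1"
```

A committee might open by selecting the four cheap, high-benefit
technologies and then re-examine the frontier of what remains:

```r
st <- selection_state(portfolio, budget = 300)
st <- select_technologies(st, c("t1", "t2", "t4", "t6"))
st
#> Selection: 4 chosen (20.17 m spent), 14 remaining, 279.83 m of 300.00 m unallocated
#>   selected: t1, t2, t4, t6

rest <- points[!(points$tech_id %in% st$selected), ]
pareto_frontier(rest)
#> [1] "t16" "t14" "t7"  "t5"  "t3"
```

The new frontier costs 172.9 million in total; picking all five and
peeling again yields `t18, t15, t11, t9, t8`, and so on until the budget
is exhausted.  The mechanical benefit-maximizing benchmark for the full
300-million budget:

```r
knapsack_optimal(points, 300)
#>  [1] "t1"  "t10" "t11" "t13" "t14" "t15" "t16" "t2"  "t4"  "t5"  "t6"  "t7"
#> [13] "t8"  "t9"
# total benefit 5.338 at cost 299.51
```

Render the chart (bubble size = evidence, color = X-factors, polyline =
frontier, dashed midrange quadrant guides):

```r
render_svg(make_chart_spec(points), "vfm.svg")
```

Or from a shell:

```sh
Rscript inst/cli/vfm.R frontier --exclude t1,t2,t4,t6
Rscript inst/cli/vfm.R chart --out vfm.svg
```

## Documentation

The methods vignette (`vignettes/vfm-methodology.Rmd`) describes the
scoring model and its assumptions, the elicitation engine and the
derivation program, the selection and knapsack semantics, chart
conventions, the synthetic generator's calibration, and known
limitations.
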