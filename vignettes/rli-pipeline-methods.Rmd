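---
title: "Backcasted Red List timelines and the Red List Index: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backcasted Red List timelines and the Red List Index: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlitools)
```

## The problem

Red List categories are reassessed at long intervals, and most category
changes between assessments are *non-genuine*: new distributional data,
taxonomic revision, or a different application of the criteria. A trend
indicator built on raw categories would therefore mostly measure changes in
knowledge. The convention adopted by global assessments — and implemented
here — is to **backcast**: assign each species a category at every epoch
using current knowledge, let an expert-judged ledger of *genuine* changes
(real improvements or deteriorations driven by changes in threats) override
the default, and compute all trend statistics from the resulting timelines.

## Category semantics

Severity order for change direction is LC < NT < VU < EN < CR < CR(PE) <
EW < EX. Two scales must not be conflated:

* **Rank** decides the direction of a change. CR(PE) outranks CR because a
  CR→CR(PE) move is a deterioration.
* **RLI weight** is capped at 5: LC 0 … CR 4, CR(PE) = EX = 5. Because
  CR(PE) and EX are weighted the same, a CR(PE)→EX transition carries
  direction `none` in all direction tallies (it is flagged
  `became_extinct` for extinction bookkeeping instead). This exclusion is
  configurable (`crpe_ex_tally = "include"`), since some reporting
  conventions count any move into EX.

Two points the category ordering alone does not settle, decided here and
exposed as parameters:

* **EW weight.** The index anchors (1 at all-LC, 0 at all-EX) do not pin
  down Extinct in the Wild. We use 5 — EW sits above CR in severity, and a
  species with no wild population contributes maximal wild extinction risk
  — with `ew_weight` as an argument.
* **EW rank between CR(PE) and EX.** Only EX > EW > CR is implied by the
  ordering convention; we place EW at 6, between CR(PE) (5) and EX (7).
  This only matters for the rare EW transitions, which the synthetic
  generator never emits by default.

Data Deficient species are excluded from ranking, weighting and the index;
they are *pinned* to DD at every epoch by the backcasting rule, which makes
the included count N of a series epoch-constant (the code asserts this
rather than assuming it). NE species are rejected by every analytical
operation.

## Backcasting and change records

`apply_backcast()` composes three rules backward from the final epoch: DD
everywhere for DD species; copy the later state backward when no
declaration covers an interval; a declaration sets the state at its
interval's start. Declarations carry the *state at interval start*, not a
delta, which makes the ledger self-consistent and order-independent, and
lets a species deteriorate in one interval and improve in the next.
Extinction is absorbing forward in time; a ledger implying departure from
EX is a "resurrection" error, and two declarations for one species-interval
are a "conflicting-ledger" error.

`derive_changes()` emits one record per interval with a rank change.
Genuineness is simply "a declaration covers this species-interval";
non-genuine records are carried (they are visible to diagnostics) but
excluded from every tabulation, index and driver summary. Re-deriving from
an emitted timeline is idempotent, which the test suite checks.

## The index

$$\mathrm{RLI} = 1 - \frac{\sum_s W(s)}{W_{EX}\,N}, \qquad W_{EX} = 5.$$

This equal-step linear form is the unique linear weighting that meets both
anchors (1 at all-LC, 0 at all-EX). Disaggregation: realms duplicate
multi-realm species into each realm's series (the best representation of a
realm's overall risk; each species still counts once globally), while
taxonomic order and breeding strategy partition the table; species with
unknown breeding strategy are omitted from the breeding disaggregation.
Slopes are annualised, $(\mathrm{RLI}_{i+1}-\mathrm{RLI}_i)/(y_{i+1}-y_i)$,
because the epoch gaps differ (24 vs 18 years); negative means
deteriorating.

A useful closed form used throughout the tests: if $d$ species deteriorate
by one weight step among $N$ included species in an interval, the index
moves by exactly $-d/(5N)$ — e.g. 100 of 1,000 gives $-0.02$.

## Summary arithmetic

Threatened fraction bounds treat DD as the only source of uncertainty:
lower assumes no DD species is threatened, upper assumes all are, and the
best estimate drops DD (and EX) from the denominator; EW stays in the
numerator because reintroduction remains possible. All displayed
percentages round half away from zero at the printed precision — this rule
reproduces every published percentage exactly (40.7/39.4/37.9% threatened,
11.3% DD, 58/39/37% driver shares, 87% deterioration share), which is how
it was chosen. Driver shares use integer percentages whose counts sum
exactly and whose percentages sum to 100 ± 1.

The fifteen raw primary drivers collapse into six groups; every driver
operating through habitat destruction or degradation (including
anthropogenic fire, native species, geological events and pollution) maps
to habitat loss/degradation; "introduced species" as a sole primary driver
warns and records as undetermined, since the only invasive-driven declines
operate through chytridiomycosis, which is coded as disease; equal
co-drivers map to "numerous".

## Threat-code grouping

The IUCN threat-classification scheme's dotted codes map to comparison
groups by prefix, exactly as listed in the documentation of
`group_threat()`. Named-agent records (8.1.2, 8.4.2) split the two chytrid
fungi from other invasives by a case-insensitive match on the epithet that
tolerates genus abbreviation ("B. dendrobatidis"). Code 7.3 (other
ecosystem modifications) is deliberately not folded into water management:
the grouping covers only 7.1 and 7.2, so 7.3 raises the same
"unmapped-code" condition as a code outside the scheme and is surfaced to
the caller rather than silently bucketed. Tallies include only ongoing and
future threats to threatened species (VU/EN/CR incl. CR(PE); EW optionally,
default off — extinct-in-wild species face no ongoing wild threats), count
each species at most once per group, and report separately the species for
which a group's threats are all in the future. A `major` flag is honoured
when present; absent, all ongoing/future threats count as major.

## Grid summaries

The grid is Behrmann cylindrical equal-area (standard parallel 30°) with
square cells sized to the requested area; presets 865 km² (richness maps)
and 7,775 km² (driver maps). Any equal-area grid satisfies the stated cell
areas — neither projection nor origin is prescribed by the convention we
follow — so the projection is a package choice. Polygon ranges (GeoJSON)
are rasterized by marking cells whose center falls inside the outer ring
plus cells hit by ring vertices and boundary points densified at half a
cell side; this approximates polygon–cell intersection well at these cell
sizes but can miss a cell a polygon merely clips at a corner. Pair-list
input (species, cell) bypasses geometry entirely and is the recommended
route when incidence is already known; it also sidesteps the question of
whether driver maps should use the historical or current range.

Richness classes are k-quantiles (default 10) of the occupied-cell richness
distribution: a cell's class is `floor(rank_min · k/n) + 1` with `rank_min`
the number of strictly poorer cells, so ties share the lowest class any of
them reaches, and fewer distinct values than classes merge classes (counted
and reported). Dominant-driver cells take the argmax of deteriorated
species by driver group; a two-way tie keeps both labels with `tie_flag`
(an intermediate map colour); three-or-more-way ties — which the two-colour
convention cannot render — and cells dominated by undetermined or numerous
drivers set `star_flag`.

## The synthetic generator

`scenario_config()` defaults encode the study conditions of the 2022
global amphibian assessment: 8,011 species over 1980/2004/2022, the
published 2022 category mix (within-threatened split partly synthetic, see
`gaa2_fixture()`), 482 and 306 deteriorations with the published driver
composition, 63 + 57 improvements, 264 multi-realm species,
breeding-strategy totals 5,320/2,452/61/178 and threat prevalences led by
agriculture at 77% of threatened species. Unpublished quantities —
realm weights, the order mix, threat timing shares, range-size and
clustering parameters — are set once at values a field herpetologist would
call plausible (e.g. 48% of species Neotropical, as published; ranges of a
few cells clustered into hotspots) and are not tuned.

Two modes: *scripted* draws the configured counts exactly (deterministic
marginals; used wherever exact arithmetic matters) and *stochastic* treats
rates as per-species Bernoulli hazards (used for statistical-recovery
properties). Generation composes backward from the final epoch: a
deterioration in an interval is realised as a declaration whose
state-at-start sits `step_size` rungs lower on the LC…CR(PE) ladder, so
generated deteriorations never produce the CR(PE)→EX direction-`none` case,
EW changes are never emitted, and DD species are never selected. Requests
that cannot be realised (improvements from LC, more changes than eligible
species) raise "infeasible-scenario".

What the generator does *not* emulate: real phylogeny and spatial ranges,
correlated threats across species, assessment error, taxonomic churn.
Passing tests therefore demonstrate the pipeline's arithmetic and rules,
not calibration against real amphibian data.

## Problem sizes and numerical choices

The test suite runs the full 8,011-species scripted scenario once, the
stochastic recovery at n = 2,000 over 3 seeds (binomial 3-SE bands), the
index oracle on 1,000 random small state sets (tolerance 1e-12; the
arithmetic is exact in double precision), and property loops of 25–200
cases under fixed seeds — a balance between coverage and a suite that runs
in well under a minute per file. Degenerate inputs have defined behaviour
throughout: all-DD sets raise "empty-after-exclusion", empty change sets
tabulate to empty tables, a single occupied cell is class 1, and zero
denominators in the summary formulas raise "degenerate-counts" rather than
returning NaN.

## Known limitations

* The RLI is a point value; no confidence intervals are computed.
* Genuineness is an input judgement; nothing infers it from evidence.
* Threat tallies ignore severity and scope of threats.
* Polygon rasterization is approximate at the cell-corner level.
* GAA1-era statistics (e.g. its 22.5% DD share) are historical context,
  not recomputed, and published quantities whose printed arithmetic is not
  self-consistent (the 39.9% growth figure, 92.9% coverage, the
  Gymnophiona 17% threatened figure with unstated denominator) are not
  reproduced.
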