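---
title: "Partner traits in quantitative flower-visitation networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partner traits in quantitative flower-visitation networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollinet)
```

## The question and the quantities

Species in plant–pollinator networks differ in *how many* partners they
use (linkage level, L) and in *how selectively* they use them relative to
partner availability (complementary specialization, d′). `pollinet`
implements a pipeline that classifies the extreme species of a community
on both axes — generalized/specialized by L, opportunistic/selective by
d′ — and then asks whether these groups differ in three traits of their
partners:

* **Evenness of partners' abundances**, Pielou's J′ = H′/ln S, where H′
  is the Shannon entropy of the partners' abundance distribution and S
  the number of partners. J′ = 1 for a single partner, by convention.
* **Partners' rank abundance**, a five-level cascade (5 = highly
  abundant … 1 = scarce) described below, averaged (unweighted) over a
  focal species' partners.
* **Partners' functional richness**: the number of distinct plant
  families (for visitor focal species) or insect functional groups (for
  plant focal species) among the partners. Ten visitor functional groups
  are distinguished by size and foraging behavior (large bees, small
  bees, flies, hoverflies, beetles, wasps, butterflies, true bugs, ants,
  others).

Profiles are computed per *monthly network snapshot* — networks
restricted to one month in one community — because only co-occurring
species can interact and because seasonal shifts in partner use are part
of the question.

## Network construction

Input data are timed focal censuses (one row per plant-census × visitor
species) and biweekly flower-density surveys. The interaction weight is
the flower visitation rate

FVR_ij = ( V_ij / (F_i · T_i) ) · D_i,

with V_ij the flowers contacted by visitor j on plant i over the period,
F_i the total flowers observed on i, T_i the total census minutes on i,
and D_i the plant's mean flower density (flowers·m⁻²) over the period's
surveys. The verbal definition of this weighting ("standardized by …
specific flower abundance") is directionally ambiguous; we follow the
rate-per-flower-scaled-by-availability reading, so abundance
*multiplies* the per-flower rate. `compute_fvr(mode =)` exposes
`"divide"` and `"none"` as alternatives.

A census is identified by (community, date, plant); effort fields must
be constant within that key and are counted once, not once per visitor
row. Censuses that recorded no visits are kept as `"NONE"` rows so that
observation effort is never lost. Censuses with zero recorded effort for
a positive contact count are an error, not a warning.

The raw integer contact-count matrix is retained alongside the FVR
matrix: d′ and its reference points are computed on counts, whose
integer allocation semantics the d_min algorithm requires. Species with
no interactions in a period are pruned from that period's network;
pruning never removes a species with a positive entry in either layer.

## Specialization indices

**Linkage level** L is the number of partners with positive weight in
the community's season network.

**Complementary specialization.** For a focal species with counts a_j on
partner j (total A, network grand total m) and partner availability q_j:

d = Σ_{a_j > 0} (a_j / A) · ln( (a_j / A) / q_j )   (nats).

Two availability modes are supported:

* `"marginal"` (the function default): q_j is the partner's marginal
  total of the same count matrix, and d_max = ln(m / A) — the value
  attained when all interactions fall on a partner used by nobody else.
* `"external"`: q_j is proportional to independently measured partner
  abundance (flower density for plant partners; observed individuals for
  visitor partners), and d_max = −ln(min_j q_j).

d_min is the smallest divergence attainable by *any* allocation of A
integer units across the available partners. It is found by
largest-remainder proportional apportionment followed by single-unit
local-search moves accepted while they lower d; an
exhaustive-enumeration oracle in the test suite confirms exactness on
hundreds of random matrices (focal totals ≤ 12, up to 5×5). Then

d′ = (d − d_min) / (d_max − d_min),

clamped to [0, 1] and defined 0 when d_max ≤ d_min (e.g. a 1×1 network).
Remainder ties in the apportionment are broken toward larger q, then
lower partner index, so results are deterministic.

The *pipeline* default is `availability = "external"`. The study design
this package serves measures flower availability independently of the
interaction records, and an availability-tracking forager should be
scored opportunistic against that independent availability. Under
marginal availability the guild's own visits inflate the apparent
availability of rare partners (a guild of rare-flower specialists makes
rare flowers look "available"), which blurs exactly the distinction the
index is meant to draw. Marginal mode remains the `dprime()` default —
it is the convention under which d_max = ln(m/A) is coherent — and is a
one-argument switch in `run_pipeline()`.

**Reliability filters.** Before selection, the season tables drop plants
censused < 30 minutes in total, visitors with < 5 observed individuals,
and species present in < 2 monthly networks. The time and count
thresholds are strict ("less than"); network presence is inclusive ("at
least"). "Observed five times" is counted as individuals, not census
events, and the presence filter is applied as an *eligibility* filter
before ranking, not after selection; both readings of the source
protocol exist, and these are the ones implemented. Visitor individuals
within a census are summed across rows of the same species; how multiple
conspecific individuals are aggregated is not specified by the protocol
we emulate, so summation is the documented choice.

**Selection.** Per community and guild, the n = 5 species with highest L
are generalized, lowest L specialized, lowest d′ opportunistic, highest
d′ selective. One species may hold several labels. Ties at the cutoff
are broken by larger season interaction total, then species name —
determinism matters more than any particular convention here.

## The abundance-rank cascade

Within one guild, one community-month (plants ranked by flower density,
visitors by observed individuals):

1. Let M be the maximum abundance. Species with abundance > 0.80·M —
   including the maximum itself — get rank 5 (*highly abundant*).
2. Among the remainder, with new maximum M′: > 0.75·M′ → rank 4.
3. Remainder, > 0.66·M″ → rank 3.
4. Remainder, > 0.50·M‴ → rank 2.
5. The rest are rank 1 (*scarce*).

Thresholds are strict, and each stage's maximum always qualifies for its
own stage. The written description of this scheme carries typographical
rank numbers that contradict its figure legend; we follow the legend
(5 = highly abundant, 1 = scarce). The third threshold is taken as 0.66
as printed, not 2/3. Zero-abundance tails are assigned rank 1 directly.

The cascade partitions the species set, is permutation-invariant, and
always gives the overall maximum rank 5 — properties asserted in the
test suite.

Community-level *heterogeneity of abundances* is reported as 1 − J′ over
all of a guild's abundances in a community-month. The source analyses
tabulate such a measure without defining it; 1 − J′ is this package's
inference and should not be quoted as the original formula.

## Partner profiles

For a focal species in a monthly network, the partners are the species
with a positive entry in either network layer (a recorded interaction
counts even when a zero measured density zeroes the FVR weight).
Evenness is computed over the *partners' abundances* — not over
interaction weights — matching the trait's definition; mean rank is the
unweighted mean over distinct partners (an interaction-weighted variant
sits behind `weighted = TRUE`); functional richness counts distinct
partner groups. Any partner missing from the abundance ranking or the
taxonomy is an error naming the species, never a silent skip.

## Statistical comparison

Traits are compared with linear mixed models: trait ~ category (or
month) with random intercepts for community and for month nested within
community, fitted with `lme4`, contrasts and single-step multiplicity
adjustment with `multcomp::glht`, Wald z statistics. The source analyses
label these GLMMs but describe normal-response linear models and report
z values; that is what is implemented, with visitor functional richness
log-transformed in the linkage-level models. When a variance component
collapses to zero (singular fit) the degenerate term is dropped and the
refit flagged in the result's `singular_fallback` field; seasonal models
that use month as a fixed factor while retaining month-within-community
in the random structure make this fallback routine rather than
exceptional. Month comparisons use all-pairs (Tukey-style) contrasts
with a compact-letter display; a many-to-one (Dunnett) option is
available, since the source's wording mixes the two conventions.

A stratified permutation test (`permutation_compare`) is provided for
small data: category labels are permuted within community-month strata
and p = (1 + #{|T_perm| ≥ |T_obs|}) / (1 + n_perm) for the
difference-of-means statistic, so p ≥ 1/(n_perm + 1) by construction.

The test suite calibrates the mixed-model path by simulation: under a
null with community and month-within-community intercepts (SD 0.5 each,
residual SD 1) and categories *balanced within strata* — the design
under which the category contrast is orthogonal to the random effects,
as a calibration null should be — the empirical type-I error at α = 0.05
over 500 replicates falls within [0.02, 0.08], and power for a 2-SD
planted difference at 20 observations per category exceeds 0.8 over 200
replicates. With categories scattered unbalanced across sparse strata
the Wald-z test is measurably liberal (≈ 0.08); users with severely
unbalanced data should prefer the permutation method.

## The synthetic community generator

`simulate_community()` emulates the census design the pipeline expects,
so that every stage can be exercised against planted ground truth:

* 4 communities × 4 months, two starting in April (3- and 6-minute
  censuses) and two in January (7.5 minutes), matching a two-island
  spring season; month indices are assigned from per-community season
  start dates, never from a shared calendar.
* On each census day every plant in bloom receives one census of the
  community's fixed duration — the equal-effort design that prevents
  abundant plants from accumulating more observation time.
* Flower densities are lognormal per species-month (median 60
  flowers·m⁻², between-species SD 1.2 on the log scale, month-to-month
  SD 0.3) within each species' phenology window. Biweekly surveys count
  open flowers over the community's surveyed area (1000 m² of belt
  transects at one site, thirty 0.5 × 0.5 m plots — 7.5 m² — elsewhere),
  so measured densities are Poisson-sampled around the truth.
* Visitor species carry planted **archetypes**: expected contacts in a
  census are base_rate × duration × flowers_observed × w_i, with
  w_i ∝ density_i^γ over the archetype's permitted plants, realized as
  Poisson counts; individuals are ceiling(contacts / 4). γ = +1 tracks
  abundance (opportunistic), γ = −1 favours rare plants (selective),
  γ = 0 is indifferent (generalized, specialized, background).

The archetypes operationalize the four partner-trait hypotheses the
pipeline is meant to recover: generalized visitors range over all
plants; specialized visitors anchor on one or two of the community's
dominant full-season bloomers (few but *common* partners); opportunistic
visitors forage among the 8 most abundant plants; selective visitors
work the 11 least abundant; background species (random moderate breadth
and activity windows) fill the community so that top/bottom-5 selection
is non-trivial. The three guaranteed full-season bloomers are also the
community dominants — abundance and flowering duration co-vary in the
communities this design emulates — which both anchors the specialized
archetype and keeps every month non-empty. Default sizes are 16 plants
and 24 visitors (5/5/5/5/4 across archetypes) per community: large
enough that the expected opportunistic-vs-selective difference in
partner functional richness is near zero (the planted "no difference"
panel) while the rank-abundance and evenness contrasts are strong, small
enough that the full pipeline runs in seconds. These defaults were fixed
by examining expectations across seeds, not any single run, and define
the package's reference conditions.

A single integer seed determines every draw. `planted_truth_report()`
cross-tabulates planted archetypes against recovered categories; with
the default configuration the pipeline recovers over 80% of planted
generalized and specialized visitors in the matching selections.

**What the generator does not emulate** — and hence what passing
recovery tests do and do not show: there is no spatial structure within
communities, no weather or time-of-day effects, no pollen transfer or
fitness, no taxonomic misidentification, and visitor "abundance" is the
number of individuals observed visiting flowers (as in the emulated
design, where independent visitor counts are unobtainable) rather than
an independent census. Plant families and visitor functional groups are
assigned uniformly at random, so partner functional richness carries
sampling noise that real phylogenetic structure would not. Plant-side
specificity categories are emergent, not planted: the generator plants
visitor behavior only, so plant-guild recovery claims are weaker than
visitor-guild ones, and the plant-side evenness contrast in particular
is near zero under these defaults.

## Numerical conventions and degenerate inputs

* All divergences and entropies are in nats; J′ uses ln.
* d′ is clamped to [0, 1]; d′ = 0 when d_max ≤ d_min (tolerance 1e-12).
* Local-search moves in d_min are accepted only if they lower d by more
  than 1e-15, so the search terminates.
* A single-species heterogeneity is 0 with a warning; an empty abundance
  table is an error.
* Zero-visit censuses, all-zero network rows/columns, and plants
  surveyed but never visited are all representable and tested.
* Singular mixed-model fits fall back as described; a plain linear model
  is the terminal fallback and is flagged.

## Problem sizes

The shipped tests run the full pipeline on the default 4-community
season (≈ 2,600 census rows), check the d_min heuristic against
exhaustive enumeration on 200+ random matrices with focal totals ≤ 12,
property-test the cascade/evenness invariants on 1,000 random instances
each, and calibrate the mixed-model path with 500 null and 200
alternative simulations — a few minutes end to end on one CPU. These
sizes are the package's reference conditions; all of them scale through
ordinary function arguments.

## Known limitations

* The FVR abundance standardization and the d′ availability mode are
  exposed as switches precisely because the verbal definitions admit
  more than one reading; results can differ materially between modes.
* Wald z inference ignores denominator-degrees-of-freedom corrections;
  at the shipped sizes the calibration is demonstrated by simulation,
  but very small or very unbalanced datasets should use
  `permutation_compare`.
* The d_min local search is exact on all enumerable cases we test, but
  no optimality proof is offered for arbitrary totals; the apportionment
  start point makes failures implausible rather than impossible.
* Morphological trait matching, floral rewards, color and scent are out
  of scope; so are network-level indices (H2′, nestedness, modularity)
  and sampling-completeness corrections.
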