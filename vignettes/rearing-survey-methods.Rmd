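---
title: "Methods: analysing drosophilid rearing surveys with rearnet"
author: "rearnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing drosophilid rearing surveys with rearnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rearnet)
```

## The data and the questions

A rearing survey collects fruit and vegetable fragments ("sample units"),
weighs them, and monitors each one in the laboratory for the adult
drosophilids that emerge. Every observation is therefore a *demonstrated
breeding record* — a fly species completed development inside a known host
taxon — which is far stronger evidence of host use than attraction to
baits. The atomic records are:

* a **plant registry**: taxon code, family, geographic origin
  (neotropical, exotic, or hybrid for crosses of mixed origin), and
  resource type (fleshy fruit FF, dry fruit DF, stem bulb SB, stem tuber
  ST, root tuber RT, vegetative leaf VL);
* a **fly registry**: species code and binary origin (neotropical or
  exotic);
* **sample units**: id, collection period, host taxon, mass in grams
  (grams avoid the decimal-separator ambiguity that kilogram notation
  invites);
* **emergence records**: sample id, fly species, count of emerged adults
  (zero counts are implicit and rejected at read time, which keeps the
  "at least one individual" rules below unambiguous).

The analyses answer three ecological questions: is sampling effort
sufficient and how does the assemblage change between periods
(rarefaction, rank-abundance, turnover, origin relative abundance); how
are flies distributed over hosts (interaction matrix, degrees, density,
success rates, mass correlations); and do exotic flies use a broader range
of resources than neotropical ones (niche breadth, origin-class matrix
occupancy)?

## Sample-based rarefaction

With `T` samples and species `i` present in `T_i` of them, the expected
richness in a random subset of `t` samples is the hypergeometric
expectation

$$E[S_t] = \sum_i \left(1 - \binom{T - T_i}{t}\Big/\binom{T}{t}\right),$$

evaluated with log-space binomial coefficients (`lchoose`) so surveys with
hundreds of samples do not overflow. The default sampling unit is the
*plant taxon* (each taxon's pooled fly list is one sample), the unit on
which survey-wide sampling sufficiency is naturally judged when collection
effort per taxon is uneven; `unit = "sample"` rarefies over individual
sample units instead. A permutation method (mean accumulation over random
sample orderings) is provided with its between-ordering standard
deviation; both methods agree at `t = T` by construction, and the analytic
curve is the exact mean of the permutation distribution. Tests verify the
analytic curve against exhaustive subset enumeration for `T <= 8` and
against an independent implementation.

## Assemblage structure

Rank-abundance tables order species by decreasing abundance with ties
broken by species code (stable, reproducible). Origin relative abundance
sums abundances per origin class and divides by the period total; raw
values are exact and percentages are rounded to one decimal with R's
round-half-even, the printed precision of survey reports. Period richness
and turnover are simple presence counts on the long abundance table.

## Host use

The interaction matrix pools emerged individuals per fly x host cell
within a scope (one period or pooled); its binary view (`>= 1`
individual) underlies degrees, occupancy and niche breadth. Two
bookkeeping choices mirror survey practice:

* **density** (flies per gram) divides by *productive* mass only — grams
  of sample units that yielded at least one fly — because mass that rotted
  unused says nothing about a host's carrying capacity once colonized;
  `denominator = "total"` is available for sensitivity;
* **success rates** count taxa whose empty-mass percentage is below 100,
  overall and for fleshy fruits versus all other resource classes pooled;
  taxa never collected are excluded (their empty-mass share is
  undefined).

Mass-richness and mass-abundance associations use Spearman's rho on
midranks. For `n <= 10` the two-sided p-value is exact, by complete
enumeration of all `n!` rank permutations (a small C++ routine walks the
permutations of the rank multiset); for larger `n` the usual
t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` applies. The cross-over
at 10 keeps the exact enumeration below four million permutations.

## Niche breadth

A fly species is a **specialist** when (i) at least two-thirds of its
breeding records fall in one plant family and (ii) every other family
holds at most a quarter of the records. Both comparisons are inclusive and
both thresholds are fractions of the *total* record count: that is the
reading under which the criterion's canonical worked example (60 records;
at least 40 in one family; no other family above 15) comes out exactly. A
`strict` flag applies the one-quarter cap to the records remaining after
removing the top family, for users who prefer the literal "remaining
records" phrasing. The default record unit is the colonized sample unit
(species x sample-unit occurrence); weighting by emerged individuals is an
option, not the default, because abundance conflates breeding-site choice
with per-site productivity.

## Origin-class matrix occupancy

Restricting to flies and hosts of unambiguous origin (hybrid-origin hosts
are excluded), the binary matrix splits into four blocks by (fly origin) x
(host origin). Each block contributes observed associations $O_c$ out of
possible $M_c$ = (flies in class) x (hosts in class), and the null of
interest is that occupancy is homogeneous across blocks at the overall
rate $\bar p = \sum O_c / \sum M_c$.

Two chi-square scales are provided:

* **count scale (default)**: the Pearson homogeneity statistic on the full
  blocks-by-outcome table (observed *and* unobserved associations),
  $\sum_c (O_c - M_c\bar p)^2 / (M_c \bar p(1-\bar p))$, df = included
  blocks − 1. Summing only the observed-association terms — a formulation
  one sometimes sees — deflates the statistic by roughly $(1-\bar p)$ and
  makes the test conservative (we measured a 2% type-I rate at a nominal
  5% before adopting the full table). Blocks with no possible pairs are
  skipped with the degrees of freedom reduced.
* **percentage scale**: the statistic computed on occupancy percentages,
  $\sum_c (pct_c - \overline{pct})^2/\overline{pct}$, optionally on
  pre-rounded values. This reproduces the convention of printed survey
  reports (equal weight per block regardless of block size) and is kept
  for comparability; it is not the default because its null distribution
  is not chi-square in general.

Post hoc, each block gets an exact binomial test of $O_c$ out of $M_c$
against $\bar p$, two-sided by the minimum-likelihood rule (sum of all
outcome probabilities no larger than the observed outcome's); the central
(doubled-tail) rule is available by flag. No multiplicity correction is
applied across the four tests, matching common practice in these surveys.
On the packaged survey table the two scales disagree in an instructive
way: the percentage-scale statistic (7.311 on the printed percentages) is
not significant, while the count-scale homogeneity test rejects strongly
and agrees with the post hoc pattern (exotic flies use exotic hosts more
than expected, neotropical flies less).

## The packaged survey summary

`load_paper_fixture()` ships a verbatim transcription of a published
two-period survey at a fruit and vegetable distribution center in central
Brazil: 50 plant taxa in 28 families (99.479 kg collected), 16 fly species
and 48,894 emerged individuals, and the four origin-class occupancy cells.
Two printed irregularities are handled downstream, never in the fixture:
the neotropical-fly x exotic-host denominator is printed as 174 although
the table's own class sizes and printed percentage imply 168 = 6 x 28
(`paper_occupancy(corrected = TRUE)` recomputes all denominators from
class sizes), and one printed percentage (24.28 for 68/280) is truncated
rather than rounded, so the report-convention chi-square of 7.311 is
reproduced exactly only when the *printed* percentages are taken as
inputs (`gof_from_percentages()`); recomputing them at full precision
gives 7.317. The printed post hoc p-values for the two neotropical-host
cells (0.067 and 0.064) are not reproducible under any natural reading of
the exact binomial construction (we obtain 0.42 and 0.72); the package
implements the natural reading and reproduces the direction and
significance of the two exotic-host cells.

## The synthetic rearing-survey generator

`generate_dataset()` draws, from one mandatory seed (three fixed
substreams: community, compatibility, survey):

1. **community**: fly counts i.i.d. from a log-series distribution whose
   parameter derives from Fisher's alpha and the species count (the
   implied community size solves $S = \alpha\log(1 + N/\alpha)$; sampling
   uses Kemp's rejection-free algorithm, valid arbitrarily close to the
   $x = 1$ boundary), normalized to relative abundances; origins Bernoulli
   per species/taxon;
2. **compatibility**: each fly x host pair is compatible with the
   probability of its origin class, `p_NN, p_NE, p_EN, p_EE`;
3. **survey**: sample units get a uniform host and a lognormal mass;
   compatible pairs produce negative-binomial counts with mean
   `mass_g * density_per_g * relabund` and size `nb_dispersion`;
   incompatible pairs never produce flies.

Defaults are the conditions of the packaged survey: 16 fly species (10
exotic), 49 unambiguous-origin hosts (28 exotic), Fisher's alpha 1.55
(implied by 16 species among roughly 49,000 individuals), compatibility
probabilities near the four observed occupancies, 200 sample units per
period across two periods with median mass 150 g (about 100 kg in total),
density 2.5 flies per compatible gram (about 0.5 flies/g overall, the
survey's magnitude) and dispersion 0.5.

The generator reproduces the features the analyses assume — dominance
skew, origin-structured host use, overdispersed counts, empty sample
units — but not temporal population dynamics, seasonality, parasitism or
competition, and hosts are sampled uniformly rather than by market
availability. Passing tests on synthetic data therefore validate the
*statistical machinery*, not any biological claim about real markets.

### Detection saturation and the validation regime

Under the survey-scale defaults, occupancy estimates the *product* of
compatibility and detection: a log-series-rare species (relative abundance
1e-4) is effectively never reared even from a fully compatible host, so
observed occupancy sits below the compatibility probability — exactly as
in real surveys, where the rarest species contribute host records far
below their true host range. This bias shrinks as sampling effort grows
(tested at three survey sizes), but at study scale it would confound
experiments whose target is the compatibility structure itself. The
statistical-validation experiments therefore use
`calibration_config()` — the same community dimensions with a flattened
abundance distribution (alpha 20), higher density (10 per gram) and 600
sample units — in which every compatible pair is detected with
probability near one. In that regime the count-scale test shows a 5–6%
type-I rate at nominal 5% (1000 replicates), over 90% power at a
compatibility contrast of 0.15 (200 replicates), and per-cell
Clopper-Pearson 95% intervals cover the true class probabilities in at
least 94% of 100 seeds. Problem sizes (1000/200/100 replicates) were
chosen to keep Monte-Carlo error well below the margins being tested
while the whole suite runs in well under a minute.

## Numerical and degenerate-input conventions

* Binomial coefficients in log space; `x/x` forms are divided before
  scaling so boundary percentages (0, 100) are bit-exact.
* Ties: Spearman uses midranks everywhere; rank-abundance breaks ties by
  species code; the minimum-likelihood binomial rule tolerates
  floating-point ties with a `1e-7` relative slack (the convention of the
  standard exact test).
* Empty inputs error early with stage names (`"no samples"`,
  `"empty assemblage"`, `"degenerate null"`); reading rejects unknown
  vocabulary tokens with row numbers; validation returns violations as
  data rather than exceptions.
* All randomness flows from explicit integer seeds; identical
  configuration and seed give byte-identical datasets.

## Limitations

* The fixture is a printed-table transcription; the full sample-level
  data of the survey are not public, so per-host densities and the mass
  correlations of the original study are not reproducible here and are
  deliberately not asserted anywhere.
* The percentage-scale chi-square is a comparability mode, not a
  calibrated test.
* Occupancy as an estimator of compatibility is downward-biased whenever
  detection is incomplete; treat survey-scale occupancy numbers as lower
  bounds on host range.
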