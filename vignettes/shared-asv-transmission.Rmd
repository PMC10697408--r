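---
title: "Tracking food-to-skin bacterial transmission with shared ASVs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking food-to-skin bacterial transmission with shared ASVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nukasv)
```

## The design and the statistic

A fermented rice-bran bed (*Nukadoko*) is a near-monoculture: one
lactic-acid-bacterium genus holds roughly 70–79 % of the community, and the
composition barely moves from day to day. Human palm skin is the opposite —
individual-specific and variable. That contrast is what makes a simple
set-based transmission statistic workable: when a bed ASV appears abundantly
on the palm of the person who just stirred it, the bed is by far the most
plausible origin.

The package's core quantity is the **shared ASV** set of a source–sink
sample pair. An ASV $f$ is shared at threshold $t$ when its relative
abundance exceeds $t$ in *both* samples:

$$\mathrm{shared} = \{ f : p^{src}_f > t \ \wedge\ p^{snk}_f > t \},
\qquad
S = 100 \sum_{f \in \mathrm{shared}} p^{snk}_f .$$

$S$ is the sink-weighted shared proportion: the percentage of the skin
community attributable to features also abundant in the bed. The threshold
(default $t = 0.01$) deliberately absorbs the technical noise floor of 16S
amplicon data — extraction, primer and sampling-method variation — at the
cost of missing low-abundance transfer. The comparison is strict (`>`): a
feature at exactly 1 % is not shared. `find_shared_asvs()` exposes a `">="`
variant for sensitivity analysis, and `shared_proportion()` can be applied
to the source vector for a source-weighted variant; both are deviations
from the default reported statistic.

Two pairing rules reflect the two study phases. During contact (days 0–14)
each skin sample is paired with the same subject's same-day bed sample —
including the pre-interaction day-0 swab, which serves as each subject's
own negative control. After stirring stops (days 15–29) skin samples are
paired against a fixed source day, default 14, the last day the bed was
touched: the bed no longer receives input from the subject, so the most
recent contacted state is the right comparator for shedding. The fixed day
is a parameter of `build_pairs()`. A skin sample with no available partner
becomes an explicit unpaired row with a reason, never a silent omission.

An important reading note: "shared" is a *membership* statement and is
symmetric in the pair; the *proportion* is not, because it is weighted by
sink abundances. Both properties are asserted in the test suite.

## Preprocessing assumptions

Organelle 16S-like reads (chloroplast, mitochondria) and classifier-level
`Unassigned` ASVs are removed before any community statistic, with exact
per-sample read accounting (`filter_organelle_unassigned()`). Matching is
by case-insensitive substring on lineage ranks, with `mitochondri` rather
than `mitochondria` to catch adjectival spellings across database releases.
Lineages resolved only to a high rank (e.g. domain alone) are *kept*:
"unassigned" is read as "unplaced", not "poorly resolved". Whether that
reading matches any particular upstream pipeline is genuinely open, so a
`min_ranks` option exists for the stricter interpretation; it is off by
default.

Counts and relative abundances are distinct classes. Threshold operations
only accept the relative type, so the 1 % rule can never silently run on
raw counts.

Genus-level summaries (`collapse_genus()`, `top_n_summary()`) rank genera
by mean relative abundance across the presented samples, ties broken
lexicographically — the ranking criterion for "top N" stacked-bar summaries
is a presentation choice, and this one is deterministic. Features without a
genus rank are grouped as `Unclassified_<lowest named rank>` so that mass
is conserved (columns still sum to 1).

## Diversity and rarefaction

`shannon()` uses base-2 logarithms by default; the base is a reporting
convention, configurable per call (base *e* reproduces `vegan::diversity`,
against which the implementation is cross-checked in the tests).

`rarefy()` draws a subsample *without replacement* — one multivariate
hypergeometric sample — implemented by sequential conditional
`rhyper()` draws, which is exact and O(features) per draw.
`rarefaction_curve()` evaluates the metric over the depth grid
$\{0, s, 2s, \dots \le D\}$ with defaults $D = 10\,000$ and $s = 500$,
averaging 10 draws per point; the grid limit matches the depth range a
typical study of this size reports, and the step/iteration defaults trade
smoothness against runtime and are exposed as parameters. Depth 0 is
defined as 0 for both metrics (the limit convention) so curves plot from
the origin, and depths exceeding a sample's total are skipped for that
sample, never extrapolated. Reproducibility is per-point: substream seeds
are derived deterministically from one master seed and the (sample, depth,
iteration) index, so evaluation order cannot change the curve.

## The simulator and its ground truth

`generate_study()` produces a dataset shaped like the real design — per
subject, a bed series over days $\{0,3,6,9,12,14\}$ and a skin series over
timepoints $\{0, 0', 3, \dots, 14, 15, 18, \dots, 29\}$ — with known truth:

* **Source community**: one dominant ASV at `dominant_mass` (drawn
  uniformly in $[0.69, 0.79]$ per subject unless fixed), remainder split by
  a flat Dirichlet draw. Day-to-day wobble is a Dirichlet perturbation with
  concentration 2000, chosen so realised day-to-day composition shifts stay
  within a few percentage points — a conservative community; `Inf` freezes
  it exactly.
* **Sink baseline**: a sparse Dirichlet draw (concentration 0.3) over the
  subject's own ASV universe, disjoint from all source universes by
  default so that every shared detection is attributable to transfer.
  `overlap_abundance` opts into one ambient source ASV present on skin at
  a fixed abundance before any contact, modelling background sharing.
* **Transfer**: one mixing event per stir,
  $(1-f)\,\mathrm{sink} + f\,\mathrm{source}$ with $f = 0.10$ by default.
  The 6 h stir-to-swab gap is absorbed as a single shedding step of 0.25 d
  before each contact-phase sample; there are no within-day dynamics.
* **Shedding**: decay only, $f_t = f \cdot 2^{-\Delta t / h}$ with
  half-life $h = 0.5$ d by default. No-contact samples decay the day-14
  state. A decay-only model is one consistent choice: a cross-sectional
  paired design cannot distinguish true colonisation from passive residue,
  and the default half-life reproduces the qualitative signature the design
  can observe (detection on day 15, none afterwards).
* **Reads**: multinomial per sample at a depth drawn uniformly from
  $[13\,053, 41\,949]$, the depth spread typical of palm and bran samples
  after organelle removal. Sixty source and eighty sink ASVs per subject
  give realistic richness (about 50–60 observed features in the bed).

The truth object records, per timepoint, the *expected* shared proportion
computed from the pre-multinomial mixture profiles at the recording
threshold, plus the transferred feature ids and all derived seeds. Tests
compare pipeline output against these expectations within binomial
sampling error — which is the correct error scale because, under the
default geometry, the shared set is effectively just the dominant ASV:
every other source ASV lands an order of magnitude below the sink threshold
after mixing.

What the simulator does **not** emulate: compositional correlation between
ASVs, growth or competition on skin, primer/extraction bias, chimeras, or
classifier uncertainty. Passing tests therefore demonstrate that the
pipeline's arithmetic and bookkeeping are correct under the stated
generative model, not that the biological inferences from any real dataset
are robust to those effects.

## Parameter-recovery properties

Two recovery checks anchor the pipeline end-to-end:

* **Transfer**: at fixed depth 30 000 and $f = 0.10$ with a 0.75 dominant
  mass, the contact-phase shared proportion matches the closed-form
  expectation per timepoint within three binomial standard errors of the
  seed-averaged mean, and every truly transferred ASV whose expected
  post-transfer sink abundance clears $1.5 t$ is detected as shared.
* **Shedding**: regressing the log expected shared proportion on day over
  the detectable no-contact timepoints returns slope $-\log 2 / h$ to
  machine precision in the noiseless (frozen-source, expectation-level)
  case, and within a seed-bootstrap confidence interval at finite depth.
  These checks run at $h = 5$ d so that several no-contact timepoints sit
  above the detection threshold and the slope is identified; at the
  default $h = 0.5$ d only day 15 is detectable, which is exactly the
  sharp-shedding signature but cannot support a regression.

## Reference-sequence curation

The `refseq_qc` functions mirror standard curation of an SSU reference
database before classifier training: cull sequences with ≥ 5 degenerate
(non-ACGT IUPAC) bases or a homopolymer of ≥ 8 bases; apply
domain-conditional length minima (archaea 16S ≥ 900 bp, bacteria 16S
≥ 1200 bp, eukaryote 18S ≥ 1400 bp); and dereplicate in "uniq" mode, where
identical (sequence, lineage) records collapse to the first occurrence but
identical sequences under different lineages all survive. The ambiguous-base
rule is stated ambiguously in common descriptions ("> 5 or more"); this
package rejects at **≥ 5**, matching the upstream tool's documented default,
and both cut-offs are parameters. U is normalised to T on ingest, so RNA
alphabets are tolerated and degeneracy counting always sees DNA. Sequences
whose domain cannot be resolved pass the length filter with a warning —
dropping them would silently shrink the database with no stated rule.
First-occurrence retention in dereplication is likewise a determinism
choice, not a semantic one.

## Numerical and degenerate-input choices

* All-zero samples are an error by default in `to_relative()`
  (they signal upstream failure); `drop_empty = TRUE` removes them loudly.
* Column-sum conservation is asserted to $10^{-9}$; shared-proportion
  conservation in the genus breakdown to the same tolerance.
* `rarefy()` refuses depths above the sample total; callers encode the
  skip policy (the curve skips, nothing extrapolates).
* Ties in top-N ranking and duplicate-record retention are broken
  deterministically (lexicographic; first occurrence).
* Integer counts are stored as doubles to avoid 32-bit overflow in totals;
  integrality is enforced at construction.

## Problem sizes

The test suite and acceptance script run entirely on simulated data at the
study's own scale: 420 features × 57 samples per study, depths 13 053 to
41 949 (or fixed 30 000 where the binomial error term must be known), 100
simulated studies for the transfer-recovery check, 20 for the bootstrap
slope, 10 000 rarefaction draws for the hypergeometric comparison, and 1000
random pairs for the brute-force equivalence of the shared-ASV scan.
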