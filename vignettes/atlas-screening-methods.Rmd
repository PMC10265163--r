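---
title: "Screening for targets highly expressed above background atlases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for targets highly expressed above background atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasscreen)
```

## The problem

A recurring question in target discovery — senolytic therapy, CAR-T target
selection, tumor-specific antigens — is whether a gene or transcript is
highly expressed in a condition of interest (say, replicative-senescent
cells) while remaining *lowly expressed everywhere else in the body*. The
"everywhere else" is represented by background expression atlases: large
compendia of RNA-seq profiles across normal tissues and cell types.
`atlasscreen` implements this screen: per feature, it asks whether an input
sample group is significantly more highly expressed than **every** category
of one or more background atlases, aggregates the calls over many
(group × background) comparisons into a consensus set, and then narrows
that set to actionable candidates (membrane-bound or secreted proteins) and
annotates it with overlaps against aged-tissue and disease gene sets.

## The screening statistic

All expression is placed on the log2 counts-per-million scale,
$x = \log_2(1 + 10^6 c / L)$ with $L$ the sample's library size. This
normalization is a deliberate design choice: it is scale-free across
studies, strictly monotone in counts, and — critically — lets a background
be represented by *summary statistics only*.

An atlas stores, per feature and category, the triple $(n, \bar{x}, s)$:
sample count, mean, and sample standard deviation of normalized expression.
Raw atlas samples are never needed at screening time, which is what makes
very large public backgrounds practical to ship and query.

"Significantly higher than every category" is operationalized as a single
test against the **adversarial category** — the category with the largest
mean for that feature (ties broken lexicographically). The test is a
one-sided Welch test computed from summaries. With
$v_g = \max(s_g^2, \varepsilon)/n_g$ for the input group and $v_b$ likewise
for the adversarial category,

$$ t = \frac{\bar{x}_g - \bar{x}_b}{\sqrt{v_g + v_b}}, \qquad
   \nu = \frac{(v_g + v_b)^2}{v_g^2/(n_g - 1) + v_b^2/(n_b - 1)}, $$

and $p$ is the upper tail of Student's $t_\nu$. When all categories share
the same $n$ and $s$, the adversarial $p$ equals the maximum of the
per-category $p$-values exactly (the largest background mean minimizes
$t$), so one test per feature stands in for testing against every category;
with unequal variances it is a conservative surrogate, at $O(1)$ rather
than $O(\#\text{categories})$ tests per feature. The test suite verifies
the max-$p$ identity and checks the summary-based screen against raw-sample
`t.test` calls to ten significant digits.

Within each comparison, $p$-values are Benjamini–Hochberg adjusted across
features; a feature is *significant* when $q \le \alpha$ **and** its log2
fold-change over the adversarial mean is at least `min_lfc`. BH is applied
within comparisons, never across them, because the aggregation mechanism
across comparisons is vote counting, not $p$-value combination.

### Parameters and defaults

| parameter   | default | units | why |
|-------------|---------|-------|-----|
| `alpha`     | 0.05    | FDR   | conventional per-comparison FDR level; a package default, not an empirical constant |
| `min_lfc`   | 1.0     | log2  | requires at least a doubling over the most-expressing normal category; a package default |
| `var_floor` | 1e-8    | (log2)² | keeps zero-variance summaries testable without materially moving any non-degenerate statistic |
| `threshold` | 0.25    | fraction | consensus rule: a feature must be called in at least a quarter of all comparisons |

Singleton categories ($n = 1$, e.g. rare cell types) are kept rather than
discarded: their sd is stored as 0 and, at test time, replaced by the
median sd of the same feature across multi-sample categories, with the
$(n-1)$ term in the Welch degrees of freedom floored at 1. This keeps rare
cell types in play as adversaries without letting a zero variance produce
infinite statistics.

## Consensus across comparisons

Each input group is screened against each atlas of the matching feature
level; the plan is the full cross product, and gene-level and
transcript-level pipelines run independently. The consensus fraction of a
feature is the number of comparisons in which it was significant divided by
the **total number of comparisons in the plan** — a feature absent from one
atlas's feature space counts as not-significant there, which is the
conservative reading of "fraction of analysis conditions". The consensus
set at threshold $\tau$ is all features with fraction $\ge \tau$; it is
antitone in $\tau$ by construction, and the suite exercises this end to
end (a feature callable in only one of six comparisons is excluded at
$\tau = 0.25$ and admitted at $\tau = 0.15$).

## Annotation and reporting

Membership filters (membrane-bound proteins, secreted proteins) are plain
order-preserving intersections. Flag libraries (aged-tissue sets, disease
signatures, protein-level evidence) mark each target by membership in the
**union** of the library's sets — the report's headline statistic is
disjunctive ("in any aged tissue"), with a long-format per-set table
available via `overlap_detail()`. Summary percentages are reported at two
precisions, one decimal and nearest whole number, rounded half away from
zero.

Local enrichment uses the one-sided Fisher exact / hypergeometric tail
with an explicit, user-supplied universe size (enrichment $p$-values are
universe-sensitive; hiding the universe in a constant invites
misinterpretation). The sensible default universe is the number of
features actually screened. Rank-combination scores that depend on
permutation tables of external web services are deliberately not
reproduced; the output is $p$, BH $q$, and an odds ratio with a Haldane
0.5 correction when a table cell is zero.

## The synthetic-data generator

The generator exists so every stage is testable without multi-gigabyte
atlas downloads. It works directly on the log2 scale the screen tests on:
per-(feature, category) means $\mu_{fc} \sim N(m_0, s_0^2)$ (defaults
$m_0 = 4$, $s_0 = 1$), samples $x \sim N(\mu_{fc}, \sigma^2)$ with
within-category noise $\sigma = 0.5$, back-transformed to pseudo-counts
$\max(\mathrm{round}(2^x - 1), 0)$ for file round-trips. Input groups draw
non-planted features at their feature-wise *maximum* category mean — so
they are, by construction, not targets — and planted features at that
maximum plus `planted_lfc`. The standard evaluation condition is 500
features, 20 categories × 10 samples, 20 planted features at +4 log2
units, input groups of 5; replicate studies of the same biology reuse the
$\mu$ matrix with fresh sampling noise.

Two scales deserve a note. Recovery evaluation (`planted_recovery()`)
screens the generated log values directly, because that is the scale the
generative model defines effects on. When the pseudo-counts are written to
files and re-normalized as CPM, planted features inflate the input group's
library size and compress the realized fold-changes (a compositional
effect real data also shows); the file-based pipeline tests run through
this path deliberately, at a correspondingly smaller planted recovery
margin. What these simulations do **not** emulate: negative-binomial count
noise, library-size heterogeneity, batch structure, or the category
composition of any real atlas — passing them shows the statistic and its
plumbing are correct, not that any particular biological target list is
right. A count-level negative-binomial generator is the natural extension
point.

Seeding uses one root seed with fixed per-stage offsets, so a replicate is
reproducible end to end within this implementation; tests assert
statistical properties rather than bitwise values except where a seed is
pinned.

## Numerical and design choices

* Duplicate feature rows in a counts file are summed (the usual gene-level
  aggregation of multi-row symbols); identifiers match case-sensitively by
  default with an opt-in `uppercase_ids` normalization.
* Atlas serialization is a flat TSV of (feature, category, n, mean, sd) at
  17 significant digits — diff-able, language-neutral, and lossless for
  IEEE doubles — plus a JSON sidecar carrying name, feature level and a
  schema version that is checked on load.
* Adversarial-category ties and ranking ties are broken lexicographically;
  result ranking is (q ascending, lfc descending, feature id ascending).
  Everything downstream of fixed inputs is deterministic.
* The problem sizes used in the shipped tests and acceptance script
  (hundreds of features, tens of categories, 20–50 simulation replicates)
  were chosen as the smallest scales at which the statistical properties
  under test are stable.

## Known limitations

* The adversarial-category reduction is conservative under strong
  heteroscedasticity: a lower-mean but high-variance category could in
  principle yield a larger per-category $p$ than the adversary. The
  equal-variance identity bounds this; users screening backgrounds with
  wildly uneven category variances should lower `alpha` rather than rely
  on the reduction being exact.
* Summary-based atlases cannot support rank or resampling tests; the Welch
  form is the price of compact backgrounds.
* No batch correction or cross-study normalization beyond CPM is applied;
  backgrounds processed with different quantifiers are comparable only to
  the extent log2 CPM makes them so.
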