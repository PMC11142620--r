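---
title: "Feature-type composition and semantic-network structure of early vocabularies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-type composition and semantic-network structure of early vocabularies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(featnet)
```

## The scientific problem

Early-learned nouns and verbs differ in the kind of semantic information
their meanings are built from. Adult-produced semantic feature norms
decompose a word's meaning into typed microfeatures: *perceptual*
(sensorimotor, `<is red>`), *functional* (interaction and use,
`<is eaten>`), *taxonomic* (category membership, `<a food>`) and
*encyclopedic* (the remaining, often social, affective or decontextualized
knowledge, `<is fun>`). Two questions follow:

1. **Composition.** Do the meanings of early-learned verbs draw on
   different mixtures of feature types than nouns?
2. **Structure.** In individual children's vocabularies, which feature
   types carry the semantic relationships among known words — and do nouns
   and verbs differ in how strongly they connect through each type, once
   chance expectations are controlled?

`featnet` implements both analyses over a CDI-style lexicon (a checklist
vocabulary of early-learned nouns and verbs) together with a synthetic-data
generator that emulates the statistical structure of the inputs, so the
whole pipeline is testable without access to the proprietary norms or the
checklist database.

## Composition analysis

Each entry's features are counted by type and divided by the entry's total
feature count, giving four proportions per word that sum to one. Raw
totals are first compared between nouns and verbs with a Welch
(unequal-variance) two-sample t test, to confirm that any compositional
difference is not an artifact of verbs simply having fewer features.

The proportions are analysed with a two-way ANOVA,
`proportion ~ feature_type * pos`, each word contributing four
observations. Two structural facts are worth knowing:

* Because every word's proportions sum to one, the part-of-speech main
  effect is *identically* zero — each word's marginal mean is 0.25
  regardless of its part of speech. The test of interest is the
  feature-type × part-of-speech interaction.
* With N words the residual degrees of freedom are 4N − 8; at the study
  size (359 nouns + 103 verbs) that is 1840.

The interaction is unpacked with estimated marginal means (via `emmeans`):
cell means per (part of speech, feature type) and the noun-minus-verb
contrast per feature type with unadjusted 95% t-intervals from the
residual mean square. In this balanced within-word design the contrast
equals the plain cell-mean difference; the proportions within a word are
not independent, so the intervals inherit the usual caveat of treating the
four rows per word as exchangeable observations (the analysis mirrors
common practice for this design). Confidence intervals on the
per-type marginal means are model-based for the same reason; intervals
computed per type from the raw columns would differ slightly.

## Semantic networks and weighted degree

A child's network has their produced words as nodes; an undirected edge
joins two words that share at least one semantic feature, weighted by the
number of shared features. Separate networks restrict the shared features
to each of the four types; the unrestricted network's weights equal the
sum of the four restricted weights. *Weighted degree* — the sum of a
node's incident edge weights — measures how strongly a word is connected
to the rest of the vocabulary; isolated words count with degree zero, and
a word's standing in the analyses is the mean weighted degree over the
child's nouns or over the child's verbs.

Internally a network is a vertex-induced submatrix of the lexicon-level
shared-feature count matrix (an incidence-matrix cross-product). This
makes the null-model simulation below a dense matrix product rather than
hundreds of thousands of explicit graph constructions.

## Normalizing degree against random networks

Raw mean degree is uninformative on its own: nouns and verbs differ in
feature composition and in how many of them a child knows, so their raw
degrees differ for trivial reasons. The package therefore normalizes each
child's value against random networks of *matched noun-verb composition*:
random draws of the same number of nouns and verbs from the lexicon, with
the same restricted network construction. The reported quantity,
*normalized degree*, is the percentile of the child's mean weighted degree
in that null distribution — 50 means "looks like a random vocabulary of
the same composition".

Simulating every observed (noun count, verb count) combination is
wasteful, so the space is sampled: PCA of the observed integer points
defines an elliptical interior (|score| ≤ 2 SD on each principal axis, on
the raw count scale by default); 15% of interior points are drawn at
random, all exterior points are kept, and the edges of the space (per
observed noun count, the minimum and maximum observed verb count, and
symmetrically) are added. Degenerate spaces (fewer than three points, or
collinear) are sampled in full. At each sampled point a configurable
number of random networks (200 by default at desk scale, 1000 at full
scale) yields per-part-of-speech mean degrees, binned into 64 equal-width
degree bins shared across the space per restriction × part of speech and
spanning `[0, max·(1 + 1/n_bins)]` so the largest observation falls inside
the last bin.

Unsampled points are filled in by piecewise-linear interpolation of each
degree bin's mass over the plane (Delaunay triangulation with barycentric
weights, via the `interp` package); outside the convex hull the nearest
sampled column is used, and interpolated columns are renormalized.
Percentiles are read off the column with mass within the containing bin
apportioned linearly — sub-bin interpolation that removes most of the
discretization bias of binned "at or below" proportions.

### Why smoothing is off by default

A Gaussian smoothing step along the degree axis (`smooth_histograms()`,
reflected at both boundaries so uniform columns are exactly invariant and
mass is conserved) is available to iron out binning and interpolation
artifacts. It is **off by default** in `normalize_children()` for a
quantitative reason: the shared degree axis spans the whole
vocabulary-size space, so a single bin is already comparable to — and a
two-bin kernel sigma substantially wider than — the *local* spread of the
null distribution at any one point. Convolving the null with a kernel
wider than its own spread symmetrically inflates its tails, which pulls
every percentile toward 50 and destroys the defining calibration property
of normalized degree (uniform on [0, 100] for random vocabularies; the
test suite checks exactly this). The within-bin linear apportionment in
`percentile_rank()` provides the artifact control that smoothing was meant
to supply, without the bias. Users who want the kernel anyway can pass
`smooth = TRUE` and a bandwidth in bins.

## Cluster-based permutation comparisons

Normalized degree is compared across vocabulary-size bins of 20 words
(children labelled by the right edge of their half-open bin). Within each
bin a **paired** t statistic is computed on within-child differences —
noun vs verb within a network type, or encyclopedic vs perceptual within a
part of speech. Bins with fewer than two pairs or constant nonzero
differences are skipped (a bin of exactly tied pairs is a clean t = 0);
maximal runs of contiguous, same-sign bins with |t| ≥ 3.29 form clusters
whose *mass* is the sum of member t statistics.

Significance comes from a permutation null that matches the paired design:
each child's two condition labels are swapped independently with
probability ½ (equivalently the within-child difference changes sign) and
the whole bin-wise-t plus clustering pipeline is re-run. The null
statistic is the maximum |cluster mass| per permutation, which controls
the family-wise error rate over bins; a pooled all-clusters null is
available via `null = "all"` for sensitivity. Empirical p values use the
(1 + count)/(1 + n_perm) correction and are never zero. Desk-scale runs
use 1000 permutations; the full-scale preset uses 10,000.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
exercised:

* **Lexicon** (`norms_config()`, `generate_lexicon()`): 359 nouns and 103
  verbs. Per-word feature totals are rounded normals truncated at ≥ 3
  (nouns mean 13.15, SD 3.42; verbs mean 12.41, SD 3.97), split across
  feature types by per-part-of-speech multinomial profiles (nouns:
  encyclopedic .27, functional .20, perceptual .41, taxonomic .12; verbs:
  .55, .03, .28, .14). Feature labels come from per-type shared pools
  (600/250/600/120 labels) with Zipf-like reuse (weight ∝ rank^−s, s = 1
  by default) — reuse is what creates shared-feature edges, and the
  heavy-tailed pool use mimics the fact that a few features (like
  `<is red>`) recur across many words. Pool sizes and the exponent are
  realism knobs, chosen once to give connected but non-saturated networks
  (roughly 1–2 shared features per word pair on average); the real norms'
  sharing distribution is not published.
* **Population** (`population_config()`, `generate_population()`):
  children aged 16–30 months with latent abilities; each word has a
  difficulty made of a rank-based spread plus an additive offset for verbs
  (+1.5 logits), so nouns dominate early vocabularies — early vocabularies
  show noun:verb ratios well above 3, and the verb share grows with
  vocabulary size. Production is a logistic function of ability + age −
  difficulty. Vocabulary-size percentiles are computed within age-month
  groups (mirroring CDI norming practice) and children at or below the
  20th percentile — the conventional late-talker cutoff — are removed.
* **Effect injection** (`inject_effect()`): scales the Zipf exponent for a
  (part of speech, feature type) cell, densifying that cell's sharing
  (e.g. multiplier 3 on verb-encyclopedic features). Crucially,
  lexicon-level densification alone is *invisible* to normalized degree:
  the null networks are drawn from the same lexicon, and percentile
  normalization is a probability integral transform under random draws, so
  any purely lexicon-level structure cancels. The published pattern is a
  fact about *which words children learn first*, not about the lexicon in
  isolation. The generator therefore couples acquisition order to the
  injected cell: with multiplier m, a word's difficulty is reduced by
  (m − 1) × its standardized same-part-of-speech hub-ness in that feature
  type's network, so early verb vocabularies are enriched for encyclopedic
  hubs. Multiplier 1 implies no coupling; multiplier 0 removes reuse
  weighting entirely (sharing by chance collision only).

What the generator does *not* emulate: real acquisition-order
heterogeneity across children (order is a single difficulty ranking plus
noise), semantic coherence of feature co-occurrence within words,
age-of-acquisition norms, or the empirical joint distribution of noun and
verb vocabulary sizes. Passing tests therefore show that the *pipeline*
recovers structure it is pointed at under controlled conditions — not that
the generator's worlds are faithful replicas of children's vocabularies.
One consequence worth knowing: even without injection, a single generated
lexicon plus a fixed acquisition order is one realization of a random
world, and its idiosyncratic sharing structure can produce genuine (for
that world) clusters; the type-I calibration of the cluster test is a
statement about the exchangeable within-child null, not about
between-world variability.

## Numerical choices and degenerate inputs

* Feature identity is exact match on case-folded, trimmed labels;
  duplicated rows collapse.
* Welch t with two constant equal groups returns t = 0, p = 1; constant
  unequal groups are an error (the df is undefined).
* Interpolation targets coinciding with sampled points reproduce the
  sampled column to 1e-9; collinear sampled points fall back to
  nearest-point lookup.
* Histogram columns must sum to 1 within 1e-9 at every populated or
  interpolated point; tiny negative barycentric round-off is clipped.
* One top-level seed governs each stage; per-(restriction, point)
  substreams are derived deterministically from it, so results are
  reproducible and byte-identical across runs at fixed seed.
* Desk-scale problem sizes (500 children, 200 networks per sampled point,
  64 bins, 1000 permutations) are the package defaults and are what the
  bundled analysis scripts and tests run; the `preset = "full"`
  configuration raises these to 1000 networks per point and 10,000
  permutations.

## Worked example

```{r example, eval = FALSE}
library(featnet)

lex <- generate_lexicon(norms_config(), seed = 1)
anova_composition(lex)

pop <- generate_population(lex, population_config(n_children = 500), seed = 2)
space <- sample_space(enumerate_space(pop), seed = 3)
hists <- assemble_histograms(space, lex, reps = 200, seed = 4)
records <- normalize_children(pop, lex, hists)
compare_pos_within_type(records, "encyclopedic", n_perm = 1000, seed = 5)
```

The numbered scripts under `analysis/` run the same stages over files and
write their tables under `results/`.

## Known limitations

* The normalization assumes the lexicon is the closed universe of words;
  children's words missing from the norms are dropped with a warning.
* Percentile ranks saturate at 0 and 100; at 200 networks per point the
  effective resolution of extreme percentiles is about half a percentile.
* The cluster procedure tests bin-wise differences; it has no sensitivity
  to effects that reverse sign within a bin range, and bin labels inherit
  the right-edge convention.
* Contrast intervals are unadjusted for multiplicity across the four
  feature types.
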