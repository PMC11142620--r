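# featnet

Feature-type composition and semantic-network structure of early noun and
verb vocabularies.

Children's early words can be described by adult-produced semantic feature
norms, with each feature typed as *encyclopedic*, *functional*,
*perceptual* or *taxonomic*. `featnet` asks two questions of a CDI-style
lexicon (a caregiver checklist of early-learned words) and a population of
child vocabulary records:

1. **Composition** — are verb meanings built from different mixtures of
   feature types than noun meanings? Answered with per-word feature-type
   proportions, a Welch t test on raw totals, and a two-way ANOVA
   (`proportion ~ feature_type * pos`) with estimated-marginal-mean
   noun−verb contrasts per feature type.
2. **Structure** — within individual children's vocabularies, which
   feature types carry the semantic relationships among words? Each
   child's words form a weighted network (edge weight = number of shared
   features of a given type); the mean *weighted degree* of the child's
   nouns and verbs is turned into a **normalized degree** — its percentile
   among random networks with the same noun-verb composition, built from
   PCA-guided sampling of the vocabulary-size space, per-point random
   network simulation, piecewise-linear interpolation of 3-D degree
   histograms, and sub-bin percentile reading. Noun-vs-verb and
   encyclopedic-vs-perceptual differences across vocabulary-size bins of
   20 words are then tested with cluster-based permutation tests (paired
   bin-wise t, |t| ≥ 3.29 clusters, max-|cluster-mass| permutation null).

A synthetic-data generator (`generate_lexicon()`,
`generate_population()`, `inject_effect()`) emulates the statistical
structure of both inputs — feature-type profiles per part of speech,
Zipf-like shared feature pools, noun-first CDI-like growth trajectories
and the >20th-percentile (late-talker) inclusion filter — so the entire
pipeline runs and is tested without any proprietary data.

## Worked example

The numbered scripts under `analysis/` run the full workflow and write
tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic norms + 500 children
Rscript analysis/02_composition.R     # composition ANOVA + contrasts
Rscript analysis/03_normalize.R       # networks, normalization, clusters
Rscript analysis/04_effect_recovery.R # injected verb-encyclopedic effect
```

`02_composition.R` prints, for a simulated study-sized lexicon (359 nouns,
103 verbs):

```
ANOVA (proportion ~ feature type * part of speech):
             term   df       SS       MS        F         p
     feature_type    3 2.41e+01 8.03e+00 6.20e+02 1.31e-278
              pos    1 1.66e-32 1.66e-32 1.29e-30  1.00e+00
 feature_type:pos    3 9.17e+00 3.06e+00 2.36e+02 1.14e-129
        Residuals 1840 2.38e+01 1.29e-02       NA        NA

Noun - verb contrasts (negative = more abundant for verbs):
 feature_type estimate    se   df  lower  upper
 encyclopedic   -0.258 0.013 1840 -0.283 -0.234
   functional    0.161 0.013 1840  0.136  0.186
   perceptual    0.141 0.013 1840  0.116  0.166
    taxonomic   -0.044 0.013 1840 -0.069 -0.019
```

The part-of-speech main effect is identically zero (each word's four
proportions sum to one), the residual df is 4·462 − 8 = 1840, and the
contrasts recover the generator's configured profiles: verb meanings lean
on encyclopedic features (noun−verb ≈ −0.26), noun meanings on functional
and perceptual ones.

`04_effect_recovery.R` injects extra verb-verb encyclopedic sharing
(reuse multiplier 3) and prints:

```
Mean normalized encyclopedic degree: verbs 99.4 vs nouns 69
Cluster-based permutation test (N vs V), t threshold 3.29, 1000 permutations
 start end direction   mass        p
    60 400     V > N -127.2 0.000999
```

i.e. the pipeline recovers a verb-above-noun normalized-degree cluster in
the encyclopedic network spanning essentially the whole range of
vocabulary development — the qualitative signature the method is built to
detect.

See the methods vignette
(`vignettes/feature-type-networks.Rmd`) for the model, parameter and
calibration details.

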