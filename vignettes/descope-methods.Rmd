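---
title: "Methods: the descope engine for contextual DE comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the descope engine for contextual DE comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A transcriptomics lab rarely owns just one differential-expression (DE)
contrast. Against a background of hundreds of public DE tables, two questions
recur: *which other experiments look like mine?* and *within one experiment,
which genes and processes drive the result?* `descope` answers both headlessly:
a similarity map over whole experiments, and a filter/brush/link query model
over genes, glued together so a gene selection made while inspecting one
experiment can re-focus the similarity map itself.

The unit of data is one DE table — one row per gene, keyed by `EnsemblID`,
with numeric dimensions such as `foldChange`, `pValue`, `baseMean`. A JSON
data dictionary declares each dimension's semantic kind; the dictionary is
authoritative and no type inference is ever attempted, so two runs of the
same import behave identically.

# The similarity map

## Model

Let $P \in [0,1]^{m \times n}$ be the matrix of p-values of $m$ experiments
over the union of their $n$ genes. Experiments are the observations, genes
the variables. We mean-center each gene column and take the first two
principal components; each experiment's scores $(\mathrm{PC}_1,
\mathrm{PC}_2)$ are its map coordinates. Experiments whose significance
profiles agree — the same genes with small p-values — land close together,
regardless of the *direction* of regulation: the map is computed from
p-values only, so a contrast and the same contrast run the other way around
(fold changes negated, p-values untouched) receive *identical* coordinates.
This is a feature, not an artifact: the opposite-direction twin of an
interesting experiment is exactly as informative, and the GO view (below)
reveals the mirrored regulation at a glance.

Assumptions worth stating:

* **Raw p-values enter the matrix.** No $-\log_{10}$; small p-values are
  compressed near 0 and the map is driven by *which* genes are significant
  rather than *how* significant. A `transform` hook on
  `assemble_pvalue_matrix()` exists for experimentation and defaults off.
* **Center, don't scale.** P-values already share the $[0,1]$ scale;
  unit-variance scaling would inflate near-constant genes into noise axes.
* **Union + imputation.** Experiments measure different gene sets. The
  universe is the union, and a missing (experiment, gene) cell is imputed
  with $p = 1$ — a gene not tested is treated as maximally non-significant —
  with every imputed cell flagged in `imputed_mask`. The alternative
  (intersecting to shared genes) silently discards information and makes the
  map depend on which experiments happen to be loaded.

## Computation

The top components are obtained by a seeded randomized SVD
(`randomized_svd()`): a Gaussian sketch of $k + 10$ columns, orthonormalized
subspace (power) iterations, then an exact SVD of the small projected matrix.
Two numerical choices matter:

* **Adaptive iteration.** A fixed, small number of power iterations is
  accurate only when the spectrum decays steeply. We iterate a minimum of 2
  times and continue until the top-$k$ score vectors change by less than
  $10^{-10}$ (relative to the leading singular value), capped at 200
  iterations. On realistic p-value matrices — which have planted structure
  and hence a spectral gap — this converges in roughly 10–25 iterations and
  agrees with an exact decomposition to ~$10^{-9}$, measured on matrices up
  to 50 experiments × 5000 genes. On gap-free input (pure noise) no method
  can pin down the top-2 subspace; the cap keeps runtime bounded and the
  result is still an orthonormal basis of a near-dominant subspace.
* **Exact fallback.** When $\min(m, n) \le 25$ the sketch saves nothing and
  an exact SVD is used outright.

Determinism is a contract: the sketch is drawn under the caller's seed
(restored afterwards), so identical seeds give bit-identical coordinates.
Component signs are fixed by requiring the largest-magnitude gene loading of
each component to be positive. Scores are computed as $X_c V$ (centered
matrix times loadings) in both paths, and duplicate p-value rows are mapped
onto their first occurrence's scores — BLAS summation order may differ by
row position, and without this the "identical profiles, identical
coordinates" guarantee would hold only to within rounding.

Degenerate inputs are refused loudly: fewer than 2 experiments or 2 genes,
any `NA` cell, and the all-constant matrix ("no variance") are typed errors.
With exactly two experiments the second component is rank-deficient and is
reported as exactly 0.

`recompute_on_selection()` re-runs the map on the current gene selection —
the computational half of the analysis loop in which a details-view
selection refines the overview. `nearest_experiments()` ranks candidates by
Euclidean distance in the PC plane, ties broken lexicographically by id so
the ranking is total and reproducible.

# The selection model

All querying reduces to one idea: an ordered chain of conjunctive clauses
evaluated against the focus experiment, yielding a gene set that every view
receives.

* Numeric clauses use `<`, `>`, `=`. `=` is *exact* equality, by design:
  a tolerance would make results depend on a hidden constant, and users who
  want a band can bracket with `<` and `>`. The canonical example
  `pValue<0.005` selects strictly smaller values — a gene at exactly 0.005
  is excluded.
* Categorical (and identifier) clauses support only `=`, read as
  case-insensitive substring containment, mirroring spreadsheet "find"
  behaviour users already trust.
* A gene with a missing value on a clause's dimension fails that clause,
  including `=`. Missingness is never silently equal to anything.
* Brush rectangles are clauses too: they carry their axis dimensions,
  transforms and a *closed* interval box in transformed space. Points on the
  boundary are selected; genes outside a transform's domain are never
  selected by a brush. Because filters and brushes are both conjunctive
  predicates, chains commute and adding a clause can only shrink the
  selection — both properties are tested.

Linking is set intersection: `link_selection()` restricts the selection to
the genes a context experiment actually measures, dropping the rest
silently. A single highlighted gene (mouse-over semantics) travels the same
way, only to views that contain it.

# Plot models

The default view is the volcano plot: $-\log_{10}(\mathrm{pValue})$ against
linear `foldChange`. Eight axis transforms are supported (`linear`, `log2`,
`log10`, `sqrt`, each with a negated `-` variant). Out-of-domain values —
$p = 0$ under `-log10` is the infamous case — are masked out of the plot and
out of brush eligibility, never clipped to a pseudo-value: clipping would
fabricate a coordinate and make boundary brushing lie.

Hex binning aggregates points on a flat-top hexagonal lattice anchored at
the lower-left of the data range, column pitch $1.5r$, row pitch
$\sqrt{3}r$, odd columns shifted up half a row. Each point goes to its
nearest centre (ties towards the smaller column, then row — a total rule so
binning is reproducible); empty hexes are omitted, so counts always sum to
the points binned. The default radius is 1/30 of the x-range (~30 columns),
a geometry choice made once for legibility. Dots versus hexes follows one
rule: dots iff the user forces them, a selection is active in another view,
or the number of genes to render is strictly below 5000 (a named,
documented constant, `dot_threshold`).

Clicking a table header moves that dimension to the x-axis and the old
x-axis to the y-axis, so any pair is two clicks away; each axis takes the
transform last used for its dimension. Small multiples of context
experiments copy the focus view's axes, transforms and *full* ranges and
refuse to zoom — their job is comparison at a shared scale, and the linked
selection arrives as highlights instead.

The GO plot's diverging colour scale interpolates blue (0,0,255) → white
(255,255,255) → red (255,0,0) piecewise-linearly, clamped at the limits.
Default limits are symmetric about 0 at the largest absolute displayed
value, so white means "no change" when fold change is mapped — "white at
the mean" would move the anchor with the data and repaint identical fold
changes differently across terms.

# GO coverage scoring

For a selection $S$ and a term with gene set $T$, the score is coverage,
$100 \cdot |S \cap T| / |T|$, sorted descending with ties broken by smaller
term then id. The denominator is deliberately the *term* size: that is what
makes the metric favour small, specific terms (a nested sub-term with the
same intersection never ranks below its parent — a tested invariant). The
alternative denominator $|S|$ would reward giant generic terms. The known
bias toward small terms is mitigated the honest way, by user-set
`min_size`/`max_size` bounds rather than a hidden correction. No enrichment
p-value is computed: the ranking is a retrieval heuristic, not a test, and
pretending otherwise with an unconditioned hypergeometric would invite
misreading. Annotations load from a flat TSV (term id/name/definition/gene)
or minimal GAF 2.x (gene and GO id columns; qualifiers ignored), entirely
offline.

# The synthetic-data generator

Everything above is testable without downloads because `generate_collection()`
emulates the statistical structure the engine exploits:

* Each of `n_clusters` (default 3) clusters owns a *signature*: a random
  `signature_fraction` (0.1) of the `n_genes` (2000) universe with a fixed
  per-gene direction. Each of `experiments_per_cluster` (5) members draws
  observed fold changes $\hat\beta = \mu + \varepsilon$, where $\mu = \pm$
  `effect_size` (1.0, log2 units) on signature genes and 0 elsewhere, and
  $\varepsilon \sim N(0, \sigma/\sqrt{n^\ast})$ with per-replicate noise
  $\sigma =$ `noise_sd` (0.5) and pseudo sample size $n^\ast = 6$,
  mimicking a small-replicate DE design.
* P-values are the two-sided tail of the Wald statistic
  $z = \hat\beta / (\sigma/\sqrt{n^\ast})$. Under this model non-signature
  genes have $z \sim N(0,1)$, hence exactly Uniform(0,1) p-values, while
  signature genes have non-centrality $\approx 4.9$ — so cluster mates share
  their small-p genes, the single property the similarity map relies on.
  `n_null_experiments` (3) experiments are all-null.
* Each experiment drops a random 2% of genes (`missing_fraction`) so the
  union-plus-imputation path is always exercised; `baseMean` is log-normal
  (median 500, $\sigma_{\log} = 1.5$), `pAdj` is Benjamini–Hochberg.
* `generate_go_annotation()` plants `enriched_term_fraction` (0.2) of
  `n_terms` (50) terms on the clusters round-robin, drawing ≥ 80% of each
  enriched term's genes from the matching signature; background terms sample
  uniformly; sizes are uniform on `term_size_range` (10–50).
* `invert_experiment()` manufactures the opposite-direction twin of any
  experiment (fold changes negated, p-values kept), the ground truth for the
  inversion-invariance property.

The defaults above *are* the study conditions the test suite measures:
planted-cluster recovery by 1-nearest-neighbour in the PC plane (≥ 90%,
averaged over 20 seeds; observed 100%), enrichment recovery (planted terms
above the 95th percentile of background coverage in ≥ 18/20 seeds), and
uniformity of null p-values (Kolmogorov–Smirnov distance < 0.05 at 2000
genes). Every draw is a deterministic function of the config seed, so the
same seed reproduces every file byte-for-byte.

What the generator does **not** emulate — and therefore what passing tests
do *not* show about real data: correlated genes (co-expression makes
effective dimensionality lower and p-values dependent), composition effects
of normalization, batch structure shared *across* experiments that is not
biology, p-value miscalibration of real DE tests at low counts, and
annotation incompleteness or bias in real GO. The synthetic world is the
cleanest case in which the engine's claims are exactly checkable; real
collections will be noisier and cluster less crisply.

# Problem sizes and runtime choices

The test suite and the acceptance script run the full property battery at
the sizes stated above: 200 random structured matrices (26–50 experiments ×
500–5000 genes) for the randomized-vs-exact PCA comparison at $10^{-6}$,
200 random filter chains on 1000-gene tables, 100 random point sets for hex
binning, 100 random annotations for GO scoring, and 20 generator seeds each
for cluster and enrichment recovery — a few minutes end to end on one core.
These sizes were chosen so each property is measured with comfortable
statistical margin while staying pleasant to run locally.

# Known limitations

* The p-value map is blind to regulation direction by construction; users
  must consult the GO plot or small multiples to distinguish a replicate
  from an inverted comparison.
* Union-with-imputation biases experiments with small gene universes toward
  the "non-significant" corner of the map; the `imputed_mask` is exposed so
  downstream analyses can weigh that.
* Coverage ranking is not an enrichment test and term scores from nested GO
  structure are not deduplicated (the ontology graph is not modelled).
* The randomized decomposition's accuracy guarantee is empirical, for
  spectra with a gap; it is not a worst-case bound.
* Collections are held in memory; nothing is incremental or out-of-core.
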