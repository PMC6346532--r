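# descope

Contextual comparison of many differential-expression (DE) experiments,
as a headless R library plus a small command-line wrapper.

## The problem

A typical RNA-seq analysis produces a DE result table — one row per gene
with a fold change, a p-value and a mean expression level — and a typical
lab or repository holds hundreds of them. `descope` supports the two
questions that follow:

1. **Which experiments resemble mine?** Experiments are embedded in a 2-D
   *similarity map*: the first two principal components of the
   experiments × genes p-value matrix. Writing $P \in [0,1]^{m\times n}$
   for the p-values of $m$ experiments over the union of their $n$ genes
   (absent genes imputed with $p = 1$), columns are mean-centered and the
   top components computed with a seeded randomized SVD — fast enough to
   recompute interactively on any gene subset. Experiments that call the
   same genes significant land close together, irrespective of regulation
   direction.
2. **Which genes and processes drive one experiment?** A cumulative
   filter/brush model (`pValue<0.005`-style clauses, rectangular brushes in
   transformed plot space) selects genes in a *focus* experiment; the
   selection links to every *context* experiment, to hex-binned volcano
   plot models, and to a GO scan that ranks terms by coverage — the
   percentage of a term's genes inside the selection.

A synthetic-data generator with planted similarity clusters, inverted
comparisons, null experiments and enriched GO terms makes the entire
workflow testable offline, with known ground truth.

## Worked example

```r
library(descope)

# a synthetic collection: 3 clusters x 5 experiments + 3 nulls, 2000 genes
cfg <- synth_config(seed = 42)
gen <- generate_collection(cfg)
coll <- set_focus(gen$collection, "cluster1_rep1")

m <- assemble_pvalue_matrix(coll)
m
#> <pvalue_matrix> 18 experiments x 2000 genes (720 imputed cells)

co <- compute_overview(m, seed = 42)
head(as.data.frame(co), 4)
#>              id       pc1       pc2
#> 1 cluster1_rep1 -6.651781 -2.291965
#> 2 cluster1_rep2 -6.642422 -2.098596
#> 3 cluster1_rep3 -6.965194 -2.066917
#> 4 cluster1_rep4 -7.085029 -2.697748
round(attr(co, "explained_variance"), 3)
#> [1] 0.121 0.119

nearest_experiments(co, "cluster1_rep1", k = 3)
#>              id  distance
#> 1 cluster1_rep2 0.1935959
#> 2 cluster1_rep3 0.3858423
#> 3 cluster1_rep5 0.5242587
```

The four cluster-1 replicates share nearly identical map positions and the
three nearest neighbours of the focus are its cluster mates: experiments
with the same significant genes cluster together. Selecting the focus
experiment's significant up-regulated genes and scanning GO terms:

```r
focus <- coll$experiments[["cluster1_rep1"]]
sel <- apply_filters(focus, list(parse_clause("pValue<0.005"),
                                 parse_clause("foldChange>0")))
sel
#> <selection_state> 95/1960 genes of 'cluster1_rep1' (2 clause(s))

go <- generate_go_annotation(cfg, gen$truth)
head(as.data.frame(scan_terms(go$annotation, sel,
                              min_size = 5, max_size = 500))[1:5], 3)
#>      term_id                     term_name term_size n_selected coverage_pct
#> 1 GO:0000004  synthetic cluster1 process 4        11          6     54.54545
#> 2 GO:0000010 synthetic cluster1 process 10        48         21     43.75000
#> 3 GO:0000007  synthetic cluster1 process 7        33         14     42.42424
```

The top-ranked terms are exactly the ones planted on cluster 1: 95 of the
focus experiment's 1960 measured genes pass both clauses, and coverage
(selected genes as a percentage of term size) ranks the enriched terms above
every background term. `go_plot_data()` turns any of these terms into the
blue–white–red per-gene rectangle model; `recompute_on_selection(coll, sel,
seed = 42)` re-draws the similarity map using only the selected genes.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
CLI=$(R -s -e 'cat(system.file("cli", "descope", package = "descope"))')
Rscript $CLI synth --seed 42 --out demo
Rscript $CLI overview --dir demo/collection --seed 42 --out coords.tsv
Rscript $CLI query --dir demo/collection --focus cluster1_rep1 \
        --where 'pValue<0.005' --where 'foldChange>0' --out ids.txt
Rscript $CLI go --dir demo/collection --focus cluster1_rep1 \
        --annotation demo/go_annotation.tsv --select ids.txt --min 5 --out terms.tsv
```

`run_workflow()` / `Rscript $CLI run --script session.json` executes whole
scripted sessions; every run writes a `session.json` log that replays to
byte-identical outputs.

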