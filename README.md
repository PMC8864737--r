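# wormpaths

Multi-level metabolic pathway annotation, hypergeometric pathway enrichment
analysis, and standardized SVG pathway-map rendering for *C. elegans*-style
genome-scale metabolic models.

## What this package is for

Genome-scale metabolic network models such as iCEL1314 (1314 genes, 907
metabolites, 2230 reactions for *C. elegans*) describe metabolism as
reactions linked to genes through boolean gene–protein–reaction rules:
alternative enzymes are "OR" genes (written `pck-1|pck-2|pck-3`), obligate
complex subunits are "AND" genes (`pdha-1&pdhb-1`). To make such a network
navigable and statistically useful, its genes are curated into a
**four-level pathway hierarchy** — from ten broad Level 1 classes (amino
acids, carbohydrates, lipids, ...) down to fine Level 4 pathways such as the
propionate shunt — and each pathway is drawn as a **standardized SVG map**:
black enzymatic edges, green transport edges, blue gene labels, orange
co-reactants, per-metabolite pathway-count squares and transport-class
circles, and a legend on every map.

`wormpaths` implements that whole toolchain for anyone working with a model
in this shape:

* **model_core** — parse and validate the model tables (genes, compartmentalised
  metabolites written `abbr[comp]`, reactions with OR/AND gene rules).
* **annotation** — the Level 1–4 gene↔pathway hierarchy with redundancy
  inheritance, summary statistics, and GMT gene-set export for GSEA-style
  tools.
* **pea** — pathway enrichment analysis over the metabolic gene universe.
* **connectivity** — per-metabolite pathway counts, transportability classes
  (cytosol↔extracellular, mitochondria↔cytosol), and the terminal-metabolite
  rules that decide whether a map terminal gets a pathway box, a transport,
  or an "other" box.
* **mapgen** — a deterministic SVG renderer for declarative YAML map
  definitions, metabolite hover cards ("Structure not available" when no
  image exists), a map linter with stable issue codes, and a gene extractor
  for rendered maps.
* **fixtures** — a seeded generator of synthetic models, annotation tables,
  maps and PEA inputs with every truth planted in a manifest.

## The statistic at the core

A user gene list is intersected with the universe of all model genes
(size *M*); the intersection is the set of *metabolic hits* (size *N*).
For a category with *n* genes, of which *k* are among the hits, the
enrichment score is *k/n* and the intersection size follows the
hypergeometric distribution

P(K = k) = C(n, k) · C(M − n, N − k) / C(M, N).

Both p-values are **k-inclusive tails**:

* enrichment: p = Σ<sub>i ≥ k</sub> P(K = i)  (probability of *k or more* hits),
* depletion:  p = Σ<sub>i ≤ k</sub> P(K = i)  (probability of *k or fewer*),

so p<sub>enrich</sub> + p<sub>deplete</sub> = 1 + P(K = k). Stored p-values
are deliberately **uncorrected**; `bonferroni_threshold(alpha, n_test)`
gives the advisory per-level cut-off α/n<sub>test</sub>, with
n<sub>test</sub> the number of categories at the level of interest.

## Worked example

```r
library(wormpaths)

spec <- toy_model_spec(seed = 7)        # 100 genes, 16 Level-4 pathways, 4 maps
dir  <- file.path(tempdir(), "wp-demo")
manifest <- generate_toy_model(spec, dir)

model <- load_model(file.path(dir, "genes.tsv"),
                    file.path(dir, "metabolites.tsv"),
                    file.path(dir, "reactions.tsv"))
model
#> <metabolic_model> 100 genes, 60 metabolites, 80 reactions (3 compartments)
#>   3 transport reactions, 3 orphan reactions (no gene rule)

aset <- load_annotations(file.path(dir, "annotations.tsv"))
annotation_stats(aset)
#> Annotated genes: 100
#> Categories per level: L1=4, L2=8, L3=12, L4=16
#> Genes in multiple pathways: 25%

pe  <- generate_pea_input(spec, dir)    # 10 genes of one pathway + background
tab <- run_pea(read_gene_list(pe$file), aset, levels = c(1, 4))
print(tab, top = 3)
#> <pea_input> 22 tokens -> 20 metabolic hits (N) of universe 100 (M); 2 unmatched
#> Level 1 (4 categories), top enrichments:
#>                category  n  k score p_enrich
#>                  energy 52 14 0.269   0.0594
#>             amino acids 17  2 0.118   0.9040
#>  cofactors and vitamins 35  4 0.114   0.9710
#> Level 4 (16 categories), top enrichments:
#>                category  n  k score p_enrich
#>  carnitine biosynthesis 10 10   1.0 1.07e-08
#>      acetate remodeling  5  1   0.2 6.81e-01
#>       chitin metabolism  5  1   0.2 6.81e-01
```

The planted category (`carnitine biosynthesis` here: all 10 of its genes in
the input) ranks first at Level 4 with score 1.0 and
p = C(90,10)/C(100,20) ≈ 1.1 × 10⁻⁸; the two junk tokens in the list are
reported as unmatched rather than silently dropped.

```r
summary(tab)                       # advisory Bonferroni pass counts per level
#>   level n_categories bonferroni_threshold n_enriched_pass n_depleted_pass
#> 1     1            4             0.012500               0               0
#> 2     4           16             0.003125               1               0

md <- load_map_definition(file.path(dir, "maps/map-02.yaml"), model = model)
classify_terminal(model, aset, md, manifest$terminals[[2]]$met,
                  rxn_pathways = manifest$rxn_pathways)
#> <terminal_classification> bcd[c] on map map-02: TRANSPORT_ENDPOINT
lint_map(md, model, aset)
#> <lint_report> clean: no issues
write_map_svg(render_map(md, model, aset), "map-02.svg")
```

`write_pea_outputs(tab, "out/")` writes `results.tsv` plus a color-coded
`results.html`; `export_gmt(aset, 4, "level4.gmt")` emits the Level 4 gene
sets in GMT format.

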