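---
title: "Methods: annotation hierarchy, enrichment statistics, and map conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation hierarchy, enrichment statistics, and map conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormpaths)
```

This vignette is the package's own account of the models and procedures it
implements: what is computed, under which assumptions, which parameters
matter, and where the design was genuinely open.

## The data model

A metabolic model in this package is the triple (genes, metabolites,
reactions) of an iCEL1314-shaped network. Metabolite identity is the
compound key (abbreviation, compartment), written `abbr[comp]` in files;
maps display the bare abbreviation. The default compartment table is
`c` = cytosol, `m` = mitochondria, `e` = extracellular; unknown codes are
accepted (they simply extend the table) but only `c/m/e` participate in the
transport-class legend. A reaction is enzymatic or transport; a transport
must move the same abbreviation between two distinct compartments. Orphan
reactions — no gene rule — are legal and common: for many transports the
transporter is simply not known.

Gene–protein–reaction rules use the flat display grammar of the maps:
`rule := chain ('|' chain)*`, `chain := gene ('&' gene)*`. `&` binds
tighter than `|` and parentheses are rejected. The published map labels are
flat, so supporting nesting would create strings that could not be
displayed verbatim; the grammar nevertheless permits mixed rules such as
`a&b|c` (an OR of an AND-chain and a single gene), since nothing rules them
out and the flat reading is unambiguous. Serialisation is the inverse of
parsing on canonical strings, which is property-tested.

## The annotation hierarchy

Genes are annotated to pathways at four nested levels; Level 1 is the
broadest (ten classes on the reference table) and Levels 2–4 refine it.
Branches that cannot usefully be subdivided are carried downward unchanged,
so the deeper levels contain *redundancy*, and per-level category counts
are non-decreasing (10/61/79/85 on the reference shape). The loader accepts
redundancy in both encodings — repeated names and blank cells (a blank
level-k cell inherits level-(k−1)) — because published tables exist in both
styles; blanks are filled level by level, top down, so a set level-4 cell
under a blank level-3 still lands under the correct inherited parent.

Two definitional choices deserve a note:

* **"Multiple pathways."** The multi-pathway fraction counts genes with
  more than one *distinct full (L1,L2,L3,L4) path*. The statistic could
  also be defined at a single level; full-path distinctness is the
  strictest reading and matches how per-gene annotations are listed, so it
  is the one implemented.
* **Category identity.** A category is the pair (level, name), matched
  case-sensitively and exactly. Silent case-folding would hide curation
  errors; a miss instead returns a fuzzy-matched suggestion list in the
  error. The same name under two levels is two categories.

GMT export writes one set per line (`name`, `"WormPaths L<level>"`, sorted
deduplicated gene ids), the format GSEA-style tools consume.

## Pathway enrichment analysis

With universe size $M$ (all model genes; 1314 on the reference network),
hits $N$ (input ∩ universe after trimming and deduplication), category size
$n$ and overlap $k$, the enrichment score is $k/n$ and

$$P(K=k) \;=\; \frac{\binom{n}{k}\binom{M-n}{N-k}}{\binom{M}{N}}.$$

Both reported tails **include $k$**: enrichment $P(K \ge k)$, depletion
$P(K \le k)$. This is implemented as `phyper(k-1, ..., lower.tail = FALSE)`
— never `1 - CDF(k)`, which would exclude $k$ — and the identity
$p_e + p_d = 1 + P(K=k)$ is asserted on every emitted row. Stored p-values
carry **no multiple-testing correction**, a deliberate choice to avoid
understating enrichment strength; `bonferroni_threshold()` and
`summary.pea_table()` provide the advisory cut-off $\alpha/n_{test}$ with
$n_{test}$ the number of categories at the level of interest.

Numerical choices: the tails are delegated to R's `phyper`/`dhyper`
(log-space-stable); the test suite checks them against an independent exact
oracle — integer Pascal-triangle binomials, exact in doubles for
$M \le 30$ because $\binom{30}{15} < 2^{53}$ — over *every* valid
$(M, n, N, k)$ with $M \le 30$, at an absolute tolerance of $10^{-12}$.
Token matching is exact after whitespace trimming; alias expansion through
the model's alias table is available but off by default, so the hit set is
deterministic. Categories that would be empty are skipped rather than
emitted with an undefined score (a well-formed annotation table produces
none). Output rows are ordered level ↑, then $p_e$ ↑, then name, so files
are byte-stable. The HTML report colors $-\log_{10} p$ on a white→red ramp
for enrichment and white→blue for depletion, saturating at 10; the
interactive original is only described as "color-coded", so this scale is a
documented package choice, not a claim about the original.

## Connectivity and terminal metabolites

Per metabolite, two quantities drive the map legend: the number of distinct
map-level pathways among its reactions (grayscale square, binned 1/2/3/≥4 —
the binning is a package choice, the square itself is the convention) and
its transport classes (cytosol↔extracellular and/or mitochondria↔cytosol
circles). Transport self-edges are excluded from the pathway count: moving
a metabolite between compartments is not a pathway membership. A reaction's
pathway membership comes from an explicit reaction→pathway table when one
is provided (map definitions carry one; curation sometimes moves a reaction
out of a pathway it would be inferred into), otherwise from the union of
its genes' annotations at the map's level. The explicit table wins on
conflict.

Terminal metabolites of a map are classified by a cascade: the map's own
defining substrate/product (`MAIN_TERMINUS`); else, connected to 1..T other
pathways → clickable `PATHWAY_BOXES`; else, no other pathway but a
legend-class transport → `TRANSPORT_ENDPOINT`; else `OTHER_BOX` (its
remaining reactions are not on any map yet); and above the threshold T, no
boxes at all (`LINK_ONLY`) so hub metabolites do not clutter the map. The
threshold defaults to **T = 2** ("more than two other pathways" suppresses
boxes); published practice also shows a laxer cut of four on busy maps, so
T is a parameter rather than a constant, and no claim is made about which
value any particular published map used.

## Map rendering and linting

Maps are declarative YAML (nodes with hand-placed pixel coordinates, origin
top-left, y downward; edges routed through waypoints; boxes; compartment
regions) — automatic layout is out of scope by design, because the
published maps are hand-drawn. The renderer emits SVG 1.1 with stable class
attributes (`wp-gene`, `wp-met`, `wp-coreactant`, `wp-legend`, ...) so that
gene extraction and styling are structural rather than color-based, and the
output is deterministic: fixed inputs give byte-identical files (element
order follows the definition; numeric formatting is fixed-point). Colors
are configuration with conventional defaults (black enzymatic, green
transport, blue genes, orange co-reactants); exact hex values are package
defaults since only the color names are conventional. Hover cards are
embedded as SVG `title` metadata (name | formula | structure);
2-D structure depiction from mol files is out of scope — cards reference
pre-rendered images or carry the exact placeholder "Structure not
available". Hyperlink targets come from a `{met}` template defaulting to
local anchors.

The linter cross-references a map against the model and the master table
and reports stable codes: `MET_UNRESOLVED`, `REACTION_UNRESOLVED`,
`DUP_NODE`, `RULE_PARSE_ERROR`, `GENE_NOT_IN_ANNOTATIONS` (all ERROR),
`GENE_LEVEL_MISMATCH`, `ORPHAN_NODE`, `TERMINAL_RULE_VIOLATION` (WARNING —
these flag curation questions rather than broken references). Terminal
violations are judged against the classifier above: a terminal that should
carry a pathway box but has none, a transport endpoint without a drawn
transport, a missing "other" box, or boxes drawn on a hub that should have
none.

## The synthetic fixture generator

The generator exists so that every module is testable without downloads,
with ground truth planted rather than inferred. Its defaults are the study
conditions the package is tested under:

* the small spec: 100 genes, 60 metabolite rows, 80 reactions, category
  counts 4/8/12/16, 25% multi-pathway genes, one planted Level 4 enrichment
  target (n = 10, k = 10, N = 20), four maps;
* `master_shaped_spec()`: 1314 genes, 907 metabolite rows, 2230 reactions,
  10/61/79/85 categories, a 32% multi-pathway fraction (planted exactly as
  `round(0.32·1314) = 420` genes, which displays as 32%), `alh-2` planted
  with exactly four pathway assignments, and an inventory of 62 maps;
* the stochastic recovery condition: a category of 20 genes with 15
  sampled into a 50-hit list over a 1000-gene universe, 100 seeded
  replicates.

The category tree is grown level by level: at each level a deterministic
subset of branches subdivides (each into at least two children) until the
target count is reached, and the remaining branches carry their name down —
exactly the redundancy mechanism of the real hierarchy. Every leaf keeps
one *single-pathway representative gene*, and reactions planted to connect
pathways use these representatives, so gene-based pathway inference on
fixture maps is unambiguous. Each map is a reaction chain whose first node
is the defining start metabolite and whose last node exercises one terminal
archetype (pathway box / transport endpoint / "other" box / suppressed-box
hub with five connections). Gene and metabolite tokens follow *C. elegans*
and BiGG-like shapes (`tgn-12`, `abc[c]`) to exercise the tokenizers
realistically.

What the generator does **not** emulate: stoichiometric balance, realistic
network topology (chains, not branched subnetworks), biochemical plausibility
of formulas and names, and the long-tailed category-size distribution of a
real curation. Passing tests therefore demonstrate that the machinery is
correct on inputs of the declared shape — not that any particular biological
conclusion holds on real data. Statistics over the published master table
require that table as input; in its absence the same checks run against the
master-shaped fixture, whose counts are planted, and they validate the
counting machinery, not the published curation.

Determinism: a single integer seed governs all randomness; generation
saves and restores the caller's RNG state, and identical specs produce
byte-identical files. PEA input replicates derive their seeds from the
spec seed plus an offset, so replicate draws are independent but
reproducible.

## Problem sizes and degenerate inputs

The test suite and the acceptance script use the fixture sizes above; the
exhaustive oracle comparison covers every hypergeometric configuration with
$M \le 30$ (about 260k tail evaluations), where the Pascal-triangle oracle
is provably exact. Degenerate inputs are defined, not errors: an empty gene
list gives $N = 0$ and $p_e = 1$ everywhere; the full universe gives
$k = n$, score 1 and $p_e = p_d = 1$ everywhere; an unknown gene token is
reported as unmatched, never guessed. Out-of-support $k$ has probability 0;
invalid $(M, n, N)$ raise domain errors.

## Known limitations

* The renderer's geometry (box sizes, label offsets, legend layout) is
  self-consistent but not claimed to match any published template
  pixel-for-pixel; arrowheads are not drawn.
* SBML import is not provided; the model dialect is the three-TSV form.
* No FDR/q-value machinery: the enrichment report is deliberately
  uncorrected with an advisory Bonferroni column, and ranked (GSEA-style)
  analysis is supported only indirectly through GMT export.
* Pathway splitting/merging is curation, not computation: the package
  honors explicit reaction→pathway tables but never rewrites them.
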