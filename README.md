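# hitdecon

Target and pathway deconvolution of phenotypic screening hits.

Phenotypic high-throughput screens return hit lists whose mechanisms are
obscured by polypharmacology: a chemically diverse set of actives gives
little direct insight into which protein targets or signalling pathways
drive the phenotype. hitdecon deconvolutes such hit lists by

1. **standardizing** every library structure (canonical SMILES, salt
   stripping, charge neutralization, full and parent InChIKeys),
2. **mapping** compounds to per-source identifiers and parsing offline dumps
   of five annotation sources — DrugBank-style XML, PharmGKB-style
   relationship TSV, IUPHAR-style interaction JSON, PubChem-style
   bioactivity tables and ChEMBL-style activity extracts — applying each
   source's filters (human targets only; a 10 µM inclusive potency cutoff
   for bioactivity annotations; pChEMBL ≥ 5; DrugBank known-action;
   single-protein binding/functional assays), plus optional user-supplied
   primary gene annotations,
3. **collating** the evidence into deduplicated compound–target pairs with
   per-source provenance,
4. **testing overrepresentation** of every hit-associated target against the
   empirical screening-collection background, and
5. **classifying** each (hit, enriched target) pair as inhibitor, activator,
   mixed, inconclusive or unknown from its activity evidence, before
6. **pathway-level** gene-set overrepresentation of the enriched targets.

The package is offline-first: every analysed byte comes from local files,
and a seeded synthetic-screen generator with planted ground truth makes the
whole pipeline testable without any database access.

## The statistical core

For target *i*, let `NB` be the total number of compound–target associations
for the screening collection, `Nhl` the number involving hit compounds,
`Tic` the associations of target *i*, and `Tihlc` those of target *i*
involving hits. The 2×2 table

|                        | in hit list  | not in hit list        | total     |
|------------------------|--------------|------------------------|-----------|
| target *i* assoc.      | Tihlc        | Tic − Tihlc            | Tic       |
| other assoc.           | Nhl − Tihlc  | NB − Tic − Nhl + Tihlc | NB − Tic  |
| total                  | Nhl          | NB − Nhl               | NB        |

is tested with the exact one-sided Fisher test,
`p = P(X ≥ Tihlc)` for `X ~ Hypergeometric(NB, Tic, Nhl)`, and p-values are
Benjamini–Hochberg adjusted across all targets with `Tihlc ≥ 1`. Targets are
flagged at a q-value (FDR) threshold and at a raw-p threshold, both 0.05 by
default. Pathway overrepresentation reuses the same exact test over gene
sets and ranks terms by the enrichment strength
`log10(observed / expected)`.

Action calls per evidence record follow the activity parameter —
Ki/pKi/INH and inhibitory concentrations (IC50, IC20, …) → inhibitor;
EC values (EC50, EC20, …) → activator; Kd/Kb/Km/Ka → inconclusive; curated
records without a parameter → unknown — and are overridden by curated
mechanism annotations (IUPHAR *Action*, ChEMBL *Action Type*) when those map
to a direction. Within a pair, both directions → mixed; a single definite
direction beats inconclusive/unknown evidence.

## Worked example

A small fully annotated screen ships with the package: 8 compounds (one salt
form, one unparseable SMILES, one without annotations), 3 hits, all five
source dumps, identifier and gene maps, and two gene sets.

```r
library(hitdecon)
toy <- system.file("extdata", "toy", package = "hitdecon")
res <- run_pipeline(run_config(
  library  = file.path(toy, "library.csv"),
  hits     = file.path(toy, "hits.txt"),
  id_map   = file.path(toy, "id_map.tsv"),
  gene_map = file.path(toy, "gene_map.tsv"),
  drugbank = file.path(toy, "drugbank.xml"),
  pharmgkb = file.path(toy, "pharmgkb.tsv"),
  iuphar   = file.path(toy, "iuphar.json"),
  pubchem  = file.path(toy, "pubchem.csv"),
  chembl   = file.path(toy, "chembl.csv"),
  gmt      = file.path(toy, "pathways.gmt")
))
res$enrichment
#> Target overrepresentation: 1 tested targets (NB=7 background, Nhl=3 hit associations)
#>   enriched at FDR 0.05: 1; at p 0.05: 1
#> # A tibble: 1 x 11
#>   uniprot_acc gene_symbol tihlc   tic   nhl    nb odds_ratio p_value q_value
#>   <chr>       <chr>       <int> <int> <int> <int>      <dbl>   <dbl>   <dbl>
#> 1 P00001      SYGA            3     3     3     7        Inf  0.0286  0.0286
res$calls
#> # A tibble: 3 x 5
#>   sample_id uniprot_acc call      n_evidence n_overrides
#>   <chr>     <chr>       <chr>          <int>       <int>
#> 1 C1        P00001      inhibitor          2           2
#> 2 C2        P00001      inhibitor          2           0
#> 3 C5        P00001      inhibitor          1           1
```

Of the 7 deduplicated compound–target pairs, all 3 hit associations point at
`P00001`, giving the exact right-tail probability 1/35 ≈ 0.0286, below the
5% FDR threshold; the evidence for all three hit–target pairs is inhibitory
(two calls corrected by curated antagonist annotations). `tidy()`, `glance()`
and `autoplot()` work on the enrichment and pathway result objects;
`generate_screen(synthetic_screen_spec(seed = 1), dir = "...")` writes a
complete synthetic screen bundle with a ground-truth manifest.

A command-line driver with verbs `standardize`, `annotate`, `collate`,
`enrich`, `classify`, `pathways`, `run-all` and `simulate` is installed at
`system.file("cli", "hitdecon.R", package = "hitdecon")`.

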