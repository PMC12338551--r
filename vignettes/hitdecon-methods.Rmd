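---
title: "Methods: target and pathway deconvolution of phenotypic screening hits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target and pathway deconvolution of phenotypic screening hits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hitdecon)
```

## The problem

A phenotypic high-throughput screen yields a hit list — compounds that move
a cellular readout — without saying which protein targets mediate the
effect. Because most bioactive small molecules are polypharmacological, the
union of all annotated targets of the hits is long and dominated by the
composition of the screening library itself: a library rich in, say,
aminergic drugs will put aminergic receptors in any hit list's annotation
profile. hitdecon therefore tests targets against the *empirical background*
of the whole screening collection rather than against a fixed reference
universe, and only then carries the enriched targets into pathway analysis.

## Compound standardization

Input structures arrive as SMILES with exact column headers `SMILES`,
`Sample ID` and optionally `Gene Symbol` (a single primary-annotation gene
per compound). Only delimited text (CSV/TSV) is read; spreadsheet files must
be exported to CSV first. Structures are canonicalized with OpenBabel, and
two InChIKeys are generated per compound: the *full* key of the structure as
supplied, and the *parent* key after salt stripping — identifier resolution
tries the full key first and falls back to the parent, because annotation
databases sometimes register the salt form and sometimes the free base.

Salt stripping keeps the fragment with the most heavy atoms among fragments
containing at least one carbon; ties break by lexicographic order of the
fragment's canonical SMILES. A structure with no organic fragment (a pure
inorganic salt) has no parent and keeps only its full key. Simple
protonation states are neutralized *after* fragment selection — the
upstream normalizer convention this mirrors names charge recombination but
not its ordering, so the ordering here is a package decision; neutralizing
after selection means the fragment-size comparison sees the structure as
drawn, and the parent key matches the neutral free base that databases
index. Pre- and post-neutralization canonical SMILES are kept in the
standardization log.

Unparseable SMILES are never dropped: the record keeps `parse_ok = FALSE`,
is excluded from identifier mapping, and surfaces in the unresolved-compound
report, so record counts always partition the input library. Duplicate
Sample IDs and duplicate structures are allowed and treated as distinct
library entries; no structure-level deduplication is performed, because
background association counts are defined per library entry.
Stereochemistry repair and tautomer canonicalization beyond what the InChI
layer provides are out of scope.

## Annotation sources and filters

Six evidence channels are harmonized into one record shape
(`sample_id`, `source`, `uniprot_acc`, activity fields, curated action
field):

* **DrugBank-style XML** (curated): targets with `known-action` equal to
  `unknown` are discarded, as are non-human targets; the UniProt accession
  comes from the target polypeptide's external identifiers.
* **PharmGKB-style relationships** (curated): chemical–gene rows; gene
  symbols resolve to UniProt accessions through a Pharos-style gene map,
  unresolvable symbols are counted and dropped.
* **IUPHAR-style interactions** (bioactivity): affinities arrive on the
  −log10 molar scale (pKi and kin) and convert as `10^(−p)` mol/L; the
  curated `Action` string is retained for the classifier. Rows without a
  parseable numeric affinity are dropped (counted) — an action-only row
  gives no potency evidence against the cutoff.
* **PubChem-style bioactivity** (bioactivity): only concentration-typed
  potency fields (IC*n*, EC*n*, AC*n*, XC50, GI50, Ki, Kd, Potency) are
  usable under a molar cutoff; categorical outcomes ("Active") are counted
  and excluded. Units nM/µM/mM/pM/M normalize to mol/L; unknown unit tokens
  drop the row with a count.
* **ChEMBL-style activity extracts** (bioactivity): human, single-protein
  targets from binding or functional assays with a pChEMBL value ≥ 5;
  `Action Type` is retained. pChEMBL is −log10 of a molar potency, so
  pChEMBL 5 is exactly the 10 µM cutoff. Rows without a pChEMBL value are
  not potency evidence and are dropped. The underlying standard type token
  (IC50, Ki, …) is kept, because the classifier needs the parameter type,
  not the derived pChEMBL scale.
* **User gene symbols** (curated): the optional `Gene Symbol` column maps
  through the same gene map; a blank column is silently ignored.

All bioactivity cutoffs are **inclusive**: a record at exactly 10 µM
(equivalently pChEMBL exactly 5) survives, matching the "5 or above"
convention at the equivalent concentration. Organism filters accept the
common spellings of human (Human/Humans/Homo sapiens/9606). Every emitted
record is human; every dropped record increments a per-source, per-reason
counter surfaced in the run report.

Network clients for the live services behind these dialects are deliberately
interface-only (`remote_enrichment_request()` refuses to run offline and a
canned-response parser is provided); all tested behaviour operates on local
files, because live annotation counts are database-version-bound and not
reproducible.

## Collation and enrichment

Evidence collapses to one pair per distinct (Sample ID, UniProt accession)
with the contributing source set and the full evidence retained — the
classifier later re-inspects activity fields for enriched targets only.
Three summary tables mirror standard practice: unique targets with
per-source flags, per-compound distinct-target counts by source plus the
unresolved list (the two partition the library), and exact
source-combination counts (upset-plot data; the tested artifact is the
counts table, plotting is a convenience).

For target *i* the contingency quantities are `NB` (all background pairs),
`Nhl` (pairs involving hits), `Tic` (pairs of target *i*) and `Tihlc`
(pairs of target *i* involving hits); the bottom-middle cell is
`NB − Tic − Nhl + Tihlc`, the unique value consistent with the margins. The
test is the exact hypergeometric right tail (one-sided, since the question
is overrepresentation; a two-sided variant sits behind the `alternative`
argument). Counts are always computed on deduplicated pairs, never on raw
evidence rows.

Only targets with `Tihlc ≥ 1` are tested and enter the BH denominator `m`:
a target never seen among hits cannot be overrepresented, and carrying its
guaranteed p = 1 through BH would only dilute the adjustment. This choice
affects which targets clear a given FDR level; the alternative (including
zero-hit targets in `m`) is strictly more conservative. The odds ratio is
reported as the unadjusted cross-product ratio, infinite when a zero cell
makes it so — p-values come from the exact test, so no continuity
correction is applied. Results sort by ascending p with ties broken by
accession, making output order deterministic.

## Action classification

Each evidence record gets a preliminary direction from its activity
parameter (see above), then a curated action override where available. The
shipped vocabulary maps agonist-family strings (agonist, partial/full
agonist, activator, positive (allosteric) modulator, opener) to *activator*
and antagonist-family strings (antagonist, inhibitor, inverse agonist,
blocker, negative (allosteric) modulator, channel blocker) to *inhibitor*;
all other strings apply no override. The vocabulary is a configurable table
because the upstream sources do not publish a closed list. Matching of
parameter tokens is case-insensitive on normalized tokens; inhibitory
concentrations match the pattern "IC" + number, `INH` matches exactly, and
a leading "p" (the −log10 scale) is stripped before matching.

Per pair: both directions present → *mixed*; exactly one → that call; only
non-directional parameters → *inconclusive*; only curated no-parameter
records → *unknown*. A definite direction beats inconclusive/unknown
within a pair — the alternative (letting one Kd row demote an otherwise
unanimous inhibitor) would discard information; this precedence is a package
interpretation, stated here because the convention it mirrors assigns single
calls per pair without spelling out the precedence. The hit × enriched-target
matrix leaves cells empty where no association exists.

## Pathway enrichment

Gene sets arrive as GMT. For each term, `observed` is the overlap of the
query with the term inside the universe, `expected` is
`|members ∩ universe| · |query| / |universe|`, and terms rank by the
enrichment strength `log10(observed/expected)`. The p-value reuses the same
exact hypergeometric tail (universe as `NB`, query as `Nhl`, term size as
`Tic`, overlap as `Tihlc`), with BH across tested terms. Terms with zero
observed members are reported with strength undefined (absent, not −∞) and
excluded from BH. The default universe is the set of genes of all targets
mapped for the screening background — the same empirical-background logic as
the target test; a whole-collection (GMT-union) universe is available by
configuration, since the remote service this mirrors does not document its
default background.

## The synthetic-screen generator

`generate_screen()` emulates inputs (a)–(f) end to end: a library of valid,
structurally distinct enumerated small molecules (scaffold × alkyl chain ×
terminal group), a configurable fraction written as salts (HCl, hydrate,
NaCl co-crystal, sulfate, acetate) and a small fraction of deliberately
unparseable strings; a hit list; evidence rows spread over the five source
dialects plus user gene annotations; identifier and gene maps; gene sets
containing each planted mechanism; and a manifest recording for every
emitted row whether it should survive its source filter and why not.

Reference conditions (the generator defaults): 2,000 compounds, 100
targets, baseline association probability 0.02 (≈ 2 annotated targets per
compound, typical of a bioactive-collection annotation density), 5% hits,
and one planted target whose association probability among hits is 5-fold
baseline. Bioactivity values draw log-normally with log10(mol/L) mean −7
and sd 1 — centred at 100 nM, as annotated ligand potencies tend to be —
so a small natural tail falls beyond the 10 µM cutoff; two boundary rows
(exactly 10 µM; pChEMBL exactly 5) are always planted to pin the inclusive
cutoffs, and decoy rows are planted to fail each individual filter
(non-human, weak, unparseable, unknown unit, sub-threshold pChEMBL,
protein complex, unknown action, unresolvable gene symbol). The evidence
source mix (10/10/25/25/30% across DrugBank/PharmGKB/IUPHAR/PubChem/ChEMBL)
reflects that bioactivity databases dominate annotation volume; user gene
annotations are governed by a separate fraction (5%) since a compound
carries at most one primary annotation. All randomness derives from the
single spec seed through a per-component counter, so bundles are
reproducible byte for byte.

`generate_null_screen()` gives every compound exactly one uniformly drawn
target and draws hits uniformly, making the per-target Fisher tables
exchangeable null draws — the design used for type-I calibration.

What the generator does *not* emulate: real ligand–target affinity
structure, correlated polypharmacology (chemically similar compounds
sharing targets), database cross-listing biases, and real identifier
collisions. Passing tests therefore demonstrate the pipeline's mechanics
and statistical behaviour, not performance on any particular real
collection.

### Power at the reference conditions

Under the reference conditions the planted target accrues on average
`Tihlc ≈ 100 × 0.1 = 10` hit associations against a null expectation of
about 2.5 — strong but small-count enrichment. With roughly 90 tested
targets, clearing a 5% FDR needs p ≲ 5×10⁻⁴, i.e. `Tihlc ≳ 10`, an event of
probability only ≈ 0.55 under `Binomial(100, 0.1)`. Recovery *rank* is much
more robust: the planted target is the top-ranked target in the large
majority of seeds. The acceptance script reports both rates as measured;
the q-threshold recovery rate at these conditions sits near 60%, a power
limitation of the small expected counts, not of the test.

## Numerical and testing choices

* The exact tail uses `phyper` directly; an independent brute-force
  binomial-coefficient summation is the oracle in the test suite, checked
  to 10⁻⁹ over every valid table with `NB ≤ 50` (~316k tables).
* BH uses `p.adjust(method = "BH")`, checked against an independently coded
  step-up on 1,000 random p-vectors of lengths 1–500.
* Null calibration pools 1,000 null screens of 500 compounds × 50 targets
  (50,000 exchangeable tests); planted recovery uses 200 seeds at the
  reference conditions; adapter fidelity uses full bundles of 150 compounds
  × 20 targets. These sizes keep the default test run around a minute of
  statistics while leaving Monte-Carlo error well below the margins tested.
* Degenerate inputs error early and by name: empty hit lists, hit IDs
  absent from the library, empty query or universe in pathway enrichment,
  invalid contingency tables, and p-values outside [0, 1].
* Pipeline outputs are byte-deterministic; the only timestamp lives in the
  JSON run report. Output CSVs carry a provenance header (package version
  and a hash of the analysis-relevant configuration).

## Known limitations

Annotation coverage bounds everything downstream: compounds without
identifier matches or surviving evidence are reported but contribute
nothing to enrichment. The 10 µM cutoff is a blunt instrument — it treats a
9.9 µM and a 1 nM interaction identically. The action classifier is
rule-based on reported parameter types and curated action strings; it does
not weigh potency, dose dependence, or assay context, and pChEMBL-bearing
rows without a standard type token are not assumed inhibitory. Pathway
results inherit the usual overrepresentation caveats (no topology, no
direction), and the choice of universe materially changes strength values —
which is why it is explicit configuration here.
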