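---
title: "Distilling metabolic annotations for microbial and viral genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distilling metabolic annotations for microbial and viral genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magdistill)
library(dplyr)
```

## The problem

Assembled metagenomes yield hundreds of metagenome-assembled genomes
(MAGs) and viral contigs whose raw annotation — millions of per-database
homology and profile-HMM hits — is unusable without distillation.
`magdistill` turns gene calls plus per-database search results into three
layers of summary: a merged per-gene annotation with a confidence rank, a
per-genome *distillate* (quality statistics and function-identifier
counts), and a per-genome *product* (pathway coverage, complex completion
and function presence), plus a rule-based caller for putative auxiliary
metabolic genes (AMGs) on viral contigs. The search computation itself
(MMseqs2/HMMER-class tools, gene callers, RNA detectors, viral detection)
is out of scope: those tools' output files are the package's input
contract.

## Annotation confidence ranks

Each gene's hits are reduced to at most one best hit per database — the
maximum bit score, kept only if strictly above the floor (default 60) —
and the surviving evidence maps to a single rank:

| rank | evidence |
|------|----------|
| A | reciprocal best hit (RBH) to KEGG, reverse bit score > 350 |
| B | RBH to UniRef90, reverse bit score > 350 |
| C | plain KEGG/KOfam or UniRef90 hit, bit score > 60 |
| D | only Pfam, dbCAN or MEROPS evidence |
| E | no significant hit (a VOGDB-only gene is rank E) |

An RBH requires the database target's top reverse hit against all input
genes to be the original query with reverse bit score strictly above 350.
Profile hits (Pfam/dbCAN/VOGDB) are kept when they cover strictly more
than 35% of the model — coverage is computed model-side, as
`(model_to − model_from + 1) / model_length` — at e-value strictly below
1e-15; KOfam models with a curated per-model threshold instead require
`bit_score >= threshold` (models with a blank threshold fall back to the
generic rule, which is deliberately distinct from a threshold of zero).
All inequalities are strict exactly as written; ties on bit score break
by lower e-value, then lexicographically smallest target id, so results
are independent of input order. UniRef90 is off by default (its memory
cost is prohibitive for many users of the upstream search); a database
not in use is treated as having no hits, which can only worsen ranks —
never improve them.

A gene is *annotated* when at least one KEGG/KOfam/UniRef/MEROPS/Pfam/
dbCAN best hit carries a description free of "hypothetical",
"uncharacterized" and "domain of unknown function" (case-insensitive
substring match — descriptions vary in case and punctuation);
*hypothetical* when such hits exist but all descriptions match (a hit
with a blank description is treated as lacking a defined annotation);
*unannotated* when none of those databases hit. KOfam participates in
both the C rank and the status rule so that the invariant *unannotated ⇒
rank E* holds whichever KO source is in use.

## Module grammar and the two completion metrics

Module definitions use the public KEGG convention: space separates
sequential steps (binding loosest), comma separates alternative paths,
`+` joins complex subunits, a leading `-` marks a component optional,
and parentheses group with unbounded nesting. The parser produces a tree
whose canonical serialization re-parses to an identical tree — a
property tested on 200 randomly generated definitions.

**Step coverage** is the fraction of top-level steps with at least one
observed, non-optional gene anywhere beneath them (substeps and subpaths
count). Optional (`-`) components are excluded from both the numerator
and the denominator, and a step consisting only of optional components
does not enter the denominator at all; the exact treatment of optional
components is a package decision, since the convention leaves it open.

**Best-path completion** views the module as a directed acyclic network:
source and sink bracket the KOs, alternatives become parallel branches,
sequences chain, and a complex collapses to one composite node weighted
by its subunit count (a complex over alternatives expands into one
composite node per subunit combination; a full step sequence nested
inside a complex is rejected as unsupported). Completion is the maximum,
over all source-to-sink paths, of present weight over total weight — a
partially present complex contributes fractionally, so a 3-subunit
complex with one subunit observed adds 1/3. Maximizing a ratio is not a
shortest-path objective, so the scorer runs dynamic programming over the
topological order, carrying at every node the Pareto frontier of
(present weight, total weight) pairs and taking the best ratio at the
sink. This is exact: the suite checks it against exhaustive path
enumeration on 200 random modules of up to 12 KOs at 1e-12.

**Function presence** is rule-based: a function is present when every
one of its identifier sets contributes at least one observed identifier,
covering both single-gene markers and either-of-several gene sets.

## Distillate and genome quality

The distillate counts, per genome, genes carrying each function
identifier (KO, CAZyme family, peptidase family, Pfam accession) named
in a *form* table that assigns identifiers to categories and
subcategories (energy, carbon utilization, transporters, organic
nitrogen, MISC). A gene is counted once per (gene, identifier) pair even
when several databases agree on the identifier, and an identifier mapped
to several form rows — e.g. a CAZyme family promiscuous for multiple
substrates — is counted in each row. Identifier matching is exact after
stripping a trailing version suffix.

Genome quality follows the MIMAG tiers. The standard names the tiers but
a reproducible rank needs numbers, so the thresholds are explicit and
overridable (`mimag_thresholds()`): *high* needs completeness > 90%,
contamination < 5%, all of 5S/16S/23S and ≥ 18 tRNAs; *medium* needs
completeness ≥ 50% and contamination < 10%; everything else — including
genomes with no completeness estimate, which the package never computes
itself — is *low*.

## Viral auxiliary scores, flags and AMG calls

On a viral contig every gene is classified from its affiliation-table
evidence code as `hallmark`, `viral_like` or `none` via an editable
mapping (upstream tools do not standardize the tokens; unmapped codes
degrade to `none` with a warning). A gene's *flanks* are all genes
strictly to its left / right on the contig — not merely the adjacent
gene — and the auxiliary score is:

1. hallmark evidence on both flanks;
2. hallmark on one flank, viral-like on the other;
3. viral-like on both flanks;
4. viral evidence on exactly one flank — or membership in a stretch of
   ≥ 3 adjacent non-viral metabolic genes (flag M and not V), which can
   raise a score to 4 but never lower a 5;
5. contigs with no viral evidence at all, and terminal genes.

When several rules apply the worst (largest) applicable score wins —
conservatism is the intent of the 4/5 tier. One configuration the rules
do not cover explicitly: a non-terminal gene whose flanks contain genes
but no viral evidence, on a contig that does have viral evidence
elsewhere (e.g. on the gene itself). The package scores it 5, reasoning
that no flank support is worse than one-sided support; the test suite's
independent transcription of the rules encodes the same reading.

Flags: `V` VOGDB replication/structure hit; `M` any identifier present
in the distillate form; `K`/`E` identifier in the known / experimentally
verified AMG list (`E ⊆ K` is enforced); `A` host attachment/entry
identifier; `P` viral-associated peptidase family; `F` within 5000 bases
of a contig end (strictly less); `T` on a contig carrying a transposon
identifier; `B` inside a run of ≥ 3 consecutive `M` genes. The bundled
K/E/A/P/transposon lists are synthetic stand-ins with the documented
schema — real curated lists drop in via `amg_call_config_from_lists()`.
The `B` run and the score-4 stretch rule share one definition of
"non-viral metabolic" (M and not V), which keeps the two rules
consistent.

A gene is called a potential AMG when its auxiliary score is strictly
below 4, it carries every required flag (default `M`) and none of the
forbidden flags (default `V`, `A`, `P`, `B`); threshold and flag sets
are user-overridable. Raising the threshold can only add calls.

```{r amg-example}
v <- generate_mock_viral_contig("H P X P H", seed = 1)
res <- annotate_viral_contigs(v$affi, v$raw_table, v$form, v$contig_lengths,
                      config = amg_call_config_from_lists())
tidy(res) %>% select(gene_id, evidence, aux_score, flags, is_amg)
```

## The product and its HTML view

`build_product_table()` assembles, per genome, the three blocks —
pathway coverage, complex completion, function presence — into one
tibble with column metadata; genome order is input order by default (an
explicit ordering argument covers lexicographic). The HTML renderer
draws a self-contained SVG heatmap with a fixed 0–1 color scale for the
fraction blocks and a binary palette for presence; hovering a cell
reports the genome, column and percent completion through native title
elements. Every cell value is copied from the table (the HTML embeds the
exact values as data attributes), never recomputed, and tables beyond
1000 genomes are split in row order into successive files of at most
1000 rows.

## What the synthetic generators emulate — and what they do not

`generate_mock_genomes()` plants per-database hits at chosen strengths
relative to the decision thresholds (forward > 60; reverse > 350 for
reciprocal plants; below 60 or below model coverage for weak plants), so
each planted gene's rank is known by construction. Contigs default to
3000 bp — above the 2500 bp retention cutoff that drops shorter contigs
before gene calling. `generate_mock_viral_contig()` converts an evidence
layout (`"H P X P H"`) into affiliation rows plus annotations whose
target gene's score and flags follow from the published rules.
`generate_mini_module_set()` emits random grammar-valid module
definitions (≤ 12 KOs) with exhaustive-path completion answers. All
randomness flows through one seed; the same seed yields byte-identical
files.

The generators have structural, not biological, fidelity: sequences are
uniform random, bit scores are drawn around thresholds rather than from
alignment statistics, and the bundled form/AMG lists are tiny synthetic
stand-ins. Passing tests therefore demonstrate that the decision rules,
graph algorithms and bookkeeping are correct — not that annotation
recovery on real communities matches any published biological result,
which depends on multi-gigabyte reference databases the package does not
ship.

## Numerical and scale choices

Completion values are exact rationals computed in double precision; the
suite compares the dynamic program to the enumeration oracle at 1e-12.
Degenerate inputs error explicitly: empty module definitions, modules
with no non-optional content, networks without a weighted path,
duplicate gene or model ids. The test suite exercises 200 random modules
for the parser round trip and the completion oracle, contigs of up to
five genes for the exhaustive auxiliary-score check (all evidence
combinations crossed with three metabolic patterns — the flank rules
depend only on the strongest evidence per flank, so they saturate well
below that length), and a 2500-genome table for heatmap chunking; these
sizes were chosen to exercise every rule branch while keeping the suite
fast on one CPU.

## Limitations

- Gene calling, homology search, RNA detection and viral detection are
  external; garbage hits in means garbage annotations out.
- Completeness/contamination and taxonomy are user-supplied; the package
  only consumes them.
- Rank C does not distinguish a KEGG C from a UniRef C — the rank system
  treats them as one tier.
- The directionality of reactions within modules is not inferred; the
  network follows the definition string's order.
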