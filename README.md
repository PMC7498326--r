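# magdistill

Distillation of metabolic annotations for microbial and viral genomes.

Annotating metagenome-assembled genomes (MAGs) produces per-gene hits
across half a dozen reference databases — far too much raw signal for a
microbiologist asking "which of my 500 genomes can fix nitrogen, ferment
sugars, or respire aerobically?". `magdistill` is for researchers who
already have assemblies, gene calls and search results (from
MMseqs2/HMMER-class tools, which stay external) and need them distilled
into genome-level metabolic statements, including auxiliary metabolic
genes (AMGs) carried by viruses.

The package implements four rule systems:

- **Confidence ranks A–E.** Per database, a gene keeps its maximum-bit-score
  hit if the score exceeds 60. Rank A is a reciprocal best hit (RBH) to
  KEGG — the target's top reverse hit against all input genes is the query,
  with reverse bit score > 350; B is an RBH to UniRef90; C a plain
  KEGG/UniRef hit (> 60); D Pfam/dbCAN/MEROPS-only evidence; E no
  significant hit. Profile hits require model coverage > 0.35 and
  e-value < 1e-15 (or a curated per-model KOfam score threshold).
- **Module completion.** KEGG-style definition strings (space = sequential
  step, comma = alternative, `+` = complex subunit, `-` = optional,
  parentheses group) are parsed into trees and directed acyclic networks.
  *Step coverage* = fraction of steps with ≥ 1 observed gene;
  *best-path completion* = max over source→sink paths of
  present-weight / total-weight, with complexes contributing fractionally
  (computed exactly by a Pareto-frontier dynamic program, verified against
  exhaustive path enumeration).
- **MIMAG quality tiers.** High: completeness > 90%, contamination < 5%,
  5S+16S+23S present, ≥ 18 tRNAs; medium: ≥ 50% / < 10%; else low.
- **Viral auxiliary scores 1–5 and AMG flags.** From flanking viral
  evidence: 1 = hallmark genes on both flanks … 5 = no viral evidence or
  terminal gene; flags `V M K E A P F T B` qualify each gene, and a
  potential AMG has score < 4, flag `M`, and none of `V A P B`.

Everything is tidyverse-native: tibbles in, tibbles out, `tidy()` /
`glance()` on results, `autoplot()` for figures, and a seeded fixture
generator so the whole pipeline runs with zero downloads.

## Worked example

Generate a miniature two-genome workspace with planted annotations and
run the full pipeline:

```r
library(magdistill)
ws <- tempfile()
generate_fixture_workspace(ws, seed = 1)
out <- run_pipeline(ws)

glance(out$annotation)
#> # A tibble: 1 × 7
#>   n_genes n_genomes n_rank_a n_rank_e n_annotated n_hypothetical n_unannotated
#> 1      10         2        2        4           6              0             4

dplyr::select(tidy(out$annotation), gene_id, rank, status) |> head(3)
#>   gene_id          rank  status
#> 1 genome_01_gene_1 A     annotated
#> 2 genome_01_gene_2 C     annotated
#> 3 genome_01_gene_3 D     annotated
```

Gene 1 was planted as a KEGG reciprocal best hit (rank A), gene 2 as a
plain KEGG hit between the 60 and 350 thresholds (rank C), gene 3 with
only a Pfam domain (rank D); the two rank-E genes per genome had either a
VOGDB-only hit or nothing. Module scoring on the same genomes:

```r
step_coverage("K00001 K00002 K00003", c("K00001", "K00003"))
#> 0.6666667   # two of three steps covered
best_path_completion("(K00001 K00002),(K00003)", "K00003")
#> 1           # the one-gene alternative path is fully present
```

Viral AMG calling from an evidence layout (hallmark genes flanking a
metabolic target):

```r
v <- generate_mock_viral_contig("H P X P H", seed = 1)
res <- annotate_viral_contigs(v$affi, v$raw_table, v$form, v$contig_lengths,
                      config = amg_call_config_from_lists())
dplyr::select(tidy(res), gene_id, evidence, aux_score, flags, is_amg)
#>   gene_id          evidence aux_score flags is_amg
#> 1 vcontig_1_gene_1 hallmark         5 VF    FALSE
#> 2 vcontig_1_gene_2 none             1 F     FALSE
#> 3 vcontig_1_gene_3 none             1 MKEF  TRUE
#> 4 vcontig_1_gene_4 none             1 F     FALSE
#> 5 vcontig_1_gene_5 hallmark         5 VF    FALSE
```

The target (gene 3) scores 1 — hallmark evidence on both flanks — and
carries the metabolism (`M`), known-AMG (`K`) and experimentally-verified
(`E`) flags, so it is called as a potential AMG; the hallmark genes
themselves are viral (`V`) and score 5 as terminal genes. `run_pipeline()`
also writes the raw annotation TSV, GFF3, per-genome GenBank files, gene
FASTAs, distillate sheets, the product TSV + HTML heatmap (chunked at
1000 genomes per page) and the vMAG/AMG summaries.

A thin CLI wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("exec","magdistill",package="magdistill"))') \
    fixtures --out ws --seed 1
Rscript .../magdistill annotate --workspace ws
Rscript .../magdistill amg --workspace ws --max-aux-score 4
```

## Package layout

- `R/read-formats.R`, `R/write-formats.R` — FASTA (Biostrings), GFF3
  (rtracklayer), GenBank, hit tables, affiliation tables, forms.
- `R/annotate.R` — best hits, RBH confirmation, profile filters, ranks,
  status, merged raw table.
- `R/module-parse.R`, `R/module-network.R` — definition grammar, step
  coverage, network construction, best-path completion, function rules.
- `R/distill.R`, `R/product.R` — genome stats, MIMAG tiers, identifier
  counts, product table and HTML heatmap.
- `R/viral.R` — viral evidence, auxiliary scores, flags, AMG calls, vMAG
  summaries, AMG product.
- `R/fixtures.R` — seeded generators and the exhaustive-path completion
  oracle.
- `inst/extdata/` — synthetic form/module/rule/AMG-list fixtures (schema
  documented in the readers; real curated tables drop in unchanged).
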