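# resmine

Target-directed (self-resistance-guided) genome mining for fungi.

Producers of bioactive secondary metabolites must avoid poisoning
themselves. When a compound inhibits an essential protein, the producer's
genome often carries a **duplicated, resistant copy of the target gene,
co-located in the compound's biosynthetic gene cluster (BGC)**. `resmine`
turns that observation into a screen for prioritizing BGCs: instead of
asking what a cluster makes, it asks whether a cluster contains a putative
resistant target — which simultaneously suggests the compound's mode of
action.

For each essential ("core") gene model the screen reports three
independent criteria:

* **D — duplication**: copy number in the query genome strictly exceeds
  the model's threshold, `median + k·σ` of the copy counts across a
  reference genome collection (population σ, `k = 1` by default, zeros
  included for genomes lacking the gene);
* **B — BGC proximity**: a hit gene's interval overlaps a BGC interval by
  ≥ 1 bp (half-open coordinates, same contig);
* **R — resistance model**: a gene matches a profile HMM of a known
  resistance factor.

Per-model metadata supports interpretation: median pairwise
**Nei–Gojobori dN/dS** with Jukes–Cantor correction
(d = −¾·ln(1 − 4p/3)) over the reference members, **ubiquity** (fraction
of reference genomes carrying the gene) and **single-copy frequency**.
Default-mode screening removes regulatory/transport/biosynthetic
functional classes (COG letters Q, K, P, U; configurable) that would
inflate false positives; exploration mode searches everything.

The package is aimed at natural-product genome miners: it consumes
GenBank/EMBL/FASTA(+coordinate table) genomes and antiSMASH-style region
annotations or plain BGC coordinate tables, and emits deterministic TSV
tables plus a static HTML report for single- and multi-genome runs.
Profile-HMM search runs through HMMER 3 (`hmmbuild`/`hmmsearch` must be on
the PATH); BGC prediction and gene calling are consumed as input, never
reimplemented.

## Worked example

The package ships a deterministic generator of synthetic collections with
planted ground truth, so the whole pipeline runs offline:

```r
library(resmine)

spec <- fixture_spec(seed = 11, planted_events = data.frame(
  model_id = "model06", genome_id = "qry1", extra_copies = 1L,
  inside_bgc = TRUE))
coll <- generate_collection(spec)

refset <- build_refset(unname(coll$ref_genomes), coll$orthologs,
                       name = "demo", annotations = coll$annotations,
                       hmm_dir = coll$hmm_dir)
#> reference_set 'demo': 10 model(s) from 5 reference genome(s)

q <- coll$query_genomes$qry1
res <- screen_genome(q, refset, detect_core_genes(q, refset, "default"))
res
#> screening_result 'qry1' (default mode)
#>   models hit: 10 (duplicated 1, BGC-proximal 1)
#>   BGCs: 3 total, 1 with core hit, 0 with resistance hit
#>   genes: 11 core of 17 total

res$rows[1:3, c("model_id", "copy_number", "duplication_threshold",
                "duplication", "proximity", "dnds_median")]
#>   model_id copy_number duplication_threshold duplication proximity dnds_median
#> 1  model06           2                     1        TRUE      TRUE   1.0070683
#> 2  model01           1                     1       FALSE     FALSE   0.5145910
#> 3  model02           1                     1       FALSE     FALSE   0.6573958
```

The planted extra copy of `model06` inside a BGC is the only model flagged
D+B: its two copies exceed the all-single-copy reference threshold of 1,
and one copy overlaps `bgc1`. The per-family dN/dS values hover near 1
because the synthetic families diverge neutrally. `res$bgc_summary` shows
which clusters carry the hits:

```r
res$bgc_summary[, c("cluster_id", "start", "end", "product_class", "n_core_hits")]
#>   cluster_id start   end product_class n_core_hits
#> 1       bgc1 15000 19000          NRPS           1
#> 2       bgc2 30000 34000           PKS           0
#> 3       bgc3 45000 49000       terpene           0
```

For file-based batch runs use `run_single()` / `run_multi()` (five TSV
tables, `manifest.json`, `report.html`; multi-genome runs add per-model
hit frequencies in [0, 1] over successful runs), or the thin CLI in
`inst/cli/resmine`:

```sh
resmine run --input genome1.gbk,genome2.gbk --refset refset_dir --out results/
resmine build-refset --genomes refs/ --orthologs orthologs.tsv --out refset_dir
```

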