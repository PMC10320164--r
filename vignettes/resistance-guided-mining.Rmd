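---
title: "Resistance-guided prioritization of fungal biosynthetic gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resistance-guided prioritization of fungal biosynthetic gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Fungal secondary metabolites are encoded by biosynthetic gene clusters
(BGCs), and genome-mining tools now predict far more BGCs than any lab can
characterize. `resmine` prioritizes BGCs by looking for evidence of
*self-resistance*: a producer of a bioactive compound whose target is one of
its own essential proteins typically carries a second, resistant copy of
that target gene, often inside the compound's BGC. The package therefore
screens a query genome for three independent signals per essential
("core") gene model:

* **Duplication (D)** — the genome carries more copies of the gene than
  expected from a reference collection;
* **BGC proximity (B)** — a copy lies within a predicted BGC's boundaries;
* **Resistance model (R)** — a gene matches a profile HMM of a known
  resistance factor.

None of these criteria alone proves resistance; their combination, together
with per-model metadata (selection pressure, ubiquity, single-copy
frequency), is what makes a BGC worth a closer look. The recommended
reading order is proximity first, then duplication of the proximal gene.

## Reference sets

A reference set is built from a collection of annotated genomes and an
ortholog-assignment table (BUSCO/OrthoDB-style: one row per member gene of
an ortholog group). For each group the builder records:

* **copy counts** per reference genome, with genomes lacking the group
  contributing count 0 — absence is information about how broadly essential
  a gene really is;
* the **duplication threshold** `median + k · stdev` of those counts.
  The standard deviation is the *population* form (divide by *n*) and the
  default multiplier is `k = 1`; neither choice is canonical in the
  literature of this tool family, so both are configuration knobs
  (`count_stats(k=)`, `run_config(duplication_k=)`), and the flag uses a
  strict inequality: a query copy number exactly at the threshold is *not*
  called duplicated;
* **ubiquity** (fraction of reference genomes with ≥ 1 copy) and
  **single-copy frequency** (fraction with exactly 1 copy);
* the **median pairwise dN/dS** over all member coding sequences
  (see below), `NA` when fewer than two members carry usable CDS;
* a **functional class** (COG category letters) taken from an annotation
  table supplied alongside the ortholog table. The ortholog table itself
  carries no functional information, so the builder accepts a separate
  `annotations` data frame; this is the package's own interface choice.

Search modes: in **default** mode, models whose class intersects the
excluded set are dropped *before* any search, because regulatory,
transport and biosynthetic genes inside BGCs are poor resistance
candidates and inflate false positives. The shipped excluded set is
`{Q, K, P, U}` — Q (secondary-metabolite biosynthesis, transport and
catabolism), K (transcription), and P/U as the transporter-annotated
classes. The mapping from the functional description to concrete COG
letters is a design choice of this package and is configurable
(`classify_and_filter(excluded=)`). **Exploration** mode skips the filter
entirely and is the identity on the model list. Models with unrecognized
class letters are retained with a logged warning rather than silently
dropped.

Reference sets are serialized as an inspectable directory bundle
(`models.tsv`, `hmms/`, `manifest.json` with a content hash) so that a set
can be diffed and versioned.

## Nei–Gojobori dN/dS

Selection pressure per model is estimated with the counting method of Nei
and Gojobori on codon-aligned member CDS pairs:

* per codon, each of the three positions contributes the fraction of its
  single-nucleotide changes that are synonymous to the synonymous site
  count `s`; changes creating a stop codon are excluded from that
  position's denominator, and `n = 3 − s`;
* site counts `N`, `S` are averaged over the two sequences;
* for codons differing at ≥ 2 positions, the synonymous/nonsynonymous
  difference counts `Sd`, `Nd` average with equal weight over all shortest
  substitution pathways; pathways through stop codons are excluded, and in
  the (rare) case where every pathway is blocked the codon pair is skipped
  with a warning;
* proportions `pN = Nd/N`, `pS = Sd/S` receive the Jukes–Cantor correction
  `d = −(3/4)·ln(1 − 4p/3)`; `ω = dN/dS`.

Two degenerate outcomes are made explicit instead of being coerced to
numbers: `saturated` when `4p/3 ≥ 1` for either class (the correction is
undefined), and `undefined_dS_zero` when `dS = 0` (identical or purely
nonsynonymously diverged sequences); `ω` is `NA` in both cases. The
per-model statistic is the **median** ω over all unordered member pairs
with a defined ω — the median, not the mean, because a single saturated or
near-saturated pair would otherwise dominate. Inputs are assumed
codon-aligned; `align_codons()` provides a protein-guided helper
(Needleman–Wunsch on translations, BLOSUM62, gap open/extend 10/0.5 —
plumbing, not a scientific claim).

The per-codon site counts and the 61×61 pathway-averaged difference counts
are precomputed once per session, so pairwise comparisons reduce to table
lookups.

## Detection and screening

Core genes are located by profile-HMM search of the query proteome. The
search engine is an *injected dependency* recorded in the run manifest; the
default engine shells out to HMMER 3 (`hmmbuild`/`hmmsearch`), and the
profile-HMM algorithms are never reimplemented. Per model, the bitscore
cutoff is the profile's trusted-cutoff line when present, else a
configurable floor (25 bits). One gene counts at most once per model (best
full-sequence hit), so multi-domain repeats within one protein cannot
inflate a copy number.

Coordinates are 0-based half-open everywhere inside the package;
conversion to/from the 1-based inclusive GenBank/EMBL convention happens
only at the format boundary, which makes overlap arithmetic unambiguous.
"Proximity" means ≥ 1 shared base between the gene's envelope and the BGC
interval on the same contig — containment is not required, and a half-open
"touch" is not an overlap. Compound `join()` CDS locations are flattened to
their outer envelope for proximity, while the CDS sequence is spliced for
dN/dS. When a genome input is a bare BGC record (no flanking genome), the
whole record is treated as one region and duplication flags are reported
`NA`: a genome-wide copy count does not exist in that mode.

Multi-genome runs aggregate per-model **hit frequencies**: the number of
genomes with ≥ 1 hit for the model divided by the number of *successful*
runs, always in [0, 1]. A model hit nowhere is absent from the table rather
than reported as a 0.0 row; a genome that fails to parse is excluded from
the denominator and recorded in the manifest — the alternative (failing the
whole batch) punishes large runs for one corrupt file. Batch outputs are
deterministic: fixed column orders, canonical row sort (flag count desc,
copy number desc, model id asc), and byte-identical TSVs for identical
inputs and configuration.

## What the synthetic generator emulates — and what it does not

`generate_collection()` builds reference and query genomes in which every
core-gene model is a protein family: a random ancestral CDS of sense
codons, diverged per member by uniform per-codon substitution (default
rate 0.05 per codon, enough divergence for realistic profile HMMs while
keeping families well separated from the random background), never
creating stops. Default scale — 5 reference genomes, 10 models of 100
codons, 60 kb single-contig genomes, 3 BGCs of 4 kb with 2 unrelated
filler genes each — is small enough that a full screen takes about two
seconds yet exercises every pipeline stage; the same sizes are used
throughout the test suite and the acceptance script (20 independent seeds
for the recovery property).

Planted events place extra family copies inside or outside BGCs and drive
a truth ledger against which duplication/proximity calls are scored. The
generator checks packing feasibility before writing anything and is
byte-deterministic given a seed.

Deliberate non-realism: single-exon CDS only (no introns), uniform base
composition, no intergenic conservation, BGCs are plain intervals with
random filler content, and family divergence is neutral (per-family ω
centres near 1, so fixture dN/dS values say nothing about purifying
selection in real core genes). Passing the planted-truth tests therefore
demonstrates the *bookkeeping* — detection, thresholds, overlap,
aggregation — not performance on real fungal genomes, where intron
structure, contamination, fragmented assemblies and reference-set
composition all matter.

## Numerical and degenerate-input policy

* Empty count vectors, empty ortholog groups with no observations, and
  missing reference genomes are errors, not silent zeros.
* A genome with zero CDS screens to an empty result (all totals zero).
* TSV cells containing tabs/newlines are sanitized to spaces (logged);
  numeric cells are written with 15 significant digits so bundles
  round-trip within 1e-9.
* Untranslatable CDS (internal stop, no `/translation`) are skipped with a
  logged warning rather than aborting the file.
* Ties in output ordering are broken by model id so runs are reproducible.

## Known limitations

* BGC prediction itself is out of scope: regions are consumed from
  antiSMASH-style GenBank files or coordinate tables.
* Gene calling is out of scope: FASTA input requires a sidecar coordinate
  table.
* Similarity networking of BGCs is out of scope; `run_multi()` can export
  per-region GenBank files as input for an external networking tool but
  never invokes it.
* The Nei–Gojobori estimator is the unweighted original; no
  transition/transversion weighting and no codon-model (ML) estimates.
* Duplication calls are threshold-based, not statistical tests; with small
  reference collections the population-stdev threshold is coarse.
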