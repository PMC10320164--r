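# One shared fixture collection + reference set per test session; building
# profiles shells out to hmmbuild, so tests reuse it instead of rebuilding.

.collection_cache <- new.env(parent = emptyenv())

shared_collection <- function() {
  if (!is.null(.collection_cache$coll)) return(.collection_cache$coll)
  spec <- fixture_spec(
    seed = 42,
    planted_events = data.frame(
      model_id = c("model03", "model07"), genome_id = "qry1",
      extra_copies = c(1L, 2L), inside_bgc = c(TRUE, FALSE),
      stringsAsFactors = FALSE),
    resistance_events = data.frame(
      model_id = "resmodel01", genome_id = "qry1", inside_bgc = TRUE,
      stringsAsFactors = FALSE))
  coll <- generate_collection(spec)
  refset <- build_refset(unname(coll$ref_genomes), coll$orthologs,
                         name = "toy", annotations = coll$annotations,
                         hmm_dir = coll$hmm_dir)
  .collection_cache$coll <- list(coll = coll, refset = refset)
  .collection_cache$coll
}

# minimal hand-built genome record (no HMM engine needed)
toy_genome <- function(genome_id = "toy",
                       genes = NULL, bgcs = NULL, contig_len = 10000L) {
  if (is.null(genes))
    genes <- gene_features(gene_id = c("g1", "g2"), contig_id = "c1",
                           start = c(100L, 1000L), end = c(400L, 1300L),
                           strand = c("+", "-"),
                           protein_seq = c("MKT", "MHV"),
                           cds_seq = c("ATGAAAACG", "ATGCACGTA"))
  if (is.null(bgcs)) bgcs <- bgc_regions()
  genome_record(genome_id, genes = genes, bgcs = bgcs,
                contigs = c(c1 = contig_len))
}

# a hand-built models table usable as a reference_set for screening tests
toy_refset <- function(model_ids = c("m1", "m2"),
                       thresholds = c(1, 1),
                       classes = c("J", "E")) {
  models <- data.frame(
    model_id = model_ids, description = "toy",
    function_class = rep_len(classes, length(model_ids)),
    count_median = rep_len(1, length(model_ids)),
    count_stdev = thresholds - 1,
    duplication_threshold = thresholds,
    ubiquity = 1, single_copy_freq = 1, dnds_median = NA_real_,
    bitscore_cutoff = 25, hmm_path = NA_character_,
    stringsAsFactors = FALSE)
  structure(list(name = "toyset", models = models,
                 n_reference_genomes = 3L,
                 mode_filter = default_excluded_classes()),
            class = "reference_set")
}

# fabricate a core-hit set list as detect_core_genes() would return
toy_hits <- function(model_id, gene_ids, bitscores = NULL) {
  if (is.null(bitscores)) bitscores <- rev(seq_along(gene_ids)) * 10 + 100
  h <- data.frame(model_id = model_id, gene_id = gene_ids,
                  bitscore = bitscores, evalue = 1e-30,
                  category = "core", stringsAsFactors = FALSE)
  h <- h[order(-h$bitscore, h$gene_id), , drop = FALSE]
  list(model_id = model_id, hits = h,
       copy_number = length(unique(gene_ids)))
}
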