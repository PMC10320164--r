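# Genome and BGC I/O: coordinate conventions, flat-file round trips, TSV
# dialect rules.

make_genbank <- function(path, cds_locations, seq_len = 600L, with_seq = TRUE,
                         translations = NULL) {
  lines <- c(sprintf("LOCUS       chrA            %6d bp    DNA     linear   UNA 01-JAN-2000",
                     seq_len),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", seq_len))
  # a /translation is always supplied: the background sequence is random, so
  # ab initio translation would hit internal stops and drop the feature
  if (is.null(translations)) translations <- rep("MKTESTPEPTIDE", length(cds_locations))
  for (i in seq_along(cds_locations)) {
    lines <- c(lines, sprintf("     CDS             %s", cds_locations[i]),
               sprintf("                     /locus_tag=\"g%d\"", i),
               sprintf("                     /translation=\"%s\"", translations[i]))
  }
  if (with_seq) {
    set.seed(1)
    s <- paste(sample(c("a", "c", "g", "t"), seq_len, replace = TRUE), collapse = "")
    lines <- c(lines, "ORIGIN")
    pos <- 1L
    while (pos <= nchar(s)) {
      chunk <- substr(s, pos, min(pos + 59L, nchar(s)))
      groups <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      lines <- c(lines, sprintf("%9d %s", pos, paste(groups, collapse = " ")))
      pos <- pos + 60L
    }
  }
  writeLines(c(lines, "//"), path)
  path
}

test_that("GenBank 1-based inclusive converts to 0-based half-open", {
  p <- tempfile(fileext = ".gbk")
  make_genbank(p, "101..400")
  g <- read_genome(p, "genbank")
  expect_equal(g$genes$start, 100L)
  expect_equal(g$genes$end, 400L)
  expect_equal(g$genes$strand, "+")
  expect_equal(nchar(g$genes$cds_seq), 300L)
  # complement strand
  make_genbank(p, "complement(61..360)")
  g <- read_genome(p, "genbank")
  expect_equal(g$genes$start, 60L)
  expect_equal(g$genes$end, 360L)
  expect_equal(g$genes$strand, "-")
})

test_that("a record with zero CDS features yields an empty gene table", {
  p <- tempfile(fileext = ".gbk")
  make_genbank(p, character())
  g <- read_genome(p, "genbank")
  expect_equal(nrow(g$genes), 0L)
  expect_equal(unname(g$contigs["chrA"]), 600L)
  # the empty genome still screens: no hits, no flags
  res <- screen_genome(g, toy_refset(), core_hits = list())
  expect_equal(nrow(res$rows), 0L)
  expect_equal(res$totals$n_genes_total, 0L)
})

test_that("joined compound locations flatten to the envelope but splice the CDS", {
  p <- tempfile(fileext = ".gbk")
  make_genbank(p, "join(101..160,201..242)")
  g <- read_genome(p, "genbank")
  expect_equal(g$genes$start, 100L)
  expect_equal(g$genes$end, 242L)
  expect_equal(nchar(g$genes$cds_seq), 60L + 42L)  # spliced, not envelope
})

test_that("untranslatable CDS (internal stop, no /translation) is skipped", {
  p <- tempfile(fileext = ".gbk")
  # ATG TAA TTT (internal stop) | ATG AAA CCC (fine), 18 bp contig
  lines <- c("LOCUS       chrA                18 bp    DNA     linear   UNA 01-JAN-2000",
             "FEATURES             Location/Qualifiers",
             "     source          1..18",
             "     CDS             1..9",
             "                     /locus_tag=\"stopgene\"",
             "     CDS             10..18",
             "                     /locus_tag=\"okgene\"",
             "ORIGIN",
             sprintf("%9d %s", 1, "atgtaattta tgaaaccc"),
             "//")
  writeLines(lines, p)
  g <- read_genome(p, "genbank")
  expect_identical(g$genes$gene_id, "okgene")
  expect_equal(g$genes$protein_seq, "MKP")
})

test_that("genome records round-trip through GenBank, EMBL and FASTA+table", {
  coll <- generate_collection(fixture_spec(seed = 3, n_models = 12,
                                           n_query_genomes = 0),
                              engine = NULL)
  g <- coll$ref_genomes$ref1
  expect_equal(nrow(g$genes), 12L + 2L * 3L)  # 12 core + 2 fillers per BGC

  gb <- tempfile(fileext = ".gbk")
  write_genome_genbank(g, gb)
  g2 <- read_genome(gb, "genbank", genome_id = g$genome_id)
  ord <- order(g$genes$start)
  expect_equal(g2$genes$gene_id, g$genes$gene_id[ord])
  expect_equal(g2$genes$start, g$genes$start[ord])
  expect_equal(g2$genes$end, g$genes$end[ord])
  expect_equal(g2$genes$strand, g$genes$strand[ord])
  expect_equal(g2$genes$protein_seq, g$genes$protein_seq[ord])
  expect_equal(g2$genes$cds_seq, g$genes$cds_seq[ord])
  expect_equal(g2$bgcs$cluster_id, g$bgcs$cluster_id)
  expect_equal(g2$bgcs$start, g$bgcs$start)
  expect_equal(g2$bgcs$end, g$bgcs$end)
  expect_equal(g2$contigs, g$contigs)

  em <- tempfile(fileext = ".embl")
  write_genome_embl(g, em)
  g3 <- read_genome(em, "embl", genome_id = g$genome_id)
  expect_equal(g3$genes, g2$genes)
  expect_equal(g3$bgcs$start, g2$bgcs$start)

  fa <- tempfile(fileext = ".fna"); tb <- tempfile(fileext = ".tsv")
  write_genome_fasta(g, fa, tb)
  g4 <- read_genome(fa, "fasta", gene_table = tb, genome_id = g$genome_id)
  expect_equal(g4$genes$gene_id, g2$genes$gene_id)
  expect_equal(g4$genes$cds_seq, g2$genes$cds_seq)

  # format auto-detection picks the right parser
  expect_equal(read_genome(gb)$genes$gene_id, g2$genes$gene_id)
  expect_equal(read_genome(em)$genes$gene_id, g2$genes$gene_id)
})

test_that("BGC coordinate tables parse, reject bad rows, and sort", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("cluster_id\tcontig_id\tstart\tend\tproduct_class",
               "bgc2\tchr1\t2000\t2900\tNRPS",
               "bgc1\tchr1\t400\t900\tterpene"), p)
  b <- read_bgc_regions(p, "tsv_table")
  expect_equal(b$cluster_id, c("bgc1", "bgc2"))  # sorted by (contig, start)
  expect_equal(b$start[1], 400L)
  expect_equal(b$end[1], 900L)
  expect_identical(unique(b$source), "coordinate_table")

  writeLines(c("cluster_id\tcontig_id\tstart\tend\tproduct_class"), p)
  expect_equal(nrow(read_bgc_regions(p, "tsv_table")), 0L)

  writeLines(c("cluster_id\tcontig_id\tstart\tend\tproduct_class",
               "ok\tchr1\t10\t20\tx",
               "bad\tchr1\t900\t400\tterpene"), p)
  expect_error(read_bgc_regions(p, "tsv_table"), "row 3")
})

test_that("antiSMASH-style region features are read from GenBank", {
  coll <- generate_collection(fixture_spec(seed = 4, n_query_genomes = 0),
                              engine = NULL)
  g <- coll$ref_genomes$ref2
  gb <- tempfile(fileext = ".gbk")
  write_genome_genbank(g, gb)
  b <- read_bgc_regions(gb, "antismash_region_gbk")
  expect_equal(b$cluster_id, g$bgcs$cluster_id)
  expect_equal(b$start, g$bgcs$start)
  expect_equal(b$end, g$bgcs$end)
  expect_equal(b$product_class, g$bgcs$product_class)
})

test_that("a single-BGC GenBank file reads as a genome of only the BGC's genes", {
  # squalestatin-style run: the input is one region file, no flanking genome
  coll <- generate_collection(fixture_spec(seed = 5, n_query_genomes = 0),
                              engine = NULL)
  g <- coll$ref_genomes$ref1
  reg <- g$bgcs[1, ]
  sel <- g$genes$start < reg$end & g$genes$end > reg$start
  slice_genes <- g$genes[sel, , drop = FALSE]
  slice_genes$start <- slice_genes$start - reg$start
  slice_genes$end <- slice_genes$end - reg$start
  slice <- genome_record("bgc_only",
                         genes = slice_genes,
                         bgcs = bgc_regions(reg$cluster_id, reg$contig_id, 0L,
                                            reg$end - reg$start, reg$product_class,
                                            "fixture"),
                         contigs = setNames(reg$end - reg$start, reg$contig_id),
                         contig_seq = setNames(substr(g$contig_seq[["chr1"]],
                                                      reg$start + 1L, reg$end),
                                               reg$contig_id))
  p <- tempfile(fileext = ".gbk")
  write_genome_genbank(slice, p)
  back <- read_genome(p, "genbank")
  expect_equal(nrow(back$genes), sum(sel))
  expect_equal(back$genes$cds_seq, slice_genes$cds_seq[order(slice_genes$start)])
})

test_that("TSV writer: header-only empty tables, round trips, tab sanitation", {
  p <- tempfile(fileext = ".tsv")
  empty <- data.frame(model_id = character(), copy_number = integer(),
                      stringsAsFactors = FALSE)
  write_tsv(empty, p)
  expect_equal(readLines(p), "model_id\tcopy_number")

  tab <- data.frame(model_id = c("m1", "m2"), score = c(1.25, -3.5),
                    note = c("plain", "free text"), stringsAsFactors = FALSE)
  write_tsv(tab, p)
  back <- read_tsv(p)
  expect_equal(back$model_id, tab$model_id)
  expect_equal(back$score, tab$score)
  expect_equal(back$note, tab$note)

  dirty <- data.frame(a = "has\ttab", b = "has\nnewline", stringsAsFactors = FALSE)
  write_tsv(dirty, p)
  back <- read_tsv(p)
  expect_equal(back$a, "has tab")
  expect_equal(back$b, "has newline")
})

test_that("invariant: valid intervals survive the coordinate conversion bijection", {
  set.seed(77)
  for (i in 1:50) {
    start0 <- sample(0:5000, 1)
    end0 <- start0 + 3 * sample(1:300, 1)
    # internal -> GenBank -> internal
    gb_start <- start0 + 1L; gb_end <- end0
    expect_equal(gb_start - 1L, start0)
    loc <- resmine:::parse_location(sprintf("%d..%d", gb_start, gb_end))
    expect_equal(min(loc$exon_start) - 1L, start0)
    expect_equal(max(loc$exon_end), end0)
  }
})
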