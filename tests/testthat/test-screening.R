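# Screening criteria: duplication flag, proximity pairs, per-genome result
# assembly, multi-genome aggregation.

test_that("duplication flag is strictly greater-than at the boundary", {
  expect_true(flag_duplication(2, 1.35))
  expect_false(flag_duplication(1, 1.0))  # copy == threshold: not duplicated
  expect_false(flag_duplication(0, 0))
  expect_false(flag_duplication(0, 1.5))
  expect_true(flag_duplication(1, 0.9))
  # accepts a models row
  expect_true(flag_duplication(2, list(duplication_threshold = 1.3499)))
})

test_that("proximity requires >= 1 shared base under half-open semantics", {
  genes <- gene_features(c("gA", "gB", "gC"), "c1",
                         start = c(100L, 100L, 950L), end = c(500L, 400L, 1200L),
                         strand = "+")
  bgcs <- bgc_regions(c("b1", "b2"), "c1", start = c(400L, 1100L),
                      end = c(900L, 1400L), product_class = "terpene")
  g <- toy_genome(genes = genes, bgcs = bgcs)
  pp <- proximity_pairs(c("gA", "gB", "gC"), g)
  # gA [100,500) overlaps b1 [400,900); gB [100,400) only touches: no pair;
  # gC [950,1200) overlaps b2 [1100,1400)
  expect_equal(pp, data.frame(gene_id = c("gA", "gC"),
                              cluster_id = c("b1", "b2"),
                              stringsAsFactors = FALSE))
  # different contigs never pair even with identical coordinates
  genes2 <- gene_features("gX", "c2", 400L, 900L, "+")
  g2 <- genome_record("two", genes = rbind(genes, genes2), bgcs = bgcs,
                      contigs = c(c1 = 10000L, c2 = 10000L))
  expect_false("gX" %in% proximity_pairs(c("gA", "gX"), g2)$gene_id)
  # a gene spanning two BGCs yields two pairs
  wide <- gene_features("gW", "c1", 300L, 1200L, "+")
  g3 <- genome_record("wide", genes = wide, bgcs = bgcs, contigs = c(c1 = 10000L))
  expect_equal(proximity_pairs("gW", g3)$cluster_id, c("b1", "b2"))
  # empty inputs give empty output
  expect_equal(nrow(proximity_pairs(character(), g)), 0L)
  expect_equal(nrow(proximity_pairs("gA", toy_genome())), 0L)
})

test_that("random layouts agree with all-position brute-force intersection", {
  set.seed(55)
  for (rep in 1:10) {
    n_genes <- 30; n_bgcs <- 4
    genes <- gene_features(sprintf("g%02d", 1:n_genes),
                           sample(c("c1", "c2"), n_genes, replace = TRUE),
                           start = (starts <- sample(0:9000, n_genes)),
                           end = starts + sample(50:600, n_genes, replace = TRUE),
                           strand = sample(c("+", "-"), n_genes, replace = TRUE))
    bs <- sample(0:8000, n_bgcs)
    bgcs <- bgc_regions(sprintf("b%d", 1:n_bgcs),
                        sample(c("c1", "c2"), n_bgcs, replace = TRUE),
                        start = bs, end = bs + sample(300:2000, n_bgcs, replace = TRUE),
                        product_class = "x")
    g <- genome_record("rand", genes = genes, bgcs = bgcs,
                       contigs = c(c1 = 20000L, c2 = 20000L))
    expect_equal(proximity_pairs(genes$gene_id, g),
                 oracle_proximity(g$genes, g$bgcs))
  }
})

test_that("screen_genome flags planted duplications and proximity correctly", {
  sc <- shared_collection()
  q <- sc$coll$query_genomes$qry1
  core <- detect_core_genes(q, sc$refset, "default")
  aux <- detect_auxiliary(q, resistance_models = sc$coll$res_hmms)
  res <- screen_genome(q, sc$refset, core, aux)
  rows <- res$rows
  r3 <- rows[rows$model_id == "model03", ]
  expect_true(r3$duplication && r3$proximity && !r3$resistance_model)
  r7 <- rows[rows$model_id == "model07", ]
  expect_true(r7$duplication && !r7$proximity)  # planted outside BGCs
  others <- rows[rows$category == "core" &
                   !rows$model_id %in% c("model03", "model07"), ]
  expect_false(any(others$duplication) || any(others$proximity))
  # resistance row: R set, proximity from its planted in-BGC location
  rr <- rows[rows$category == "resistance", ]
  expect_true(rr$resistance_model && rr$proximity)
  # every proximal cluster_id appears in the BGC summary
  expect_true(all(res$proximity$cluster_id %in% res$bgc_summary$cluster_id))
  # rows sort: flagged models first, then by copy number, then id
  nflags <- (rows$duplication %in% TRUE) + (rows$proximity %in% TRUE) +
    (rows$resistance_model %in% TRUE)
  expect_true(all(diff(nflags) <= 0 | diff(rows$copy_number) <= 0))
  expect_equal(rows$model_id[1], "model03")
})

test_that("screening totals are self-consistent with the rows and summary", {
  sc <- shared_collection()
  q <- sc$coll$query_genomes$qry1
  core <- detect_core_genes(q, sc$refset, "default")
  aux <- detect_auxiliary(q, resistance_models = sc$coll$res_hmms)
  res <- screen_genome(q, sc$refset, core, aux)
  rt <- resmine:::recompute_totals(res)
  for (f in names(rt)) expect_equal(res$totals[[f]], rt[[f]], info = f)
  expect_equal(res$totals$n_genes_total, nrow(q$genes))
  expect_equal(res$totals$n_bgcs, 3L)
  expect_equal(res$totals$n_bgcs_with_core_hit, 1L)
  expect_equal(res$totals$n_bgcs_with_res_hit, 1L)
})

test_that("a genome with zero BGCs has no proximity and empty BGC summary", {
  g <- toy_genome()
  rs <- toy_refset()
  hits <- list(m1 = toy_hits("m1", c("g1", "g2")))
  res <- screen_genome(g, rs, hits)
  expect_false(any(res$rows$proximity))
  expect_equal(nrow(res$bgc_summary), 0L)
  expect_equal(res$totals$n_bgcs, 0L)
  expect_equal(res$totals$n_bgcs_with_core_hit, 0L)
  expect_equal(res$totals$n_bgcs_with_res_hit, 0L)
  expect_true(res$rows$duplication[1])  # 2 copies > threshold 1 still flags D
})

test_that("a resistance hit outside every BGC sets R without touching BGC counts", {
  genes <- gene_features(c("g1", "gres"), "c1", start = c(100L, 5000L),
                         end = c(400L, 5300L), strand = "+")
  bgcs <- bgc_regions("b1", "c1", 600L, 2000L, "NRPS")
  g <- genome_record("t", genes = genes, bgcs = bgcs, contigs = c(c1 = 10000L))
  aux <- data.frame(model_id = "res1", gene_id = "gres", bitscore = 200,
                    evalue = 1e-50, category = "resistance",
                    stringsAsFactors = FALSE)
  res <- screen_genome(g, toy_refset(), list(m1 = toy_hits("m1", "g1")), aux)
  rr <- res$rows[res$rows$model_id == "res1", ]
  expect_true(rr$resistance_model)
  expect_false(rr$proximity)
  expect_equal(res$totals$n_bgcs_with_res_hit, 0L)
})

test_that("criteria independence: auxiliary searches never change core D/B flags", {
  sc <- shared_collection()
  q <- sc$coll$query_genomes$qry1
  core <- detect_core_genes(q, sc$refset, "default")
  aux <- detect_auxiliary(q, resistance_models = sc$coll$res_hmms)
  with_aux <- screen_genome(q, sc$refset, core, aux)
  without <- screen_genome(q, sc$refset, core, NULL)
  a <- with_aux$rows[with_aux$rows$category == "core",
                     c("model_id", "duplication", "proximity")]
  b <- without$rows[, c("model_id", "duplication", "proximity")]
  a <- a[order(a$model_id), ]; b <- b[order(b$model_id), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("single-copy models away from gene-free BGCs raise no flags", {
  genes <- gene_features(c("g1", "g2"), "c1", start = c(100L, 3000L),
                         end = c(400L, 3300L), strand = "+")
  bgcs <- bgc_regions("b1", "c1", 6000L, 8000L, "PKS")
  g <- genome_record("quiet", genes = genes, bgcs = bgcs, contigs = c(c1 = 10000L))
  hits <- list(m1 = toy_hits("m1", "g1"), m2 = toy_hits("m2", "g2"))
  res <- screen_genome(g, toy_refset(), hits)
  expect_false(any(res$rows$duplication))
  expect_false(any(res$rows$proximity))
  expect_false(any(res$rows$resistance_model))
})

test_that("duplication_k rescales thresholds at screening time", {
  rs <- toy_refset(model_ids = "m1", thresholds = 1.5)  # median 1, stdev 0.5
  g <- toy_genome()
  hits <- list(m1 = toy_hits("m1", c("g1", "g2")))  # copy number 2
  expect_true(screen_genome(g, rs, hits)$rows$duplication[1])       # 2 > 1.5
  expect_false(screen_genome(g, rs, hits, duplication_k = 2)$rows$duplication[1])  # 2 > 2 fails
  expect_true(screen_genome(g, rs, hits, duplication_k = 0.5)$rows$duplication[1])
})

test_that("multi-genome frequencies count hit genomes over all runs", {
  rs <- toy_refset(model_ids = c("m1", "m2", "m3"), thresholds = c(1, 1, 1))
  mk <- function(gid, models) {
    g <- toy_genome(gid)
    hits <- setNames(lapply(models, function(m) toy_hits(m, "g1")), models)
    screen_genome(g, rs, hits)
  }
  results <- list(mk("g1", c("m1", "m2")), mk("g2", "m1"),
                  mk("g3", c("m1", "m2")), mk("g4", "m1"))
  agg <- aggregate_multi(results)
  expect_equal(agg$n_genomes, 4L)
  m <- agg$models
  expect_equal(m$frequency[m$model_id == "m1"], 1.0)
  expect_equal(m$frequency[m$model_id == "m2"], 0.5)
  expect_false("m3" %in% m$model_id)  # hit nowhere: absent, not a 0.0 row
  expect_true(all(m$frequency >= 0 & m$frequency <= 1))
  expect_true(all(m$frequency %in% c(0.25, 0.5, 0.75, 1.0)))
  expect_equal(nrow(agg$per_genome), 4L)
  expect_error(aggregate_multi(results[1]), ">= 2")
})
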