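# Reference-set construction: duplication thresholds, ubiquity, single-copy
# frequency, functional-class filtering, bundle round trip.

test_that("count statistics use the median plus population stdev", {
  expect_equal(count_stats(c(1, 1, 1, 1, 1)),
               c(median = 1, stdev = 0, threshold = 1))
  st <- count_stats(c(1, 1, 1, 1, 2, 1, 1))
  expect_equal(st[["median"]], 1)
  expect_equal(st[["stdev"]], 0.3499271, tolerance = 1e-6)
  expect_equal(st[["threshold"]], 1.3499271, tolerance = 1e-6)
  # zeros are observations, not missing data
  st <- count_stats(c(0, 0, 0, 2))
  expect_equal(st[["median"]], 0)
  expect_equal(st[["threshold"]], 0 + st[["stdev"]])
  expect_equal(st[["stdev"]], sqrt(mean((c(0, 0, 0, 2) - 0.5)^2)))
  expect_error(count_stats(numeric()), "no reference observations")
})

test_that("count statistics match the brute-force oracle on random vectors", {
  set.seed(19)
  for (i in 1:100) {
    x <- sample(0:6, sample(3:40, 1), replace = TRUE)
    expect_equal(count_stats(x), oracle_count_stats(x), tolerance = 1e-12)
  }
})

test_that("threshold >= median with equality only for constant counts", {
  set.seed(20)
  for (i in 1:50) {
    x <- sample(0:4, 10, replace = TRUE)
    st <- count_stats(x)
    expect_gte(st[["threshold"]], st[["median"]])
    if (length(unique(x)) > 1) expect_gt(st[["threshold"]], st[["median"]])
    else expect_equal(st[["threshold"]], st[["median"]])
  }
  # the multiplier k scales the margin
  x <- c(1, 1, 1, 2)
  expect_equal(count_stats(x, k = 2)[["threshold"]],
               count_stats(x)[["median"]] + 2 * count_stats(x)[["stdev"]])
})

test_that("ubiquity and single-copy frequency are the stated fractions", {
  expect_equal(ubiquity(c(1, 2, 0, 1, 1, 0, 1, 1, 1, 1)), 0.8)
  expect_equal(ubiquity(rep(0, 5)), 0)
  expect_equal(ubiquity(c(1, 3, 2)), 1)
  expect_equal(single_copy_freq(c(1, 1, 2, 1)), 0.75)
  expect_equal(single_copy_freq(c(2, 2, 2)), 0)
  expect_error(ubiquity(integer()), "no reference")
  expect_error(single_copy_freq(integer()), "no reference")
  set.seed(8)
  for (i in 1:20) {
    x <- sample(0:3, 12, replace = TRUE)
    expect_equal(single_copy_freq(x), sum(x == 1) / 12)
    expect_true(ubiquity(x) >= 0 && ubiquity(x) <= 1)
    expect_true(single_copy_freq(x) >= 0 && single_copy_freq(x) <= 1)
  }
})

test_that("default mode removes excluded classes; exploration keeps everything", {
  models <- data.frame(
    model_id = c("mQ", "mK", "mJ", "mQJ", "mUnk", "mP"),
    function_class = c("Q", "K", "J", "QJ", "9", "P"),
    stringsAsFactors = FALSE)
  def <- classify_and_filter(models, "default")
  expect_setequal(def$model_id, c("mJ", "mUnk"))  # unknown retained, warned
  exp <- classify_and_filter(models, "exploration")
  expect_identical(exp, models)  # exploration is the identity
  # default output is always a subset of the input
  expect_true(all(def$model_id %in% models$model_id))
  # custom excluded set
  only_k <- classify_and_filter(models, "default", excluded = "K")
  expect_setequal(only_k$model_id, c("mQ", "mJ", "mQJ", "mUnk", "mP"))
})

make_stub_genomes <- function(counts_by_model, cds_by_model = NULL) {
  # counts_by_model: named list model -> integer vector (one per genome)
  n_genomes <- length(counts_by_model[[1]])
  genomes <- list()
  ortho <- data.frame(ortholog_group_id = character(), genome_id = character(),
                      gene_id = character(), stringsAsFactors = FALSE)
  for (gi in seq_len(n_genomes)) {
    gid <- paste0("g", gi)
    genes <- data.frame(gene_id = character(), contig_id = character(),
                        start = integer(), end = integer(), strand = character(),
                        protein_seq = character(), cds_seq = character(),
                        stringsAsFactors = FALSE)
    pos <- 0L
    for (m in names(counts_by_model)) {
      for (k in seq_len(counts_by_model[[m]][gi])) {
        gene <- sprintf("%s_%s_%d", gid, m, k)
        cds <- if (!is.null(cds_by_model)) cds_by_model[[m]][[gi]] else "ATGAAA"
        genes[nrow(genes) + 1L, ] <- list(gene, "c1", pos, pos + nchar(cds),
                                          "+", "MK", cds)
        pos <- pos + nchar(cds) + 10L
        ortho[nrow(ortho) + 1L, ] <- list(m, gid, gene)
      }
    }
    genomes[[gid]] <- genome_record(gid, genes = genes, contigs = c(c1 = 100000L))
  }
  list(genomes = unname(genomes), orthologs = ortho)
}

test_that("build_refset populates one model per group with all statistics", {
  st <- make_stub_genomes(list(mA = c(1, 1, 1, 1, 1), mB = c(2, 1, 1, 1, 1),
                               mC = c(0, 0, 0, 0, 0)))
  empty_hmms <- tempfile(); dir.create(empty_hmms)
  rs <- build_refset(st$genomes, st$orthologs, name = "stub",
                     hmm_dir = empty_hmms, dnds = FALSE)
  expect_s3_class(rs, "reference_set")
  expect_equal(rs$n_reference_genomes, 5L)
  expect_setequal(rs$models$model_id, c("mA", "mB"))  # mC has no rows at all
  a <- rs$models[rs$models$model_id == "mA", ]
  expect_equal(a$duplication_threshold, 1)
  expect_equal(a$ubiquity, 1)
  expect_equal(a$single_copy_freq, 1)
  # planted duplication in 1 of 5 genomes: threshold strictly in (1, 2)
  b <- rs$models[rs$models$model_id == "mB", ]
  expect_gt(b$duplication_threshold, 1)
  expect_lt(b$duplication_threshold, 2)
  expect_equal(b$single_copy_freq, 0.8)
})

test_that("a group with rows in some genomes counts zeros for the others", {
  st <- make_stub_genomes(list(mA = c(1, 0, 0, 0)))
  empty_hmms <- tempfile(); dir.create(empty_hmms)
  rs <- build_refset(st$genomes, st$orthologs, hmm_dir = empty_hmms, dnds = FALSE)
  a <- rs$models[rs$models$model_id == "mA", ]
  expect_equal(a$ubiquity, 0.25)
  expect_equal(a$count_median, 0)
  expect_equal(a$duplication_threshold, 0 + a$count_stdev)
})

test_that("build_refset rejects ortholog rows for unsupplied genomes", {
  st <- make_stub_genomes(list(mA = c(1, 1)))
  st$orthologs[nrow(st$orthologs) + 1L, ] <- list("mA", "ghost", "ghost_g1")
  expect_error(build_refset(st$genomes, st$orthologs, hmm_dir = tempdir(),
                            dnds = FALSE),
               "ghost")
})

test_that("build_refset is deterministic and fills dN/dS from member CDS", {
  set.seed(13)
  cds1 <- random_sense_cds(30)
  co <- substring(cds1, seq(1, nchar(cds1), 3), seq(3, nchar(cds1), 3))
  co[5] <- "GGA"; co[6] <- "GGG"
  cds2 <- paste(co, collapse = "")
  st <- make_stub_genomes(list(mA = c(1, 1)),
                          cds_by_model = list(mA = list(cds1, cds2)))
  empty_hmms <- tempfile(); dir.create(empty_hmms)
  rs1 <- build_refset(st$genomes, st$orthologs, hmm_dir = empty_hmms)
  rs2 <- build_refset(st$genomes, st$orthologs, hmm_dir = empty_hmms)
  expect_identical(rs1$models, rs2$models)
  expected <- pairwise_dnds(cds1, cds2)
  if (expected$status == "ok")
    expect_equal(rs1$models$dnds_median[1], expected$omega)
  else
    expect_true(is.na(rs1$models$dnds_median[1]))
})

test_that("annotation classes flow into the models and the mode filter", {
  sc <- shared_collection()
  rs <- sc$refset
  expect_equal(nrow(rs$models), 10L)
  expect_equal(rs$n_reference_genomes, 5L)
  expect_false(any(is.na(rs$models$function_class)))
  expect_true(all(rs$models$duplication_threshold == 1))  # refs single copy
  expect_true(all(rs$models$ubiquity == 1))
  expect_true(all(!is.na(rs$models$hmm_path)))
  # neutral mutation process: per-model dN/dS defined for diverged families
  expect_true(all(is.finite(rs$models$dnds_median)))
})

test_that("reference-set bundles round-trip through the directory format", {
  sc <- shared_collection()
  dir <- tempfile("bundle_")
  write_refset(sc$refset, dir)
  expect_true(file.exists(file.path(dir, "models.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(dir.exists(file.path(dir, "hmms")))
  back <- read_refset(dir)
  expect_equal(back$name, sc$refset$name)
  expect_equal(back$n_reference_genomes, sc$refset$n_reference_genomes)
  m1 <- sc$refset$models[order(sc$refset$models$model_id), ]
  m2 <- back$models
  expect_equal(m2$model_id, m1$model_id)
  expect_equal(m2$duplication_threshold, m1$duplication_threshold)
  expect_equal(m2$dnds_median, m1$dnds_median, tolerance = 1e-9)
  expect_true(all(file.exists(m2$hmm_path)))
  expect_error(read_refset(tempfile()), "not found")
})
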