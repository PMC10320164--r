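# Screening criteria: gene duplication (D), BGC proximity (B), known
# resistance model (R); per-genome result assembly and multi-genome
# aggregation.

#' Duplication flag for one model
#'
#' A core-gene model is flagged as duplicated when the query genome's copy
#' number strictly exceeds the model's duplication threshold
#' (`median + k * stdev` over the reference genomes). The inequality is
#' strict: `copy_number == threshold` is not a duplication.
#'
#' @param copy_number non-negative integer.
#' @param threshold numeric duplication threshold (or a models row / list
#'   with a `duplication_threshold` field).
#' @return logical.
#' @export
flag_duplication <- function(copy_number, threshold) {
  if (is.list(threshold) || is.data.frame(threshold))
    threshold <- threshold$duplication_threshold
  stopifnot(copy_number >= 0, is.finite(threshold))
  copy_number > threshold
}

#' Gene/BGC proximity pairs by interval intersection
#'
#' A (gene, cluster) pair is emitted when the hit gene and the BGC share a
#' contig and their half-open intervals overlap by at least one base
#' (containment is not required; a half-open "touch" where `gene.end ==
#' bgc.start` is not an overlap). A gene overlapping two BGCs yields two
#' pairs. Overlap is computed with GenomicRanges.
#'
#' @param hits data.frame with a `gene_id` column (e.g. HMM hits), or a
#'   character vector of gene ids.
#' @param genome a [genome_record()] supplying gene locations and BGCs.
#' @return data.frame `gene_id`, `cluster_id`, sorted by (gene_id,
#'   cluster_id), possibly empty.
#' @export
proximity_pairs <- function(hits, genome) {
  gene_ids <- if (is.data.frame(hits)) unique(hits$gene_id) else unique(hits)
  empty <- data.frame(gene_id = character(), cluster_id = character(),
                      stringsAsFactors = FALSE)
  genes <- genome$genes[genome$genes$gene_id %in% gene_ids, , drop = FALSE]
  bgcs <- genome$bgcs
  if (nrow(genes) == 0L || nrow(bgcs) == 0L) return(empty)
  # 0-based half-open -> 1-based closed for IRanges
  gr_genes <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  gr_bgcs <- GenomicRanges::GRanges(
    seqnames = bgcs$contig_id,
    ranges = IRanges::IRanges(start = bgcs$start + 1L, end = bgcs$end))
  ov <- GenomicRanges::findOverlaps(gr_genes, gr_bgcs, minoverlap = 1L)
  if (length(ov) == 0L) return(empty)
  out <- data.frame(gene_id = genes$gene_id[S4Vectors::queryHits(ov)],
                    cluster_id = bgcs$cluster_id[S4Vectors::subjectHits(ov)],
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$gene_id, out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen one query genome against a reference set
#'
#' Combines per-model core-gene hit sets ([detect_core_genes()]) and
#' auxiliary hits ([detect_auxiliary()]) into a screening result: one row
#' per model with at least one hit, carrying copy number, the duplication
#' flag D (strict `copy_number > threshold`), the BGC-proximity flag B (any
#' hit gene overlapping a BGC), and the resistance-model flag R (the model is
#' a known resistance factor); per-BGC hit counts; and genome totals. Rows
#' are sorted by (number of true flags desc, copy_number desc, model_id asc).
#'
#' @param genome a [genome_record()].
#' @param refset a `reference_set`.
#' @param core_hits result of [detect_core_genes()].
#' @param aux_hits result of [detect_auxiliary()] (optional).
#' @param mode search mode used (recorded; filtering already happened in
#'   detection).
#' @param duplication_k when not `NULL`, thresholds are recomputed as
#'   `count_median + duplication_k * count_stdev` instead of the reference
#'   set's stored threshold.
#' @param suppress_duplication set for BGC-only inputs where genome-wide copy
#'   numbers are meaningless: D is reported `NA` for every row.
#' @return object of class `screening_result`: list with `genome_id`, `mode`,
#'   `rows` (data.frame), `proximity` (data.frame model_id, gene_id,
#'   cluster_id), `bgc_summary` (data.frame), `totals` (list).
#' @export
screen_genome <- function(genome, refset, core_hits, aux_hits = NULL,
                          mode = "default", duplication_k = NULL,
                          suppress_duplication = FALSE) {
  models <- refset$models
  midx <- setNames(seq_len(nrow(models)), models$model_id)
  thresholds <- models$duplication_threshold
  if (!is.null(duplication_k))
    thresholds <- models$count_median + duplication_k * models$count_stdev

  rows <- data.frame(model_id = character(), category = character(),
                     copy_number = integer(), duplication_threshold = numeric(),
                     duplication = logical(), proximity = logical(),
                     resistance_model = logical(), n_proximity_pairs = integer(),
                     proximity_pairs = character(), function_class = character(),
                     dnds_median = numeric(), ubiquity = numeric(),
                     single_copy_freq = numeric(), stringsAsFactors = FALSE)
  prox_all <- data.frame(model_id = character(), gene_id = character(),
                         cluster_id = character(), stringsAsFactors = FALSE)
  core_gene_ids <- character()

  add_row <- function(model_id, category, hits_df, copy_number, threshold,
                      fclass, dnds_med, ubiq, scf) {
    pp <- proximity_pairs(hits_df, genome)
    dup <- if (suppress_duplication || is.na(threshold)) NA
           else flag_duplication(copy_number, threshold)
    if (category != "core") dup <- if (suppress_duplication) NA else FALSE
    list(row = data.frame(
           model_id = model_id, category = category,
           copy_number = copy_number, duplication_threshold = threshold,
           duplication = dup, proximity = nrow(pp) > 0L,
           resistance_model = category == "resistance",
           n_proximity_pairs = nrow(pp),
           proximity_pairs = paste(sprintf("%s:%s", pp$gene_id, pp$cluster_id),
                                   collapse = ","),
           function_class = fclass, dnds_median = dnds_med,
           ubiquity = ubiq, single_copy_freq = scf,
           stringsAsFactors = FALSE),
         pairs = pp)
  }

  for (m in names(core_hits)) {
    hs <- core_hits[[m]]
    i <- midx[[m]]
    r <- add_row(m, "core", hs$hits, hs$copy_number, thresholds[i],
                 models$function_class[i], models$dnds_median[i],
                 models$ubiquity[i], models$single_copy_freq[i])
    rows <- rbind(rows, r$row)
    if (nrow(r$pairs))
      prox_all <- rbind(prox_all, cbind(model_id = m, r$pairs))
    core_gene_ids <- union(core_gene_ids, unique(hs$hits$gene_id))
  }

  res_gene_ids <- character()
  if (!is.null(aux_hits) && nrow(aux_hits)) {
    for (m in unique(aux_hits$model_id)) {
      h <- aux_hits[aux_hits$model_id == m, , drop = FALSE]
      cat <- h$category[1]
      r <- add_row(m, cat, h, length(unique(h$gene_id)), NA_real_,
                   NA_character_, NA_real_, NA_real_, NA_real_)
      rows <- rbind(rows, r$row)
      if (nrow(r$pairs))
        prox_all <- rbind(prox_all, cbind(model_id = m, r$pairs))
      if (cat == "resistance") res_gene_ids <- union(res_gene_ids, unique(h$gene_id))
    }
  }

  # per-BGC summary: distinct core-hit and resistance-hit genes per cluster
  bgcs <- genome$bgcs
  bgc_summary <- data.frame(cluster_id = character(), contig_id = character(),
                            start = integer(), end = integer(),
                            product_class = character(),
                            n_core_hits = integer(), n_resistance_hits = integer(),
                            stringsAsFactors = FALSE)
  if (nrow(bgcs)) {
    core_pp <- proximity_pairs(core_gene_ids, genome)
    res_pp <- proximity_pairs(res_gene_ids, genome)
    for (i in seq_len(nrow(bgcs))) {
      cid <- bgcs$cluster_id[i]
      bgc_summary[nrow(bgc_summary) + 1L, ] <- list(
        cid, bgcs$contig_id[i], bgcs$start[i], bgcs$end[i],
        bgcs$product_class[i],
        length(unique(core_pp$gene_id[core_pp$cluster_id == cid])),
        length(unique(res_pp$gene_id[res_pp$cluster_id == cid])))
    }
  }

  nflags <- rowSums(cbind(rows$duplication %in% TRUE,
                          rows$proximity %in% TRUE,
                          rows$resistance_model %in% TRUE))
  ord <- order(-nflags, -rows$copy_number, rows$model_id)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  if (nrow(prox_all)) {
    prox_all <- prox_all[order(prox_all$model_id, prox_all$gene_id,
                               prox_all$cluster_id), , drop = FALSE]
    rownames(prox_all) <- NULL
  }

  totals <- list(
    n_bgcs = nrow(bgcs),
    n_bgcs_with_core_hit = sum(bgc_summary$n_core_hits > 0L),
    n_bgcs_with_res_hit = sum(bgc_summary$n_resistance_hits > 0L),
    n_core_genes_found = length(core_gene_ids),
    n_genes_total = nrow(genome$genes),
    n_models_hit = sum(rows$category == "core"),
    n_models_duplicated = sum(rows$duplication %in% TRUE & rows$category == "core"),
    n_models_proximal = sum(rows$proximity %in% TRUE & rows$category == "core"),
    n_genes_duplicated_models = sum(rows$copy_number[rows$duplication %in% TRUE &
                                                       rows$category == "core"]))

  structure(list(genome_id = genome$genome_id, mode = mode, rows = rows,
                 proximity = prox_all, bgc_summary = bgc_summary,
                 totals = totals,
                 suppress_duplication = suppress_duplication),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  t <- x$totals
  cat("screening_result '", x$genome_id, "' (", x$mode, " mode)\n", sep = "")
  cat("  models hit: ", t$n_models_hit, " (duplicated ", t$n_models_duplicated,
      ", BGC-proximal ", t$n_models_proximal, ")\n", sep = "")
  cat("  BGCs: ", t$n_bgcs, " total, ", t$n_bgcs_with_core_hit, " with core hit, ",
      t$n_bgcs_with_res_hit, " with resistance hit\n", sep = "")
  cat("  genes: ", t$n_core_genes_found, " core of ", t$n_genes_total, " total\n",
      sep = "")
  invisible(x)
}

#' Recompute a screening result's totals from its rows (self-consistency)
#' @noRd
recompute_totals <- function(result) {
  rows <- result$rows
  core <- rows[rows$category == "core", , drop = FALSE]
  core_genes <- unique(unlist(lapply(
    strsplit(core$proximity_pairs[nzchar(core$proximity_pairs)], ","),
    function(x) sub(":.*$", "", x))))
  list(n_bgcs = nrow(result$bgc_summary),
       n_bgcs_with_core_hit = sum(result$bgc_summary$n_core_hits > 0L),
       n_bgcs_with_res_hit = sum(result$bgc_summary$n_resistance_hits > 0L),
       n_models_hit = nrow(core),
       n_models_duplicated = sum(core$duplication %in% TRUE),
       n_models_proximal = sum(core$proximity %in% TRUE))
}

#' Aggregate screening results across genomes
#'
#' Per model, the hit frequency is the number of genomes with at least one
#' hit for that model divided by the total number of (successful) runs, so
#' every frequency lies in `[0, 1]`. A model with no hit in any genome is
#' absent from the table rather than reported as a zero row; a model absent
#' from an individual genome still counts that genome in the denominator.
#'
#' @param results list of `screening_result` (>= 2).
#' @return object of class `multi_genome_summary`: list with `models`
#'   (data.frame model_id, category, frequency, n_genomes_hit,
#'   n_genomes_total, genomes), `per_genome` (totals data.frame) and
#'   `n_genomes`.
#' @export
aggregate_multi <- function(results) {
  stopifnot(length(results) >= 2L,
            all(vapply(results, inherits, logical(1), "screening_result")))
  n <- length(results)
  gids <- vapply(results, `[[`, character(1), "genome_id")
  model_rows <- list()
  for (r in results) {
    for (i in seq_len(nrow(r$rows))) {
      m <- r$rows$model_id[i]
      if (is.null(model_rows[[m]]))
        model_rows[[m]] <- list(category = r$rows$category[i], genomes = character())
      model_rows[[m]]$genomes <- c(model_rows[[m]]$genomes, r$genome_id)
    }
  }
  ids <- sort(names(model_rows))
  models <- data.frame(
    model_id = ids,
    category = vapply(ids, function(m) model_rows[[m]]$category, character(1)),
    frequency = vapply(ids, function(m) length(unique(model_rows[[m]]$genomes)) / n,
                       numeric(1)),
    n_genomes_hit = vapply(ids, function(m) length(unique(model_rows[[m]]$genomes)),
                           integer(1)),
    n_genomes_total = n,
    genomes = vapply(ids, function(m)
      paste(sort(unique(model_rows[[m]]$genomes)), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  models <- models[order(-models$frequency, models$model_id), , drop = FALSE]
  rownames(models) <- NULL
  per_genome <- do.call(rbind, lapply(results, function(r)
    data.frame(genome_id = r$genome_id, as.data.frame(r$totals),
               stringsAsFactors = FALSE)))
  rownames(per_genome) <- NULL
  structure(list(models = models, per_genome = per_genome, n_genomes = n,
                 genome_ids = gids),
            class = "multi_genome_summary")
}
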