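# Batch entry points: run configuration, single- and multi-genome runs,
# deterministic TSV outputs, run manifest and a static HTML summary.

#' Run configuration
#'
#' @param refset a `reference_set` object or a bundle directory path.
#' @param mode `"default"` (functional-class filtering on) or
#'   `"exploration"` (all models searched).
#' @param search_resistance,search_duf toggle the auxiliary searches.
#' @param resistance_models,duf_models named vectors model_id -> profile path
#'   (custom models; empty by default).
#' @param custom_core optional named vector of additional core profiles
#'   appended to the reference set (cutoff = profile trusted cutoff or the
#'   bitscore floor).
#' @param duplication_k duplication-threshold multiplier
#'   (threshold = median + k * stdev).
#' @param excluded_classes COG letters removed in default mode.
#' @param bgc_dialect `"antismash_region_gbk"` or `"tsv_table"` for separate
#'   BGC input files.
#' @param bgc_only treat each input as a bare BGC record: the whole record
#'   becomes one region and duplication flags are suppressed (no genome-wide
#'   copy counts exist).
#' @param engine HMM engine ([hmmer_engine()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(refset, mode = c("default", "exploration"),
                       search_resistance = FALSE, search_duf = FALSE,
                       resistance_models = character(), duf_models = character(),
                       custom_core = character(), duplication_k = 1,
                       excluded_classes = default_excluded_classes(),
                       bgc_dialect = c("antismash_region_gbk", "tsv_table"),
                       bgc_only = FALSE, engine = hmmer_engine()) {
  mode <- match.arg(mode)
  bgc_dialect <- match.arg(bgc_dialect)
  if (is.character(refset)) refset <- read_refset(refset)
  stopifnot(inherits(refset, "reference_set"), is.numeric(duplication_k))
  structure(list(refset = refset, mode = mode,
                 search_resistance = isTRUE(search_resistance),
                 search_duf = isTRUE(search_duf),
                 resistance_models = resistance_models,
                 duf_models = duf_models, custom_core = custom_core,
                 duplication_k = duplication_k,
                 excluded_classes = excluded_classes,
                 bgc_dialect = bgc_dialect, bgc_only = isTRUE(bgc_only),
                 engine = engine),
            class = "run_config")
}

#' @noRd
config_echo <- function(config) {
  list(mode = config$mode, refset = config$refset$name,
       search_resistance = config$search_resistance,
       search_duf = config$search_duf,
       duplication_k = config$duplication_k,
       excluded_classes = config$excluded_classes,
       bgc_dialect = config$bgc_dialect, bgc_only = config$bgc_only,
       n_custom_core = length(config$custom_core),
       n_resistance_models = length(config$resistance_models),
       n_duf_models = length(config$duf_models))
}

#' Append custom core profiles to a reference set's model table
#' @noRd
extend_refset <- function(refset, custom_core, floor = 25) {
  if (length(custom_core) == 0L) return(refset)
  ids <- names(custom_core) %||% sub("\\.hmm$", "", basename(custom_core))
  add <- data.frame(model_id = ids, description = "custom core model",
                    function_class = NA_character_, count_median = NA_real_,
                    count_stdev = NA_real_, duplication_threshold = NA_real_,
                    ubiquity = NA_real_, single_copy_freq = NA_real_,
                    dnds_median = NA_real_,
                    bitscore_cutoff = vapply(custom_core, function(p) {
                      tc <- hmm_trusted_cutoff(p); if (is.na(tc)) floor else tc
                    }, numeric(1)),
                    hmm_path = unname(custom_core), stringsAsFactors = FALSE)
  refset$models <- rbind(refset$models, add)
  refset
}

#' Deterministic TSV export of one screening result
#' @noRd
write_result_tables <- function(result, dir) {
  rows <- result$rows
  core <- rows[rows$category == "core", , drop = FALSE]
  write_tsv(rows, file.path(dir, "coregenes.tsv"))
  dup <- core[core$duplication %in% TRUE, , drop = FALSE]
  write_tsv(dup[, c("model_id", "copy_number", "duplication_threshold",
                    "function_class", "dnds_median", "ubiquity",
                    "single_copy_freq")],
            file.path(dir, "duplications.tsv"))
  write_tsv(result$proximity, file.path(dir, "proximity.tsv"))
  write_tsv(result$bgc_summary, file.path(dir, "bgc_summary.tsv"))
  t <- result$totals
  summary <- data.frame(genome_id = result$genome_id, mode = result$mode,
                        n_bgcs = t$n_bgcs,
                        n_bgcs_with_core_hit = t$n_bgcs_with_core_hit,
                        n_bgcs_with_res_hit = t$n_bgcs_with_res_hit,
                        n_core_genes_found = t$n_core_genes_found,
                        n_genes_total = t$n_genes_total,
                        n_models_hit = t$n_models_hit,
                        n_models_duplicated = t$n_models_duplicated,
                        n_models_proximal = t$n_models_proximal,
                        n_genes_duplicated_models = t$n_genes_duplicated_models,
                        stringsAsFactors = FALSE)
  write_tsv(summary, file.path(dir, "summary.tsv"))
  invisible(dir)
}

#' @noRd
html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' @noRd
html_table <- function(df, caption) {
  if (nrow(df) == 0L)
    return(sprintf("<h3>%s</h3>\n<p><em>no rows</em></p>", html_escape(caption)))
  head_row <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                    collapse = ""), "</tr>")
  body <- vapply(seq_len(nrow(df)), function(i)
    paste0("<tr>", paste0("<td>",
                          html_escape(vapply(df[i, , drop = FALSE], function(v)
                            if (is.na(v)) "" else format(v, scientific = FALSE),
                            character(1))),
                          "</td>", collapse = ""), "</tr>"), character(1))
  sprintf("<h3>%s</h3>\n<table border=\"1\" cellspacing=\"0\">%s\n%s</table>",
          html_escape(caption), head_row, paste(body, collapse = "\n"))
}

#' @noRd
render_report_html <- function(result, path, note = NULL) {
  t <- result$totals
  parts <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/><title>screening report</title></head><body>",
    sprintf("<h1>Screening report: %s</h1>", html_escape(result$genome_id)),
    sprintf("<!-- generated %s -->", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    if (!is.null(note)) sprintf("<p><strong>%s</strong></p>", html_escape(note)),
    sprintf(paste0("<p>Mode: %s. Models hit: %d (duplicated %d, BGC-proximal %d). ",
                   "BGCs: %d total, %d with core hit, %d with resistance hit. ",
                   "Genes: %d core of %d total.</p>"),
            html_escape(result$mode), t$n_models_hit, t$n_models_duplicated,
            t$n_models_proximal, t$n_bgcs, t$n_bgcs_with_core_hit,
            t$n_bgcs_with_res_hit, t$n_core_genes_found, t$n_genes_total),
    html_table(result$rows, "Core genes and screening criteria (D/B/R)"),
    html_table(result$proximity, "BGC proximity pairs"),
    html_table(result$bgc_summary, "BGC summary"),
    "</body></html>")
  writeLines(parts[!vapply(parts, is.null, logical(1))], path)
  invisible(path)
}

#' @noRd
screen_one <- function(genome, bgc_path, config) {
  refset <- extend_refset(config$refset, config$custom_core)
  if (!is.null(bgc_path)) {
    bg <- read_bgc_regions(bgc_path, config$bgc_dialect)
    genome$bgcs <- bg
    genome <- genome_record(genome$genome_id, genome$genes, bg, genome$contigs,
                            genome$contig_seq)
  }
  if (config$bgc_only && nrow(genome$bgcs) == 0L) {
    # whole record treated as one region per contig
    genome$bgcs <- bgc_regions(cluster_id = paste0(names(genome$contigs), "_bgc"),
                               contig_id = names(genome$contigs),
                               start = rep(0L, length(genome$contigs)),
                               end = unname(genome$contigs),
                               product_class = rep("", length(genome$contigs)),
                               source = "coordinate_table")
  }
  core_hits <- detect_core_genes(genome, refset, config$mode,
                                 engine = config$engine,
                                 excluded = config$excluded_classes)
  aux_hits <- NULL
  if (config$search_resistance || config$search_duf)
    aux_hits <- detect_auxiliary(genome,
                                 resistance_models = config$resistance_models,
                                 duf_models = config$duf_models,
                                 search_resistance = config$search_resistance,
                                 search_duf = config$search_duf,
                                 engine = config$engine)
  screen_genome(genome, refset, core_hits, aux_hits, mode = config$mode,
                duplication_k = config$duplication_k,
                suppress_duplication = config$bgc_only)
}

#' Run the screening pipeline on a single genome
#'
#' Reads the genome, applies the reference set and screening criteria, and
#' writes into `out_dir`: `manifest.json` (tool and engine versions, config
#' echo, input hashes, status), the five TSV tables (`coregenes.tsv`,
#' `duplications.tsv`, `proximity.tsv`, `bgc_summary.tsv`, `summary.tsv`)
#' and a static `report.html`. TSV output is byte-deterministic for
#' identical inputs and configuration.
#'
#' @param genome_path input genome (GenBank, EMBL, or FASTA with sidecar).
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @param bgc_path optional separate BGC annotation file.
#' @param gene_table sidecar TSV for FASTA input.
#' @param format input format (default auto-detect).
#' @return the `screening_result`, invisibly; outputs in `out_dir`.
#' @export
run_single <- function(genome_path, config, out_dir, bgc_path = NULL,
                       gene_table = NULL, format = "auto") {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(genome_path)) stop("input file not found: ", genome_path)
  genome <- read_genome(genome_path, format = format, gene_table = gene_table)
  result <- screen_one(genome, bgc_path, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_result_tables(result, out_dir)
  note <- if (config$bgc_only)
    "BGC-only input: no genome-wide copy counts; duplication flags suppressed."
  render_report_html(result, file.path(out_dir, "report.html"), note = note)
  manifest <- list(
    tool = "resmine", version = as.character(packageVersion("resmine")),
    engine = config$engine$version,
    config = config_echo(config),
    inputs = list(genome = list(path = genome_path,
                                md5 = unname(tools::md5sum(genome_path))),
                  bgc = if (!is.null(bgc_path))
                    list(path = bgc_path, md5 = unname(tools::md5sum(bgc_path)))),
    genomes = list(list(genome_id = result$genome_id, status = "ok")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(result)
}

#' Run the screening pipeline on multiple genomes
#'
#' Each genome is screened into its own subdirectory (same layout as
#' [run_single()]); results are then aggregated with [aggregate_multi()]
#' into `multi_summary.tsv` (per-model hit frequency in `[0, 1]`) and
#' `multi_genomes.tsv` (per-genome totals). A genome that fails to parse or
#' screen does not abort the run: the failure is recorded in the manifest
#' and the frequency denominator is the number of successful runs. With
#' `bigscape_input = TRUE` the per-genome BGC regions are exported as
#' GenBank files under `bigscape_input/` ready for an external gene-cluster
#' -family networking tool (which is never invoked here).
#'
#' @param genome_paths character vector (>= 2) of input files.
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @param bigscape_input also write per-BGC region GenBank files.
#' @return the `multi_genome_summary`, invisibly.
#' @export
run_multi <- function(genome_paths, config, out_dir, bigscape_input = FALSE) {
  stopifnot(inherits(config, "run_config"), length(genome_paths) >= 2L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  statuses <- list()
  results <- list()
  for (i in seq_along(genome_paths)) {
    p <- genome_paths[i]
    sub <- file.path(out_dir, sprintf("genome_%02d_%s", i,
                                      sub("\\.[^.]*$", "", basename(p))))
    r <- tryCatch(run_single(p, config, sub),
                  error = function(e) e)
    if (inherits(r, "error")) {
      rm_log("genome ", basename(p), " failed: ", conditionMessage(r))
      statuses[[i]] <- list(path = p, status = "failed",
                            error = conditionMessage(r))
    } else {
      statuses[[i]] <- list(path = p, status = "ok", genome_id = r$genome_id,
                            dir = basename(sub))
      results[[length(results) + 1L]] <- r
    }
  }
  if (length(results) < 1L) stop("all genomes failed; nothing to aggregate")
  summary <- NULL
  if (length(results) >= 2L) {
    summary <- aggregate_multi(results)
    write_tsv(summary$models, file.path(out_dir, "multi_summary.tsv"))
    write_tsv(summary$per_genome, file.path(out_dir, "multi_genomes.tsv"))
  }
  if (bigscape_input) {
    bdir <- file.path(out_dir, "bigscape_input")
    dir.create(bdir, showWarnings = FALSE)
    for (i in seq_along(genome_paths)) {
      if (statuses[[i]]$status != "ok") next
      g <- tryCatch(read_genome(genome_paths[i]), error = function(e) NULL)
      if (is.null(g) || is.null(g$contig_seq)) next
      for (j in seq_len(nrow(g$bgcs))) {
        reg <- g$bgcs[j, ]
        sel <- g$genes$contig_id == reg$contig_id &
          g$genes$start < reg$end & g$genes$end > reg$start
        genes <- g$genes[sel, , drop = FALSE]
        genes$start <- pmax(genes$start - reg$start, 0L)
        genes$end <- pmin(genes$end - reg$start, reg$end - reg$start)
        slice_seq <- substr(g$contig_seq[[reg$contig_id]], reg$start + 1L, reg$end)
        slice <- genome_record(paste0(g$genome_id, "_", reg$cluster_id),
                               genes = validate_gene_table(genes),
                               bgcs = bgc_regions(reg$cluster_id, reg$contig_id,
                                                  0L, reg$end - reg$start,
                                                  reg$product_class, reg$source),
                               contigs = setNames(reg$end - reg$start, reg$contig_id),
                               contig_seq = setNames(slice_seq, reg$contig_id))
        write_genome_genbank(slice, file.path(bdir, paste0(slice$genome_id, ".gbk")))
      }
    }
  }
  manifest <- list(
    tool = "resmine", version = as.character(packageVersion("resmine")),
    engine = config$engine$version, config = config_echo(config),
    n_inputs = length(genome_paths), n_successful = length(results),
    genomes = statuses)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary %||% results[[1]])
}
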