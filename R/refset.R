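# Reference-set construction: per-model duplication thresholds, ubiquity,
# single-copy frequency, functional class and median pairwise dN/dS, built
# from a genome collection plus an ortholog-assignment table.

#' Shipped default excluded COG categories for default-mode filtering
#'
#' Q (secondary metabolite biosynthesis, transport and catabolism),
#' K (transcription / regulation), and the transporter-annotated classes
#' P (inorganic ion transport) and U (intracellular trafficking and
#' secretion). Default-mode screening removes core-gene models whose
#' functional class intersects this set, to reduce false-positive targets
#' that are more likely biosynthetic or regulatory than resistant; the set
#' is configurable everywhere it is consumed.
#'
#' @return character vector of COG category letters.
#' @export
default_excluded_classes <- function() c("Q", "K", "P", "U")

#' Median, population standard deviation and duplication threshold of
#' per-genome ortholog counts
#'
#' The duplication threshold for a core-gene model is
#' `median + k * stdev` of its copy counts across the reference genomes
#' (zeros included: a genome lacking the gene contributes count 0). The
#' standard deviation is the population form (divide by n).
#'
#' @param counts non-empty integer vector, one entry per reference genome.
#' @param k threshold multiplier (default 1).
#' @return named numeric vector `c(median =, stdev =, threshold =)`.
#' @examples
#' count_stats(c(1, 1, 1, 1, 2, 1, 1))
#' @export
count_stats <- function(counts, k = 1) {
  if (length(counts) == 0L) stop("model has no reference observations")
  stopifnot(is.numeric(counts), all(counts >= 0))
  m <- median(counts)
  s <- pop_sd(counts)
  c(median = m, stdev = s, threshold = m + k * s)
}

#' Ubiquity: fraction of reference genomes carrying at least one copy
#'
#' @param counts_per_genome integer vector, one entry per reference genome.
#' @return numeric in `[0, 1]`.
#' @export
ubiquity <- function(counts_per_genome) {
  if (length(counts_per_genome) == 0L) stop("model has no reference observations")
  mean(counts_per_genome >= 1)
}

#' Single-copy frequency: fraction of reference genomes with exactly one copy
#'
#' @param counts_per_genome integer vector, one entry per reference genome.
#' @return numeric in `[0, 1]`.
#' @export
single_copy_freq <- function(counts_per_genome) {
  if (length(counts_per_genome) == 0L) stop("model has no reference observations")
  mean(counts_per_genome == 1)
}

#' Filter core-gene models by functional class and search mode
#'
#' `exploration` mode is the identity (all models searched). `default` mode
#' removes models whose functional class (one or more COG category letters)
#' intersects the excluded set, dropping regulatory, transport and
#' biosynthetic functions that are unlikely resistance targets. Models with
#' an unrecognized class letter are retained with a logged warning.
#'
#' @param models a models data.frame (see [build_refset()]) with a
#'   `function_class` column, or a `reference_set`.
#' @param mode `"default"` or `"exploration"`.
#' @param excluded character vector of excluded COG letters.
#' @return the filtered models data.frame (same columns).
#' @export
classify_and_filter <- function(models, mode = c("default", "exploration"),
                                excluded = default_excluded_classes()) {
  mode <- match.arg(mode)
  if (inherits(models, "reference_set")) models <- models$models
  stopifnot(is.data.frame(models), "function_class" %in% names(models))
  if (mode == "exploration") return(models)
  classes <- strsplit(ifelse(is.na(models$function_class), "",
                             models$function_class), "")
  known <- c(LETTERS, "")
  unknown <- vapply(classes, function(cl) any(!cl %in% known), logical(1))
  if (any(unknown))
    rm_log("unknown function class letter(s) in model(s): ",
           paste(models$model_id[unknown], collapse = ", "), " (retained)")
  drop <- vapply(classes, function(cl) any(cl %in% excluded), logical(1))
  out <- models[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an ortholog-assignment table
#'
#' TSV with columns `ortholog_group_id`, `genome_id`, `gene_id`: one row per
#' member gene; absence of a group from a genome is simply the absence of
#' rows.
#'
#' @param path TSV file.
#' @return data.frame of class `ortholog_table`.
#' @export
read_ortholog_table <- function(path) {
  tab <- read_tsv(path, colClasses = "character")
  need <- c("ortholog_group_id", "genome_id", "gene_id")
  if (!all(need %in% names(tab)))
    stop("ortholog table must have columns: ", paste(need, collapse = ", "))
  class(tab) <- c("ortholog_table", "data.frame")
  tab
}

#' Per-genome copy counts for one ortholog group
#' @noRd
group_counts <- function(orthologs, group_id, roster) {
  sub <- orthologs[orthologs$ortholog_group_id == group_id, , drop = FALSE]
  cnt <- table(factor(sub$genome_id, levels = roster))
  as.integer(cnt)
}

#' Build a reference set from a genome collection and an ortholog table
#'
#' For every ortholog group the builder computes copy counts across the
#' reference genomes (count 0 where absent), the duplication threshold
#' `median + k * stdev` ([count_stats()]), [ubiquity()], [single_copy_freq()],
#' and the median pairwise Nei-Gojobori dN/dS over member coding sequences
#' ([model_dnds_median()]; `NA` when fewer than two members carry a usable
#' CDS). Functional classes and descriptions come from the optional
#' `annotations` table; profile HMMs are either supplied per model (already
#' built) or built from the member proteins with the injected HMM engine.
#'
#' @param genomes list of [genome_record()] covering the table's roster.
#' @param orthologs an `ortholog_table` (or data.frame with its columns).
#' @param name reference-set name (e.g. `"ascomycota"`).
#' @param annotations optional data.frame `model_id`, `function_class`,
#'   `description`.
#' @param hmm_dir optional directory of pre-built `<model_id>.hmm` profiles;
#'   when `NULL`, profiles are built from member proteins via `engine`.
#' @param engine HMM engine from [hmmer_engine()] (used only when profiles
#'   must be built).
#' @param k duplication-threshold multiplier.
#' @param bitscore_floor default per-model bitscore cutoff when the profile
#'   carries no trusted cutoff.
#' @param dnds compute per-model median dN/dS (set `FALSE` to skip).
#' @return object of class `reference_set`: list with `name`, `models`
#'   (data.frame: model_id, description, function_class, count_median,
#'   count_stdev, duplication_threshold, ubiquity, single_copy_freq,
#'   dnds_median, bitscore_cutoff, hmm_path), `n_reference_genomes`,
#'   `mode_filter`.
#' @export
build_refset <- function(genomes, orthologs, name = "refset",
                         annotations = NULL, hmm_dir = NULL,
                         engine = hmmer_engine(), k = 1,
                         bitscore_floor = 25, dnds = TRUE) {
  stopifnot(length(genomes) >= 1L)
  roster <- vapply(genomes, function(g) g$genome_id, character(1))
  orthologs <- as.data.frame(orthologs)
  missing <- setdiff(unique(orthologs$genome_id), roster)
  if (length(missing))
    stop("genome(s) in ortholog table but not supplied: ",
         paste(missing, collapse = ", "))
  gene_lookup <- list()
  for (g in genomes) gene_lookup[[g$genome_id]] <-
    setNames(g$genes$cds_seq, g$genes$gene_id)
  prot_lookup <- list()
  for (g in genomes) prot_lookup[[g$genome_id]] <-
    setNames(g$genes$protein_seq, g$genes$gene_id)
  groups <- sort(unique(orthologs$ortholog_group_id))
  n <- length(groups)
  models <- data.frame(model_id = groups, description = NA_character_,
                       function_class = NA_character_,
                       count_median = NA_real_, count_stdev = NA_real_,
                       duplication_threshold = NA_real_,
                       ubiquity = NA_real_, single_copy_freq = NA_real_,
                       dnds_median = NA_real_, bitscore_cutoff = bitscore_floor,
                       hmm_path = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    idx <- match(models$model_id, annotations$model_id)
    models$function_class <- as.character(annotations$function_class[idx])
    if ("description" %in% names(annotations))
      models$description <- as.character(annotations$description[idx])
  }
  build_dir <- NULL
  for (i in seq_len(n)) {
    gid <- groups[i]
    counts <- group_counts(orthologs, gid, roster)
    st <- count_stats(counts, k = k)
    models$count_median[i] <- st[["median"]]
    models$count_stdev[i] <- st[["stdev"]]
    models$duplication_threshold[i] <- st[["threshold"]]
    models$ubiquity[i] <- ubiquity(counts)
    models$single_copy_freq[i] <- single_copy_freq(counts)
    sub <- orthologs[orthologs$ortholog_group_id == gid, , drop = FALSE]
    if (dnds) {
      cds <- vapply(seq_len(nrow(sub)), function(r) {
        lk <- gene_lookup[[sub$genome_id[r]]]
        if (is.null(lk)) NA_character_ else unname(lk[sub$gene_id[r]])
      }, character(1))
      cds <- cds[!is.na(cds)]
      if (length(cds) >= 2L && length(unique(nchar(cds))) == 1L)
        models$dnds_median[i] <- model_dnds_median(cds)
    }
    if (!is.null(hmm_dir)) {
      p <- file.path(hmm_dir, paste0(gid, ".hmm"))
      if (file.exists(p)) models$hmm_path[i] <- p
    } else {
      prots <- vapply(seq_len(nrow(sub)), function(r) {
        lk <- prot_lookup[[sub$genome_id[r]]]
        if (is.null(lk)) NA_character_ else unname(lk[sub$gene_id[r]])
      }, character(1))
      prots <- prots[!is.na(prots)]
      if (length(prots) >= 1L) {
        if (is.null(build_dir)) {
          build_dir <- tempfile("refset_hmms_")
          dir.create(build_dir)
        }
        models$hmm_path[i] <- engine$build(prots, gid,
                                           file.path(build_dir, paste0(gid, ".hmm")))
      }
    }
    tc <- if (!is.na(models$hmm_path[i])) hmm_trusted_cutoff(models$hmm_path[i]) else NA_real_
    if (!is.na(tc)) models$bitscore_cutoff[i] <- tc
  }
  structure(list(name = name, models = models,
                 n_reference_genomes = length(roster),
                 mode_filter = default_excluded_classes(),
                 engine_version = engine$version),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set '", x$name, "': ", nrow(x$models), " model(s) from ",
      x$n_reference_genomes, " reference genome(s)\n", sep = "")
  invisible(x)
}

#' Write a reference set as an inspectable bundle directory
#'
#' Layout: `models.tsv` (all per-model metadata), `hmms/<model_id>.hmm`
#' (profile copies) and `manifest.json` (name, genome count, mode filter,
#' content hash, package version).
#'
#' @param refset a `reference_set`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_refset <- function(refset, dir) {
  stopifnot(inherits(refset, "reference_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hmm_dir <- file.path(dir, "hmms")
  dir.create(hmm_dir, showWarnings = FALSE)
  models <- refset$models
  for (i in seq_len(nrow(models))) {
    if (!is.na(models$hmm_path[i]) && file.exists(models$hmm_path[i])) {
      dest <- file.path(hmm_dir, paste0(models$model_id[i], ".hmm"))
      if (normalizePath(models$hmm_path[i]) != suppressWarnings(normalizePath(dest, mustWork = FALSE)))
        file.copy(models$hmm_path[i], dest, overwrite = TRUE)
      models$hmm_path[i] <- file.path("hmms", paste0(models$model_id[i], ".hmm"))
    }
  }
  models <- models[order(models$model_id), , drop = FALSE]
  write_tsv(models, file.path(dir, "models.tsv"))
  manifest <- list(name = refset$name,
                   n_reference_genomes = refset$n_reference_genomes,
                   mode_filter = refset$mode_filter,
                   engine_version = refset$engine_version %||% NA,
                   package_version = as.character(packageVersion("resmine")),
                   models_hash = unname(tools::md5sum(file.path(dir, "models.tsv"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a reference-set bundle written by [write_refset()]
#'
#' @param dir bundle directory.
#' @return a `reference_set` with `hmm_path` resolved to absolute paths.
#' @export
read_refset <- function(dir) {
  if (!dir.exists(dir)) stop("reference set not found: ", dir)
  mpath <- file.path(dir, "models.tsv")
  if (!file.exists(mpath)) stop("not a reference-set bundle (no models.tsv): ", dir)
  models <- read_tsv(mpath)
  models$model_id <- as.character(models$model_id)
  for (col in c("description", "function_class", "hmm_path"))
    models[[col]] <- as.character(models[[col]])
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  has <- !is.na(models$hmm_path)
  models$hmm_path[has] <- file.path(normalizePath(dir), models$hmm_path[has])
  structure(list(name = manifest$name, models = models,
                 n_reference_genomes = manifest$n_reference_genomes,
                 mode_filter = unlist(manifest$mode_filter),
                 engine_version = manifest$engine_version),
            class = "reference_set")
}
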