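# Profile-HMM detection of core genes, known resistance factors and DUF
# domains in query proteomes. The HMM engine is an injected dependency; the
# default implementation shells out to HMMER 3 (hmmbuild / hmmsearch). The
# profile-HMM algorithms themselves are never reimplemented here.

#' HMMER 3 search engine
#'
#' Returns an engine object with three fields: `version` (string recorded in
#' run manifests), `build(proteins, model_name, hmm_path)` which builds a
#' profile from a character vector of member protein sequences (aligned with
#' mafft first when lengths differ), and `search(hmm_paths, proteins)` which
#' searches named profiles against a named protein vector and returns a
#' data.frame `model_id`, `gene_id`, `bitscore`, `evalue` (best full-sequence
#' hit per model/gene pair, so one gene counts at most once per model).
#'
#' @param hmmbuild,hmmsearch,mafft paths to the executables (found on PATH
#'   by default).
#' @return an object of class `hmm_engine`.
#' @export
hmmer_engine <- function(hmmbuild = Sys.which("hmmbuild"),
                         hmmsearch = Sys.which("hmmsearch"),
                         mafft = Sys.which("mafft")) {
  if (!nzchar(hmmbuild) || !nzchar(hmmsearch))
    stop("HMMER executables (hmmbuild/hmmsearch) not found on PATH")
  ver <- tryCatch({
    out <- system2(hmmsearch, "-h", stdout = TRUE)
    ln <- grep("^# HMMER", out, value = TRUE)
    if (length(ln)) sub("^# ", "", ln[1]) else "HMMER (unknown version)"
  }, error = function(e) "HMMER (unknown version)")

  write_fasta <- function(seqs, path) {
    stopifnot(!is.null(names(seqs)))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con, sep = "\n")
    path
  }

  build <- function(proteins, model_name, hmm_path) {
    if (length(proteins) == 0L) stop("no member proteins for model ", model_name)
    names(proteins) <- sprintf("m%03d", seq_along(proteins))
    tmp_fa <- tempfile(fileext = ".fa")
    on.exit(unlink(tmp_fa), add = TRUE)
    write_fasta(proteins, tmp_fa)
    msa <- tmp_fa
    if (length(unique(nchar(proteins))) > 1L) {
      if (!nzchar(mafft)) stop("member proteins unaligned and mafft not available")
      msa <- tempfile(fileext = ".afa")
      on.exit(unlink(msa), add = TRUE)
      system2(mafft, c("--auto", "--quiet", tmp_fa), stdout = msa)
    }
    log <- system2(hmmbuild, c("--amino", "-n", model_name, hmm_path, msa),
                   stdout = TRUE, stderr = TRUE)
    if (!file.exists(hmm_path))
      stop("hmmbuild failed for model ", model_name, ": ",
           paste(tail(log, 3), collapse = " / "))
    hmm_path
  }

  search <- function(hmm_paths, proteins) {
    empty <- data.frame(model_id = character(), gene_id = character(),
                        bitscore = numeric(), evalue = numeric(),
                        stringsAsFactors = FALSE)
    if (length(proteins) == 0L || length(hmm_paths) == 0L) return(empty)
    missing <- hmm_paths[!file.exists(hmm_paths)]
    if (length(missing)) stop("profile HMM file not found: ", missing[1])
    tmp_fa <- tempfile(fileext = ".fa")
    tmp_hmm <- tempfile(fileext = ".hmm")
    tmp_tbl <- tempfile(fileext = ".tbl")
    on.exit(unlink(c(tmp_fa, tmp_hmm, tmp_tbl)), add = TRUE)
    write_fasta(proteins, tmp_fa)
    # concatenate profiles so one hmmsearch call covers all models
    chunks <- unlist(lapply(unique(hmm_paths), readLines), use.names = FALSE)
    writeLines(chunks, tmp_hmm)
    log <- system2(hmmsearch,
                   c("--noali", "--tblout", tmp_tbl, "-E", "1e6",
                     "--cpu", "1", tmp_hmm, tmp_fa),
                   stdout = TRUE, stderr = TRUE)
    if (!file.exists(tmp_tbl))
      stop("hmmsearch failed: ", paste(tail(log, 3), collapse = " / "))
    lines <- readLines(tmp_tbl)
    lines <- lines[!startsWith(lines, "#")]
    if (!length(lines)) return(empty)
    toks <- strsplit(trimws(lines), "[[:space:]]+")
    df <- data.frame(
      model_id = vapply(toks, `[[`, character(1), 3L),
      gene_id = vapply(toks, `[[`, character(1), 1L),
      bitscore = as.numeric(vapply(toks, `[[`, character(1), 6L)),
      evalue = as.numeric(vapply(toks, `[[`, character(1), 5L)),
      stringsAsFactors = FALSE)
    # tblout already reports one line per (profile, sequence); keep best-score
    # line defensively should an engine emit duplicates
    df <- df[order(df$model_id, df$gene_id, -df$bitscore), , drop = FALSE]
    df <- df[!duplicated(df[, c("model_id", "gene_id")]), , drop = FALSE]
    rownames(df) <- NULL
    df
  }

  structure(list(name = "hmmer", version = ver, build = build, search = search),
            class = "hmm_engine")
}

#' Read a profile's trusted-cutoff (TC) bitscore line, if present
#' @noRd
hmm_trusted_cutoff <- function(hmm_path) {
  if (!file.exists(hmm_path)) return(NA_real_)
  hdr <- readLines(hmm_path, n = 30L)
  tc <- grep("^TC\\s", hdr, value = TRUE)
  if (!length(tc)) return(NA_real_)
  suppressWarnings(as.numeric(strsplit(trimws(tc[1]), "[[:space:]]+")[[1]][2]))
}

#' Search profile HMMs against a proteome with per-model score cutoffs
#'
#' Runs the engine once over all profiles and keeps hits with
#' `bitscore >= cutoff` for their model. A gene counts at most once per model
#' (best full-sequence hit).
#'
#' @param proteins named character vector gene_id -> amino-acid sequence.
#' @param hmm_paths named character vector model_id -> profile path.
#' @param cutoffs named numeric vector model_id -> bitscore cutoff; models
#'   without an entry fall back to `default_cutoff`.
#' @param category hit category label (`core`, `resistance`, `duf`, `custom`).
#' @param engine an `hmm_engine`.
#' @param default_cutoff fallback bitscore cutoff.
#' @return data.frame `model_id`, `gene_id`, `bitscore`, `evalue`, `category`,
#'   sorted by model then descending bitscore.
#' @export
search_models <- function(proteins, hmm_paths, cutoffs = numeric(),
                          category = "core", engine = hmmer_engine(),
                          default_cutoff = 25) {
  stopifnot(category %in% c("core", "resistance", "duf", "custom"))
  hits <- engine$search(hmm_paths, proteins)
  if (nrow(hits)) {
    cut <- unname(cutoffs[hits$model_id])
    cut[is.na(cut)] <- default_cutoff
    hits <- hits[hits$bitscore >= cut, , drop = FALSE]
  }
  hits$category <- rep_len(category, nrow(hits))
  hits <- hits[order(hits$model_id, -hits$bitscore, hits$gene_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Group hits into per-model hit sets with copy numbers
#' @noRd
hits_to_hitsets <- function(hits) {
  out <- list()
  for (m in unique(hits$model_id)) {
    h <- hits[hits$model_id == m, , drop = FALSE]
    h <- h[order(-h$bitscore, h$gene_id), , drop = FALSE]
    rownames(h) <- NULL
    out[[m]] <- list(model_id = m, hits = h,
                     copy_number = length(unique(h$gene_id)))
  }
  out
}

#' Detect core genes in a query genome
#'
#' Filters the reference set's models by search mode ([classify_and_filter()];
#' default mode drops excluded functional classes before any search), then
#' searches the remaining profiles against the genome's proteome with each
#' model's bitscore cutoff.
#'
#' @param genome a [genome_record()].
#' @param refset a `reference_set`.
#' @param mode `"default"` or `"exploration"`.
#' @param engine an `hmm_engine`.
#' @param excluded excluded classes for default mode.
#' @return named list model_id -> hit set (`model_id`, `hits` data.frame
#'   sorted by descending bitscore, `copy_number` = distinct genes hit);
#'   models with no qualifying hit are absent.
#' @export
detect_core_genes <- function(genome, refset, mode = c("default", "exploration"),
                              engine = hmmer_engine(),
                              excluded = default_excluded_classes()) {
  mode <- match.arg(mode)
  models <- classify_and_filter(refset$models, mode, excluded)
  models <- models[!is.na(models$hmm_path), , drop = FALSE]
  proteins <- setNames(genome$genes$protein_seq, genome$genes$gene_id)
  proteins <- proteins[!is.na(proteins)]
  if (nrow(models) == 0L || length(proteins) == 0L) return(list())
  hits <- search_models(proteins,
                        setNames(models$hmm_path, models$model_id),
                        setNames(models$bitscore_cutoff, models$model_id),
                        category = "core", engine = engine)
  hits_to_hitsets(hits)
}

#' Detect auxiliary hits: known resistance factors and DUF domains
#'
#' Each category is independently togglable; a disabled category contributes
#' nothing. Profiles are plain HMMER3 files; the per-model cutoff is the
#' profile's trusted cutoff when present, else `default_cutoff`.
#'
#' @param genome a [genome_record()].
#' @param resistance_models,duf_models named character vectors
#'   model_id -> profile path (may be empty).
#' @param search_resistance,search_duf category flags.
#' @param engine an `hmm_engine`.
#' @param default_cutoff fallback bitscore cutoff.
#' @return data.frame of hits (`model_id`, `gene_id`, `bitscore`, `evalue`,
#'   `category` in resistance/duf), possibly empty.
#' @export
detect_auxiliary <- function(genome, resistance_models = character(),
                             duf_models = character(),
                             search_resistance = TRUE, search_duf = TRUE,
                             engine = hmmer_engine(), default_cutoff = 25) {
  proteins <- setNames(genome$genes$protein_seq, genome$genes$gene_id)
  proteins <- proteins[!is.na(proteins)]
  out <- list()
  run_cat <- function(paths, cat) {
    if (length(paths) == 0L || length(proteins) == 0L) return(NULL)
    cuts <- vapply(paths, hmm_trusted_cutoff, numeric(1))
    cuts[is.na(cuts)] <- default_cutoff
    search_models(proteins, paths, setNames(cuts, names(paths)),
                  category = cat, engine = engine,
                  default_cutoff = default_cutoff)
  }
  if (isTRUE(search_resistance)) out$res <- run_cat(resistance_models, "resistance")
  if (isTRUE(search_duf)) out$duf <- run_cat(duf_models, "duf")
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(model_id = character(), gene_id = character(),
                      bitscore = numeric(), evalue = numeric(),
                      category = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
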