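# Genome and BGC I/O. Internal coordinates are 0-based half-open everywhere;
# conversion to/from the 1-based inclusive GenBank/EMBL convention happens
# only at the format boundary.

#' Construct a gene feature table
#'
#' Genes are kept as a data.frame with one row per CDS: `gene_id` (unique
#' within the genome), `contig_id`, `start`/`end` (0-based half-open
#' integers, `start < end`), `strand` (`+`/`-`), `protein_seq` and `cds_seq`
#' (optional, `NA` when absent; `cds_seq` length divisible by 3).
#'
#' @param gene_id,contig_id,start,end,strand,protein_seq,cds_seq vectors of
#'   equal length (protein/cds may be omitted).
#' @return validated data.frame of class `gene_table`.
#' @export
gene_features <- function(gene_id, contig_id, start, end, strand,
                          protein_seq = NA_character_, cds_seq = NA_character_) {
  df <- data.frame(gene_id = as.character(gene_id),
                   contig_id = as.character(contig_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   protein_seq = as.character(protein_seq),
                   cds_seq = as.character(cds_seq),
                   stringsAsFactors = FALSE)
  validate_gene_table(df)
}

#' @noRd
validate_gene_table <- function(df) {
  if (nrow(df)) {
    if (anyDuplicated(df$gene_id))
      stop("duplicate gene_id: ", df$gene_id[duplicated(df$gene_id)][1])
    if (any(df$start < 0L) || any(df$end <= df$start))
      stop("gene intervals must satisfy 0 <= start < end")
    if (!all(df$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    has_cds <- !is.na(df$cds_seq)
    if (any(nchar(df$cds_seq[has_cds]) %% 3L != 0L))
      stop("cds_seq length must be divisible by 3")
  }
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Construct a BGC region table
#'
#' One row per biosynthetic gene cluster: `cluster_id` (unique per genome),
#' `contig_id`, `start`/`end` (0-based half-open), `product_class` (free
#' text) and `source` (`antismash_region`, `coordinate_table` or `fixture`).
#' Rows are sorted by (contig_id, start).
#'
#' @param cluster_id,contig_id,start,end,product_class,source vectors of
#'   equal length.
#' @return validated, sorted data.frame of class `bgc_table`.
#' @export
bgc_regions <- function(cluster_id = character(), contig_id = character(),
                        start = integer(), end = integer(),
                        product_class = character(), source = "coordinate_table") {
  df <- data.frame(cluster_id = as.character(cluster_id),
                   contig_id = as.character(contig_id),
                   start = as.integer(start), end = as.integer(end),
                   product_class = as.character(product_class),
                   source = rep_len(as.character(source), length(cluster_id)),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (anyDuplicated(df$cluster_id))
      stop("duplicate cluster_id: ", df$cluster_id[duplicated(df$cluster_id)][1])
    if (any(df$end <= df$start)) stop("BGC intervals must satisfy start < end")
    df <- df[order(df$contig_id, df$start, df$cluster_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("bgc_table", "data.frame")
  df
}

#' Construct a genome record
#'
#' Container for one query or reference genome: gene features, BGC regions
#' and contig lengths. Every gene and BGC must lie on a declared contig and
#' within its length.
#'
#' @param genome_id genome identifier.
#' @param genes a [gene_features()] table.
#' @param bgcs a [bgc_regions()] table.
#' @param contigs named integer vector contig_id -> length (bp).
#' @param contig_seq optional named character vector contig_id -> sequence.
#' @return object of class `genome_record`.
#' @export
genome_record <- function(genome_id, genes = gene_features(character(), character(),
                                                           integer(), integer(), character()),
                          bgcs = bgc_regions(), contigs, contig_seq = NULL) {
  genes <- validate_gene_table(as.data.frame(genes))
  if (!inherits(bgcs, "bgc_table")) {
    bgcs <- bgc_regions(bgcs$cluster_id, bgcs$contig_id, bgcs$start, bgcs$end,
                        bgcs$product_class, bgcs$source %||% "coordinate_table")
  }
  stopifnot(is.numeric(contigs), !is.null(names(contigs)))
  contigs <- setNames(as.integer(contigs), names(contigs))
  for (df in list(genes, bgcs)) {
    if (nrow(df)) {
      missing <- setdiff(df$contig_id, names(contigs))
      if (length(missing)) stop("feature on undeclared contig: ", missing[1])
      if (any(df$end > contigs[df$contig_id]))
        stop("feature extends past contig end in genome ", genome_id)
    }
  }
  structure(list(genome_id = genome_id, genes = genes, bgcs = bgcs,
                 contigs = contigs, contig_seq = contig_seq),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("genome_record '", x$genome_id, "': ", length(x$contigs), " contig(s), ",
      nrow(x$genes), " gene(s), ", nrow(x$bgcs), " BGC(s)\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Flat-file location parsing (GenBank / EMBL share the syntax)

#' Parse a GenBank/EMBL location string into strand + exon table (1-based
#' inclusive); compound join() locations keep all segments. Partial-end
#' markers (< >) are stripped.
#' @noRd
parse_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", gsub("[[:space:]]", "", loc))
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  if (grepl("^order\\(", loc)) loc <- sub("^order\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  m <- regmatches(parts, regexec("^(\\d+)\\.\\.(\\d+)$", parts))
  single <- regmatches(parts, regexec("^(\\d+)$", parts))
  starts <- ends <- integer(0)
  for (i in seq_along(parts)) {
    if (length(m[[i]]) == 3L) {
      starts <- c(starts, as.integer(m[[i]][2])); ends <- c(ends, as.integer(m[[i]][3]))
    } else if (length(single[[i]]) == 2L) {
      starts <- c(starts, as.integer(single[[i]][2])); ends <- c(ends, as.integer(single[[i]][2]))
    } else {
      stop("unparseable location segment: '", parts[i], "'")
    }
  }
  if (!length(starts)) stop("empty location: '", loc, "'")
  list(strand = strand, exon_start = starts, exon_end = ends)
}

#' Reverse complement of a plain character DNA string
#' @noRd
revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]), collapse = "")
}

#' Splice a CDS from a contig sequence given 1-based inclusive exons
#' @noRd
splice_cds <- function(contig_seq, exon_start, exon_end, strand) {
  pieces <- substring(contig_seq, exon_start, exon_end)
  s <- paste(pieces, collapse = "")
  if (strand == "-") s <- revcomp(s)
  s
}

# ---------------------------------------------------------------------------
# GenBank

#' Split a flat file into records on '//' terminators
#' @noRd
split_records <- function(lines) {
  idx <- grep("^//", lines)
  if (!length(idx)) stop("no record terminator '//' found")
  begin <- c(1L, head(idx, -1L) + 1L)
  mapply(function(b, e) lines[b:(e - 1L)], begin, idx, SIMPLIFY = FALSE)
}

#' Extract the feature table lines into a list of (key, location, qualifiers)
#' @noRd
parse_feature_block <- function(flines) {
  feats <- list()
  cur <- NULL
  for (ln in flines) {
    key <- substr(ln, 6, 20)
    body <- substr(ln, 22, nchar(ln))
    if (grepl("^\\S", substr(ln, 6, 6)) && nzchar(trimws(key))) {
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      cur <- list(key = trimws(key), loc = trimws(body), quals = character())
    } else if (!is.null(cur)) {
      body <- trimws(body)
      if (startsWith(body, "/")) {
        cur$quals <- c(cur$quals, body)
      } else if (length(cur$quals)) {
        # continuation of the previous qualifier value
        n <- length(cur$quals)
        sep <- if (grepl("\"$", body) || grepl("translation", cur$quals[n])) "" else " "
        cur$quals[n] <- paste0(cur$quals[n], sep, body)
      } else {
        cur$loc <- paste0(cur$loc, body)
      }
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  feats
}

#' @noRd
qualifier_value <- function(quals, name) {
  pat <- paste0("^/", name, "=")
  hit <- quals[grepl(pat, quals)]
  if (!length(hit)) return(NA_character_)
  v <- sub(pat, "", hit[1])
  gsub("\"", "", v)
}

#' @noRd
parse_genbank_record <- function(rlines) {
  locus <- rlines[grepl("^LOCUS", rlines)][1]
  if (is.na(locus)) stop("GenBank record missing LOCUS line")
  toks <- strsplit(trimws(locus), "[[:space:]]+")[[1]]
  contig_id <- toks[2]
  len <- suppressWarnings(as.integer(toks[3]))
  fstart <- grep("^FEATURES", rlines)
  ostart <- grep("^ORIGIN", rlines)
  seq_str <- ""
  if (length(ostart)) {
    seq_lines <- rlines[(ostart[1] + 1L):length(rlines)]
    seq_str <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }
  feats <- list()
  if (length(fstart)) {
    fend <- if (length(ostart)) ostart[1] - 1L else length(rlines)
    if (fend > fstart[1]) feats <- parse_feature_block(rlines[(fstart[1] + 1L):fend])
  }
  if (is.na(len) || len <= 0L) len <- nchar(seq_str)
  list(contig_id = contig_id, length = len, seq = seq_str, features = feats)
}

#' @noRd
record_features_to_tables <- function(rec, source_label) {
  genes <- data.frame(gene_id = character(), contig_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      protein_seq = character(), cds_seq = character(),
                      stringsAsFactors = FALSE)
  bgcs <- data.frame(cluster_id = character(), contig_id = character(),
                     start = integer(), end = integer(),
                     product_class = character(), source = character(),
                     stringsAsFactors = FALSE)
  n_cds <- 0L
  for (f in rec$features) {
    if (f$key == "CDS") {
      n_cds <- n_cds + 1L
      loc <- tryCatch(parse_location(f$loc), error = function(e)
        stop("record '", rec$contig_id, "' CDS ", n_cds, ": ", conditionMessage(e)))
      start0 <- min(loc$exon_start) - 1L
      end0 <- max(loc$exon_end)
      gid <- qualifier_value(f$quals, "locus_tag")
      if (is.na(gid)) gid <- qualifier_value(f$quals, "gene")
      if (is.na(gid)) gid <- qualifier_value(f$quals, "protein_id")
      if (is.na(gid)) gid <- sprintf("%s_cds%03d", rec$contig_id, n_cds)
      prot <- qualifier_value(f$quals, "translation")
      if (!is.na(prot)) prot <- gsub("[[:space:]]", "", prot)
      cds <- NA_character_
      if (nzchar(rec$seq)) {
        cds <- splice_cds(rec$seq, loc$exon_start, loc$exon_end, loc$strand)
        if (nchar(cds) %% 3L != 0L) cds <- NA_character_
      }
      if (is.na(prot)) {
        if (is.na(cds)) {
          rm_log("skipping CDS '", gid, "': no translation and no sequence")
          next
        }
        tr <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                                 if.fuzzy.codon = "solve"))
        tr <- sub("\\*$", "", tr)
        if (grepl("\\*", tr)) {
          rm_log("skipping CDS '", gid, "': internal stop codon, untranslatable")
          next
        }
        prot <- tr
      }
      genes[nrow(genes) + 1L, ] <- list(gid, rec$contig_id, start0, end0,
                                        loc$strand, prot, cds)
    } else if (f$key %in% c("region", "cluster", "protocluster")) {
      loc <- parse_location(f$loc)
      note <- qualifier_value(f$quals, "note")
      num <- qualifier_value(f$quals, "region_number")
      prod <- qualifier_value(f$quals, "product")
      if (is.na(prod)) prod <- ""
      cid <- if (!is.na(note) && startsWith(note, "cluster_id:")) {
        sub("^cluster_id:", "", note)
      } else if (!is.na(num)) {
        paste0(rec$contig_id, "_region", num)
      } else {
        sprintf("%s_region%03d", rec$contig_id, nrow(bgcs) + 1L)
      }
      bgcs[nrow(bgcs) + 1L, ] <- list(cid, rec$contig_id,
                                      min(loc$exon_start) - 1L, max(loc$exon_end),
                                      prod, source_label)
    }
  }
  list(genes = genes, bgcs = bgcs)
}

#' @noRd
read_flat_genome <- function(path, genome_id, dialect) {
  lines <- readLines(path, warn = FALSE)
  recs <- lapply(split_records(lines), function(r) {
    if (dialect == "genbank") parse_genbank_record(r) else parse_embl_record(r)
  })
  contigs <- setNames(vapply(recs, function(r) r$length, integer(1)),
                      vapply(recs, function(r) r$contig_id, character(1)))
  seqs <- setNames(vapply(recs, function(r) r$seq, character(1)), names(contigs))
  tabs <- lapply(recs, record_features_to_tables,
                 source_label = "antismash_region")
  genes <- do.call(rbind, lapply(tabs, `[[`, "genes"))
  bgcs <- do.call(rbind, lapply(tabs, `[[`, "bgcs"))
  genome_record(genome_id,
                genes = validate_gene_table(genes),
                bgcs = bgc_regions(bgcs$cluster_id, bgcs$contig_id, bgcs$start,
                                   bgcs$end, bgcs$product_class, bgcs$source),
                contigs = contigs,
                contig_seq = if (all(nzchar(seqs))) seqs else NULL)
}

#' @noRd
parse_embl_record <- function(rlines) {
  idline <- rlines[grepl("^ID", rlines)][1]
  if (is.na(idline)) stop("EMBL record missing ID line")
  toks <- strsplit(trimws(sub("^ID", "", idline)), "[;[:space:]]+")[[1]]
  contig_id <- toks[toks != ""][1]
  lenm <- regmatches(idline, regexec("(\\d+)\\s+BP", idline))[[1]]
  len <- if (length(lenm) == 2L) as.integer(lenm[2]) else NA_integer_
  ft <- rlines[startsWith(rlines, "FT")]
  # re-pad FT lines into the GenBank feature-table column layout
  ftg <- paste0("     ", substr(ft, 6, nchar(ft)))
  sstart <- grep("^SQ", rlines)
  seq_str <- ""
  if (length(sstart) && sstart[1] < length(rlines)) {
    seq_lines <- rlines[(sstart[1] + 1L):length(rlines)]
    seq_str <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }
  if (is.na(len) || len <= 0L) len <- nchar(seq_str)
  list(contig_id = contig_id, length = len, seq = seq_str,
       features = parse_feature_block(ftg))
}

# ---------------------------------------------------------------------------
# Readers

#' Read a query genome
#'
#' Supported formats: `genbank` / `embl` flat files (one record per contig;
#' 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention; compound `join()` locations are flattened to their
#' outer envelope for coordinates while the CDS sequence is spliced), and
#' `fasta` with a sidecar gene-coordinate TSV (columns `gene_id`,
#' `contig_id`, `start`, `end`, `strand`, `protein_seq`[, `cds_seq`],
#' already 0-based half-open). CDS features lacking a translation that
#' cannot be translated (internal stop) are skipped with a logged warning.
#' antiSMASH-style `region` features present in GenBank/EMBL input are
#' collected as BGC regions.
#'
#' @param path input file.
#' @param format one of `"auto"`, `"genbank"`, `"embl"`, `"fasta"`.
#' @param gene_table sidecar TSV path (required for FASTA input).
#' @param genome_id identifier; default is the file base name.
#' @return a [genome_record()].
#' @export
read_genome <- function(path, format = c("auto", "genbank", "embl", "fasta"),
                        gene_table = NULL, genome_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  genome_id <- genome_id %||% sub("\\.(gbk|gb|gbff|genbank|embl|dat|fa|fna|fasta)$", "",
                                  basename(path))
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (startsWith(first, "LOCUS")) "genbank"
              else if (startsWith(first, "ID")) "embl"
              else if (startsWith(first, ">")) "fasta"
              else stop("cannot auto-detect format of ", path,
                        " (line 1: '", substr(first, 1, 30), "')")
  }
  if (format %in% c("genbank", "embl"))
    return(read_flat_genome(path, genome_id, format))
  # FASTA + sidecar table
  if (is.null(gene_table))
    stop("FASTA input requires a sidecar gene-coordinate table (gene_table=)")
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  contigs <- setNames(Biostrings::width(seqs), names(seqs))
  tab <- read_tsv(gene_table, colClasses = "character")
  need <- c("gene_id", "contig_id", "start", "end", "strand")
  if (!all(need %in% names(tab)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  cs <- setNames(as.character(seqs), names(seqs))
  n <- nrow(tab)
  prot <- if ("protein_seq" %in% names(tab)) tab$protein_seq else rep(NA_character_, n)
  cds <- if ("cds_seq" %in% names(tab)) tab$cds_seq else rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (is.na(cds[i]) || !nzchar(cds[i])) {
      cds[i] <- splice_cds(cs[[tab$contig_id[i]]],
                           as.integer(tab$start[i]) + 1L, as.integer(tab$end[i]),
                           tab$strand[i])
      if (nchar(cds[i]) %% 3L != 0L) cds[i] <- NA_character_
    }
    if (is.na(prot[i]) || !nzchar(prot[i])) {
      if (is.na(cds[i])) {
        prot[i] <- NA_character_
        next
      }
      tr <- sub("\\*$", "", as.character(
        Biostrings::translate(Biostrings::DNAString(cds[i]), if.fuzzy.codon = "solve")))
      prot[i] <- if (grepl("\\*", tr)) NA_character_ else tr
    }
  }
  keep <- !is.na(prot)
  if (any(!keep)) rm_log("skipping ", sum(!keep), " untranslatable gene(s) from sidecar table")
  genome_record(genome_id,
                genes = gene_features(tab$gene_id[keep], tab$contig_id[keep],
                                      as.integer(tab$start[keep]),
                                      as.integer(tab$end[keep]),
                                      tab$strand[keep], prot[keep], cds[keep]),
                contigs = contigs, contig_seq = cs)
}

#' Read BGC regions
#'
#' Two dialects: `antismash_region_gbk` (GenBank files whose `region` /
#' `cluster` features carry the boundaries, as written by antiSMASH-style
#' predictors) and `tsv_table` (columns `cluster_id`, `contig_id`, `start`,
#' `end`, `product_class`; 0-based half-open). Regions may overlap; the
#' result is sorted by (contig_id, start). A table row with `end <= start`
#' is rejected with its row number.
#'
#' @param path input file.
#' @param dialect `"antismash_region_gbk"` or `"tsv_table"`.
#' @param feature_type for the GenBank dialect, which feature key carries the
#'   boundaries (default `"region"`; `"cluster"`/`"protocluster"` accepted).
#' @return a [bgc_regions()] table.
#' @export
read_bgc_regions <- function(path, dialect = c("antismash_region_gbk", "tsv_table"),
                             feature_type = "region") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (dialect == "tsv_table") {
    tab <- read_tsv(path, colClasses = "character")
    if (nrow(tab) == 0L) return(bgc_regions())
    need <- c("cluster_id", "contig_id", "start", "end", "product_class")
    if (!all(need %in% names(tab)))
      stop("BGC table must have columns: ", paste(need, collapse = ", "))
    start <- as.integer(tab$start); end <- as.integer(tab$end)
    bad <- which(end <= start)
    if (length(bad))
      stop("BGC table row ", bad[1] + 1L, ": end <= start (", tab$cluster_id[bad[1]], ")")
    return(bgc_regions(tab$cluster_id, tab$contig_id, start, end,
                       tab$product_class, "coordinate_table"))
  }
  g <- read_flat_genome(path, genome_id = "bgc_input", dialect = "genbank")
  bg <- g$bgcs
  if (feature_type != "region" && nrow(bg) == 0L)
    rm_log("no '", feature_type, "' features found in ", basename(path))
  bg
}

# ---------------------------------------------------------------------------
# Writers

#' @noRd
wrap_qualifier <- function(name, value, width = 58L) {
  txt <- paste0("/", name, "=\"", value, "\"")
  out <- character()
  while (nchar(txt) > width) {
    out <- c(out, substr(txt, 1, width))
    txt <- substr(txt, width + 1L, nchar(txt))
  }
  c(out, txt)
}

#' Write a genome record as a GenBank flat file
#'
#' One record per contig with `source`, `region` (for BGCs) and `CDS`
#' features; internal 0-based half-open coordinates are converted to the
#' 1-based inclusive GenBank convention. Output is deterministic byte-for-byte
#' given the same record.
#'
#' @param genome a [genome_record()] with contig sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_genbank <- function(genome, path) {
  stopifnot(inherits(genome, "genome_record"))
  if (is.null(genome$contig_seq))
    stop("genome record has no contig sequences; cannot write GenBank")
  con <- file(path, open = "wb")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con, sep = "\n")
  for (cid in names(genome$contigs)) {
    len <- genome$contigs[[cid]]
    w(sprintf("LOCUS       %-17s %9d bp    DNA     linear   UNA 01-JAN-2000", cid, len))
    w(sprintf("DEFINITION  %s %s.", genome$genome_id, cid))
    w("FEATURES             Location/Qualifiers")
    w(sprintf("     source          1..%d", len))
    w(sprintf("                     /organism=\"%s\"", genome$genome_id))
    bg <- genome$bgcs[genome$bgcs$contig_id == cid, , drop = FALSE]
    for (i in seq_len(nrow(bg))) {
      w(sprintf("     region          %d..%d", bg$start[i] + 1L, bg$end[i]))
      w(sprintf("                     /region_number=\"%d\"", i))
      w(sprintf("                     /note=\"cluster_id:%s\"", bg$cluster_id[i]))
      w(sprintf("                     /product=\"%s\"", bg$product_class[i]))
    }
    gn <- genome$genes[genome$genes$contig_id == cid, , drop = FALSE]
    gn <- gn[order(gn$start, gn$gene_id), , drop = FALSE]
    for (i in seq_len(nrow(gn))) {
      loc <- sprintf("%d..%d", gn$start[i] + 1L, gn$end[i])
      if (gn$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      w(sprintf("     CDS             %s", loc))
      w(sprintf("                     /locus_tag=\"%s\"", gn$gene_id[i]))
      if (!is.na(gn$protein_seq[i]))
        for (ln in wrap_qualifier("translation", gn$protein_seq[i]))
          w(sprintf("                     %s", ln))
    }
    w("ORIGIN")
    seq <- tolower(genome$contig_seq[[cid]])
    pos <- 1L
    while (pos <= nchar(seq)) {
      chunk <- substr(seq, pos, min(pos + 59L, nchar(seq)))
      groups <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      w(sprintf("%9d %s", pos, paste(groups, collapse = " ")))
      pos <- pos + 60L
    }
    w("//")
  }
  invisible(path)
}

#' Write a genome record as an EMBL flat file
#'
#' Mirror of [write_genome_genbank()] in the EMBL dialect (ID/FT/SQ lines).
#'
#' @param genome a [genome_record()] with contig sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_embl <- function(genome, path) {
  stopifnot(inherits(genome, "genome_record"))
  if (is.null(genome$contig_seq))
    stop("genome record has no contig sequences; cannot write EMBL")
  con <- file(path, open = "wb")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con, sep = "\n")
  ftl <- function(key, body) {
    if (nzchar(key)) w(sprintf("FT   %-15s %s", key, body))
    else w(sprintf("FT   %-15s %s", "", body))
  }
  for (cid in names(genome$contigs)) {
    len <- genome$contigs[[cid]]
    w(sprintf("ID   %s; SV 1; linear; genomic DNA; STD; UNC; %d BP.", cid, len))
    w("FH   Key             Location/Qualifiers")
    ftl("source", sprintf("1..%d", len))
    ftl("", sprintf("/organism=\"%s\"", genome$genome_id))
    bg <- genome$bgcs[genome$bgcs$contig_id == cid, , drop = FALSE]
    for (i in seq_len(nrow(bg))) {
      ftl("region", sprintf("%d..%d", bg$start[i] + 1L, bg$end[i]))
      ftl("", sprintf("/region_number=\"%d\"", i))
      ftl("", sprintf("/note=\"cluster_id:%s\"", bg$cluster_id[i]))
      ftl("", sprintf("/product=\"%s\"", bg$product_class[i]))
    }
    gn <- genome$genes[genome$genes$contig_id == cid, , drop = FALSE]
    gn <- gn[order(gn$start, gn$gene_id), , drop = FALSE]
    for (i in seq_len(nrow(gn))) {
      loc <- sprintf("%d..%d", gn$start[i] + 1L, gn$end[i])
      if (gn$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      ftl("CDS", loc)
      ftl("", sprintf("/locus_tag=\"%s\"", gn$gene_id[i]))
      if (!is.na(gn$protein_seq[i]))
        for (ln in wrap_qualifier("translation", gn$protein_seq[i]))
          ftl("", ln)
    }
    seq <- tolower(genome$contig_seq[[cid]])
    w(sprintf("SQ   Sequence %d BP;", len))
    pos <- 1L
    while (pos <= nchar(seq)) {
      chunk <- substr(seq, pos, min(pos + 59L, nchar(seq)))
      groups <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      w(sprintf("     %-66s %d", paste(groups, collapse = " "),
                min(pos + 59L, nchar(seq))))
      pos <- pos + 60L
    }
    w("//")
  }
  invisible(path)
}

#' Write the FASTA + sidecar gene table representation of a genome
#'
#' @param genome a [genome_record()] with contig sequences.
#' @param fasta_path,table_path output paths.
#' @return invisibly, a list with both paths.
#' @export
write_genome_fasta <- function(genome, fasta_path, table_path) {
  stopifnot(inherits(genome, "genome_record"))
  if (is.null(genome$contig_seq)) stop("genome record has no contig sequences")
  dss <- Biostrings::DNAStringSet(genome$contig_seq[names(genome$contigs)])
  Biostrings::writeXStringSet(dss, fasta_path, width = 70L)
  gn <- genome$genes[order(genome$genes$contig_id, genome$genes$start,
                           genome$genes$gene_id), , drop = FALSE]
  write_tsv(gn, table_path)
  invisible(list(fasta = fasta_path, table = table_path))
}
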