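# Deterministic synthetic-data generator: reference genome collections,
# ortholog tables, planted core-gene families, duplications, BGCs and
# resistance genes, so every pipeline stage is testable offline.
#
# Each core-gene model is realized as a protein family: one random ancestral
# CDS (sense codons only, single exon, no introns) diverged per member by
# uniform per-codon substitution at the stated rate, never creating stops.
# Reference genomes carry one baseline copy of every family; query genomes
# additionally carry the planted extra copies, inside or outside BGCs.

#' Fixture specification
#'
#' @param seed RNG seed; the same spec yields byte-identical outputs.
#' @param n_ref_genomes reference genomes (roster of the ortholog table).
#' @param n_models core-gene families.
#' @param genome_length contig length in bp (one contig per genome).
#' @param n_bgcs BGC regions planted per genome.
#' @param n_query_genomes query genomes to generate.
#' @param planted_events data.frame `model_id`, `genome_id`, `extra_copies`,
#'   `inside_bgc` describing planted duplications (usually on query genomes).
#' @param codon_mutation_rate per-codon substitution probability in `[0, 1]`
#'   applied when deriving each family member from the ancestor.
#' @param gene_length_codons codons per core gene.
#' @param n_res_models known-resistance-factor families to generate.
#' @param resistance_events data.frame `model_id`, `genome_id`, `inside_bgc`
#'   placing resistance genes on query genomes.
#' @param function_classes optional named vector model_id -> COG letter(s);
#'   defaults cycle through non-excluded classes.
#' @param bgc_width BGC width in bp.
#' @return validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_ref_genomes = 5L, n_models = 10L,
                         genome_length = 60000L, n_bgcs = 3L,
                         n_query_genomes = 1L,
                         planted_events = NULL, codon_mutation_rate = 0.05,
                         gene_length_codons = 100L, n_res_models = 1L,
                         resistance_events = NULL, function_classes = NULL,
                         bgc_width = 4000L) {
  stopifnot(codon_mutation_rate >= 0, codon_mutation_rate <= 1,
            n_ref_genomes >= 1, n_models >= 1, n_bgcs >= 0)
  spec <- list(seed = as.integer(seed), n_ref_genomes = as.integer(n_ref_genomes),
               n_models = as.integer(n_models),
               genome_length = as.integer(genome_length),
               n_bgcs = as.integer(n_bgcs),
               n_query_genomes = as.integer(n_query_genomes),
               planted_events = planted_events,
               codon_mutation_rate = codon_mutation_rate,
               gene_length_codons = as.integer(gene_length_codons),
               n_res_models = as.integer(n_res_models),
               resistance_events = resistance_events,
               function_classes = function_classes,
               bgc_width = as.integer(bgc_width))
  model_ids <- sprintf("model%02d", seq_len(spec$n_models))
  genome_ids <- c(sprintf("ref%d", seq_len(spec$n_ref_genomes)),
                  if (spec$n_query_genomes > 0)
                    sprintf("qry%d", seq_len(spec$n_query_genomes)))
  for (ev in list(planted_events, resistance_events)) {
    if (!is.null(ev)) {
      if (!all(ev$genome_id %in% genome_ids))
        stop("planted event references undeclared genome: ",
             setdiff(ev$genome_id, genome_ids)[1])
    }
  }
  if (!is.null(planted_events) && !all(planted_events$model_id %in% model_ids))
    stop("planted event references undeclared model: ",
         setdiff(planted_events$model_id, model_ids)[1])
  spec$model_ids <- model_ids
  spec$ref_ids <- genome_ids[seq_len(spec$n_ref_genomes)]
  spec$query_ids <- setdiff(genome_ids, spec$ref_ids)
  class(spec) <- "fixture_spec"
  spec
}

#' Sense codons of the standard genetic code
#' @noRd
sense_codons <- function() {
  code <- genetic_code()
  names(code)[code != "*"]
}

#' Random CDS as a vector of sense codons
#' @noRd
random_cds_codons <- function(n_codons, codons = sense_codons()) {
  sample(codons, n_codons, replace = TRUE)
}

#' Mutate a codon vector: per codon, with probability `rate`, substitute one
#' random position with a random different base, never creating a stop.
#' @noRd
mutate_codons <- function(codons, rate, code = genetic_code()) {
  if (rate <= 0) return(codons)
  hit <- which(stats::runif(length(codons)) < rate)
  for (i in hit) {
    ch <- strsplit(codons[i], "")[[1]]
    pos <- sample.int(3L, 1L)
    bases <- sample(setdiff(.BASES, ch[pos]))
    for (b in bases) {
      cand <- ch; cand[pos] <- b
      cand <- paste(cand, collapse = "")
      if (code[[cand]] != "*") { codons[i] <- cand; break }
    }
  }
  codons
}

#' @noRd
translate_codons <- function(codons, code = genetic_code()) {
  paste(unname(code[codons]), collapse = "")
}

#' Generate a synthetic reference collection with planted truth
#'
#' Produces reference genomes (one baseline copy of every core-gene family,
#' placed outside BGCs), query genomes (baseline copies plus the planted
#' duplications and resistance genes), the ortholog-assignment table over the
#' reference roster, per-model annotations (functional classes), profile
#' HMMs built from the reference family members with the injected engine,
#' and a planted-truth ledger listing exactly which (genome, model) pairs
#' should be flagged duplicated (D) and BGC-proximal (B).
#'
#' @param spec a [fixture_spec()].
#' @param engine HMM engine used to build family profiles (`NULL` to skip
#'   profile building).
#' @param hmm_dir directory for the profiles (default a tempdir).
#' @return list with `ref_genomes`, `query_genomes` (lists of
#'   [genome_record()]), `orthologs`, `annotations`, `truth`,
#'   `resistance_truth`, `core_hmms`, `res_hmms` (named path vectors) and
#'   `spec`.
#' @export
generate_collection <- function(spec, engine = hmmer_engine(),
                                hmm_dir = tempfile("fixture_hmms_")) {
  stopifnot(inherits(spec, "fixture_spec"))
  gene_bp <- 3L * spec$gene_length_codons
  slot_bp <- gene_bp + 100L
  # feasibility: BGCs plus baseline genes (plus worst-case planted copies)
  # must fit on the contig before anything is generated or written
  n_events <- if (is.null(spec$planted_events)) 0L
              else sum(spec$planted_events$extra_copies)
  need <- spec$n_bgcs * (spec$bgc_width + 200L) +
    (spec$n_models + n_events + 2L) * slot_bp
  if (need > spec$genome_length)
    stop("infeasible packing: need >= ", need, " bp but genome_length is ",
         spec$genome_length)
  max_in_bgc <- (spec$bgc_width - 200L) %/% slot_bp
  set.seed(spec$seed)

  code <- genetic_code()
  ancestors <- lapply(spec$model_ids, function(m)
    random_cds_codons(spec$gene_length_codons))
  names(ancestors) <- spec$model_ids
  res_ids <- if (spec$n_res_models > 0) sprintf("resmodel%02d", seq_len(spec$n_res_models))
             else character()
  res_ancestors <- lapply(res_ids, function(m)
    random_cds_codons(spec$gene_length_codons))
  names(res_ancestors) <- res_ids

  class_pool <- c("J", "E", "O", "C", "F", "G", "H", "I", "L", "M")
  fclass <- spec$function_classes
  if (is.null(fclass))
    fclass <- setNames(rep_len(class_pool, spec$n_models), spec$model_ids)
  annotations <- data.frame(model_id = spec$model_ids,
                            function_class = unname(fclass[spec$model_ids]),
                            description = paste("synthetic essential core gene family",
                                                spec$model_ids),
                            stringsAsFactors = FALSE)

  ortho <- data.frame(ortholog_group_id = character(), genome_id = character(),
                      gene_id = character(), stringsAsFactors = FALSE)
  member_prots <- setNames(vector("list", length(spec$model_ids)), spec$model_ids)
  res_member_prots <- setNames(vector("list", length(res_ids)), res_ids)

  build_genome <- function(gid, is_query) {
    ev <- spec$planted_events
    ev <- if (!is.null(ev)) ev[ev$genome_id == gid, , drop = FALSE] else NULL
    rev_ <- spec$resistance_events
    rev_ <- if (!is.null(rev_)) rev_[rev_$genome_id == gid, , drop = FALSE] else NULL

    # plan genes: one baseline copy per core model + planted extras + one
    # copy per planted resistance model + 2 filler genes per BGC
    plan <- data.frame(label = character(), model_id = character(),
                       where = character(), bgc = integer(),
                       stringsAsFactors = FALSE)
    for (m in spec$model_ids)
      plan[nrow(plan) + 1L, ] <- list("core", m, "outside", NA_integer_)
    bgc_cycle <- 0L
    if (!is.null(ev)) for (i in seq_len(nrow(ev))) {
      for (k in seq_len(ev$extra_copies[i])) {
        if (isTRUE(ev$inside_bgc[i])) {
          bgc_cycle <- bgc_cycle + 1L
          plan[nrow(plan) + 1L, ] <- list("core", ev$model_id[i], "inside",
                                          ((bgc_cycle - 1L) %% spec$n_bgcs) + 1L)
        } else {
          plan[nrow(plan) + 1L, ] <- list("core", ev$model_id[i], "outside",
                                          NA_integer_)
        }
      }
    }
    if (!is.null(rev_)) for (i in seq_len(nrow(rev_))) {
      if (isTRUE(rev_$inside_bgc[i])) {
        bgc_cycle <- bgc_cycle + 1L
        plan[nrow(plan) + 1L, ] <- list("res", rev_$model_id[i], "inside",
                                        ((bgc_cycle - 1L) %% spec$n_bgcs) + 1L)
      } else {
        plan[nrow(plan) + 1L, ] <- list("res", rev_$model_id[i], "outside",
                                        NA_integer_)
      }
    }
    if (spec$n_bgcs > 0) for (b in seq_len(spec$n_bgcs))
      for (k in 1:2) plan[nrow(plan) + 1L, ] <- list("filler", NA_character_,
                                                     "inside", b)

    # BGC intervals, evenly spaced
    bgc_start <- integer(0)
    if (spec$n_bgcs > 0)
      bgc_start <- vapply(seq_len(spec$n_bgcs), function(i)
        as.integer(floor(spec$genome_length * i / (spec$n_bgcs + 1L))), integer(1))
    bgc_end <- bgc_start + spec$bgc_width
    products <- c("NRPS", "PKS", "terpene", "indole")
    bgcs <- bgc_regions(cluster_id = if (spec$n_bgcs > 0) sprintf("bgc%d", seq_len(spec$n_bgcs)) else character(),
                        contig_id = rep("chr1", spec$n_bgcs),
                        start = bgc_start, end = bgc_end,
                        product_class = rep_len(products, spec$n_bgcs),
                        source = "fixture")

    n_inside <- table(factor(plan$bgc[plan$where == "inside"],
                             levels = seq_len(max(spec$n_bgcs, 1L))))
    if (spec$n_bgcs > 0 && any(n_inside > max_in_bgc))
      stop("infeasible packing: too many genes planted inside one BGC")

    # free intervals outside BGCs (with 100 bp clearance)
    free <- list()
    cursor <- 100L
    for (b in seq_len(spec$n_bgcs)) {
      if (bgc_start[b] - 100L > cursor) free[[length(free) + 1L]] <- c(cursor, bgc_start[b] - 100L)
      cursor <- bgc_end[b] + 100L
    }
    if (spec$genome_length - 100L > cursor)
      free[[length(free) + 1L]] <- c(cursor, spec$genome_length - 100L)

    genes <- data.frame(gene_id = character(), contig_id = character(),
                        start = integer(), end = integer(), strand = character(),
                        protein_seq = character(), cds_seq = character(),
                        stringsAsFactors = FALSE)
    inside_counter <- setNames(rep(0L, spec$n_bgcs),
                               as.character(seq_len(max(spec$n_bgcs, 0L))))
    free_i <- 1L
    free_pos <- if (length(free)) free[[1]][1] else 0L
    gnum <- 0L
    place <- function(where, bgc) {
      if (where == "inside") {
        k <- inside_counter[[as.character(bgc)]]
        start <- bgc_start[bgc] + 100L + k * slot_bp
        inside_counter[[as.character(bgc)]] <<- k + 1L
        return(start)
      }
      while (free_i <= length(free) && free_pos + gene_bp > free[[free_i]][2]) {
        free_i <<- free_i + 1L
        if (free_i <= length(free)) free_pos <<- free[[free_i]][1]
      }
      if (free_i > length(free)) stop("infeasible packing: ran out of intergenic space")
      start <- free_pos
      free_pos <<- free_pos + slot_bp
      start
    }

    for (i in seq_len(nrow(plan))) {
      gnum <- gnum + 1L
      gid_gene <- sprintf("%s_g%03d", gid, gnum)
      if (plan$label[i] == "core") {
        codons <- mutate_codons(ancestors[[plan$model_id[i]]],
                                spec$codon_mutation_rate, code)
      } else if (plan$label[i] == "res") {
        codons <- mutate_codons(res_ancestors[[plan$model_id[i]]],
                                spec$codon_mutation_rate, code)
      } else {
        codons <- random_cds_codons(spec$gene_length_codons)
      }
      cds <- paste(codons, collapse = "")
      prot <- translate_codons(codons, code)
      start <- place(plan$where[i], plan$bgc[i])
      strand <- sample(c("+", "-"), 1L)
      genes[nrow(genes) + 1L, ] <- list(gid_gene, "chr1", start,
                                        start + gene_bp, strand, prot, cds)
      if (plan$label[i] == "core" && !is_query) {
        ortho[nrow(ortho) + 1L, ] <<- list(plan$model_id[i], gid, gid_gene)
        member_prots[[plan$model_id[i]]] <<-
          c(member_prots[[plan$model_id[i]]], prot)
      }
      if (plan$label[i] == "res" && !is_query)
        res_member_prots[[plan$model_id[i]]] <<-
          c(res_member_prots[[plan$model_id[i]]], prot)
    }

    # contig sequence: random background, genes stamped in at their positions
    contig <- paste(sample(.BASES, spec$genome_length, replace = TRUE),
                    collapse = "")
    for (i in seq_len(nrow(genes))) {
      s <- genes$cds_seq[i]
      if (genes$strand[i] == "-") s <- revcomp(s)
      substr(contig, genes$start[i] + 1L, genes$end[i]) <- s
    }
    genome_record(gid, genes = validate_gene_table(genes), bgcs = bgcs,
                  contigs = c(chr1 = spec$genome_length),
                  contig_seq = c(chr1 = contig))
  }

  # resistance families also need reference members for profile building:
  # each reference genome carries one copy of each resistance family placed
  # outside BGCs only when profiles are requested; we instead derive profile
  # members directly from the ancestor to keep reference genomes core-only.
  for (m in res_ids)
    res_member_prots[[m]] <- vapply(seq_len(max(spec$n_ref_genomes, 3L)),
                                    function(k) translate_codons(
                                      mutate_codons(res_ancestors[[m]],
                                                    spec$codon_mutation_rate, code)),
                                    character(1))

  ref_genomes <- lapply(spec$ref_ids, build_genome, is_query = FALSE)
  names(ref_genomes) <- spec$ref_ids
  query_genomes <- lapply(spec$query_ids, build_genome, is_query = TRUE)
  names(query_genomes) <- spec$query_ids

  # planted-truth ledger over query genomes x core models
  truth <- data.frame(genome_id = character(), model_id = character(),
                      expected_duplication = logical(),
                      expected_proximity = logical(), stringsAsFactors = FALSE)
  for (q in spec$query_ids) {
    ev <- spec$planted_events
    ev <- if (!is.null(ev)) ev[ev$genome_id == q, , drop = FALSE] else NULL
    for (m in spec$model_ids) {
      extra <- if (!is.null(ev)) sum(ev$extra_copies[ev$model_id == m]) else 0L
      inb <- if (!is.null(ev)) any(ev$inside_bgc[ev$model_id == m] &
                                     ev$extra_copies[ev$model_id == m] > 0) else FALSE
      truth[nrow(truth) + 1L, ] <- list(q, m, extra > 0L, isTRUE(inb))
    }
  }
  res_truth <- data.frame(genome_id = character(), model_id = character(),
                          expected_proximity = logical(), stringsAsFactors = FALSE)
  if (!is.null(spec$resistance_events)) {
    rev_ <- spec$resistance_events
    for (i in seq_len(nrow(rev_)))
      res_truth[nrow(res_truth) + 1L, ] <- list(rev_$genome_id[i],
                                                rev_$model_id[i],
                                                isTRUE(rev_$inside_bgc[i]))
  }

  core_hmms <- res_hmms <- character()
  if (!is.null(engine)) {
    dir.create(hmm_dir, recursive = TRUE, showWarnings = FALSE)
    core_hmms <- vapply(spec$model_ids, function(m)
      engine$build(member_prots[[m]], m, file.path(hmm_dir, paste0(m, ".hmm"))),
      character(1))
    res_hmms <- vapply(res_ids, function(m)
      engine$build(res_member_prots[[m]], m, file.path(hmm_dir, paste0(m, ".hmm"))),
      character(1))
  }

  list(ref_genomes = ref_genomes, query_genomes = query_genomes,
       orthologs = structure(ortho, class = c("ortholog_table", "data.frame")),
       annotations = annotations, truth = truth, resistance_truth = res_truth,
       core_hmms = core_hmms, res_hmms = res_hmms, hmm_dir = hmm_dir,
       spec = spec)
}

#' Write a generated collection to disk in the pipeline's own input formats
#'
#' GenBank files for every genome (`<genome_id>.gbk`, BGC regions included
#' as `region` features), `orthologs.tsv`, `annotations.tsv`, `truth.tsv`
#' and the profile HMMs under `hmms/`.
#'
#' @param collection result of [generate_collection()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in c(collection$ref_genomes, collection$query_genomes))
    write_genome_genbank(g, file.path(dir, paste0(g$genome_id, ".gbk")))
  write_tsv(collection$orthologs, file.path(dir, "orthologs.tsv"))
  write_tsv(collection$annotations, file.path(dir, "annotations.tsv"))
  write_tsv(collection$truth, file.path(dir, "truth.tsv"))
  if (length(collection$core_hmms) || length(collection$res_hmms)) {
    hd <- file.path(dir, "hmms")
    dir.create(hd, showWarnings = FALSE)
    for (p in c(collection$core_hmms, collection$res_hmms))
      file.copy(p, file.path(hd, basename(p)), overwrite = TRUE)
  }
  invisible(dir)
}
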