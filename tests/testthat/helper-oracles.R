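# Independent oracles, deliberately implemented differently from the package
# code paths they check.

oracle_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- setNames(as.character(Biostrings::GENETIC_CODE),
                                         names(Biostrings::GENETIC_CODE))
    code
  }
})

oracle_sense_codons <- function() {
  code <- oracle_code()
  names(code)[code != "*"]
}

# site counts by explicit enumeration of the 9 single-base mutants
oracle_site_counts <- function(codon) {
  code <- oracle_code()
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    muts <- vapply(c("A", "C", "G", "T"), function(b) {
      ch <- strsplit(codon, "")[[1]]
      if (ch[pos] == b) return(NA_character_)
      ch[pos] <- b
      paste(ch, collapse = "")
    }, character(1))
    muts <- muts[!is.na(muts)]
    aas <- unname(code[muts])
    keep <- aas != "*"
    if (any(keep)) s <- s + sum(aas[keep] == aa) / sum(keep)
  }
  c(n = 3 - s, s = s)
}

.oracle_cache <- new.env(parent = emptyenv())

# exhaustive substitution-pathway enumeration by depth-first recursion;
# returns average (sd, nd) over complete pathways avoiding stop codons,
# or NULL if every pathway is blocked. Results are memoized (pure function
# of the codon pair); the enumeration itself stays independent of the
# package implementation.
oracle_pair_counts <- function(c1, c2) {
  key <- paste0(c1, c2)
  if (!is.null(.oracle_cache[[key]])) {
    v <- .oracle_cache[[key]]
    return(if (identical(v, "blocked")) NULL else v)
  }
  code <- oracle_code()
  rec <- function(cur, target) {
    dif <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(dif)) return(list(s = 0, n = 0, k = 1L))
    tot <- list(s = 0, n = 0, k = 0L)
    for (p in dif) {
      ch <- strsplit(cur, "")[[1]]
      ch[p] <- strsplit(target, "")[[1]][p]
      nxt <- paste(ch, collapse = "")
      if (code[[nxt]] == "*") next
      sub <- rec(nxt, target)
      if (sub$k == 0L) next
      syn_step <- code[[cur]] == code[[nxt]]
      tot$s <- tot$s + sub$s + sub$k * as.numeric(syn_step)
      tot$n <- tot$n + sub$n + sub$k * as.numeric(!syn_step)
      tot$k <- tot$k + sub$k
    }
    tot
  }
  r <- rec(c1, c2)
  out <- if (r$k == 0L) NULL else c(sd = r$s / r$k, nd = r$n / r$k)
  .oracle_cache[[key]] <- if (is.null(out)) "blocked" else out
  out
}

oracle_site_counts_cached <- function(codon) {
  key <- paste0("site_", codon)
  if (is.null(.oracle_cache[[key]])) .oracle_cache[[key]] <- oracle_site_counts(codon)
  .oracle_cache[[key]]
}

# full-pipeline brute force for codon-aligned sequences: proportions only
oracle_pnps <- function(cds1, cds2) {
  code <- oracle_code()
  sense <- oracle_sense_codons()
  co1 <- substring(cds1, seq(1, nchar(cds1), 3), seq(3, nchar(cds1), 3))
  co2 <- substring(cds2, seq(1, nchar(cds2), 3), seq(3, nchar(cds2), 3))
  N <- S <- Nd <- Sd <- 0
  for (i in seq_along(co1)) {
    if (!(co1[i] %in% sense) || !(co2[i] %in% sense)) next
    d <- oracle_pair_counts(co1[i], co2[i])
    if (is.null(d)) next
    s1 <- oracle_site_counts_cached(co1[i]); s2 <- oracle_site_counts_cached(co2[i])
    N <- N + (s1[["n"]] + s2[["n"]]) / 2
    S <- S + (s1[["s"]] + s2[["s"]]) / 2
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  c(pN = if (N > 0) Nd / N else 0, pS = if (S > 0) Sd / S else 0,
    N = N, S = S, Nd = Nd, Sd = Sd)
}

# literal all-position interval intersection (same-contig, half-open)
oracle_proximity <- function(genes, bgcs) {
  out <- data.frame(gene_id = character(), cluster_id = character(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(genes))) {
    gpos <- seq.int(genes$start[i], genes$end[i] - 1L)
    for (j in seq_len(nrow(bgcs))) {
      if (genes$contig_id[i] != bgcs$contig_id[j]) next
      bpos <- seq.int(bgcs$start[j], bgcs$end[j] - 1L)
      if (length(intersect(gpos, bpos)) > 0L)
        out[nrow(out) + 1L, ] <- list(genes$gene_id[i], bgcs$cluster_id[j])
    }
  }
  out <- out[order(out$gene_id, out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# sort-and-middle median plus divide-by-n standard deviation
oracle_count_stats <- function(x) {
  sx <- sort(x)
  n <- length(sx)
  med <- if (n %% 2 == 1) sx[(n + 1) / 2] else (sx[n / 2] + sx[n / 2 + 1]) / 2
  sdev <- sqrt(sum((x - sum(x) / n)^2) / n)
  c(median = med, stdev = sdev, threshold = med + sdev)
}

random_sense_cds <- function(n_codons) {
  paste(sample(oracle_sense_codons(), n_codons, replace = TRUE), collapse = "")
}
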