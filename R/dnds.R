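# Nei-Gojobori pairwise dN/dS with Jukes-Cantor correction.
#
# Counting estimator: per-codon synonymous/nonsynonymous site fractions,
# substitution-pathway enumeration for codons differing at >= 2 positions,
# proportions corrected with d = -(3/4) * log(1 - 4p/3).

.dnds_env <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")

#' Genetic code lookup as a named character vector (codon -> amino acid)
#' @noRd
genetic_code <- function() {
  if (is.null(.dnds_env$code))
    .dnds_env$code <- setNames(as.character(Biostrings::GENETIC_CODE),
                               names(Biostrings::GENETIC_CODE))
  .dnds_env$code
}

#' Synonymous/nonsynonymous site counts for one codon
#'
#' For each of the three codon positions, the fraction of the possible
#' single-nucleotide changes that are synonymous is accumulated into the
#' synonymous site count `s`; changes that would create a stop codon are
#' excluded from that position's denominator. `n = 3 - s`.
#'
#' @param codon a 3-character string over A/C/G/T, not a stop codon.
#' @param code named character vector codon -> amino acid (default standard
#'   code, stops as `"*"`).
#' @return named numeric vector `c(n = , s = )`.
#' @examples
#' codon_site_counts("GGG") # s = 1, n = 2
#' codon_site_counts("ATG") # s = 0, n = 3
#' @export
codon_site_counts <- function(codon, code = genetic_code()) {
  stopifnot(nchar(codon) == 3L)
  ch <- strsplit(codon, "")[[1]]
  if (!all(ch %in% .BASES)) stop("ambiguous base in codon: ", codon)
  aa <- code[[codon]]
  if (aa == "*") stop("stop codon has no site counts: ", codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; valid <- 0L
    for (b in setdiff(.BASES, ch[pos])) {
      mut <- ch; mut[pos] <- b
      maa <- code[[paste(mut, collapse = "")]]
      if (maa == "*") next
      valid <- valid + 1L
      if (maa == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  c(n = 3 - s, s = s)
}

#' Pathway-averaged synonymous/nonsynonymous difference counts for one codon
#' pair. Pathways passing through a stop codon are excluded; counts are
#' averaged with equal weight over the remaining shortest pathways. Returns
#' c(sd, nd), or NULL when every pathway is blocked.
#' @noRd
codon_pair_diff_counts <- function(c1, c2, code) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diff <- which(a != b)
  if (length(diff) == 0L) return(c(sd = 0, nd = 0))
  syn_tot <- 0; nsyn_tot <- 0; n_paths <- 0L
  for (ord in small_permutations(diff)) {
    cur <- a; syn <- 0L; nsyn <- 0L; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- b[pos]
      cur_aa <- code[[paste(cur, collapse = "")]]
      nxt_aa <- code[[paste(nxt, collapse = "")]]
      if (nxt_aa == "*") { blocked <- TRUE; break }
      if (nxt_aa == cur_aa) syn <- syn + 1L else nsyn <- nsyn + 1L
      cur <- nxt
    }
    if (!blocked) {
      syn_tot <- syn_tot + syn; nsyn_tot <- nsyn_tot + nsyn
      n_paths <- n_paths + 1L
    }
  }
  if (n_paths == 0L) return(NULL)
  c(sd = syn_tot / n_paths, nd = nsyn_tot / n_paths)
}

#' Memoized per-codon site counts and per-pair difference counts over the 61
#' sense codons. Built once per session.
#' @noRd
dnds_tables <- function() {
  if (!is.null(.dnds_env$tables)) return(.dnds_env$tables)
  code <- genetic_code()
  sense <- names(code)[code != "*"]
  sites <- t(vapply(sense, codon_site_counts, numeric(2), code = code))
  k <- length(sense)
  sd_tab <- matrix(NA_real_, k, k, dimnames = list(sense, sense))
  nd_tab <- sd_tab
  for (i in seq_len(k)) for (j in i:k) {
    d <- codon_pair_diff_counts(sense[i], sense[j], code)
    if (!is.null(d)) {
      sd_tab[i, j] <- sd_tab[j, i] <- d[["sd"]]
      nd_tab[i, j] <- nd_tab[j, i] <- d[["nd"]]
    }
  }
  .dnds_env$tables <- list(sense = sense, sites = sites, sd = sd_tab, nd = nd_tab)
  .dnds_env$tables
}

#' Jukes-Cantor distance; NA when 4p/3 >= 1 (saturated)
#' @noRd
jukes_cantor <- function(p) {
  if (is.na(p) || 4 * p / 3 >= 1) return(NA_real_)
  -3 / 4 * log(1 - 4 * p / 3)
}

#' Pairwise Nei-Gojobori dN/dS
#'
#' Sequences must be codon-aligned, equal length, divisible by three. Gapped
#' codons (`-`), codons with ambiguity characters and stop codons are skipped.
#' Synonymous (S) and nonsynonymous (N) site counts are averaged over the two
#' sequences; difference counts (Sd, Nd) average with equal weight over all
#' shortest substitution pathways, pathways through stop codons excluded.
#' Proportions pN = Nd/N and pS = Sd/S receive the Jukes-Cantor correction
#' d = -(3/4) log(1 - 4p/3); omega = dN/dS.
#'
#' @param cds1,cds2 nucleotide strings (upper or lower case).
#' @return an object of class `dnds_result`: list with `n_sites`, `s_sites`,
#'   `n_diffs`, `s_diffs`, `pN`, `pS`, `dN`, `dS`, `omega`, `n_codons`
#'   (codons compared) and `status`, one of `ok`, `saturated`,
#'   `undefined_dS_zero`, `length_mismatch`.
#' @examples
#' pairwise_dnds("ATGGGGTTT", "ATGGGATTT")
#' @export
pairwise_dnds <- function(cds1, cds2) {
  cds1 <- toupper(cds1); cds2 <- toupper(cds2)
  res <- list(n_sites = NA_real_, s_sites = NA_real_, n_diffs = NA_real_,
              s_diffs = NA_real_, pN = NA_real_, pS = NA_real_,
              dN = NA_real_, dS = NA_real_, omega = NA_real_,
              n_codons = 0L, status = "length_mismatch")
  class(res) <- "dnds_result"
  if (nchar(cds1) != nchar(cds2) || nchar(cds1) %% 3L != 0L) return(res)
  tab <- dnds_tables()
  co1 <- substring(cds1, seq(1, nchar(cds1), 3), seq(3, nchar(cds1), 3))
  co2 <- substring(cds2, seq(1, nchar(cds2), 3), seq(3, nchar(cds2), 3))
  usable <- co1 %in% tab$sense & co2 %in% tab$sense
  skipped_blocked <- 0L
  N <- S <- Nd <- Sd <- 0
  n_used <- 0L
  for (i in which(usable)) {
    sdv <- tab$sd[co1[i], co2[i]]
    if (is.na(sdv)) { skipped_blocked <- skipped_blocked + 1L; next }
    ndv <- tab$nd[co1[i], co2[i]]
    s1 <- tab$sites[co1[i], ]; s2 <- tab$sites[co2[i], ]
    N <- N + (s1[["n"]] + s2[["n"]]) / 2
    S <- S + (s1[["s"]] + s2[["s"]]) / 2
    Sd <- Sd + sdv; Nd <- Nd + ndv
    n_used <- n_used + 1L
  }
  if (skipped_blocked > 0L)
    rm_log(skipped_blocked, " codon pair(s) skipped: all substitution pathways blocked by stops")
  if (n_used == 0L) {
    # degenerate: nothing comparable (all gaps/ambiguous); zero distance
    res[c("n_sites", "s_sites", "n_diffs", "s_diffs", "pN", "pS", "dN", "dS")] <- 0
    res$status <- "undefined_dS_zero"
    return(res)
  }
  res$n_sites <- N; res$s_sites <- S; res$n_diffs <- Nd; res$s_diffs <- Sd
  res$n_codons <- n_used
  res$pN <- if (N > 0) Nd / N else 0
  res$pS <- if (S > 0) Sd / S else 0
  res$dN <- jukes_cantor(res$pN)
  res$dS <- jukes_cantor(res$pS)
  if (is.na(res$dN) || is.na(res$dS)) {
    res$status <- "saturated"
  } else if (res$dS == 0) {
    res$status <- "undefined_dS_zero"
  } else {
    res$omega <- res$dN / res$dS
    res$status <- "ok"
  }
  res
}

#' @export
print.dnds_result <- function(x, ...) {
  cat("Nei-Gojobori pairwise dN/dS (", x$n_codons, " codons)\n", sep = "")
  cat(sprintf("  N = %.4f  S = %.4f  Nd = %.4f  Sd = %.4f\n",
              x$n_sites, x$s_sites, x$n_diffs, x$s_diffs))
  cat(sprintf("  pN = %s  pS = %s  dN = %s  dS = %s  omega = %s  [%s]\n",
              format(x$pN), format(x$pS), format(x$dN), format(x$dS),
              format(x$omega), x$status))
  invisible(x)
}

#' Median dN/dS over all member pairs of one core-gene model
#'
#' Computes [pairwise_dnds()] for every unordered pair of member coding
#' sequences and returns the median omega over pairs with status `ok`
#' (`NA` when no pair yields a defined omega).
#'
#' @param members character vector of codon-aligned CDS (>= 2 for a result).
#' @return numeric median omega, or `NA`.
#' @export
model_dnds_median <- function(members) {
  members <- members[!is.na(members) & nzchar(members)]
  if (length(members) < 2L) return(NA_real_)
  omegas <- c()
  for (i in seq_len(length(members) - 1L)) {
    for (j in (i + 1L):length(members)) {
      r <- pairwise_dnds(members[[i]], members[[j]])
      if (r$status == "ok") omegas <- c(omegas, r$omega)
    }
  }
  if (length(omegas) == 0L) return(NA_real_)
  median(omegas)
}

#' Protein-guided codon alignment of two coding sequences
#'
#' Helper for unaligned inputs: globally aligns the two translations
#' (Needleman-Wunsch, BLOSUM62, gap open 10 / extend 0.5) and back-maps the
#' alignment onto codons, inserting `---` for gaps, so the result can be fed
#' to [pairwise_dnds()].
#'
#' @param cds1,cds2 nucleotide strings with length divisible by 3.
#' @return list with codon-aligned `cds1` and `cds2` of equal length.
#' @export
align_codons <- function(cds1, cds2) {
  stopifnot(nchar(cds1) %% 3 == 0, nchar(cds2) %% 3 == 0)
  p1 <- as.character(Biostrings::translate(Biostrings::DNAString(toupper(cds1)),
                                           if.fuzzy.codon = "solve"))
  p2 <- as.character(Biostrings::translate(Biostrings::DNAString(toupper(cds2)),
                                           if.fuzzy.codon = "solve"))
  p1 <- sub("\\*$", "", p1); p2 <- sub("\\*$", "", p2)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  a1 <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  a2 <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  co1 <- substring(cds1, seq(1, nchar(cds1), 3), seq(3, nchar(cds1), 3))
  co2 <- substring(cds2, seq(1, nchar(cds2), 3), seq(3, nchar(cds2), 3))
  i1 <- i2 <- 1L
  out1 <- out2 <- character(length(a1))
  for (k in seq_along(a1)) {
    if (a1[k] == "-") out1[k] <- "---" else { out1[k] <- co1[i1]; i1 <- i1 + 1L }
    if (a2[k] == "-") out2[k] <- "---" else { out2[k] <- co2[i2]; i2 <- i2 + 1L }
  }
  list(cds1 = paste(out1, collapse = ""), cds2 = paste(out2, collapse = ""))
}
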