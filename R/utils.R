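#' @keywords internal
"_PACKAGE"

#' @importFrom stats median sd setNames
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Package log message, suppressible via options(resmine.verbose = FALSE)
#' @noRd
rm_log <- function(...) {
  if (isTRUE(getOption("resmine.verbose", TRUE))) message("[resmine] ", ...)
  invisible(NULL)
}

#' Sanitize free-text fields for the TSV dialect
#'
#' Tabs, carriage returns and newlines inside cells would break the
#' tab-separated dialect; they are replaced by a single space (logged).
#' @noRd
sanitize_cells <- function(x) {
  bad <- grepl("[\t\r\n]", x)
  if (any(bad, na.rm = TRUE)) {
    rm_log("sanitized ", sum(bad, na.rm = TRUE),
           " cell(s) containing tab/newline characters")
    x[which(bad)] <- gsub("[\t\r\n]+", " ", x[which(bad)])
  }
  x
}

#' Write a summary table as TSV
#'
#' All tabular outputs go through this writer: UTF-8, tab separated, header
#' row, no quoting, `NA` for missing values. Character cells containing tab
#' or newline characters are sanitized to a single space so the dialect stays
#' unambiguous. Column order is the data frame's; callers are responsible for
#' a deterministic row sort.
#'
#' @param table a data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(table, path) {
  stopifnot(is.data.frame(table))
  for (j in seq_along(table)) {
    if (is.character(table[[j]]) || is.factor(table[[j]]))
      table[[j]] <- sanitize_cells(as.character(table[[j]]))
    if (is.numeric(table[[j]]))
      table[[j]] <- vapply(table[[j]], function(v) {
        if (is.na(v)) NA_character_
        else format(v, scientific = FALSE, trim = TRUE, digits = 15)
      }, character(1))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path file path.
#' @param colClasses passed to [utils::read.delim()].
#' @return data.frame with character/numeric columns as inferred.
#' @export
read_tsv <- function(path, colClasses = NA) {
  read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = "NA", colClasses = colClasses,
             fileEncoding = "UTF-8")
}

#' All permutations of a small integer vector (n <= 3 in practice)
#' @noRd
small_permutations <- function(x) {
  n <- length(x)
  if (n <= 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in small_permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Population standard deviation (divide by n, not n - 1)
#' @noRd
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
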