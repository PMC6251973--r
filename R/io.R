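#' Write a data frame as a provenance-stamped TSV
#'
#' Tables are tab-separated with a commented (`#`) header block carrying
#' provenance (package version plus any key-value pairs supplied), so every
#' output records how it was produced. Times are decimal hours throughout.
#' Missing values (e.g. censored division times, empty-bin fractions) are
#' written as empty fields.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param provenance Named character/numeric vector written as
#'   `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cyclefate %s", as.character(packageVersion("cyclefate"))),
             con)
  if (length(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), as.character(provenance)),
               con)
  suppressWarnings(
    write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                na = ""))
  invisible(path)
}

#' Read a provenance-stamped TSV
#'
#' Counterpart of [write_tsv()]: skips `#` comment lines and optionally
#' checks that required columns are present, failing with the name of the
#' first missing column.
#'
#' @param path Input path.
#' @param required Character vector of column names that must be present.
#' @return Data frame.
#' @export
read_tsv <- function(path, required = NULL) {
  x <- read.delim(path, comment.char = "#", sep = "\t",
                  stringsAsFactors = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("malformed table '", path, "': missing column '", missing[1], "'")
  x
}

#' Read an expression matrix TSV
#'
#' Expects a `gene_id` column followed by one column per hourly timepoint
#' (header = hours; an `X` prefix added by R to numeric headers is
#' stripped).
#'
#' @param path Input path.
#' @return Numeric matrix with gene ids as rownames.
#' @export
read_expression_matrix <- function(path) {
  x <- read_tsv(path, required = "gene_id")
  m <- as.matrix(x[, setdiff(names(x), "gene_id"), drop = FALSE])
  rownames(m) <- x$gene_id
  colnames(m) <- sub("^X", "", colnames(m))
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix TSV
#'
#' @param mat Numeric matrix, genes in rows.
#' @param path Output path.
#' @param provenance Passed to [write_tsv()].
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, provenance = NULL) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write_tsv(df, path, provenance = provenance)
}

#' Read a gene-set file (one id per line)
#'
#' @param path Input path; blank lines and `#` comments are ignored.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a flat key-value config file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and `#`
#' comments ignored.
#'
#' @param path Input path.
#' @return Named character vector.
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed config line: '", lines[bad][1], "'")
  setNames(trimws(vapply(m, `[`, character(1), 3L)),
           trimws(vapply(m, `[`, character(1), 2L)))
}
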