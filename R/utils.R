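#' @keywords internal
"_PACKAGE"

# DNA/RNA alphabet helpers. Internal coordinates throughout the package are
# 1-based closed (the IRanges convention); BED input is converted on read.

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Complement a vector of single DNA bases
#' @param base character vector of bases in \code{A,C,G,T,N}
#' @return complemented bases
#' @keywords internal
complement_base <- function(base) {
  out <- unname(COMPLEMENT[toupper(base)])
  if (anyNA(out)) stop("non-ACGTN base in complement_base()")
  out
}

#' Reverse-complement a DNA sequence given as a single string
#' @param seq character scalar
#' @return character scalar
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Report a DNA base in the RNA alphabet (T becomes U)
#' @param base character vector
#' @keywords internal
as_rna <- function(base) {
  ifelse(toupper(base) == "T", "U", toupper(base))
}

# True iff two DNA bases form a Watson-Crick pair (A:T, C:G only; no wobble).
wc_pair <- function(a, b) {
  COMPLEMENT[toupper(a)] == toupper(b) & toupper(a) %in% DNA_BASES
}

#' Percentage of a count over a total, rounded to one decimal place
#'
#' The reporting convention used by all summary tables: \code{100 * count /
#' total} rounded to 1 dp, e.g. 2380 of 2413 sites is 98.6.
#'
#' @param count numeric numerator
#' @param total numeric denominator
#' @return numeric percentage, NA when total is zero
#' @export
pct <- function(count, total) {
  ifelse(total > 0, round(100 * count / total, 1), NA_real_)
}

# --- tab-separated artifact I/O ------------------------------------------
# All tabular pipeline outputs are TSV with a header line starting '#'.

#' Write a pipeline TSV (tab-separated, '#'-prefixed header)
#' @param df data.frame
#' @param path output path
#' @export
write_pipeline_tsv <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a pipeline TSV written by [write_pipeline_tsv()]
#' @param path input path
#' @return data.frame
#' @export
read_pipeline_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) stop("not a pipeline TSV (no '#' header): ", path)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                          col.names = cols, stringsAsFactors = FALSE,
                          colClasses = NA, comment.char = "")
  df
}

# Site keys used to index per-site tables.
site_key <- function(chrom, pos) paste0(chrom, ":", pos)

`%||%` <- function(a, b) if (is.null(a)) b else a
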