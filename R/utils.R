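# Internal helpers shared across modules.

flv_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Effect category levels
#'
#' The eight mutually exclusive primary effect categories used throughout the
#' package, ordered by severity (most severe first). `stop_splice` unites
#' stop-gained, stop-lost and splice-region changes.
#'
#' @format Character vector of length 8.
#' @export
CATEGORY_LEVELS <- c(
  "frameshift", "stop_splice", "missense", "synonymous",
  "intron", "upstream", "downstream", "intergenic"
)

DNA_BASES <- c("A", "C", "G", "T")

dna_complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

dna_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(dna_complement(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Translate one codon with the standard nuclear genetic code; unknown -> "X".
codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[toupper(codon)]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

# Extract bases at 1-based positions from a chromosome string (vectorised).
genome_bases <- function(genome, chrom, pos) {
  if (!chrom %in% names(genome)) {
    flv_stop("chromosome '%s' absent from genome (have: %s)",
             chrom, paste(names(genome), collapse = ", "))
  }
  substring(genome[[chrom]], pos, pos)
}

genome_substr <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    flv_stop("chromosome '%s' absent from genome", chrom)
  }
  substr(genome[[chrom]], start, end)
}

# TSV with a single commented header line naming the columns.
write_tsv_commented <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

read_tsv_commented <- function(path, col.names, colClasses = NA) {
  if (!file.exists(path)) flv_stop("file not found: %s", path)
  first <- readLines(path, n = 1L)
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = colClasses,
                          col.names = col.names, blank.lines.skip = TRUE)
  if (length(first) == 1L && !startsWith(first, "#") && nrow(df) > 0) {
    # tolerate an uncommented header row naming the same columns
    if (all(as.character(unlist(df[1, ])) == col.names)) df <- df[-1, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write a set of result tables as TSV files
#'
#' Serialises each table in a named list to `<dir>/<name>.tsv` with a commented
#' header line naming the columns.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_report <- function(tables, dir) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    flv_stop("write_report() requires a fully named list of tables")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(tables), function(nm) {
    write_tsv_commented(as.data.frame(tables[[nm]]), file.path(dir, paste0(nm, ".tsv")))
  }, character(1))
  invisible(paths)
}
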