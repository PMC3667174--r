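#' Read and write FASTA / FASTQ files
#'
#' Thin wrappers around Biostrings readers/writers returning plain named
#' character vectors, with lowercase bases normalised to uppercase (with a
#' warning). FASTQ is written with a fixed Q35 placeholder quality.
#'
#' @param path File path.
#' @param seqs Named character vector of sequences (names become record
#'   ids).
#' @param width Line-wrap width for FASTA output (default 70).
#' @return Readers return a named character vector; writers return `path`
#'   invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  normalize_seqs(out)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = width)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  normalize_seqs(out)
}

#' @rdname read_fasta
#' @export
write_fastq <- function(seqs, path) {
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("read%06d", seq_along(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep("D", n), collapse = ""), ""))  # Sanger Q35 placeholder
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

normalize_seqs <- function(seqs) {
  lower <- grepl("[acgtn]", seqs)
  if (any(lower)) {
    warning(sprintf("%d record(s) contained lowercase bases; uppercased",
                    sum(lower)))
    seqs[lower] <- toupper(seqs[lower])
  }
  seqs
}

#' Read / write a genotype matrix as CSV
#'
#' Rows are markers, columns samples; codes `A`, `B`, `H` and `-` for
#' missing. The parent columns are listed in a leading comment-free header
#' convention: the first two columns after the marker id are taken as the
#' parents when `parents = NULL` and their names start with `P_`.
#'
#' @param gm A `genotype_matrix`.
#' @param path File path.
#' @param parents Optional character vector of parent column names used when
#'   reading.
#' @return `read_genotype_matrix` returns a `genotype_matrix`; the writer
#'   returns `path` invisibly.
#' @export
write_genotype_matrix <- function(gm, path) {
  x <- unclass(gm)
  x[is.na(x)] <- "-"
  df <- data.frame(marker = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path, parents = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m[m == "-" | m == ""] <- NA_character_
  if (is.null(parents)) {
    cand <- grep("^P_", colnames(m), value = TRUE)
    if (length(cand) == 2L) parents <- cand
  }
  genotype_matrix(m, parents = parents)
}

#' Read / write a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numeric where possible, `TRUE`/`FALSE` as logical. Unknown keys (not
#' present in `defaults`) are rejected so misspelled parameters fail loudly.
#'
#' @param path File path.
#' @param defaults Named list of known keys and default values (see
#'   [pipeline_config()]).
#' @param config Named list to write.
#' @return `read_config` returns the merged named list.
#' @export
read_config <- function(path, defaults = pipeline_config()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- defaults
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
    else if (val %in% c("TRUE", "FALSE")) as.logical(val)
    else val
  }
  out
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, as.character, "")), path)
  invisible(path)
}
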