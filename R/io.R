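#' Read sequences from a FASTA file
#'
#' Thin wrapper over Biostrings returning a plain named character vector;
#' the alphabet (nucleotide vs amino acid) is not enforced here and is
#' auto-detected by downstream functions.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' Deterministic output: records in input order, 60-column wrapping, LF
#' line endings, so identical inputs give byte-identical files.
#'
#' @param sequences named character vector.
#' @param path output file.
#' @param width line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(!is.null(names(sequences)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con, sep = "\n")
    s <- sequences[[i]]
    n <- nchar(s)
    starts <- seq.int(1L, max(n, 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con,
               sep = "\n")
  }
  invisible(path)
}

#' Write a synthetic library to disk
#'
#' Emits `<prefix>reads.fasta`, `<prefix>truth.tsv` (ground-truth table)
#' and `<prefix>config.json` (configuration echo).
#'
#' @param library output of [generate_library()].
#' @param prefix output path prefix (directories must exist).
#' @return Character vector of the three paths, invisibly.
#' @export
write_library <- function(library, prefix) {
  fa <- paste0(prefix, "reads.fasta")
  tsv <- paste0(prefix, "truth.tsv")
  js <- paste0(prefix, "config.json")
  write_fasta(library$reads, fa)
  utils::write.table(library$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(library$config), js, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(fa, tsv, js))
}
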