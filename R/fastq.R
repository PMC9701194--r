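#' Write reads to a 4-line FASTQ file
#'
#' Phred+33 with a constant quality score.
#'
#' @param seqs Character vector of read sequences.
#' @param path Output path (`.gz` handled transparently).
#' @param ids Read identifiers; defaults to `read_1 .. read_n`.
#' @param qual Constant Phred quality (default 37, i.e. "F").
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, ids = NULL, qual = 37L) {
  ids <- ids %||% paste0("read_", seq_along(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  qchar <- rawToChar(as.raw(33L + qual))
  quals <- Biostrings::BStringSet(strrep(qchar, nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals,
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (`.gz` handled transparently).
#' @return Tibble with columns `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read FASTQ file: ", path))
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(
    read_id = sub("\\s.*$", "", names(x) %||% as.character(seq_along(x))),
    seq = as.character(x)
  )
}
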