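#' Read sequences from FASTA/FASTQ
#'
#' Thin wrapper over Biostrings (gzip-transparent, multi-record). The
#' format is inferred from the file extension unless given.
#'
#' @param path file path.
#' @param format `"fasta"`, `"fastq"`, or `NULL` to infer.
#' @return named character vector of sequences (names truncated at the
#'   first whitespace).
#' @export
read_sequences <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such sequence file: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs named character vector of sequences.
#' @param path output path (`.gz` compresses).
#' @param format `"fasta"` (default) or `"fastq"`; FASTQ gets constant
#'   maximum quality since the error model is substitution-only.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(seqs)
  if (format == "fastq") {
    q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
      paste(rep("I", n), collapse = ""), ""))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}
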