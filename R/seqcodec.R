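#' @title Packed k-mer codec
#' @description DNA words of length k <= 32 are packed 2 bits/base into a
#'   64-bit word (A=00, C=01, G=10, T=11; base 0 in the lowest-order bits).
#'   Because R lacks a native 64-bit integer, an `encoded_kmers` vector
#'   stores the two exact unsigned 32-bit halves of each word as doubles.
#' @name seqcodec
NULL

new_encoded_kmers <- function(hi, lo, k) {
  structure(list(hi = as.numeric(hi), lo = as.numeric(lo), k = as.integer(k)),
            class = "encoded_kmers")
}

#' Encode DNA strings as packed k-mers
#'
#' @param seq character vector of equal-length DNA strings over A/C/G/T
#'   (case-insensitive). Any other character is an error: windows with
#'   ambiguous bases must be skipped by the caller (see [read_to_kmers()]).
#' @param k word length in bases, `1 <= k <= 32`; defaults to the length of
#'   the first string.
#' @return an `encoded_kmers` vector.
#' @examples
#' x <- encode_kmer(c("ACGT", "TTTT"))
#' decode_kmer(x)
#' @export
encode_kmer <- function(seq, k = nchar(seq[1])) {
  stopifnot(k >= 1, k <= 32)
  enc <- cpp_encode(as.character(seq), as.integer(k))
  new_encoded_kmers(enc$hi, enc$lo, k)
}

#' Decode packed k-mers back to strings
#' @param x an `encoded_kmers` vector.
#' @return character vector of k-length DNA strings.
#' @export
decode_kmer <- function(x) {
  stopifnot(inherits(x, "encoded_kmers"))
  cpp_decode(x$hi, x$lo, x$k)
}

#' Reverse complement of a DNA string
#' @param seq character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  k <- nchar(seq)
  stopifnot(all(k == k[1]), k[1] <= 32)
  x <- encode_kmer(seq, k[1])
  rc <- cpp_revcomp(x$hi, x$lo, x$k)
  cpp_decode(rc$hi, rc$lo, x$k)
}

#' Canonical form of a k-mer
#'
#' The lexicographically smaller of a k-mer and its reverse complement,
#' making matching strand-independent. Idempotent and reverse-complement
#' invariant.
#'
#' @param seq character vector of k-length DNA strings.
#' @param k word length; defaults to the string length.
#' @return an `encoded_kmers` vector of canonical forms.
#' @export
canonical_kmer <- function(seq, k = nchar(seq[1])) {
  x <- encode_kmer(seq, k)
  can <- cpp_canonical(x$hi, x$lo, x$k)
  new_encoded_kmers(can$hi, can$lo, x$k)
}

#' Hamming distance between packed k-mers, in bases
#'
#' A base differing in either or both of its 2 bits counts once. Computed
#' on the packed words by collapsing each 2-bit symbol of the XOR to a
#' single differing/equal flag and popcounting.
#'
#' @param x,y `encoded_kmers` vectors of equal `k`; lengths are recycled if
#'   one of them has length 1.
#' @return integer vector of base distances.
#' @export
hamming_distance <- function(x, y) {
  stopifnot(inherits(x, "encoded_kmers"), inherits(y, "encoded_kmers"))
  if (x$k != y$k) stop("k-mer lengths differ: ", x$k, " vs ", y$k)
  nx <- length(x$hi); ny <- length(y$hi)
  if (nx != ny) {
    if (nx == 1) { x <- x[rep(1L, ny)] } else if (ny == 1) {
      y <- y[rep(1L, nx)]
    } else stop("lengths differ and neither is 1")
  }
  cpp_hamming(x$hi, x$lo, y$hi, y$lo)
}

#' Canonical k-mer stream of a read
#'
#' Slides a window over the read and emits canonical k-mers; every window
#' containing a non-ACGT character (N or other IUPAC codes) is skipped,
#' soft-masked lowercase is uppercased. A read shorter than the window
#' yields an empty stream. With `minimizer_window = w > k`, each canonical
#' w-mer is reduced to its lexicographically smallest k-mer substring and
#' consecutive duplicate minimizers are collapsed (off by default).
#'
#' @param read a single DNA string.
#' @param k k-mer length (default 32).
#' @param minimizer_window `NULL` (default, plain canonical k-mers) or an
#'   integer window `> k`, e.g. 35.
#' @return an `encoded_kmers` vector (possibly empty).
#' @export
read_to_kmers <- function(read, k = 32, minimizer_window = NULL) {
  stopifnot(length(read) == 1)
  mw <- if (is.null(minimizer_window)) 0L else as.integer(minimizer_window)
  out <- cpp_reads_to_kmers(as.character(read), as.integer(k), mw)
  new_encoded_kmers(out$hi, out$lo, k)
}

# batch variant: returns encoded_kmers plus the 1-based source-read index
reads_to_kmer_stream <- function(reads, k = 32, minimizer_window = NULL) {
  mw <- if (is.null(minimizer_window)) 0L else as.integer(minimizer_window)
  out <- cpp_reads_to_kmers(as.character(reads), as.integer(k), mw)
  list(kmers = new_encoded_kmers(out$hi, out$lo, k), read = out$read)
}

#' @export
length.encoded_kmers <- function(x) length(x$hi)

#' @export
`[.encoded_kmers` <- function(x, i) new_encoded_kmers(x$hi[i], x$lo[i], x$k)

#' @export
as.character.encoded_kmers <- function(x, ...) decode_kmer(x)

#' @export
print.encoded_kmers <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<encoded_kmers> %d x %d-mer(s)\n", n, x$k))
  if (n > 0) print(utils::head(decode_kmer(x), 10))
  invisible(x)
}

#' @export
c.encoded_kmers <- function(...) {
  xs <- list(...)
  k <- xs[[1]]$k
  stopifnot(all(vapply(xs, function(e) e$k, 0L) == k))
  new_encoded_kmers(unlist(lapply(xs, `[[`, "hi")),
                    unlist(lapply(xs, `[[`, "lo")), k)
}

#' @export
unique.encoded_kmers <- function(x, ...) {
  key <- paste(x$hi, x$lo)
  x[!duplicated(key)]
}
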