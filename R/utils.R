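# shared helpers

# display rounding for report averages: round half away from zero
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# the 61 sense codons of the standard code and their amino acids
.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  # first position slowest, third fastest -- the order of the one-letter string
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), 4L),
                   rep(bases, 16L))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  names(aa) <- codons
  aa
})

sense_codons <- function() names(.codon_table)[.codon_table != "*"]

is_stop_codon <- function(codon) .codon_table[codon] == "*"

#' Translate coding nucleotide sequences
#'
#' Standard-code translation of complete codon sequences.  Stop codons are
#' not expected inside the generator's genes; any that appear (e.g. in
#' hand-built inputs) are rendered as `X`.
#'
#' @param nt character vector of nucleotide sequences, lengths multiples of 3.
#' @return character vector of amino-acid sequences.
#' @export
translate_cds <- function(nt) {
  vapply(nt, function(s) {
    n <- nchar(s)
    if (n %% 3L != 0L) stopf("sequence length %d is not a multiple of 3", n)
    codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- .codon_table[toupper(codons)]
    aa[is.na(aa) | aa == "*"] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse complement of nucleotide sequences
#' @param x character vector over A/C/G/T/N.
#' @return character vector.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtN", "TGCAtgcaN", x))
}

# sample one element even when x has length 1
sample_one <- function(x) x[sample.int(length(x), 1L)]

# convert a vector of integer Phred scores to a quality string (offset 33)
phred_to_string <- function(q) rawToChar(as.raw(q + 33L))

# convert a quality string to integer Phred scores
string_to_phred <- function(s) as.integer(charToRaw(s)) - 33L
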