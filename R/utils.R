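DNA_BASES <- c("A", "C", "G", "T")

# round half-up (not banker's) to `digits`; matches how percentages and %GC
# are conventionally printed in primer tables
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

is_dna <- function(x, allow_n = FALSE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  !is.na(x) & nzchar(x) & !grepl(sprintf("[^%s]", alphabet), x)
}

# uppercase, map RNA U to T
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  bad <- which(!is_dna(x, allow_n = allow_n))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s %d is empty or contains characters outside {%s}",
      what, bad[1], if (allow_n) "A,C,G,T,N" else "A,C,G,T"
    ))
  }
  invisible(x)
}

#' Reverse complement of DNA sequences
#'
#' @param seq Character vector of DNA sequences (`A`, `C`, `G`, `T`, `N`).
#' @return Character vector of reverse complements. The operation is
#'   involutive: `reverse_complement(reverse_complement(x))` is `x`.
#' @examples
#' reverse_complement(c("ACGT", "AAAC"))
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_seq(seq)
  assert_dna(seq, what = "sequence", allow_n = TRUE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# split sequences into a character matrix (rows = sequences); all equal length
seq_char_matrix <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) == 1)
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    nrow = length(seqs), byrow = TRUE
  )
}

# interval tibble (0-based half-open) -> GRanges (1-based closed)
intervals_to_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    s <- x$strand
    s[!s %in% c("+", "-")] <- "*"
    s
  } else {
    "*"
  }
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

granges_to_intervals <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- "."
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = s
  )
}

validate_intervals <- function(x, what = "intervals") {
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s must have columns %s", what, paste(need, collapse = ", ")))
  }
  if (any(x$start < 0) || any(x$end <= x$start)) {
    abort(sprintf("%s contain a negative or inverted interval", what))
  }
  invisible(x)
}
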