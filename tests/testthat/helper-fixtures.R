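# shared fixture builders; everything is generated in code, no binary files

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exhaustive best global alignment score over all monotone alignments
# (linear gap penalty); independent of the package's aligner
brute_force_alignment_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i > nchar(a) && j > nchar(b)) {
      return(0)
    }
    best <- -Inf
    if (i <= nchar(a) && j <= nchar(b)) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= nchar(a)) best <- max(best, gap + rec(i + 1, j))
    if (j <= nchar(b)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# score a 2-row alignment under the same linear-gap scheme
score_two_row_alignment <- function(aln, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(aln$aligned[1], "")[[1]]
  b <- strsplit(aln$aligned[2], "")[[1]]
  sum(ifelse(a == "-" | b == "-", gap, ifelse(a == b, match, mismatch)))
}

# small annotation tibble on one chromosome
toy_annotation <- function() {
  tibble::tibble(
    chrom = "chr1",
    start = c(100L, 400L, 900L),
    end = c(300L, 700L, 1200L),
    strand = c("+", "-", "+"),
    repeat_name = c("L1HS", "L1PA2", "AluY"),
    repeat_class = c("LINE", "LINE", "SINE"),
    repeat_family = c("L1", "L1", "Alu")
  )
}

# minimal RepeatMasker .out text (3 header lines + data rows)
write_rm_out <- function(rows, path) {
  header <- c(
    "   SW   perc perc perc  query     position in query     matching  repeat         position in repeat",
    "score   div. del. ins.  sequence  begin  end   (left)   repeat    class/family   begin end (left) ID",
    ""
  )
  writeLines(c(header, rows), path)
}

# genome tibble with a primer-pair template planted at a known offset
plant_template <- function(background, fwd, rev, insert_at, spacer) {
  tpl <- paste0(fwd, spacer, lineprimer::reverse_complement(rev))
  seq <- paste0(
    substr(background, 1, insert_at),
    tpl,
    substr(background, insert_at + 1, nchar(background))
  )
  tibble::tibble(id = "chr1", seq = seq)
}

# substitute the base at 1-based position i of a string with a different base
substitute_base <- function(s, i) {
  old <- substr(s, i, i)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  paste0(substr(s, 1, i - 1), new, substr(s, i + 1, nchar(s)))
}
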