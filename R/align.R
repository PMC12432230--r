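#' Star-progressive multiple alignment of subfamily consensuses
#'
#' Aligns every consensus to the first (youngest) one by global
#' Needleman-Wunsch with a linear gap penalty, then merges the pairwise
#' alignments into one multiple alignment under the usual "once a gap, always
#' a gap" rule. For repeat lineages that diverge mainly by substitution this
#' is an adequate stand-in for a full MSA program, and an externally computed
#' alignment can always be supplied via [accept_external_msa()] instead.
#'
#' @param consensuses Sequence tibble (`id`, `seq`) with >= 2 rows.
#' @param match,mismatch,gap Scoring parameters (linear gap penalty per gap
#'   character).
#' @return Alignment tibble with columns `id` and `aligned` (equal-length
#'   strings over `A,C,G,T,N,-`); removing `-` recovers each input.
#' @export
progressive_align <- function(consensuses, match = 1, mismatch = -1, gap = -2) {
  stopifnot(all(c("id", "seq") %in% names(consensuses)))
  if (nrow(consensuses) < 2) abort("need >= 2 sequences to align")
  if (anyDuplicated(consensuses$id)) abort("sequence ids must be unique")
  seqs <- normalize_seq(consensuses$seq)
  assert_dna(seqs, what = "sequence", allow_n = TRUE)

  center <- seqs[1]
  L <- nchar(center)
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE
  )
  pairwise <- purrr::map(seqs[-1], function(other) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(center), Biostrings::DNAString(other),
      type = "global", substitutionMatrix = sm,
      gapOpening = 0, gapExtension = -gap
    )
    split_pairwise(
      as.character(Biostrings::alignedPattern(al)),
      as.character(Biostrings::alignedSubject(al)), L
    )
  })

  # master gap counts per slot (before residue 1 ... after residue L)
  G <- Reduce(pmax, purrr::map(pairwise, "gaps"), rep(0L, L + 1L))
  center_chars <- strsplit(center, "", fixed = TRUE)[[1]]

  build_row <- function(residues, inserts) {
    out <- character(2L * L + 1L)
    for (k in 0:L) {
      ins <- inserts[[k + 1L]]
      out[2L * k + 1L] <- paste0(
        paste(ins, collapse = ""),
        strrep("-", G[k + 1L] - length(ins))
      )
      if (k < L) out[2L * k + 2L] <- residues[k + 1L]
    }
    paste(out, collapse = "")
  }

  center_row <- build_row(center_chars, rep(list(character(0)), L + 1L))
  other_rows <- purrr::map_chr(pairwise, function(pw) build_row(pw$residues, pw$inserts))
  tibble(id = consensuses$id, aligned = c(center_row, other_rows))
}

# decompose one pairwise alignment against the center sequence into:
#   gaps[k+1]     number of center-gap columns in slot k (between center
#                 residues k and k+1; slot 0 = before the first residue)
#   inserts[k+1]  the other sequence's characters in those columns
#   residues[j]   the other sequence's character aligned to center residue j
split_pairwise <- function(center_aln, other_aln, L) {
  cc <- strsplit(center_aln, "", fixed = TRUE)[[1]]
  oc <- strsplit(other_aln, "", fixed = TRUE)[[1]]
  gaps <- integer(L + 1L)
  inserts <- rep(list(character(0)), L + 1L)
  residues <- character(L)
  k <- 0L
  for (i in seq_along(cc)) {
    if (cc[i] == "-") {
      gaps[k + 1L] <- gaps[k + 1L] + 1L
      inserts[[k + 1L]] <- c(inserts[[k + 1L]], oc[i])
    } else {
      k <- k + 1L
      residues[k] <- oc[i]
    }
  }
  list(gaps = gaps, inserts = inserts, residues = residues)
}

#' Validate an externally computed multiple alignment
#'
#' Accepts the aligned-FASTA output of an external MSA program (e.g. Clustal
#' Omega) or an alignment tibble, and validates it into the same shape
#' [progressive_align()] produces.
#'
#' @param x Path to an aligned FASTA file, or a tibble with `id` and
#'   `aligned` (or `seq`) columns.
#' @return Alignment tibble (`id`, `aligned`).
#' @export
accept_external_msa <- function(x) {
  if (is.character(x) && length(x) == 1) {
    set <- Biostrings::readBStringSet(x)
    if (length(set) == 0) abort("alignment file contains no records")
    x <- tibble(id = sub("\\s.*$", "", names(set)), aligned = unname(as.character(set)))
  }
  if (!"aligned" %in% names(x) && "seq" %in% names(x)) {
    x <- rename(x, aligned = "seq")
  }
  stopifnot(all(c("id", "aligned") %in% names(x)))
  if (nrow(x) < 2) abort("alignment must contain >= 2 sequences")
  if (anyDuplicated(x$id)) abort("alignment ids must be unique")
  aligned <- normalize_seq(x$aligned)
  if (length(unique(nchar(aligned))) != 1) {
    abort("ragged alignment: aligned sequences differ in length")
  }
  degapped <- gsub("-", "", aligned, fixed = TRUE)
  bad <- which(!is_dna(degapped, allow_n = TRUE))
  if (length(bad) > 0) {
    abort(sprintf("alignment row '%s' contains non-DNA characters", x$id[bad[1]]))
  }
  tibble(id = x$id, aligned = aligned)
}

#' Number of columns of an alignment tibble
#' @param alignment Alignment tibble (`id`, `aligned`).
#' @return Integer column count.
#' @export
n_alignment_columns <- function(alignment) {
  nchar(alignment$aligned[1])
}
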