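#' Find mismatch-tolerant, 3'-anchored primer binding sites
#'
#' A genomic window is a binding site when the Hamming distance to the primer
#' over its full length is at most `max_mismatch` AND the primer's 3'-terminal
#' `anchor_len` bases match exactly (mismatches near the 3' end abolish
#' extension, which is why in-silico PCR anchors there). Both strands are
#' scanned; on the minus strand the primer must match the reverse complement
#' of the genomic window. `N` in the genome never matches. Candidate windows
#' are seeded from exact anchor hits and then verified over the full primer.
#'
#' @param genome Sequence tibble (`id`, `seq`); `N` allowed.
#' @param primer Primer sequence, 5' to 3' (no `N`).
#' @param max_mismatch Maximum Hamming mismatches over the full primer.
#' @param anchor_len Length of the exact-match 3' anchor (>= 1, shorter than
#'   the primer).
#' @param primer_name Label carried into the output.
#' @return Tibble of sites sorted by (`chrom`, `start`, `strand`): columns
#'   `chrom`, `start`, `end` (0-based half-open, length = primer length),
#'   `strand`, `mismatches`, `primer_name`.
#' @export
find_binding_sites <- function(genome, primer, max_mismatch = 2L,
                               anchor_len = 5L, primer_name = "primer") {
  stopifnot(all(c("id", "seq") %in% names(genome)))
  primer <- normalize_seq(primer)
  assert_dna(primer, what = "primer", allow_n = FALSE)
  L <- nchar(primer)
  if (anchor_len < 1 || anchor_len >= L) {
    abort("anchor_len must satisfy 1 <= anchor_len < primer length")
  }
  rcp <- reverse_complement(primer)

  hits <- purrr::map2(genome$id, genome$seq, function(chrom, gseq) {
    n <- nchar(gseq)
    if (n < L) {
      return(NULL)
    }
    subject <- Biostrings::DNAString(gseq)

    verify <- function(window_start1, pattern) {
      ok <- window_start1 >= 1 & window_start1 + L - 1 <= n
      ws <- window_start1[ok]
      if (length(ws) == 0) {
        return(NULL)
      }
      windows <- substring(gseq, ws, ws + L - 1L)
      mism <- integer(length(ws))
      pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
      for (j in seq_len(L)) {
        mism <- mism + (substring(windows, j, j) != pc[j])
      }
      keep <- mism <= max_mismatch
      tibble(start1 = ws[keep], mismatches = mism[keep])
    }

    # plus strand: anchor = primer's 3'-terminal bases, at the window's end
    anchor_p <- substring(primer, L - anchor_len + 1L, L)
    ap <- Biostrings::start(Biostrings::matchPattern(anchor_p, subject, fixed = TRUE))
    plus <- verify(ap - (L - anchor_len), primer)

    # minus strand: primer matches revcomp(window); equivalently revcomp(primer)
    # matches the window, with the anchor at the window's start
    anchor_m <- substring(rcp, 1L, anchor_len)
    am <- Biostrings::start(Biostrings::matchPattern(anchor_m, subject, fixed = TRUE))
    minus <- verify(am, rcp)

    bind_rows(
      if (!is.null(plus) && nrow(plus) > 0) mutate(plus, strand = "+"),
      if (!is.null(minus) && nrow(minus) > 0) mutate(minus, strand = "-")
    ) |>
      mutate(chrom = chrom)
  })

  out <- bind_rows(hits)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), mismatches = integer(), primer_name = character()
    ))
  }
  out |>
    mutate(
      start = as.integer(.data$start1 - 1L), end = as.integer(.data$start1 - 1L + L),
      primer_name = primer_name, mismatches = as.integer(.data$mismatches)
    ) |>
    select("chrom", "start", "end", "strand", "mismatches", "primer_name") |>
    arrange(.data$chrom, .data$start, .data$strand)
}

# pair forward-orientation sites (left primer on +, right primer on -) into
# product intervals within the size window
pair_sites <- function(left_plus, right_minus, min_product, max_product) {
  if (nrow(left_plus) == 0 || nrow(right_minus) == 0) {
    return(NULL)
  }
  dplyr::inner_join(
    rename(left_plus, f_start = "start", f_end = "end", f_mm = "mismatches"),
    rename(right_minus, r_start = "start", r_end = "end", r_mm = "mismatches"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    filter(
      .data$r_start >= .data$f_end,
      .data$r_end - .data$f_start >= min_product,
      .data$r_end - .data$f_start <= max_product
    ) |>
    mutate(start = .data$f_start, end = .data$r_end) |>
    select("chrom", "start", "end", "f_mm", "r_mm")
}

#' Predict PCR amplicons for a primer pair on a genome
#'
#' Pairs every forward-primer plus-strand site with every downstream
#' reverse-primer minus-strand site on the same chromosome within the product
#' size window, and symmetrically the reverse-orientation products (the pair
#' amplifying a repeat copy that sits on the minus strand). The default
#' product ceiling of 1000 bp mirrors the usual insert-size bound for
#' paired-end amplicon mapping.
#'
#' @param genome Sequence tibble (`id`, `seq`).
#' @param pair One-row tibble (or named list) with `fwd_seq` and `rev_seq`,
#'   e.g. a row of [design_pairs()] output.
#' @param max_product,min_product Product length window in bp.
#' @param max_mismatch,anchor_len Site-matching parameters, see
#'   [find_binding_sites()].
#' @param pair_name Label used in the amplicon `name` field
#'   (`<pair_name>_<product_len>`).
#' @return Amplicon tibble sorted by coordinate: `chrom`, `start`, `end`,
#'   `strand` (`+` = forward-orientation product), `product_len`, `f_mm`,
#'   `r_mm`, `seq`, `name`.
#' @export
predict_amplicons <- function(genome, pair, max_product = 1000L,
                              min_product = 40L, max_mismatch = 2L,
                              anchor_len = 5L, pair_name = "pair") {
  fwd <- pair$fwd_seq[[1]]
  rev <- pair$rev_seq[[1]]
  f_sites <- find_binding_sites(genome, fwd, max_mismatch, anchor_len, "F")
  r_sites <- find_binding_sites(genome, rev, max_mismatch, anchor_len, "R")

  plus <- pair_sites(
    filter(f_sites, .data$strand == "+"), filter(r_sites, .data$strand == "-"),
    min_product, max_product
  )
  minus <- pair_sites(
    filter(r_sites, .data$strand == "+"), filter(f_sites, .data$strand == "-"),
    min_product, max_product
  )
  out <- bind_rows(
    if (!is.null(plus) && nrow(plus) > 0) mutate(plus, strand = "+"),
    if (!is.null(minus) && nrow(minus) > 0) {
      # in reverse-orientation products the reverse primer is the left site
      mutate(minus, strand = "-", f_mm2 = .data$r_mm, r_mm = .data$f_mm, f_mm = .data$f_mm2) |>
        select(-"f_mm2")
    }
  )
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), product_len = integer(), f_mm = integer(),
      r_mm = integer(), seq = character(), name = character()
    ))
  }
  seqs <- setNames(genome$seq, genome$id)
  out |>
    distinct(.data$chrom, .data$start, .data$end, .data$strand, .keep_all = TRUE) |>
    mutate(
      product_len = as.integer(.data$end - .data$start),
      seq = unname(substring(seqs[.data$chrom], .data$start + 1L, .data$end)),
      name = paste0(pair_name, "_", .data$product_len)
    ) |>
    select(
      "chrom", "start", "end", "strand", "product_len",
      "f_mm", "r_mm", "seq", "name"
    ) |>
    arrange(.data$chrom, .data$start, .data$end, .data$strand)
}

#' Exhaustive in-silico PCR oracle (testing aid)
#'
#' Position-by-position rescan of every genomic window under the same match
#' rules as [predict_amplicons()], with no anchor seeding or indexing. Kept
#' deliberately independent of the production code path so the two can be
#' compared; refuses genomes over 100 kb.
#'
#' @inheritParams predict_amplicons
#' @return Amplicon tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `product_len`, `f_mm`, `r_mm`, `seq`, `name`.
#' @export
brute_force_pcr_oracle <- function(genome, pair, max_product = 1000L,
                                   min_product = 40L, max_mismatch = 2L,
                                   anchor_len = 5L, pair_name = "pair") {
  if (sum(nchar(genome$seq)) > 100000) {
    abort("oracle refuses genomes over 100 kb")
  }
  fwd <- normalize_seq(pair$fwd_seq[[1]])
  rev <- normalize_seq(pair$rev_seq[[1]])

  scan_sites <- function(gchars, primer) {
    L <- nchar(primer)
    n <- length(gchars)
    if (n < L) {
      return(list(plus = integer(0), minus = integer(0), plus_mm = integer(0), minus_mm = integer(0)))
    }
    m <- n - L + 1L
    W <- vapply(seq_len(L), function(j) gchars[j:(m + j - 1L)], character(m))
    if (m == 1L) W <- matrix(W, nrow = 1L)
    pc <- strsplit(primer, "", fixed = TRUE)[[1]]
    rc <- strsplit(reverse_complement(primer), "", fixed = TRUE)[[1]]
    neq_p <- W != matrix(pc, nrow = m, ncol = L, byrow = TRUE)
    neq_r <- W != matrix(rc, nrow = m, ncol = L, byrow = TRUE)
    mm_p <- rowSums(neq_p)
    mm_r <- rowSums(neq_r)
    anchor_cols_p <- (L - anchor_len + 1L):L # 3' anchor at window end on +
    anchor_cols_r <- 1L:anchor_len # at window start on -
    ok_p <- mm_p <= max_mismatch & rowSums(neq_p[, anchor_cols_p, drop = FALSE]) == 0
    ok_r <- mm_r <= max_mismatch & rowSums(neq_r[, anchor_cols_r, drop = FALSE]) == 0
    list(
      plus = which(ok_p) - 1L, plus_mm = mm_p[ok_p],
      minus = which(ok_r) - 1L, minus_mm = mm_r[ok_r]
    )
  }

  rows <- list()
  for (ci in seq_len(nrow(genome))) {
    chrom <- genome$id[ci]
    gseq <- genome$seq[ci]
    gchars <- strsplit(gseq, "", fixed = TRUE)[[1]]
    fs <- scan_sites(gchars, fwd)
    rs <- scan_sites(gchars, rev)
    lf <- nchar(fwd)
    lr <- nchar(rev)

    emit <- function(left_starts, left_mm, left_len, right_starts, right_mm,
                     right_len, strand, left_is_f) {
      for (i in seq_along(left_starts)) {
        for (j in seq_along(right_starts)) {
          s <- left_starts[i]
          e <- right_starts[j] + right_len
          if (right_starts[j] >= s + left_len &&
            e - s >= min_product && e - s <= max_product) {
            rows[[length(rows) + 1L]] <<- tibble(
              chrom = chrom, start = s, end = e, strand = strand,
              f_mm = as.integer(if (left_is_f) left_mm[i] else right_mm[j]),
              r_mm = as.integer(if (left_is_f) right_mm[j] else left_mm[i]),
              seq = substring(gseq, s + 1L, e)
            )
          }
        }
      }
    }
    emit(fs$plus, fs$plus_mm, lf, rs$minus, rs$minus_mm, lr, "+", TRUE)
    emit(rs$plus, rs$plus_mm, lr, fs$minus, fs$minus_mm, lf, "-", FALSE)
  }

  out <- bind_rows(rows)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), product_len = integer(), f_mm = integer(),
      r_mm = integer(), seq = character(), name = character()
    ))
  }
  out |>
    distinct(.data$chrom, .data$start, .data$end, .data$strand, .keep_all = TRUE) |>
    mutate(
      start = as.integer(.data$start), end = as.integer(.data$end),
      product_len = as.integer(.data$end - .data$start),
      name = paste0(pair_name, "_", .data$product_len)
    ) |>
    select(
      "chrom", "start", "end", "strand", "product_len",
      "f_mm", "r_mm", "seq", "name"
    ) |>
    arrange(.data$chrom, .data$start, .data$end, .data$strand)
}
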