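#' Percent GC content of primer sequences
#'
#' @param seq Character vector of DNA sequences (no `N`).
#' @return Numeric vector, `100 * (#G + #C) / length`, rounded half-up to one
#'   decimal (the convention used in primer tables).
#' @examples
#' gc_percent("GACATCTACACCGAAAACCC") # 50.0
#' @export
gc_percent <- function(seq) {
  seq <- normalize_seq(seq)
  assert_dna(seq, what = "primer", allow_n = FALSE)
  gc <- nchar(gsub("[AT]", "", seq))
  round_half_up(100 * gc / nchar(seq), 1)
}

# SantaLucia unified nearest-neighbor parameters:
# dH kcal/mol, dS cal/(mol K), 5'->3' dinucleotides (complements share values)
NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
NN_INIT_GC <- c(dh = 0.1, ds = -2.8)
NN_INIT_AT <- c(dh = 2.3, ds = 4.1)

#' Primer melting temperature
#'
#' Two standard methods are available. `wallace` is the rule-of-thumb
#' `2(A+T) + 4(G+C)`. `nn_santalucia` is the unified nearest-neighbor model
#' (duplex dH/dS summed over dinucleotide stacks plus terminal initiation
#' terms), with the entropic salt correction `0.368 (N-1) ln[Na+]` and
#' `Tm = 1000 dH / (dS_salt + R ln(Ct/4)) - 273.15` for non-self-complementary
#' primers in excess over template.
#'
#' @param seq Character vector of DNA sequences (no `N`).
#' @param method `"wallace"` or `"nn_santalucia"`.
#' @param na_mM Monovalent cation concentration in mM (nearest-neighbor
#'   method only).
#' @param primer_nM Total primer concentration in nM (nearest-neighbor
#'   method only).
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' melting_temperature("AAAA", method = "wallace") # 8
#' @export
melting_temperature <- function(seq, method = c("wallace", "nn_santalucia"),
                                na_mM = 50, primer_nM = 500) {
  method <- match.arg(method)
  seq <- normalize_seq(seq)
  assert_dna(seq, what = "primer", allow_n = FALSE)
  if (method == "wallace") {
    gc <- nchar(gsub("[AT]", "", seq))
    at <- nchar(seq) - gc
    return(2 * at + 4 * gc)
  }
  purrr::map_dbl(seq, function(s) {
    n <- nchar(s)
    if (n < 2) abort("nearest-neighbor Tm needs >= 2 bases")
    stacks <- substring(s, 1:(n - 1), 2:n)
    ends <- c(substring(s, 1, 1), substring(s, n, n))
    init <- purrr::map(ends, function(b) {
      if (b %in% c("G", "C")) NN_INIT_GC else NN_INIT_AT
    })
    dh <- sum(NN_DH[stacks]) + sum(purrr::map_dbl(init, "dh"))
    ds <- sum(NN_DS[stacks]) + sum(purrr::map_dbl(init, "ds"))
    ds_salt <- ds + 0.368 * (n - 1) * log(na_mM / 1000)
    r_gas <- 1.987 # cal/(mol K)
    ct <- primer_nM * 1e-9
    1000 * dh / (ds_salt + r_gas * log(ct / 4)) - 273.15
  })
}

#' Design constraints for primer pairs
#'
#' @param len_range Allowed primer length (min, max) in nt.
#' @param gc_range Allowed %GC (min, max).
#' @param tm_method Melting-temperature method, see [melting_temperature()].
#' @param tm_range Optional allowed Tm window in degrees C (`NULL` = no Tm
#'   filter; pairs are still ranked by Tm balance).
#' @param require_diag_in_3prime_k Optional integer: if set, each primer's
#'   discriminating base must lie within the last `k` bases of its 3' end
#'   (allele-specific-PCR placement). Default `NULL`: a discriminating base
#'   anywhere in the footprint suffices.
#' @param product_range Allowed product length (min, max) in bp; the default
#'   spans the short products favoured for qPCR amplicons on repeats.
#' @return List of class `design_constraints`.
#' @export
design_constraints <- function(len_range = c(18L, 22L),
                               gc_range = c(35, 60),
                               tm_method = "wallace",
                               tm_range = NULL,
                               require_diag_in_3prime_k = NULL,
                               product_range = c(50L, 200L)) {
  if (len_range[1] > len_range[2] || gc_range[1] > gc_range[2] ||
    product_range[1] > product_range[2]) {
    abort("constraint ranges must be non-empty")
  }
  if (len_range[1] < 15 || len_range[2] > 35) {
    abort("primer lengths must lie within 15-35 nt")
  }
  structure(
    list(
      len_range = as.integer(len_range), gc_range = gc_range,
      tm_method = tm_method, tm_range = tm_range,
      require_diag_in_3prime_k = require_diag_in_3prime_k,
      product_range = as.integer(product_range)
    ),
    class = "design_constraints"
  )
}

# enumerate footprints of lengths in len_range that cover >= 1 position in
# `diag`, within [lo, hi); returns tibble(start, end)
enumerate_footprints <- function(diag, lo, hi, len_range) {
  out <- purrr::map(seq(len_range[1], len_range[2]), function(l) {
    starts <- unique(unlist(purrr::map(diag, function(p) {
      a <- max(lo, p - l + 1L)
      b <- min(p, hi - l)
      if (a > b) integer(0) else a:b
    })))
    if (length(starts) == 0) {
      return(NULL)
    }
    tibble(start = as.integer(starts), end = as.integer(starts + l))
  })
  distinct(bind_rows(out))
}

#' Design ranked primer pairs for candidate regions
#'
#' Enumerates every forward/reverse footprint placement inside each candidate
#' region such that each footprint covers at least one discriminating
#' position, both primers satisfy the length/GC(/Tm) constraints, and the
#' footprints do not overlap. The forward primer is the consensus substring;
#' the reverse primer is the reverse complement of its template footprint.
#' Pairs are ranked by Tm balance (`|Tm_F - Tm_R|` ascending), then combined
#' closeness of %GC to 50, then leftmost placement — a deterministic order.
#'
#' @param regions Candidate-region tibble from
#'   [enumerate_candidate_regions()] (one or more rows).
#' @param target_consensus The target subfamily's ungapped consensus
#'   sequence (single string).
#' @param constraints A [design_constraints()] object.
#' @return Tibble of primer pairs: footprints, sequences, per-primer %GC and
#'   Tm, `product_len` (`rev_end - fwd_start`), and `rank` within each
#'   region's pool (1 = best).
#' @export
design_pairs <- function(regions, target_consensus,
                         constraints = design_constraints()) {
  stopifnot(inherits(constraints, "design_constraints"))
  target_consensus <- normalize_seq(target_consensus)
  empty <- tibble(
    target = character(), region_start = integer(), region_end = integer(),
    fwd_start = integer(), fwd_end = integer(), rev_start = integer(),
    rev_end = integer(), fwd_seq = character(), rev_seq = character(),
    fwd_gc = numeric(), rev_gc = numeric(), fwd_tm = numeric(),
    rev_tm = numeric(), product_len = integer(), rank = integer()
  )
  if (nrow(regions) == 0) {
    return(empty)
  }
  if (max(regions$end) > nchar(target_consensus)) {
    abort("candidate region extends past the end of the target consensus")
  }

  per_region <- purrr::pmap(regions, function(target, start, end,
                                              left_start, left_end,
                                              right_start, right_end,
                                              left_diag, right_diag, ...) {
    fwd <- enumerate_footprints(left_diag, start, end, constraints$len_range)
    rev <- enumerate_footprints(right_diag, start, end, constraints$len_range)
    if (nrow(fwd) == 0 || nrow(rev) == 0) {
      return(NULL)
    }

    prep <- function(fp, orientation, diag) {
      fp$seq <- substring(target_consensus, fp$start + 1L, fp$end)
      if (orientation == "R") fp$seq <- reverse_complement(fp$seq)
      keep <- !grepl("N", fp$seq, fixed = TRUE)
      fp <- fp[keep, , drop = FALSE]
      if (nrow(fp) == 0) {
        return(fp)
      }
      k <- constraints$require_diag_in_3prime_k
      if (!is.null(k)) {
        # 3' end sits at the footprint's right edge for F, left edge for R
        ok <- purrr::map2_lgl(fp$start, fp$end, function(s, e) {
          if (orientation == "F") {
            any(diag >= e - k & diag < e)
          } else {
            any(diag >= s & diag < s + k)
          }
        })
        fp <- fp[ok, , drop = FALSE]
        if (nrow(fp) == 0) {
          return(fp)
        }
      }
      fp$gc <- gc_percent(fp$seq)
      fp <- fp[fp$gc >= constraints$gc_range[1] & fp$gc <= constraints$gc_range[2], , drop = FALSE]
      if (nrow(fp) == 0) {
        return(fp)
      }
      fp$tm <- melting_temperature(fp$seq, method = constraints$tm_method)
      if (!is.null(constraints$tm_range)) {
        fp <- fp[fp$tm >= constraints$tm_range[1] & fp$tm <= constraints$tm_range[2], , drop = FALSE]
      }
      fp
    }

    fwd <- prep(fwd, "F", left_diag)
    rev <- prep(rev, "R", right_diag)
    if (nrow(fwd) == 0 || nrow(rev) == 0) {
      return(NULL)
    }

    pairs <- tidyr::crossing(
      rename(fwd, fwd_start = "start", fwd_end = "end", fwd_seq = "seq", fwd_gc = "gc", fwd_tm = "tm"),
      rename(rev, rev_start = "start", rev_end = "end", rev_seq = "seq", rev_gc = "gc", rev_tm = "tm")
    ) |>
      filter(.data$rev_start >= .data$fwd_end) |>
      mutate(
        target = target, region_start = start, region_end = end,
        product_len = .data$rev_end - .data$fwd_start
      ) |>
      filter(
        .data$product_len >= constraints$product_range[1],
        .data$product_len <= constraints$product_range[2]
      )
    pairs
  })

  pairs <- bind_rows(per_region)
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(empty)
  }
  pairs |>
    mutate(
      tm_diff = abs(.data$fwd_tm - .data$rev_tm),
      gc_off = abs(.data$fwd_gc - 50) + abs(.data$rev_gc - 50)
    ) |>
    arrange(.data$tm_diff, .data$gc_off, .data$fwd_start, .data$rev_start) |>
    mutate(rank = row_number()) |>
    select(
      "target", "region_start", "region_end", "fwd_start", "fwd_end",
      "rev_start", "rev_end", "fwd_seq", "rev_seq", "fwd_gc", "rev_gc",
      "fwd_tm", "rev_tm", "product_len", "rank"
    )
}
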