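#' Parameters for the repeat-lineage simulator
#'
#' The simulator emulates a lineage like the primate LINE1 L1PA series: a
#' youngest consensus from which progressively older subfamilies derive by
#' stepwise substitution, and a genome carrying individually diverged,
#' optionally 5'-truncated copies of every subfamily.
#'
#' @param n_subfamilies Number of subfamilies (>= 2), youngest first.
#' @param consensus_length Consensus length in bp (>= 100; shorter sequences
#'   cannot host a primer pair).
#' @param step_substitution_rate Per-site substitution probability between
#'   adjacent subfamilies in the lineage.
#' @param copies_per_subfamily Number of genomic copies planted per subfamily.
#' @param copy_divergence Per-site substitution probability applied
#'   independently to each planted copy.
#' @param truncation_prob Probability that a planted copy is 5'-truncated
#'   (most genomic LINE1 copies are).
#' @param truncation_range Fraction interval of consensus length removed from
#'   the 5' end of a truncated copy.
#' @param genome_length Length of the random background sequence into which
#'   copies are spliced (the final genome is longer by the summed copy
#'   lengths).
#' @param seed Integer seed; fully determines all simulator output.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_subfamilies = 6L,
                       consensus_length = 7000L,
                       step_substitution_rate = 0.02,
                       copies_per_subfamily = 30L,
                       copy_divergence = 0.03,
                       truncation_prob = 0.5,
                       truncation_range = c(0.1, 0.9),
                       genome_length = 300000L,
                       seed = 1L) {
  p <- list(
    n_subfamilies = as.integer(n_subfamilies),
    consensus_length = as.integer(consensus_length),
    step_substitution_rate = step_substitution_rate,
    copies_per_subfamily = as.integer(copies_per_subfamily),
    copy_divergence = copy_divergence,
    truncation_prob = truncation_prob,
    truncation_range = truncation_range,
    genome_length = as.integer(genome_length),
    seed = as.integer(seed)
  )
  rates <- c(p$step_substitution_rate, p$copy_divergence, p$truncation_prob, p$truncation_range)
  if (any(rates < 0 | rates > 1)) {
    abort("all rates and fractions must lie in [0, 1]")
  }
  if (p$n_subfamilies < 2) abort("n_subfamilies must be >= 2")
  if (p$consensus_length < 100) {
    abort("consensus_length must be >= 100 (too short to host primer pairs)")
  }
  if (p$truncation_range[1] > p$truncation_range[2]) {
    abort("truncation_range must be increasing")
  }
  if (p$copies_per_subfamily < 0 || p$genome_length < 1) {
    abort("copies_per_subfamily must be >= 0 and genome_length >= 1")
  }
  structure(p, class = "sim_params")
}

# substitute each site independently with probability `rate`, always to a
# different base (uniform over the 3 alternatives)
mutate_seq <- function(chars, rate) {
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) > 0) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    idx <- (match(chars[hit], DNA_BASES) - 1L + shift) %% 4L + 1L
    chars[hit] <- DNA_BASES[idx]
  }
  chars
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a lineage of progressively diverged subfamily consensuses
#'
#' Subfamily `i + 1` derives from subfamily `i` by i.i.d. substitutions at
#' `step_substitution_rate` per site; names are ordered youngest to oldest
#' (`SF01` youngest), mirroring how young repeat subfamilies carry
#' recently-acquired bases that distinguish them from older ones.
#'
#' @param params A [sim_params()] object.
#' @return Sequence tibble (`id`, `seq`) of consensuses, youngest first.
#' @export
simulate_lineage <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_local_seed(params$seed, {
    chars <- sample(DNA_BASES, params$consensus_length, replace = TRUE)
    rows <- vector("list", params$n_subfamilies)
    for (i in seq_len(params$n_subfamilies)) {
      if (i > 1) chars <- mutate_seq(chars, params$step_substitution_rate)
      rows[[i]] <- tibble(
        id = sprintf("SF%02d", i),
        seq = paste(chars, collapse = "")
      )
    }
    bind_rows(rows)
  })
}

#' Plant diverged subfamily copies into a random genome
#'
#' Builds an i.i.d. uniform A/C/G/T background of `genome_length` bp, then
#' splices in `copies_per_subfamily` copies of every consensus at random,
#' non-overlapping positions on random strands. Each copy is independently
#' mutated at `copy_divergence` per site and, with probability
#' `truncation_prob`, loses a uniform fraction in `truncation_range` of its
#' 5' end.
#'
#' @param params A [sim_params()] object.
#' @param consensuses Sequence tibble from [simulate_lineage()].
#' @return List with `genome` (sequence tibble, single chromosome `chr1`),
#'   `annotation` (tibble `chrom`, `start`, `end`, `strand`, `repeat_name`,
#'   `repeat_class`, `repeat_family`), and `truth` (per-copy tibble with the
#'   realized divergence and truncation of every planted copy).
#' @export
plant_copies <- function(params, consensuses) {
  stopifnot(inherits(params, "sim_params"))
  stopifnot(all(c("id", "seq") %in% names(consensuses)))
  with_local_seed(params$seed + 1L, {
    background <- sample(DNA_BASES, params$genome_length, replace = TRUE)
    n_copies <- params$copies_per_subfamily * nrow(consensuses)
    if (n_copies == 0) {
      return(list(
        genome = tibble(id = "chr1", seq = paste(background, collapse = "")),
        annotation = tibble(
          chrom = character(), start = integer(), end = integer(),
          strand = character(), repeat_name = character(),
          repeat_class = character(), repeat_family = character()
        ),
        truth = tibble()
      ))
    }

    copies <- tidyr::expand_grid(
      subfamily = consensuses$id,
      copy = seq_len(params$copies_per_subfamily)
    )
    cons_chars <- lapply(setNames(consensuses$seq, consensuses$id), function(s) {
      strsplit(s, "", fixed = TRUE)[[1]]
    })

    built <- purrr::pmap(copies, function(subfamily, copy) {
      chars <- mutate_seq(cons_chars[[subfamily]], params$copy_divergence)
      n_sub <- sum(chars != cons_chars[[subfamily]])
      truncated <- runif(1) < params$truncation_prob
      trunc_frac <- 0
      if (truncated) {
        trunc_frac <- runif(1, params$truncation_range[1], params$truncation_range[2])
        drop <- max(1L, floor(trunc_frac * length(chars)))
        chars <- chars[-seq_len(drop)]
      }
      strand <- sample(c("+", "-"), 1)
      seq <- paste(chars, collapse = "")
      if (strand == "-") seq <- reverse_complement(seq)
      list(
        subfamily = subfamily, copy = copy, seq = seq, strand = strand,
        realized_divergence = n_sub / params$consensus_length,
        truncated = truncated, trunc_frac = trunc_frac
      )
    })

    # splice copies between background positions; coordinates are exact so
    # annotation intervals equal planted intervals by construction
    cuts <- sort(sample.int(params$genome_length + 1L, n_copies, replace = TRUE) - 1L)
    lens <- purrr::map_int(built, function(b) nchar(b$seq))
    offsets <- cumsum(c(0L, head(lens, -1L)))
    starts <- cuts + offsets
    pieces <- character(2L * n_copies + 1L)
    prev <- 0L
    for (i in seq_len(n_copies)) {
      pieces[2L * i - 1L] <- paste(background[seq_len(cuts[i] - prev) + prev], collapse = "")
      pieces[2L * i] <- built[[i]]$seq
      prev <- cuts[i]
    }
    pieces[2L * n_copies + 1L] <- paste(background[seq(prev + 1L, length.out = params$genome_length - prev)], collapse = "")
    genome_seq <- paste(pieces, collapse = "")

    truth <- tibble(
      copy_id = sprintf("%s_c%03d", copies$subfamily, copies$copy),
      subfamily = purrr::map_chr(built, "subfamily"),
      chrom = "chr1",
      start = starts,
      end = starts + lens,
      strand = purrr::map_chr(built, "strand"),
      realized_divergence = purrr::map_dbl(built, "realized_divergence"),
      truncated = purrr::map_lgl(built, "truncated"),
      trunc_frac = purrr::map_dbl(built, "trunc_frac"),
      full_length = lens >= 0.9 * params$consensus_length
    )
    annotation <- tibble(
      chrom = truth$chrom, start = truth$start, end = truth$end,
      strand = truth$strand, repeat_name = truth$subfamily,
      repeat_class = "LINE", repeat_family = "L1"
    )
    list(
      genome = tibble(id = "chr1", seq = genome_seq),
      annotation = annotation,
      truth = truth
    )
  })
}

#' Simulate sequenced-fragment intervals concentrated on chosen loci
#'
#' Emulates the template intervals of properly paired amplicon-seq read
#' pairs: each fragment is drawn from an annotated locus with probability
#' proportional to the weight of the locus' category, then placed uniformly
#' within the locus.
#'
#' @param annotation Annotation tibble (needs `chrom`, `start`, `end`,
#'   `repeat_name`).
#' @param weights Named numeric vector mapping `repeat_name` categories to
#'   sampling weight; loci whose category is absent get weight 0.
#' @param n_fragments Number of fragments to draw.
#' @param frag_len Fragment length in bp.
#' @param seed Integer seed.
#' @return Interval tibble (`chrom`, `start`, `end`, `name`, `strand`) with
#'   `name` = the source locus' category.
#' @export
simulate_fragments <- function(annotation, weights, n_fragments, frag_len = 150L, seed = 1L) {
  validate_intervals(annotation, "annotation")
  w <- unname(weights[match(annotation$repeat_name, names(weights))])
  w[is.na(w)] <- 0
  if (all(w == 0)) abort("all locus weights are zero")
  if (n_fragments == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), strand = character()
    ))
  }
  with_local_seed(seed, {
    rows <- sample.int(nrow(annotation), n_fragments, replace = TRUE, prob = w)
    lo <- annotation$start[rows]
    hi <- pmax(lo, annotation$end[rows] - frag_len)
    start <- lo + floor(runif(n_fragments) * (hi - lo + 1L))
    tibble(
      chrom = annotation$chrom[rows],
      start = as.integer(start),
      end = as.integer(start + frag_len),
      name = annotation$repeat_name[rows],
      strand = annotation$strand[rows] %||% "."
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
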