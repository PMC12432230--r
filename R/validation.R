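#' Per-category report for sequenced fragments
#'
#' Amplicon-seq readout: assigns every fragment (the template interval of a
#' properly paired read pair) to an annotation category by majority overlap
#' and tabulates counts/percentages, exactly as [selectivity_report()] does
#' for predicted amplicons. With `stranded = TRUE` only fragments whose
#' orientation matches the annotated element count toward it (RNA-seq mode);
#' the default is unstranded, appropriate for double-stranded PCR products.
#'
#' @param fragments Interval tibble of fragments; duplicates allowed (PCR
#'   duplicates are retained in amplicon-seq).
#' @param annotations Annotation tibble with `repeat_name`.
#' @param lineage_names Subfamily labels of the lineage under study.
#' @param stranded Count only strand-matched overlaps.
#' @return A `category_report` (see [selectivity_report()]).
#' @export
count_fragments_by_category <- function(fragments, annotations, lineage_names,
                                        stranded = FALSE) {
  if (nrow(fragments) == 0) {
    return(new_category_report(integer(0), lineage_names))
  }
  cat <- assign_interval(fragments, annotations, lineage_names, stranded = stranded)
  new_category_report(table(cat), lineage_names)
}

#' Call amplified loci from fragment pileups
#'
#' Merges overlapping fragments into maximal intervals and retains an
#' interval when at least `min_support` fragments overlap it — the
#' operational definition of an "amplified locus" in amplicon-seq: a genomic
#' site with reproducible fragment support rather than a stray alignment.
#'
#' @param fragments Interval tibble of fragments.
#' @param min_support Minimum number of supporting fragments (inclusive,
#'   "at least").
#' @return Tibble of loci sorted by coordinate: `chrom`, `start`, `end`,
#'   `support`.
#' @export
call_amplified_loci <- function(fragments, min_support = 3L) {
  if (min_support < 1) abort("min_support must be >= 1")
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(), support = integer()
  )
  if (nrow(fragments) == 0) {
    return(empty)
  }
  validate_intervals(fragments, "fragments")
  fgr <- intervals_to_granges(fragments)
  GenomicRanges::strand(fgr) <- "*"
  merged <- GenomicRanges::reduce(fgr)
  support <- GenomicRanges::countOverlaps(merged, fgr)
  keep <- support >= min_support
  out <- granges_to_intervals(merged[keep])
  out$support <- as.integer(support[keep])
  out |>
    select("chrom", "start", "end", "support") |>
    arrange(.data$chrom, .data$start, .data$end)
}

#' Intersect amplified loci with annotation tracks
#'
#' @param loci Locus tibble (e.g. from [call_amplified_loci()]).
#' @param tracks An `annotation_tracks` object from
#'   [build_annotation_tracks()].
#' @return Tibble (`track`, `n_loci`): for each track, the number of loci
#'   overlapping it by >= 1 bp. A locus may count in several tracks (the
#'   full-length tracks nest inside `all_line1` by construction).
#' @export
intersect_loci_with_tracks <- function(loci, tracks) {
  stopifnot(inherits(tracks, "annotation_tracks"))
  counts <- purrr::imap(tracks, function(track, name) {
    n <- if (nrow(loci) == 0 || nrow(track) == 0) {
      0L
    } else {
      lgr <- intervals_to_granges(loci)
      tgr <- intervals_to_granges(track)
      GenomicRanges::strand(lgr) <- "*"
      GenomicRanges::strand(tgr) <- "*"
      sum(IRanges::overlapsAny(lgr, tgr))
    }
    tibble(track = name, n_loci = n)
  })
  bind_rows(counts)
}

#' Per-locus FPKM and per-subfamily sums
#'
#' FPKM = `1e9 * count / (length * total_fragments)` per locus (fragments per
#' kilobase of locus per million counted fragments; numerically identical to
#' RPKM when fragments rather than reads are counted). Per-subfamily
#' expression is the sum of FPKM over member loci.
#'
#' @param counts Tibble with one row per locus: `locus` (id), `subfamily`,
#'   `length` (bp, > 0), `count` (fragments).
#' @param total_fragments Total counted fragments used as the denominator;
#'   defaults to `sum(counts$count)`. Must be > 0.
#' @return Object of class `expression_table`: list of tibbles `per_locus`
#'   (`locus`, `subfamily`, `length`, `count`, `fpkm`) and `per_subfamily`
#'   (`subfamily`, `fpkm`).
#' @export
fpkm_per_subfamily <- function(counts, total_fragments = NULL) {
  need <- c("locus", "subfamily", "length", "count")
  if (!all(need %in% names(counts))) {
    abort(sprintf("counts must have columns %s", paste(need, collapse = ", ")))
  }
  if (any(counts$length <= 0)) abort("locus lengths must be > 0")
  total_fragments <- total_fragments %||% sum(counts$count)
  if (total_fragments <= 0) abort("total_fragments must be > 0")
  per_locus <- counts |>
    mutate(fpkm = 1e9 * .data$count / (.data$length * total_fragments)) |>
    select("locus", "subfamily", "length", "count", "fpkm")
  per_subfamily <- per_locus |>
    group_by(.data$subfamily) |>
    summarise(fpkm = sum(.data$fpkm), .groups = "drop")
  structure(
    list(per_locus = per_locus, per_subfamily = per_subfamily),
    class = "expression_table",
    total_fragments = total_fragments
  )
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf(
    "Expression table: %d loci, %d subfamilies, %g counted fragments\n",
    nrow(x$per_locus), nrow(x$per_subfamily), attr(x, "total_fragments")
  ))
  print(x$per_subfamily)
  invisible(x)
}

#' Tidy an expression table (per-locus rows)
#' @param x An `expression_table`.
#' @param ... Unused.
#' @return The per-locus tibble.
#' @method tidy expression_table
#' @export
tidy.expression_table <- function(x, ...) x$per_locus

#' One-row summary of an expression table
#' @param x An `expression_table`.
#' @param ... Unused.
#' @return Tibble with locus/subfamily counts and the total FPKM.
#' @method glance expression_table
#' @export
glance.expression_table <- function(x, ...) {
  tibble(
    n_loci = nrow(x$per_locus),
    n_subfamilies = nrow(x$per_subfamily),
    total_fragments = attr(x, "total_fragments"),
    total_fpkm = sum(x$per_locus$fpkm)
  )
}

#' Bar chart of per-subfamily expression
#' @param object An `expression_table`.
#' @param ... Unused.
#' @return A ggplot of summed FPKM per subfamily.
#' @method autoplot expression_table
#' @export
autoplot.expression_table <- function(object, ...) {
  df <- object$per_subfamily
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subfamily, y = .data$fpkm)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "summed FPKM") +
    ggplot2::theme_minimal()
}
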