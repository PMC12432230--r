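#' Build the four standard repeat annotation tracks
#'
#' Produces the track set used to summarise amplicon-seq results against a
#' LINE1-style annotation: (i) all annotated elements (merged), (ii) the
#' genomic complement, (iii) full-length elements (record length strictly
#' greater than `full_length_min`, >6 kb by default for genomic LINE1s), and
#' (iv) the subset of full-length elements that intersect a supplied set of
#' intact loci.
#'
#' @param annotations Annotation tibble (`chrom`, `start`, `end`, plus
#'   `repeat_name`); all records are treated as members of the repeat family
#'   of interest.
#' @param chrom_sizes Named integer vector, chromosome name to length; must
#'   cover every annotated chromosome.
#' @param intact_loci Optional interval tibble of independently curated
#'   intact loci; `NULL` means no intactness evidence, so the intact track is
#'   empty.
#' @param full_length_min Minimum record length (exclusive) for the
#'   full-length track, in bp.
#' @return Object of class `annotation_tracks`: a named list of interval
#'   tibbles `all_line1`, `non_line1`, `full_length`, `full_length_intact`.
#'   Satisfies `full_length_intact` within `full_length` within `all_line1`,
#'   and `all_line1` + `non_line1` partition the genome.
#' @export
build_annotation_tracks <- function(annotations, chrom_sizes,
                                    intact_loci = NULL,
                                    full_length_min = 6000L) {
  validate_intervals(annotations, "annotations")
  missing_chrom <- setdiff(unique(annotations$chrom), names(chrom_sizes))
  if (length(missing_chrom) > 0) {
    abort(sprintf("annotation chromosome '%s' absent from chrom_sizes", missing_chrom[1]))
  }
  seqinfo <- GenomeInfoDb::Seqinfo(
    seqnames = names(chrom_sizes),
    seqlengths = as.integer(chrom_sizes)
  )
  gr <- GenomicRanges::GRanges(
    seqnames = factor(annotations$chrom, levels = names(chrom_sizes)),
    ranges = IRanges::IRanges(start = annotations$start + 1L, end = annotations$end),
    strand = "*",
    seqinfo = seqinfo
  )

  all_line1 <- GenomicRanges::reduce(gr)
  non_line1 <- GenomicRanges::gaps(all_line1)
  non_line1 <- non_line1[GenomicRanges::strand(non_line1) == "*"]

  fl_records <- gr[GenomicRanges::width(gr) > full_length_min]
  full_length <- GenomicRanges::reduce(fl_records)

  if (!is.null(intact_loci) && nrow(intact_loci) > 0) {
    igr <- intervals_to_granges(intact_loci)
    GenomicRanges::strand(igr) <- "*"
    keep <- IRanges::overlapsAny(full_length, igr)
    full_length_intact <- full_length[keep]
  } else {
    full_length_intact <- full_length[0]
  }

  structure(
    list(
      all_line1 = granges_to_intervals(all_line1),
      non_line1 = granges_to_intervals(non_line1),
      full_length = granges_to_intervals(full_length),
      full_length_intact = granges_to_intervals(full_length_intact)
    ),
    class = "annotation_tracks"
  )
}

#' Assign intervals to annotation categories by majority overlap
#'
#' Each interval is assigned to the annotation record it shares the most
#' base pairs with (ties broken by longer annotation record, then
#' lexicographic `repeat_name`, which makes the result invariant to
#' annotation order). The winner's `repeat_name` is the category if it is in
#' `lineage_names`; other repeat names map to `other_LINE1`; intervals with
#' no overlap map to `non_LINE1`.
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`, optional
#'   `strand`).
#' @param annotations Annotation tibble with `repeat_name`.
#' @param lineage_names Subfamily labels of the lineage under study.
#' @param stranded If `TRUE`, only same-strand overlaps count (RNA-seq style
#'   strand-matched assignment); default `FALSE` for double-stranded PCR
#'   products.
#' @return Character vector of categories, one per input interval.
#' @export
assign_interval <- function(intervals, annotations, lineage_names,
                            stranded = FALSE) {
  validate_intervals(intervals, "intervals")
  if (nrow(intervals) == 0) {
    return(character(0))
  }
  category <- rep("non_LINE1", nrow(intervals))
  if (nrow(annotations) == 0) {
    return(category)
  }
  qgr <- intervals_to_granges(intervals)
  sgr <- intervals_to_granges(annotations)
  if (!stranded) {
    GenomicRanges::strand(qgr) <- "*"
    GenomicRanges::strand(sgr) <- "*"
  }
  ov <- GenomicRanges::findOverlaps(qgr, sgr, ignore.strand = !stranded)
  if (length(ov) == 0) {
    return(category)
  }
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  width <- GenomicRanges::width(IRanges::pintersect(qgr[qh], sgr[sh]))
  cand <- tibble(
    q = qh,
    overlap = width,
    ann_len = annotations$end[sh] - annotations$start[sh],
    name = annotations$repeat_name[sh]
  ) |>
    arrange(.data$q, desc(.data$overlap), desc(.data$ann_len), .data$name) |>
    distinct(.data$q, .keep_all = TRUE)
  winner <- cand$name
  category[cand$q] <- ifelse(winner %in% lineage_names, winner, "other_LINE1")
  category
}

new_category_report <- function(counts, lineage_names) {
  categories <- c(lineage_names, "other_LINE1", "non_LINE1")
  total <- sum(counts)
  n <- as.vector(counts)[match(categories, names(counts))]
  n[is.na(n)] <- 0L
  percent <- if (total > 0) round_half_up(100 * n / total, 1) else rep(NA_real_, length(n))
  report <- tibble(category = categories, count = as.integer(n), percent = percent)
  top2 <- if (total > 0) {
    sum(sort(report$percent, decreasing = TRUE)[1:2], na.rm = TRUE)
  } else {
    NA_real_
  }
  structure(report,
    class = c("category_report", class(report)),
    total = as.integer(total), top2_share = top2
  )
}

#' Per-subfamily selectivity report for predicted amplicons
#'
#' Assigns every amplicon to a category via [assign_interval()] and tabulates
#' counts and percentages per category (each lineage subfamily, plus
#' `other_LINE1` and `non_LINE1`). Also records the top-2 category share —
#' the fraction captured by the two predominant (typically closely related)
#' subfamilies, the usual headline selectivity figure.
#'
#' @param amplicons Amplicon tibble (e.g. from [predict_amplicons()]).
#' @param annotations Annotation tibble with `repeat_name`.
#' @param lineage_names Subfamily labels of the lineage under study.
#' @return A `category_report`: a tibble (`category`, `count`, `percent`)
#'   with attributes `total` and `top2_share`; see [glance.category_report()].
#'   With zero amplicons an explicit empty report (total 0, percents `NA`) is
#'   returned.
#' @export
selectivity_report <- function(amplicons, annotations, lineage_names) {
  if (nrow(amplicons) == 0) {
    return(new_category_report(integer(0), lineage_names))
  }
  cat <- assign_interval(amplicons, annotations, lineage_names)
  new_category_report(table(cat), lineage_names)
}

#' Count annotated copies of a subfamily
#'
#' @param annotations Annotation tibble with `repeat_name`.
#' @param subfamily Subfamily label.
#' @param min_len Minimum record length in bp (inclusive).
#' @return Integer count of records with `repeat_name == subfamily` and
#'   length >= `min_len`.
#' @export
copy_number <- function(annotations, subfamily, min_len = 0L) {
  sum(annotations$repeat_name == subfamily &
    (annotations$end - annotations$start) >= min_len)
}

#' @export
print.category_report <- function(x, ...) {
  cat(sprintf(
    "Category report: %d intervals, top-2 category share %.1f%%\n",
    attr(x, "total"), attr(x, "top2_share")
  ))
  NextMethod()
}

#' Tidy a category report
#' @param x A `category_report`.
#' @param ... Unused.
#' @return Plain tibble (`category`, `count`, `percent`).
#' @method tidy category_report
#' @export
tidy.category_report <- function(x, ...) {
  tibble(category = x$category, count = x$count, percent = x$percent)
}

#' One-row summary of a category report
#' @param x A `category_report`.
#' @param ... Unused.
#' @return Tibble with `total`, `top_category`, `top_percent`, `top2_share`.
#' @method glance category_report
#' @export
glance.category_report <- function(x, ...) {
  ord <- order(x$count, decreasing = TRUE)
  tibble(
    total = attr(x, "total"),
    top_category = if (attr(x, "total") > 0) x$category[ord[1]] else NA_character_,
    top_percent = if (attr(x, "total") > 0) x$percent[ord[1]] else NA_real_,
    top2_share = attr(x, "top2_share")
  )
}

#' Bar chart of a category report
#' @param object A `category_report`.
#' @param ... Unused.
#' @return A ggplot: percent of intervals per annotation category.
#' @method autoplot category_report
#' @export
autoplot.category_report <- function(object, ...) {
  df <- tidy(object)
  df$category <- factor(df$category, levels = df$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "% of intervals",
      title = sprintf("Assignment of %d intervals", attr(object, "total"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
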