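#' Find subfamily-discriminating alignment columns
#'
#' A column discriminates the target subfamily when the target's residue is a
#' base (`A`, `C`, `G`, `T`) and differs from the residue of every other
#' subfamily in the comparison set. A gap in a non-target row counts as
#' "different" (a base versus its absence is PCR-discriminating); a gap or
#' `N` in the target row never discriminates, since a primer must physically
#' overlap a defined base.
#'
#' @param alignment Alignment tibble (`id`, `aligned`).
#' @param target Subfamily id whose specific bases are sought.
#' @param comparison Character vector of subfamily ids to compare against
#'   (default: all other rows). Specificity is always relative to this set,
#'   mirroring how primer design for a young subfamily compares it only
#'   against its close relatives.
#' @return Tibble with one row per discriminating column: `column` (0-based
#'   alignment column), `residue` (target base), `consensus_pos` (0-based
#'   position on the target's ungapped consensus), and `residues` (list
#'   column of named per-subfamily residues).
#' @export
find_discriminating_columns <- function(alignment, target, comparison = NULL) {
  stopifnot(all(c("id", "aligned") %in% names(alignment)))
  if (!target %in% alignment$id) {
    abort(sprintf("target '%s' is not a row of the alignment", target))
  }
  comparison <- comparison %||% setdiff(alignment$id, target)
  missing_ids <- setdiff(comparison, alignment$id)
  if (length(missing_ids) > 0) {
    abort(sprintf("comparison subfamily '%s' is not in the alignment", missing_ids[1]))
  }
  comparison <- setdiff(comparison, target)
  rows <- c(target, comparison)
  mat <- seq_char_matrix(alignment$aligned[match(rows, alignment$id)])

  target_chars <- mat[1, ]
  is_base <- target_chars %in% DNA_BASES
  if (length(comparison) == 0) {
    differs_all <- rep(TRUE, ncol(mat))
  } else {
    others <- mat[-1, , drop = FALSE]
    differs_all <- colSums(others == matrix(target_chars,
      nrow = nrow(others), ncol = ncol(others), byrow = TRUE
    )) == 0
  }
  hit <- which(is_base & differs_all)

  consensus_pos <- cumsum(target_chars != "-") - 1L
  tibble(
    column = hit - 1L,
    residue = target_chars[hit],
    consensus_pos = consensus_pos[hit],
    residues = purrr::map(hit, function(j) setNames(mat[, j], rows))
  )
}

#' Enumerate candidate amplicon regions flanked by discriminating bases
#'
#' Scans all pairs of discriminating positions on the target consensus and
#' emits, for every pair that fits, a candidate region whose left primer
#' footprint covers the left position and whose right footprint covers the
#' right position. Regions longer than `max_region_len` are rejected; this
#' default reflects the short (~150-200 bp) products favoured for qPCR on
#' repeat elements.
#'
#' @param diag_positions Integer vector of 0-based discriminating positions
#'   on the target consensus (e.g. `consensus_pos` from
#'   [find_discriminating_columns()]).
#' @param max_region_len Maximum region span in bp.
#' @param footprint_len_range Allowed primer footprint lengths (min, max).
#' @param target Optional target subfamily label carried through to output.
#' @param consensus_length Optional consensus length used to clip footprints.
#' @return Tibble of candidate regions, deduplicated and sorted by
#'   (`start`, `end`, footprint starts): columns `target`, `start`, `end`,
#'   `left_start`, `left_end`, `right_start`, `right_end`, plus list columns
#'   `left_diag` / `right_diag` of discriminating positions inside each
#'   footprint (both always non-empty).
#' @export
enumerate_candidate_regions <- function(diag_positions,
                                        max_region_len = 200L,
                                        footprint_len_range = c(18L, 22L),
                                        target = NA_character_,
                                        consensus_length = NULL) {
  empty <- tibble(
    target = character(), start = integer(), end = integer(),
    left_start = integer(), left_end = integer(),
    right_start = integer(), right_end = integer(),
    left_diag = list(), right_diag = list()
  )
  pos <- sort(unique(as.integer(diag_positions)))
  if (length(pos) < 2) {
    return(empty)
  }
  fl_min <- as.integer(footprint_len_range[1])
  fl_max <- as.integer(footprint_len_range[2])

  pairs <- tidyr::expand_grid(p = pos, q = pos) |> filter(.data$q > .data$p)
  if (nrow(pairs) == 0) {
    return(empty)
  }
  # the region extends fl_max past both discriminating positions so that any
  # footprint placement covering them fits, including placements that put the
  # discriminating base at a primer's 3' terminus
  regions <- pairs |>
    mutate(
      start = pmax(0L, .data$p - fl_max + 1L),
      end = .data$q + fl_max,
      left_start = pmax(0L, .data$p - fl_min + 1L),
      left_end = .data$left_start + fl_min,
      right_start = .data$q,
      right_end = .data$q + fl_min
    ) |>
    filter(
      .data$q > .data$p, # footprints must not overlap
      .data$end - .data$start <= max_region_len
    )
  if (!is.null(consensus_length)) {
    regions <- filter(regions, .data$end <= consensus_length)
  }
  if (nrow(regions) == 0) {
    return(empty)
  }
  regions <- regions |>
    mutate(
      target = target,
      left_diag = purrr::map2(.data$left_start, .data$left_end, function(a, b) pos[pos >= a & pos < b]),
      right_diag = purrr::map2(.data$right_start, .data$right_end, function(a, b) pos[pos >= a & pos < b])
    ) |>
    select(
      "target", "start", "end", "left_start", "left_end",
      "right_start", "right_end", "left_diag", "right_diag"
    ) |>
    distinct(.data$start, .data$end, .data$left_start, .data$right_start, .keep_all = TRUE) |>
    arrange(.data$start, .data$end, .data$left_start, .data$right_start)
  regions
}
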