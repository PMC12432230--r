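#' Read a FASTA file into a sequence tibble
#'
#' Reads plain or gzip-compressed FASTA. Sequences are uppercased, RNA `U` is
#' mapped to `T`, and the alphabet is restricted to `A`, `C`, `G`, `T`, `N`;
#' anything else is a format error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character) and `seq` (character), in
#'   file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ac", "gt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    abort(sprintf("FASTA file '%s' contains no records", path))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    abort(sprintf("FASTA record %d has an empty id", which(!nzchar(ids))[1]))
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id '%s'", ids[duplicated(ids)][1]))
  }
  seqs <- normalize_seq(as.character(set))
  bad <- which(!is_dna(seqs, allow_n = TRUE))
  if (length(bad) > 0) {
    abort(sprintf(
      "FASTA record '%s' is empty or contains non-DNA characters", ids[bad[1]]
    ))
  }
  tibble(id = unname(ids), seq = unname(seqs))
}

#' Write a sequence tibble to FASTA
#'
#' @param x Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  lines <- unlist(purrr::map2(x$id, x$seq, function(id, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3-BED6 file
#'
#' Coordinates are kept 0-based half-open (the native BED convention).
#' Missing BED6 fields are filled with defaults (`name = "."`, `score = 0`,
#' `strand = "."`).
#'
#' @param path Path to a tab-separated BED file.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), score = numeric(), strand = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("BED line %d has fewer than 3 fields", which(nf < 3)[1]))
  }
  get <- function(i, default) {
    purrr::map_chr(fields, function(f) if (length(f) >= i) f[i] else default)
  }
  start <- suppressWarnings(as.integer(get(2, NA)))
  end <- suppressWarnings(as.integer(get(3, NA)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(sprintf(
      "BED line %d: invalid interval (start must be >= 0 and < end)", bad[1]
    ))
  }
  strand <- get(6, ".")
  if (any(!strand %in% c("+", "-", "."))) {
    abort(sprintf(
      "BED line %d: strand must be one of +, -, .",
      which(!strand %in% c("+", "-", "."))[1]
    ))
  }
  tibble(
    chrom = get(1, "."),
    start = start,
    end = end,
    name = get(4, "."),
    score = suppressWarnings(as.numeric(get(5, "0"))),
    strand = strand
  )
}

#' Write intervals as BED6
#'
#' @param x Tibble with at least `chrom`, `start`, `end`; optional `name`,
#'   `score`, `strand` (defaults `"."`, `0`, `"."`).
#' @param path Output path.
#' @return `path`, invisibly. `read_bed(write_bed(x))` reproduces `x` for the
#'   fields present.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, "BED intervals")
  name <- if ("name" %in% names(x)) x$name else "."
  score <- if ("score" %in% names(x)) x$score else 0
  strand <- if ("strand" %in% names(x)) x$strand else "."
  lines <- paste(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
    format(x$end, scientific = FALSE, trim = TRUE),
    name, format(score, scientific = FALSE, trim = TRUE), strand,
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read RepeatMasker .out annotation
#'
#' Parses the standard RepeatMasker `.out` layout (3 header lines, then
#' whitespace-separated columns; query coordinates 1-based inclusive).
#' Coordinates are converted to 0-based half-open at this boundary and strand
#' `C` is mapped to `-`.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return Annotation tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `repeat_name`, `repeat_class`, `repeat_family`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) >= 3) lines <- lines[-seq_len(3)]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), repeat_name = character(),
    repeat_class = character(), repeat_family = character()
  )
  if (length(lines) == 0) {
    return(empty)
  }
  fields <- strsplit(lines, "\\s+")
  nf <- lengths(fields)
  if (any(nf < 11)) {
    abort(sprintf(
      "RepeatMasker .out line %d has %d fields (>= 11 expected)",
      which(nf < 11)[1], min(nf)
    ))
  }
  col <- function(i) purrr::map_chr(fields, i)
  begin <- suppressWarnings(as.integer(col(6)))
  end <- suppressWarnings(as.integer(col(7)))
  if (any(is.na(begin) | is.na(end) | begin < 1 | end < begin)) {
    abort("RepeatMasker .out: malformed query begin/end coordinates")
  }
  strand <- col(9)
  strand[strand == "C"] <- "-"
  classfam <- strsplit(col(11), "/", fixed = TRUE)
  tibble(
    chrom = col(5),
    start = begin - 1L,
    end = end,
    strand = strand,
    repeat_name = col(10),
    repeat_class = purrr::map_chr(classfam, 1),
    repeat_family = purrr::map_chr(classfam, function(x) {
      if (length(x) >= 2) x[2] else NA_character_
    })
  )
}
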