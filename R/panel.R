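#' Reference panel of L1PA subfamily-selective primers
#'
#' Six experimentally validated primer pairs targeting LINE1 L1PA subfamilies
#' of different evolutionary ages (L1HS through L1PA17), shipped with the
#' package as a plain-FASTA fixture. Useful as realistic input for
#' [gc_percent()], [melting_temperature()] and [predict_amplicons()], and as
#' the reference surface for the package's own tests.
#'
#' @return Tibble with columns `pair` (e.g. `"P1"`), `orientation` (`F`/`R`),
#'   `target` (intended subfamily), `seq`, `length`, `gc_percent`.
#' @examples
#' l1pa_primer_panel()
#' @export
l1pa_primer_panel <- function() {
  path <- system.file("extdata", "l1pa_primer_panel.fa", package = "lineprimer")
  set <- Biostrings::readBStringSet(path)
  full_ids <- names(set)
  seqs <- as.character(set)
  tibble(
    pair = sub("_.*$", "", sub("\\s.*$", "", full_ids)),
    orientation = sub("^.*_([FR]).*$", "\\1", sub("\\s.*$", "", full_ids)),
    target = sub("^\\S+\\s+", "", full_ids),
    seq = unname(seqs),
    length = nchar(unname(seqs)),
    gc_percent = gc_percent(unname(seqs))
  )
}
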