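default_config <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    sim = list(
      n_subfamilies = 6L, consensus_length = 7000L,
      step_substitution_rate = 0.02, copies_per_subfamily = 30L,
      copy_divergence = 0.03, truncation_prob = 0.5,
      truncation_range = c(0.1, 0.9), genome_length = 300000L
    ),
    diagnose = list(
      target = NULL, comparison = NULL,
      max_region_len = 200L, footprint_len_range = c(18L, 22L)
    ),
    design = list(
      len_range = c(18L, 22L), gc_range = c(35, 60),
      tm_method = "wallace", tm_range = NULL,
      require_diag_in_3prime_k = 5L,
      max_regions = 40L, max_pairs = 5L
    ),
    ispcr = list(
      max_mismatch = 2L, anchor_len = 5L,
      max_product = 1000L, min_product = 40L
    ),
    score = list(full_length_frac = 0.9),
    validate = list(n_fragments = 1000L, frag_len = 150L, min_support = 3L)
  )
}

check_keys <- function(supplied, defaults, path = "") {
  unknown <- setdiff(names(supplied), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key '%s%s'", path, unknown[1]))
  }
  for (k in names(supplied)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.null(supplied[[k]]) && is.list(supplied[[k]])) {
        check_keys(supplied[[k]], defaults[[k]], paste0(path, k, "$"))
      }
    }
  }
  invisible(TRUE)
}

merge_config <- function(supplied, defaults) {
  for (k in names(supplied)) {
    if (is.list(defaults[[k]]) && is.list(supplied[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(supplied[[k]], defaults[[k]])
    } else {
      # keep explicit NULLs (list assignment would otherwise drop the key)
      defaults[k] <- list(supplied[[k]])
    }
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Returns the default end-to-end configuration, optionally overridden by the
#' named values in `...` (nested lists per stage: `sim`, `diagnose`,
#' `design`, `ispcr`, `score`, `validate`, plus global `seed` and `outdir`).
#' Unknown keys are rejected before any stage runs.
#'
#' @param ... Overrides, e.g. `run_config(seed = 7, sim = list(copies_per_subfamily = 10))`.
#' @return Config list of class `run_config`.
#' @export
run_config <- function(...) {
  supplied <- list(...)
  defaults <- default_config()
  check_keys(supplied, defaults)
  structure(merge_config(supplied, defaults), class = "run_config")
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a validated `run_config`; for
#'   `write_run_config`, `path` invisibly. Configurations round-trip.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A `run_config` object.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

write_tsv_plain <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- purrr::map_chr(df[[j]], function(v) paste(v, collapse = ","))
    }
  }
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Run the full design-and-validation pipeline on simulated data
#'
#' Executes the six stages in order — simulate a lineage and genome, diagnose
#' discriminating columns and candidate regions for the target subfamily,
#' design primer pairs, predict amplicons by in-silico PCR for the top pairs,
#' score each pair's per-subfamily selectivity, and validate a simulated
#' fragment readout (per-category fractions, amplified-locus calling, track
#' intersection). Every stage writes its declared plain-text outputs to
#' `outdir`, and a manifest records the md5 of every file; re-running with
#' the same config reproduces byte-identical outputs.
#'
#' The "best" pair is the evaluated pair whose predicted amplicons have the
#' highest combined share in the target and adjacent-subfamily categories —
#' the same in-silico screening step a primer designer performs before
#' ordering oligos.
#'
#' @param config A [run_config()] object.
#' @param outdir Output directory (created if needed); overrides
#'   `config$outdir`.
#' @return Object of class `lineprimer_run`: list with `manifest`,
#'   `pair_scores`, `best_pair`, `report` (best pair's `category_report`),
#'   `track_counts`, `fragment_report`, `loci`, `consensuses`, `target`,
#'   `config`.
#' @export
run_pipeline <- function(config = run_config(), outdir = config$outdir) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(outdir)) abort("an output directory is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  emit <- function(stage, name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    files <<- c(files, setNames(path, stage))
    path
  }

  # -- stage 1: simulate -----------------------------------------------------
  params <- do.call(sim_params, c(config$sim, list(seed = config$seed)))
  consensuses <- simulate_lineage(params)
  planted <- plant_copies(params, consensuses)
  annotation <- planted$annotation
  genome <- planted$genome
  emit("simulate", "consensus.fa", function(p) write_fasta(consensuses, p))
  emit("simulate", "genome.fa", function(p) write_fasta(genome, p))
  emit("simulate", "annotation.bed", function(p) {
    write_bed(mutate(annotation, name = .data$repeat_name), p)
  })
  emit("simulate", "truth.tsv", function(p) write_tsv_plain(planted$truth, p))

  # -- stage 2: diagnose -----------------------------------------------------
  target <- config$diagnose$target %||% consensuses$id[1]
  comparison <- config$diagnose$comparison %||% setdiff(consensuses$id, target)
  alignment <- progressive_align(consensuses)
  columns <- find_discriminating_columns(alignment, target, comparison)
  target_consensus <- consensuses$seq[consensuses$id == target]
  regions <- enumerate_candidate_regions(
    columns$consensus_pos,
    max_region_len = config$diagnose$max_region_len,
    footprint_len_range = config$diagnose$footprint_len_range,
    target = target,
    consensus_length = nchar(target_consensus)
  )
  emit("diagnose", "columns.tsv", function(p) {
    write_tsv_plain(select(columns, -"residues"), p)
  })
  emit("diagnose", "regions.tsv", function(p) write_tsv_plain(regions, p))

  # -- stage 3: design -------------------------------------------------------
  constraints <- design_constraints(
    len_range = config$design$len_range,
    gc_range = config$design$gc_range,
    tm_method = config$design$tm_method,
    tm_range = config$design$tm_range,
    require_diag_in_3prime_k = config$design$require_diag_in_3prime_k
  )
  use_regions <- head(regions, config$design$max_regions)
  pairs <- design_pairs(use_regions, target_consensus, constraints)
  top_pairs <- pairs |>
    distinct(.data$region_start, .keep_all = TRUE) |>
    head(config$design$max_pairs) |>
    mutate(pair_name = sprintf("%s_pair%d", target, row_number()))
  emit("design", "primers.tsv", function(p) write_tsv_plain(top_pairs, p))
  if (nrow(top_pairs) == 0) {
    abort("design stage produced no primer pairs under the given constraints")
  }

  # -- stage 4: in-silico PCR ------------------------------------------------
  amplicons_by_pair <- purrr::map(seq_len(nrow(top_pairs)), function(i) {
    predict_amplicons(
      genome, top_pairs[i, ],
      max_product = config$ispcr$max_product,
      min_product = config$ispcr$min_product,
      max_mismatch = config$ispcr$max_mismatch,
      anchor_len = config$ispcr$anchor_len,
      pair_name = top_pairs$pair_name[i]
    )
  })

  # -- stage 5: score --------------------------------------------------------
  lineage_names <- consensuses$id
  t_idx <- match(target, lineage_names)
  adjacent <- lineage_names[c(t_idx - 1, t_idx + 1)]
  adjacent <- adjacent[!is.na(adjacent)]
  pair_scores <- purrr::map2(amplicons_by_pair, seq_len(nrow(top_pairs)), function(amp, i) {
    rep <- selectivity_report(amp, annotation, lineage_names)
    tdf <- tidy(rep)
    share <- function(cats) sum(tdf$percent[tdf$category %in% cats], na.rm = TRUE)
    tibble(
      pair_name = top_pairs$pair_name[i],
      n_amplicons = attr(rep, "total"),
      target_percent = if (attr(rep, "total") > 0) share(target) else 0,
      target_or_adjacent_percent = if (attr(rep, "total") > 0) share(c(target, adjacent)) else 0,
      top2_share = attr(rep, "top2_share")
    )
  }) |> bind_rows()
  best_i <- order(-pair_scores$target_or_adjacent_percent, -pair_scores$n_amplicons)[1]
  best_amplicons <- amplicons_by_pair[[best_i]]
  report <- selectivity_report(best_amplicons, annotation, lineage_names)

  chrom_sizes <- setNames(nchar(genome$seq), genome$id)
  tracks <- build_annotation_tracks(
    annotation, chrom_sizes,
    intact_loci = filter(planted$truth, .data$full_length, !.data$truncated) |>
      select("chrom", "start", "end"),
    full_length_min = floor(config$score$full_length_frac * config$sim$consensus_length)
  )
  emit("ispcr", "amplicons.bed", function(p) write_bed(best_amplicons, p))
  emit("score", "pair_scores.tsv", function(p) write_tsv_plain(pair_scores, p))
  emit("score", "report.tsv", function(p) write_tsv_plain(tidy(report), p))
  emit("score", "track_all_line1.bed", function(p) write_bed(tracks$all_line1, p))
  emit("score", "track_full_length.bed", function(p) write_bed(tracks$full_length, p))

  # -- stage 6: validate -----------------------------------------------------
  frag_source <- if (nrow(best_amplicons) > 0) {
    mutate(best_amplicons, repeat_name = .data$name)
  } else {
    mutate(annotation, name = .data$repeat_name)
  }
  frag_weights <- setNames(
    rep(1, length(unique(frag_source$repeat_name))),
    unique(frag_source$repeat_name)
  )
  fragments <- simulate_fragments(
    frag_source, frag_weights,
    n_fragments = config$validate$n_fragments,
    frag_len = config$validate$frag_len,
    seed = config$seed + 2L
  )
  fragment_report <- count_fragments_by_category(fragments, annotation, lineage_names)
  loci <- call_amplified_loci(fragments, min_support = config$validate$min_support)
  track_counts <- intersect_loci_with_tracks(loci, tracks)
  emit("validate", "fragments.bed", function(p) write_bed(fragments, p))
  emit("validate", "loci.bed", function(p) {
    write_bed(mutate(loci, score = .data$support), p)
  })
  emit("validate", "fragment_report.tsv", function(p) write_tsv_plain(tidy(fragment_report), p))
  emit("validate", "track_counts.tsv", function(p) write_tsv_plain(track_counts, p))

  manifest <- tibble(
    stage = names(files),
    file = basename(unname(files)),
    md5 = unname(tools::md5sum(unname(files))),
    bytes = unname(file.size(unname(files)))
  )
  emit("manifest", "manifest.tsv", function(p) write_tsv_plain(manifest, p))

  structure(
    list(
      manifest = manifest,
      pair_scores = pair_scores,
      best_pair = top_pairs[best_i, ],
      amplicons = best_amplicons,
      report = report,
      track_counts = track_counts,
      fragment_report = fragment_report,
      loci = loci,
      consensuses = consensuses,
      target = target,
      config = config
    ),
    class = "lineprimer_run"
  )
}

#' @export
print.lineprimer_run <- function(x, ...) {
  cat(sprintf(
    "lineprimer run: target %s, %d pair(s) evaluated\n",
    x$target, nrow(x$pair_scores)
  ))
  print(x$pair_scores)
  invisible(x)
}

#' One-row summary of a pipeline run
#' @param x A `lineprimer_run`.
#' @param ... Unused.
#' @return Tibble with the best pair's name, amplicon count, target and
#'   target-or-adjacent percentages.
#' @method glance lineprimer_run
#' @export
glance.lineprimer_run <- function(x, ...) {
  best <- x$pair_scores[x$pair_scores$pair_name == x$best_pair$pair_name, ]
  tibble(
    target = x$target,
    best_pair = best$pair_name,
    n_amplicons = best$n_amplicons,
    target_percent = best$target_percent,
    target_or_adjacent_percent = best$target_or_adjacent_percent
  )
}
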