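test_that("annotation tracks implement the full-length and complement rules", {
  ann <- tibble::tibble(
    chrom = "chr1",
    start = c(1000L, 10000L),
    end = c(7500L, 10300L),
    repeat_name = c("L1HS", "L1PA2")
  )
  tr <- build_annotation_tracks(ann, c(chr1 = 20000L))
  expect_equal(nrow(tr$full_length), 1L)
  expect_equal(tr$full_length$start, 1000L)
  # complement partitions the chromosome
  expect_equal(
    sum(tr$all_line1$end - tr$all_line1$start) +
      sum(tr$non_line1$end - tr$non_line1$start),
    20000L
  )
  expect_equal(nrow(tr$full_length_intact), 0L)

  tr2 <- build_annotation_tracks(ann, c(chr1 = 20000L),
    intact_loci = tibble::tibble(chrom = "chr1", start = 1200L, end = 1300L)
  )
  expect_equal(nrow(tr2$full_length_intact), 1L)

  expect_error(build_annotation_tracks(ann, c(chr2 = 5000L)), "chrom_sizes")
})

test_that("interval assignment follows majority overlap with stable tie-breaks", {
  ann <- toy_annotation()
  lineage <- c("L1HS", "L1PA2")
  q <- tibble::tibble(
    chrom = "chr1",
    start = c(150L, 180L, 2000L, 650L),
    end = c(250L, 430L, 2100L, 950L)
  )
  got <- assign_interval(q, ann, lineage)
  expect_equal(got[1], "L1HS") # fully inside
  expect_equal(got[2], "L1HS") # 120 bp on L1HS vs 30 bp on L1PA2
  expect_equal(got[3], "non_LINE1") # unannotated
  expect_equal(got[4], "other_LINE1") # majority on AluY, outside the lineage

  # permutation invariance, including an exact tie broken by name
  tie_ann <- tibble::tibble(
    chrom = "chr1", start = c(0L, 100L), end = c(100L, 200L),
    repeat_name = c("B", "A")
  )
  tie_q <- tibble::tibble(chrom = "chr1", start = 50L, end = 150L)
  expect_equal(assign_interval(tie_q, tie_ann, c("A", "B")), "A")
  expect_equal(assign_interval(tie_q, tie_ann[2:1, ], c("A", "B")), "A")
  set.seed(8)
  shuffled <- ann[sample(nrow(ann)), ]
  expect_equal(assign_interval(q, shuffled, lineage), got)
})

test_that("selectivity report percentages and top-2 share are exact", {
  ann <- toy_annotation()
  lineage <- c("L1HS", "L1PA2")
  amp <- tibble::tibble(
    chrom = "chr1",
    start = c(rep(120L, 7), rep(450L, 2), 5000L),
    end = c(rep(220L, 7), rep(550L, 2), 5100L)
  )
  rep <- selectivity_report(amp, ann, lineage)
  td <- tidy(rep)
  expect_equal(td$count[td$category == "L1HS"], 7L)
  expect_equal(td$percent[td$category == "L1HS"], 70.0)
  expect_equal(td$percent[td$category == "L1PA2"], 20.0)
  expect_equal(td$percent[td$category == "non_LINE1"], 10.0)
  expect_equal(attr(rep, "top2_share"), 90.0)
  expect_equal(sum(td$count), attr(rep, "total"))
  expect_equal(sum(td$percent), 100, tolerance = 0.1)

  one <- selectivity_report(amp[1:3, ], ann, lineage)
  expect_equal(tidy(one)$percent[1], 100.0)

  none <- selectivity_report(amp[0, ], ann, lineage)
  expect_equal(attr(none, "total"), 0L)
  expect_true(all(is.na(tidy(none)$percent)))

  g <- glance(rep)
  expect_equal(g$top_category, "L1HS")
  expect_equal(g$top2_share, 90.0)
})

test_that("copy numbers count annotation records with a length floor", {
  ann <- tibble::tibble(
    chrom = "chr1", start = c(0L, 100L, 300L), end = c(50L, 200L, 6500L),
    repeat_name = c("L1HS", "L1HS", "L1HS")
  )
  expect_equal(copy_number(ann, "L1HS"), 3L)
  expect_equal(copy_number(ann, "L1HS", min_len = 7000), 0L)
  expect_equal(copy_number(ann, "L1PA2"), 0L)

  p <- sim_params(
    n_subfamilies = 3, consensus_length = 300, copies_per_subfamily = 4,
    genome_length = 10000, truncation_prob = 0, seed = 3
  )
  planted <- plant_copies(p, simulate_lineage(p))
  expect_equal(copy_number(planted$annotation, "SF02"), 4L)
})

test_that("category reports plot without error", {
  ann <- toy_annotation()
  amp <- tibble::tibble(chrom = "chr1", start = 120L, end = 220L)
  p <- autoplot(selectivity_report(amp, ann, c("L1HS", "L1PA2")))
  expect_s3_class(p, "ggplot")
})
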