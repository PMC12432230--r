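test_that("fragment category fractions mirror interval assignment", {
  ann <- toy_annotation()
  lineage <- c("L1HS", "L1PA2")
  frags <- tibble::tibble(
    chrom = "chr1",
    start = c(rep(150L, 6), rep(500L, 3), 3000L),
    end = c(rep(250L, 6), rep(600L, 3), 3100L)
  )
  rep <- count_fragments_by_category(frags, ann, lineage)
  td <- tidy(rep)
  expect_equal(td$percent[td$category == "L1HS"], 60.0)
  expect_equal(td$percent[td$category == "L1PA2"], 30.0)
  expect_equal(td$percent[td$category == "non_LINE1"], 10.0)

  off <- dplyr::mutate(frags, start = start + 10000L, end = end + 10000L)
  rep_off <- count_fragments_by_category(off, ann, lineage)
  expect_equal(tidy(rep_off)$percent[tidy(rep_off)$category == "non_LINE1"], 100.0)

  set.seed(4)
  perm <- frags[sample(nrow(frags)), ]
  expect_equal(tidy(count_fragments_by_category(perm, ann, lineage)), td)
})

test_that("strand-matched counting only credits same-strand fragments", {
  ann <- toy_annotation() # L1HS on +, L1PA2 on -
  lineage <- c("L1HS", "L1PA2")
  frags <- tibble::tibble(
    chrom = "chr1", start = c(150L, 150L), end = c(250L, 250L),
    strand = c("+", "-")
  )
  td <- tidy(count_fragments_by_category(frags, ann, lineage, stranded = TRUE))
  expect_equal(td$count[td$category == "L1HS"], 1L)
  expect_equal(td$count[td$category == "non_LINE1"], 1L)
  td2 <- tidy(count_fragments_by_category(frags, ann, lineage, stranded = FALSE))
  expect_equal(td2$count[td2$category == "L1HS"], 2L)
})

test_that("amplified loci require the minimum fragment support", {
  frags <- tibble::tibble(
    chrom = "chr1",
    start = c(100L, 150L, 180L, 5000L, 5050L),
    end = c(300L, 350L, 380L, 5200L, 5250L)
  )
  loci <- call_amplified_loci(frags, min_support = 3)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$support, 3L) # boundary case: exactly three is retained
  expect_equal(loci$start, 100L)
  expect_equal(loci$end, 380L)

  expect_equal(nrow(call_amplified_loci(frags[0, ], 3)), 0L)
  expect_error(call_amplified_loci(frags, 0), "min_support")
})

test_that("locus calling is monotone in support and idempotent under merging", {
  set.seed(19)
  frags <- tibble::tibble(
    chrom = "chr1",
    start = as.integer(sample(0:5000, 120, replace = TRUE))
  ) |> dplyr::mutate(end = start + 150L)
  called <- lapply(1:5, function(k) call_amplified_loci(frags, k))
  for (k in 2:5) {
    prev <- paste(called[[k - 1]]$start, called[[k - 1]]$end)
    cur <- paste(called[[k]]$start, called[[k]]$end)
    expect_true(all(cur %in% prev))
  }
  merged <- call_amplified_loci(frags, 1)
  again <- call_amplified_loci(merged, 1)
  expect_equal(again$start, merged$start)
  expect_equal(again$end, merged$end)
  expect_true(all(again$support == 1L))
})

test_that("called loci coincide with the weighted source loci", {
  ann <- tibble::tibble(
    chrom = "chr1",
    start = c(0L, 10000L, 20000L), end = c(3000L, 13000L, 23000L),
    strand = "+", repeat_name = c("A", "B", "C")
  )
  frags <- simulate_fragments(ann, c(A = 0.5, B = 0.5), 200, frag_len = 200, seed = 12)
  loci <- call_amplified_loci(frags, min_support = 3)
  # every called locus sits inside a weighted source locus, and both are hit
  expect_true(all(loci$start >= 0 & loci$end <= 13000))
  expect_true(any(loci$start < 3000))
  expect_true(any(loci$start >= 10000))
})

test_that("track intersection counts respect track nesting", {
  ann <- tibble::tibble(
    chrom = "chr1", start = c(1000L, 12000L), end = c(8000L, 12400L),
    repeat_name = c("L1HS", "L1PA2")
  )
  tracks <- build_annotation_tracks(
    ann, c(chr1 = 30000L),
    intact_loci = tibble::tibble(chrom = "chr1", start = 2000L, end = 2100L)
  )
  loci <- tibble::tibble(
    chrom = "chr1",
    start = c(1500L, 25000L),
    end = c(1700L, 25200L)
  )
  counts <- intersect_loci_with_tracks(loci, tracks)
  lookup <- setNames(counts$n_loci, counts$track)
  expect_equal(lookup[["all_line1"]], 1L)
  expect_equal(lookup[["full_length"]], 1L)
  expect_equal(lookup[["full_length_intact"]], 1L)
  expect_equal(lookup[["non_line1"]], 1L)

  shuffled <- tracks
  shuffled$all_line1 <- shuffled$all_line1[rev(seq_len(nrow(shuffled$all_line1))), ]
  expect_equal(intersect_loci_with_tracks(loci, shuffled)$n_loci, counts$n_loci)
})

test_that("FPKM follows the formula with additivity and scale invariance", {
  counts <- tibble::tibble(
    locus = c("l1", "l2", "l3"),
    subfamily = c("S1", "S1", "S2"),
    length = c(1000L, 2000L, 500L),
    count = c(10L, 40L, 5L)
  )
  et <- fpkm_per_subfamily(counts, total_fragments = 1e6)
  expect_equal(et$per_locus$fpkm[1], 10.0) # 1e9 * 10 / (1000 * 1e6)
  s1 <- et$per_subfamily$fpkm[et$per_subfamily$subfamily == "S1"]
  expect_equal(s1, sum(et$per_locus$fpkm[1:2]))

  doubled <- dplyr::mutate(counts, count = count * 2L)
  et2 <- fpkm_per_subfamily(doubled, total_fragments = 2e6)
  expect_equal(et2$per_locus$fpkm, et$per_locus$fpkm)

  expect_error(fpkm_per_subfamily(dplyr::mutate(counts, length = 0L)), "length")
  expect_error(fpkm_per_subfamily(counts, total_fragments = 0), "total")

  expect_s3_class(autoplot(et), "ggplot")
  expect_equal(nrow(tidy(et)), 3L)
  expect_equal(glance(et)$n_subfamilies, 2L)
})
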