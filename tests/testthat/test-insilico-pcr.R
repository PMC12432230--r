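test_that("exact binding sites are found on both strands with zero mismatches", {
  set.seed(61)
  primer <- random_dna(20)
  bg <- random_dna(2000)
  g_plus <- tibble::tibble(id = "chr1", seq = paste0(bg, primer, random_dna(100)))
  s <- find_binding_sites(g_plus, primer, max_mismatch = 0)
  expect_equal(nrow(s), 1L)
  expect_equal(s$strand, "+")
  expect_equal(s$start, 2000L)
  expect_equal(s$mismatches, 0L)
  expect_equal(s$end - s$start, 20L)

  g_minus <- tibble::tibble(id = "chr1", seq = paste0(bg, reverse_complement(primer)))
  s2 <- find_binding_sites(g_minus, primer, max_mismatch = 0)
  expect_equal(s2$strand, "-")
})

test_that("mismatches outside the 3' anchor are tolerated, inside are not", {
  set.seed(62)
  primer <- random_dna(20)
  bg <- random_dna(1000)
  # substitution 8 nt from the 3' end (position 13 of 20): outside a 5-nt anchor
  site_mid <- substitute_base(primer, 13)
  g1 <- tibble::tibble(id = "chr1", seq = paste0(bg, site_mid))
  s1 <- find_binding_sites(g1, primer, max_mismatch = 1, anchor_len = 5)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$mismatches, 1L)

  # the same substitution inside the anchor (position 18 of 20)
  site_anchor <- substitute_base(primer, 18)
  g2 <- tibble::tibble(id = "chr1", seq = paste0(bg, site_anchor))
  s2 <- find_binding_sites(g2, primer, max_mismatch = 1, anchor_len = 5)
  expect_equal(nrow(s2), 0L)

  # N in the genome never matches
  g3 <- tibble::tibble(id = "chr1", seq = paste0(bg, substr(primer, 1, 10), "N", substr(primer, 12, 20)))
  s3 <- find_binding_sites(g3, primer, max_mismatch = 0, anchor_len = 5)
  expect_equal(nrow(s3), 0L)

  expect_error(find_binding_sites(g1, "ACGT", anchor_len = 4), "anchor_len")
})

test_that("amplicons require opposing sites within the product window", {
  set.seed(63)
  fwd <- random_dna(20)
  rev <- random_dna(22)
  pair <- list(fwd_seq = fwd, rev_seq = rev)
  bg <- random_dna(3000)

  g <- plant_template(bg, fwd, rev, 1500, random_dna(110))
  amp <- predict_amplicons(g, pair)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$product_len, 20L + 110L + 22L)
  expect_equal(amp$strand, "+")

  # forward site alone
  g_f <- tibble::tibble(id = "chr1", seq = paste0(bg, fwd, random_dna(200)))
  expect_equal(nrow(predict_amplicons(g_f, pair)), 0L)

  # spacing beyond max_product
  g_far <- plant_template(bg, fwd, rev, 1500, random_dna(1200))
  expect_equal(nrow(predict_amplicons(g_far, pair)), 0L)

  # duplicate templates give two amplicons
  g_dup <- plant_template(g$seq[1], fwd, rev, 200, random_dna(80))
  expect_equal(nrow(predict_amplicons(g_dup, pair)), 2L)
})

test_that("a template on the minus strand yields a reverse-orientation product", {
  set.seed(64)
  fwd <- random_dna(20)
  rev <- random_dna(20)
  pair <- list(fwd_seq = fwd, rev_seq = rev)
  template <- paste0(fwd, random_dna(100), reverse_complement(rev))
  g <- tibble::tibble(
    id = "chr1",
    seq = paste0(random_dna(500), reverse_complement(template), random_dna(500))
  )
  amp <- predict_amplicons(g, pair)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$strand, "-")
  expect_equal(amp$product_len, 140L)
  # the product begins with the reverse primer's plus-strand site
  expect_identical(substr(amp$seq, 1, 20), rev)
})

test_that("fast prediction equals the exhaustive oracle on random genomes", {
  set.seed(65)
  for (case in 1:30) {
    mm <- sample(0:2, 1)
    anchor <- sample(c(3L, 5L), 1)
    fwd <- random_dna(sample(18:22, 1))
    rev <- random_dna(sample(18:22, 1))
    bg <- random_dna(6000)
    # plant 0-3 templates, each with a few random substitutions
    for (t in seq_len(sample(0:3, 1))) {
      tpl <- paste0(fwd, random_dna(sample(50:250, 1)), reverse_complement(rev))
      for (v in seq_len(sample(0:2, 1))) {
        tpl <- substitute_base(tpl, sample(nchar(tpl), 1))
      }
      at <- sample(nchar(bg) - 1, 1)
      bg <- paste0(substr(bg, 1, at), tpl, substr(bg, at + 1, nchar(bg)))
    }
    g <- tibble::tibble(id = "chr1", seq = bg)
    pair <- list(fwd_seq = fwd, rev_seq = rev)
    fast <- predict_amplicons(g, pair, max_mismatch = mm, anchor_len = anchor)
    slow <- brute_force_pcr_oracle(g, pair, max_mismatch = mm, anchor_len = anchor)
    expect_equal(as.data.frame(fast), as.data.frame(slow), info = paste("case", case))
  }
})

test_that("reverse-complementing the genome mirrors amplicon coordinates", {
  set.seed(66)
  fwd <- random_dna(20)
  rev <- random_dna(20)
  bg <- random_dna(4000)
  g <- plant_template(bg, fwd, rev, 1000, random_dna(90))
  n <- nchar(g$seq)
  g_rc <- tibble::tibble(id = "chr1", seq = reverse_complement(g$seq))

  a <- predict_amplicons(g, list(fwd_seq = fwd, rev_seq = rev))
  b <- predict_amplicons(g_rc, list(fwd_seq = fwd, rev_seq = rev))
  expect_equal(nrow(a), nrow(b))
  expect_setequal(n - a$end, b$start)
  expect_setequal(n - a$start, b$end)
  expect_setequal(a$product_len, b$product_len)
})

test_that("emitted amplicon sequences satisfy the site rules when re-checked", {
  set.seed(67)
  fwd <- random_dna(20)
  rev <- random_dna(21)
  bg <- random_dna(5000)
  g <- plant_template(bg, substitute_base(fwd, 4), rev, 2500, random_dna(120))
  amp <- predict_amplicons(g, list(fwd_seq = fwd, rev_seq = rev), max_mismatch = 2)
  expect_gt(nrow(amp), 0)
  hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (i in seq_len(nrow(amp))) {
    s <- amp$seq[i]
    left <- substr(s, 1, nchar(fwd))
    right <- substr(s, nchar(s) - nchar(rev) + 1, nchar(s))
    expect_lte(hamming(left, fwd), 2)
    expect_lte(hamming(right, reverse_complement(rev)), 2)
  }
})

test_that("the oracle refuses oversized genomes and handles empty input", {
  big <- tibble::tibble(id = "chr1", seq = strrep("A", 150000))
  expect_error(
    brute_force_pcr_oracle(big, list(fwd_seq = "ACGTACGTACGTACGTACGT", rev_seq = "ACGTACGTACGTACGTACGT")),
    "100 kb"
  )
  none <- tibble::tibble(id = character(), seq = character())
  expect_equal(nrow(brute_force_pcr_oracle(none, list(fwd_seq = "ACGTACGTAC", rev_seq = "ACGTACGTAC"))), 0L)
})
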