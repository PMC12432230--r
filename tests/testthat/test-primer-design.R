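test_that("%GC is computed exactly and rejects undefined bases", {
  expect_equal(gc_percent("GGGG"), 100)
  expect_equal(gc_percent("ATAT"), 0)
  expect_equal(gc_percent("GACATCTACACCGAAAACCC"), 50.0)
  expect_equal(gc_percent("TCGTCAAAATCATTCTCCATCC"), 40.9)
  expect_equal(gc_percent("TCCATTCTCCCCGTCACTTTC"), 52.4)
  expect_error(gc_percent("ACGN"), "primer")
  expect_error(gc_percent(""), "primer")
})

test_that("Wallace rule melting temperatures", {
  expect_equal(melting_temperature("AAAA", "wallace"), 8)
  expect_equal(melting_temperature("GGGG", "wallace"), 16)
  # A+T = 10, G+C = 10 -> 2*10 + 4*10
  expect_equal(melting_temperature("GACATCTACACCGAAAACCC", "wallace"), 60)
})

test_that("nearest-neighbor Tm matches an independent implementation", {
  # frozen from Biopython Tm_NN (SantaLucia unified parameters, Na+ 50 mM,
  # Ct/4 = 125 nM, entropic salt correction)
  expect_equal(melting_temperature("GACATCTACACCGAAAACCC", "nn_santalucia"),
    53.5791, tolerance = 1e-4)
  expect_equal(melting_temperature("TCGTCAAAATCATTCTCCATCC", "nn_santalucia"),
    53.5609, tolerance = 1e-4)
  expect_equal(melting_temperature("ACCAGCCACTGCAAAATC", "nn_santalucia"),
    53.6454, tolerance = 1e-4)
  expect_error(melting_temperature("ACGT", "nearest"), "arg")
})

test_that("reverse complement is correct and involutive", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  set.seed(2)
  x <- replicate(10, random_dna(sample(5:40, 1)))
  expect_equal(reverse_complement(reverse_complement(x)), x)
  expect_error(reverse_complement("ACGX"))
})

test_that("designed primers are consensus substrings meeting all constraints", {
  set.seed(21)
  consensus <- random_dna(400)
  regs <- enumerate_candidate_regions(c(60L, 170L), consensus_length = 400)
  pairs <- design_pairs(regs, consensus)
  expect_gt(nrow(pairs), 0)
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs[i, ]
    expect_identical(substr(consensus, pr$fwd_start + 1, pr$fwd_end), pr$fwd_seq)
    expect_identical(
      substr(consensus, pr$rev_start + 1, pr$rev_end),
      reverse_complement(pr$rev_seq)
    )
  }
  expect_equal(pairs$fwd_gc, gc_percent(pairs$fwd_seq))
  expect_equal(pairs$rev_gc, gc_percent(pairs$rev_seq))
  expect_true(all(pairs$product_len == pairs$rev_end - pairs$fwd_start))
  expect_true(all(pairs$product_len <= 200))
  expect_true(all(pairs$fwd_gc >= 35 & pairs$fwd_gc <= 60))
  # footprints cover the discriminating positions they were built around
  expect_true(all(pairs$fwd_start <= 60 & pairs$fwd_end > 60))
  expect_true(all(pairs$rev_start <= 170 & pairs$rev_end > 170))
  # deterministic ranking
  expect_identical(pairs, design_pairs(regs, consensus))
})

test_that("infeasible GC constraints yield an empty pair list", {
  consensus <- strrep("AT", 200)
  regs <- enumerate_candidate_regions(c(60L, 170L), consensus_length = 400)
  pairs <- design_pairs(regs, consensus, design_constraints(gc_range = c(40, 60)))
  expect_equal(nrow(pairs), 0)
})

test_that("3'-terminal placement of the discriminating base can be required", {
  set.seed(31)
  consensus <- random_dna(400)
  regs <- enumerate_candidate_regions(c(60L, 170L), consensus_length = 400)
  k <- 5L
  pairs <- design_pairs(
    regs, consensus,
    design_constraints(require_diag_in_3prime_k = k)
  )
  expect_gt(nrow(pairs), 0)
  # forward 3' end is the footprint's right edge, reverse 3' end its left edge
  expect_true(all(pairs$fwd_end - 60 <= k & pairs$fwd_end - 60 >= 1))
  expect_true(all(170 - pairs$rev_start < k))
})

test_that("unique feasible placement is returned exactly", {
  # one discriminating pair, product window pinned to the minimum geometry
  consensus <- random_dna(300)
  regs <- enumerate_candidate_regions(c(50L, 120L),
    footprint_len_range = c(18L, 18L), consensus_length = 300
  )
  cons <- design_constraints(
    len_range = c(18L, 18L),
    gc_range = c(0, 100),
    product_range = c(105L, 105L) # forces fwd at [33,51) and rev at [120,138)
  )
  pairs <- design_pairs(regs, consensus, cons)
  # exhaustive check: enumerate all placements covering the two positions
  feasible <- 0L
  for (fs in (50 - 17):50) {
    for (rs in (120 - 17):120) {
      if (rs >= fs + 18 && (rs + 18) - fs == 105) feasible <- feasible + 1L
    }
  }
  expect_equal(nrow(pairs), feasible)
  expect_equal(feasible, 1L)
  expect_equal(pairs$fwd_start, 33L)
  expect_equal(pairs$rev_start, 120L)
})
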