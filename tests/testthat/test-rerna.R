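test_that("read mapping places exact substrings and respects the budget", {
  set.seed(61)
  locus <- random_dna(400)
  reads <- rep(substr(locus, 101, 150), 10)
  prof <- map_reads(reads, locus)
  expect_equal(prof$n_mapped, 10L)
  expect_equal(prof$coverage[101:150], rep(10L, 50))
  expect_equal(sum(prof$coverage), 500L)
  # three mismatches exceed the default budget of two
  r3 <- substr(locus, 101, 150)
  substr(r3, 20, 22) <- chartr("ACGT", "GTAC", substr(r3, 20, 22))
  prof3 <- map_reads(r3, locus)
  expect_equal(prof3$n_unmapped, 1L)
  # ambiguous placements are discarded, and the tally balances
  locus2 <- paste0(locus, substr(locus, 101, 160))
  tie <- substr(locus, 101, 160)
  pt <- map_reads(tie, locus2)
  expect_equal(pt$n_ties, 1L)
  expect_equal(pt$n_mapped + pt$n_unmapped + pt$n_ties, 1L)
})

test_that("boundary calling returns the plateau run containing the peak", {
  prof <- structure(list(coverage = c(rep(0L, 10), rep(20L, 30),
                                      rep(0L, 10)),
                         plateau = 20, locus_id = "x"),
                    class = "rerna_profile")
  cb <- call_boundaries(prof)
  expect_equal(cb$interval, c(11L, 40L))
  expect_equal(cb$length, 30L)
  expect_length(cb$secondary, 0L)
  # two disjoint plateaus: the one holding the maximum wins
  prof2 <- structure(list(coverage = c(rep(0L, 5), rep(20L, 10), rep(0L, 5),
                                       rep(30L, 10), rep(0L, 5)),
                          plateau = median(c(rep(20, 10), rep(30, 10))),
                          locus_id = "x"),
                     class = "rerna_profile")
  cb2 <- call_boundaries(prof2)
  expect_equal(cb2$interval, c(21L, 30L))
  expect_length(cb2$secondary, 1L)
  expect_equal(cb2$secondary[[1]], c(6L, 15L))
  prof0 <- structure(list(coverage = rep(0L, 10), plateau = 0,
                          locus_id = "x"), class = "rerna_profile")
  expect_error(call_boundaries(prof0), "zero")
})

test_that("noise-free simulated reRNAs are called exactly", {
  set.seed(62)
  locus <- random_dna(600)
  sim <- gen_smallrna_reads(smallrna_sim_config(locus, 151, 300,
                                                n_reads = 300,
                                                end_noise_sd = 0, seed = 1))
  prof <- map_reads(sim$reads, locus)
  expect_equal(prof$n_mapped, length(sim$reads))
  expect_equal(prof$coverage, sim$truth$pileup)
  cb <- call_boundaries(prof)
  expect_equal(cb$interval, c(151L, 300L))
})

test_that("extension past a feature is signed and side-aware", {
  expect_equal(extension_beyond(c(101, 265), 250, "right"), 15)
  expect_equal(extension_beyond(c(101, 250), 250, "right"), 0)
  expect_equal(extension_beyond(c(101, 240), 250, "right"), -10)
  expect_equal(extension_beyond(c(101, 265), 110, "left"), 9)
  expect_equal(extension_beyond(c(101, 265), 95, "left"), -6)
})

test_that("pseudoknot register classes WC and wobble pairs antiparallel", {
  seq <- paste0("GAAAC", "AAAAA", "GUUUC")
  pk <- pk_check(seq, c(1, 5), c(11, 15))
  expect_equal(pk$n_wc, 5L)
  expect_equal(pk$n_none, 0L)
  # GU wobble is classed separately
  seq2 <- paste0("GAAAU", "AAAAA", "GUUUC")  # U:G at the first couple
  pk2 <- pk_check(seq2, c(1, 5), c(11, 15))
  expect_equal(pk2$n_wc, 4L)
  expect_equal(pk2$n_gu, 1L)
  # DNA alphabet accepted
  pk3 <- pk_check("GAAACAAAAAGTTTC", c(1, 5), c(11, 15))
  expect_equal(pk3$n_wc, 5L)
  expect_error(pk_check(seq, c(1, 5), c(4, 8)), "overlap")
  expect_error(pk_check(seq, c(1, 5), c(11, 14)), "equal length")
})

test_that("compensatory mutations break and restore pairing exhaustively", {
  base <- paste0("GAAAC", "AAAAA", "GUUUC")
  pk0 <- pk_check(base, c(1, 5), c(11, 15))$n_wc
  for (i in 1:5) {
    ch <- strsplit(base, "")[[1]]
    partner <- 15 - (i - 1)  # antiparallel partner of region A position i
    # disrupt: flip the region A base to its partner's own base
    disrupted <- base
    substr(disrupted, i, i) <- strsplit(base, "")[[1]][partner]
    n1 <- pk_check(disrupted, c(1, 5), c(11, 15))$n_wc
    expect_equal(n1, pk0 - 1L)
    # compensate: flip the partner to restore complementarity
    comp <- disrupted
    substr(comp, partner, partner) <-
      chartr("ACGU", "UGCA", substr(disrupted, i, i))
    n2 <- pk_check(comp, c(1, 5), c(11, 15))$n_wc
    expect_equal(n2, pk0)
  }
})

test_that("guide-relative mutations parse, validate and round-trip", {
  seq <- "AAAAUAAAAA"  # U at position 5
  m <- apply_mutation(seq, "U-3A", guide_start = 8)
  expect_equal(substr(m, 5, 5), "A")
  expect_equal(apply_mutation(m, "A-3U", guide_start = 8), seq)
  expect_error(apply_mutation(seq, "C-3A", guide_start = 8),
               "expected C, found U")
  expect_error(apply_mutation(seq, "U-30A", guide_start = 8), "outside")
  # DNA sequences receive the substitution in their own alphabet
  d <- apply_mutation("AAAATAAAAA", "U-3A", guide_start = 8)
  expect_equal(substr(d, 5, 5), "A")
  d2 <- apply_mutation("AATAAAAAAA", "A-3U", guide_start = 8)
  expect_equal(substr(d2, 5, 5), "T")
})
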