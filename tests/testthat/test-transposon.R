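test_that("IS-family assignment follows the transposase label sets", {
  expect_equal(classify_is_family(c("Y1_Tnp"))$family, "IS200_605")
  expect_equal(classify_is_family(c("Resolvase"))$family, "IS607")
  expect_equal(classify_is_family(c("Y1_Tnp", "transpos_IS607"))$family,
               "CONFLICT")
  expect_equal(classify_is_family(c("ABC_transporter"))$family,
               "UNCLASSIFIED")
  # accessions and case-insensitive names both work
  expect_equal(classify_is_family("pfam01797")$family, "IS200_605")
  expect_equal(classify_is_family("NF033518")$family, "IS607")
  expect_equal(classify_is_family("recombinase")$family, "IS607")
  expect_equal(classify_is_family("transpos_IS607 superfamily")$family,
               "IS607")
  ev <- classify_is_family(c("Y1_Tnp", "kinase"))
  expect_equal(ev$evidence, "Y1_Tnp")
})

test_that("TSD detection recovers planted duplications exactly", {
  loc <- gen_transposon_locus(transposon_sim_config(
    300, tsd_length = 4, flank_length = 60, seed = 21))
  expect_equal(detect_tsd(loc$insertion, loc$truth$element_interval),
               loc$truth$tsd)
  # full planted length range, several seeds each
  for (k in 2:12) {
    loc <- gen_transposon_locus(transposon_sim_config(
      200, tsd_length = k, flank_length = 40, seed = 100 + k))
    expect_equal(nchar(detect_tsd(loc$insertion,
                                  loc$truth$element_interval)), k)
  }
  # IS607 crossover leaves no duplication
  is6 <- gen_transposon_locus(transposon_sim_config(
    300, is_family = "IS607", flank_length = 60, seed = 21))
  expect_null(detect_tsd(is6$insertion, is6$truth$element_interval))
  expect_error(detect_tsd("ACGTACGTAAACGT", c(5, 8)), "k_max")
})

test_that("empty-site verification accepts either TSD-copy removal", {
  loc <- gen_transposon_locus(transposon_sim_config(
    300, tsd_length = 5, flank_length = 60, seed = 31))
  tr <- loc$truth
  expect_true(verify_empty_site(loc$insertion, tr$element_interval,
                                tr$tsd, loc$empty))
  # removing the left TSD copy instead reconstructs the same empty allele
  k <- nchar(tr$tsd)
  alt_empty <- paste0(substr(loc$insertion, 1, tr$element_interval[1] - k - 1),
                      substr(loc$insertion, tr$element_interval[2] + 1,
                             nchar(loc$insertion)))
  expect_identical(alt_empty, loc$empty)
  # a single-nucleotide deletion breaks it
  broken <- paste0(substr(loc$empty, 1, 10), substr(loc$empty, 12,
                                                    nchar(loc$empty)))
  expect_false(verify_empty_site(loc$insertion, tr$element_interval,
                                 tr$tsd, broken))
})

test_that("TIR detection recovers planted repeats and their degeneracy", {
  loc <- gen_transposon_locus(transposon_sim_config(
    400, tsd_length = 4, tir_length = 20, tir_mismatches = 0,
    flank_length = 60, seed = 41))
  hit <- detect_tir(loc$truth$element)
  expect_equal(hit$left, c(1L, 20L))
  expect_equal(hit$right, c(381L, 400L))
  expect_equal(hit$mismatches, 0L)
  loc2 <- gen_transposon_locus(transposon_sim_config(
    400, tsd_length = 4, tir_length = 20, tir_mismatches = 2,
    flank_length = 60, seed = 41))
  expect_equal(detect_tir(loc2$truth$element)$mismatches, 2L)
})

test_that("TIR calls agree with a brute-force existence oracle", {
  set.seed(55)
  for (i in 1:40) {
    el <- random_dna(160)
    got <- detect_tir(el, window = 30, min_len = 8)
    want <- oracle_tir_exists(el, window = 30, min_len = 8)
    expect_equal(!is.null(got), want)
  }
})

test_that("GG crossover flags respond to each boundary independently", {
  is6 <- gen_transposon_locus(transposon_sim_config(
    300, is_family = "IS607", flank_length = 60, seed = 13))
  expect_equal(check_is607_boundaries(is6$insertion,
                                      is6$truth$element_interval),
               c(LE = TRUE, RE = TRUE))
  # GG at LE only
  seq <- paste0(strrep("A", 10), "GGCAT", strrep("A", 5), "CAT",
                strrep("A", 10))
  expect_equal(check_is607_boundaries(seq, c(11, 23)),
               c(LE = TRUE, RE = FALSE))
  # eukaryotic elements carry GG at a junction only by chance (1/16 each)
  set.seed(3)
  flags <- t(replicate(60, {
    loc <- gen_transposon_locus(transposon_sim_config(
      150, tsd_length = 3, tir_length = 10, flank_length = 30,
      seed = sample.int(1e6, 1)))
    check_is607_boundaries(loc$insertion, loc$truth$element_interval)
  }))
  expect_lt(mean(flags), 0.25)
})

test_that("element copy search finds full-identity copies with 2 kb flanks", {
  set.seed(17)
  el <- random_dna(500)
  genome <- paste0(random_dna(3000), el, random_dna(4000), el,
                   random_dna(3000))
  hits <- find_element_copies(genome, el)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$start, c(3001L, 7501L))
  expect_equal(hits$identity, c(1, 1))
  expect_equal(hits$flank_start, c(1001L, 5501L))
  expect_equal(hits$flank_end, c(5500L, 10000L))
  # a diverged copy below the identity floor is not reported
  weak <- local({ set.seed(18); mutate_seq(el, 0.15,
                                           alphabet = c("A", "C", "G", "T")) })
  genome2 <- paste0(random_dna(1000), weak, random_dna(1000))
  expect_equal(nrow(find_element_copies(genome2, el, min_identity = 0.9)),
               0L)
  # flanks clip at contig ends
  genome3 <- paste0(random_dna(100), el, random_dna(100))
  h3 <- find_element_copies(genome3, el)
  expect_equal(h3$flank_start, 1L)
  expect_equal(h3$flank_end, nchar(genome3))
})
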