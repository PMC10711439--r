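test_that("generators are byte-identical across runs for a fixed seed", {
  f1 <- gen_protein_family(protein_family_config(3, 3, seed = 5))
  f2 <- gen_protein_family(protein_family_config(3, 3, seed = 5))
  expect_identical(f1, f2)
  l1 <- gen_transposon_locus(transposon_sim_config(300, flank_length = 50,
                                                   seed = 5))
  l2 <- gen_transposon_locus(transposon_sim_config(300, flank_length = 50,
                                                   seed = 5))
  expect_identical(l1, l2)
  t1 <- gen_tam_reads(tam_sim_config(reads_per_sample = 2000, seed = 5))
  t2 <- gen_tam_reads(tam_sim_config(reads_per_sample = 2000, seed = 5))
  expect_identical(t1, t2)
  t3 <- gen_tam_reads(tam_sim_config(reads_per_sample = 2000, seed = 6))
  expect_false(identical(t1$truth$input_counts, t3$truth$input_counts))
})

test_that("protein-family truth labels are self-consistent with the matcher", {
  for (cls in c("DPG", "DPhiG")) for (ep in c("E_alt", "E_can")) {
    fam <- gen_protein_family(protein_family_config(
      5, 5, cls, ep, seed = 11))
    got <- vapply(fam$seq, function(s) classify_fingerprint(s)$category, "")
    expect_equal(unname(got), fam$class)
  }
})

test_that("zero-noise positives hit their class; DPhiG/E_can never FANZOR_LIKE", {
  fam <- gen_protein_family(protein_family_config(10, 0, "DPG", "E_alt",
                                                  seed = 2))
  expect_true(all(fam$class == "FANZOR_LIKE"))
  fam2 <- gen_protein_family(protein_family_config(10, 0, "DPhiG", "E_can",
                                                   seed = 2))
  got <- vapply(fam2$seq, function(s) classify_fingerprint(s)$category, "")
  expect_false(any(got == "FANZOR_LIKE"))
})

test_that("decoy purity matches a direct oracle scan", {
  set.seed(33)
  decoys <- replicate(500, random_protein(400))
  frac_matcher <- mean(vapply(decoys, function(s)
    classify_fingerprint(s)$category %in% c("FANZOR_LIKE", "E_ALT_DPHIG"),
    logical(1)))
  frac_oracle <- mean(vapply(decoys, function(s)
    oracle_fingerprint(s) %in% c("FANZOR_LIKE", "E_ALT_DPHIG"), logical(1)))
  expect_equal(frac_matcher, frac_oracle)
})

test_that("transposon truth records reconstruct the planted architecture", {
  cfg <- transposon_sim_config(400, tsd_length = 6, tir_length = 24,
                               tir_mismatches = 3, flank_length = 60,
                               seed = 8)
  loc <- gen_transposon_locus(cfg)
  tr <- loc$truth
  el <- substr(loc$insertion, tr$element_interval[1], tr$element_interval[2])
  expect_identical(el, tr$element)
  expect_identical(paste0(substr(loc$insertion, 1,
                                 tr$element_interval[1] - 1),
                          substr(loc$insertion,
                                 tr$element_interval[2] + nchar(tr$tsd) + 1,
                                 nchar(loc$insertion))),
                   loc$empty)
  # IS607: single GG at the empty junction, GG...GG element
  is6 <- gen_transposon_locus(transposon_sim_config(
    300, is_family = "IS607", flank_length = 60, seed = 8))
  fl <- 60
  expect_equal(substr(is6$empty, fl + 1, fl + 2), "GG")
  expect_equal(substr(is6$truth$element, 1, 2), "GG")
  expect_equal(substr(is6$truth$element, nchar(is6$truth$element) - 1,
                      nchar(is6$truth$element)), "GG")
  expect_null(is6$truth$tsd)
})

test_that("undepleted TAM libraries are statistically uniform between samples", {
  hits <- 0L
  for (seed in 1:10) {
    sim <- gen_tam_reads(tam_sim_config(depletion_factor = 1,
                                        reads_per_sample = 100000L,
                                        seed = seed),
                         emit_reads = FALSE)
    p <- suppressWarnings(stats::chisq.test(
      cbind(sim$truth$input_counts, sim$truth$output_counts))$p.value)
    if (p >= 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("degenerate TAM configs produce empty tables and clear errors", {
  sim <- gen_tam_reads(tam_sim_config(reads_per_sample = 0, seed = 1))
  expect_length(sim$input_reads, 0L)
  expect_equal(sum(sim$truth$input_counts), 0L)
  cin <- extract_tams(sim$input_reads, tam_sim_config(seed = 1)$anchor)
  expect_equal(cin$total_extracted, 0L)
  expect_error(depletion_scores(cin, cin), "zero")
})

test_that("paired families carry the coupling signal in their truth record", {
  fam <- gen_paired_families(paired_family_config(30, coupling = 1,
                                                  seed = 4))
  expect_equal(fam$truth$dist_a, fam$truth$dist_b)
  fam0 <- gen_paired_families(paired_family_config(30, coupling = 0,
                                                   seed = 4))
  expect_false(identical(fam0$truth$dist_a, fam0$truth$dist_b))
  expect_equal(nrow(fam$pairing), 30L)
})

test_that("small-RNA reads tile the planted interval and log a pileup", {
  set.seed(14)
  locus <- random_dna(500)
  sim <- gen_smallrna_reads(smallrna_sim_config(locus, 101, 250,
                                                n_reads = 200,
                                                end_noise_sd = 0, seed = 3))
  expect_true(all(sim$reads == substr(locus, 101, 250)))
  expect_equal(max(sim$truth$pileup), 200L)
  expect_equal(sum(sim$truth$pileup > 0), 150L)
  # jittered reads remain substrings of the locus
  simj <- gen_smallrna_reads(smallrna_sim_config(locus, 101, 250,
                                                 n_reads = 50,
                                                 end_noise_sd = 2, seed = 3))
  expect_true(all(vapply(simj$reads, function(r)
    grepl(r, locus, fixed = TRUE), logical(1))))
})

test_that("homolog-ladder rungs sit near their nominal identities", {
  lad <- gen_homolog_ladder(ladder_config(n_per_rung = 10, seed = 6))
  region <- function(s) substr(s, 31, 90)
  anc <- lad$seed_alignment[1]
  for (g in c(0.8, 0.6, 0.4, 0.3)) {
    ids <- lad$truth$id[!is.na(lad$truth$rung) & lad$truth$rung == g]
    obs <- mean(vapply(ids, function(id) {
      a <- strsplit(region(lad$database[[id]]), "")[[1]]
      b <- strsplit(unname(anc), "")[[1]]
      mean(a == b)
    }, numeric(1)))
    expect_lt(abs(obs - g), 0.12)
  }
})
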