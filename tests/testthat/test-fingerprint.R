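make_fanzor <- function(mid = "P", spacer = 120, e_gap = 6, zf1 = 12,
                        zf2 = 4, pre = "", post = "") {
  paste0(pre, "D", mid, "G", strrep("A", spacer), "E", strrep("A", e_gap),
         "CAAC", strrep("A", zf1), "CAAC", strrep("A", zf2), "D", post)
}

test_that("minimal full-pattern instances classify as expected", {
  expect_equal(classify_fingerprint(make_fanzor())$category, "FANZOR_LIKE")
  expect_equal(classify_fingerprint(make_fanzor(mid = "L"))$category,
               "E_ALT_DPHIG")
  # spacer one below the lower bound breaks the arrangement
  expect_false(classify_fingerprint(make_fanzor(spacer = 119))$category %in%
                 c("FANZOR_LIKE", "E_ALT_DPHIG"))
  expect_equal(classify_fingerprint(make_fanzor(spacer = 160))$category,
               "FANZOR_LIKE")
  expect_false(classify_fingerprint(make_fanzor(spacer = 161))$category %in%
                 c("FANZOR_LIKE", "E_ALT_DPHIG"))
})

test_that("RuvC1 motif finder distinguishes DPG, D-phi-G and non-motifs", {
  r <- find_ruvc1("ADPGA")
  expect_equal(nrow(r), 1L)
  expect_equal(r$d_index, 2L)
  expect_equal(r$motif_class, "DPG")
  expect_equal(find_ruvc1("ADLGA")$motif_class, "DPhiG")
  expect_equal(nrow(find_ruvc1("ADKGA")), 0L)  # K outside phi and P
  for (phi in c("I", "L", "F", "W", "Y", "M"))
    expect_equal(find_ruvc1(paste0("AD", phi, "GA"))$motif_class, "DPhiG")
})

test_that("zinc-finger motif finder handles bounds and overlaps", {
  seq <- paste0(strrep("A", 5), "CAAC", strrep("A", 12), "CAAC",
                strrep("A", 4), "D", strrep("A", 5))
  z <- find_zf_motifs(seq)
  expect_equal(nrow(z), 1L)
  expect_equal(z$spacer1, 12L)
  expect_equal(z$spacer2, 4L)
  # spacer bound violations
  bad <- paste0("CAAC", strrep("A", 19), "CAAC", strrep("A", 4), "D")
  expect_equal(nrow(find_zf_motifs(bad)), 0L)
  bad2 <- paste0("CAAC", strrep("A", 12), "CAAC", strrep("A", 9), "D")
  expect_equal(nrow(find_zf_motifs(bad2)), 0L)
  # X never matches the literal C/D anchors but passes wildcard slots
  expect_equal(nrow(find_zf_motifs(sub("^CAAC", "XAAC", bad))), 0L)
  wl <- paste0("CXXC", strrep("X", 12), "CXXC", strrep("X", 4), "D")
  expect_equal(nrow(find_zf_motifs(wl)), 1L)
})

test_that("zinc-finger enumeration matches the substring-scan oracle", {
  set.seed(421)
  for (i in 1:300) {
    # C/D-enriched alphabet so motifs actually occur
    s <- paste(sample(c("A", "C", "D", "E", "G"), 120, replace = TRUE,
                      prob = c(.2, .35, .25, .1, .1)), collapse = "")
    got <- find_zf_motifs(s)
    want <- oracle_zf_motifs(s)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got[, c("c1", "c3", "d_end")],
                   want[, c("c1", "c3", "d_end")])
    }
  }
})

test_that("classification agrees with the regex oracle on random input", {
  set.seed(7)
  n_agree <- 0L
  for (i in 1:2000) {
    s <- random_protein(400)
    expect_equal(classify_fingerprint(s)$category, oracle_fingerprint(s))
  }
  # and on planted positives of every class
  for (seed in 1:10) {
    for (cls in c("DPG", "DPhiG")) for (ep in c("E_alt", "E_can")) {
      fam <- gen_protein_family(protein_family_config(
        3, 0, cls, ep, seed = seed))
      for (s in fam$seq)
        expect_equal(classify_fingerprint(s)$category, oracle_fingerprint(s))
    }
  }
})

test_that("inflating a spacer past its bound never promotes the category", {
  ranks <- c(FANZOR_LIKE = 5, E_ALT_DPHIG = 4, CANONICAL = 3,
             AMBIGUOUS = 2, INCOMPLETE = 1)
  base <- make_fanzor(spacer = 150)
  r0 <- ranks[classify_fingerprint(base)$category]
  for (extra in c(5, 15, 30)) {
    inflated <- make_fanzor(spacer = 150 + extra)
    expect_lte(ranks[classify_fingerprint(inflated)$category], r0)
  }
  wide <- sub("CAAC", paste0("CAAC", strrep("A", 7)), make_fanzor())
  expect_lte(ranks[classify_fingerprint(wide)$category], r0)
})

test_that("scan_database tabulates fractions over all categories", {
  pos <- make_fanzor()
  neg <- strrep("A", 300)
  seqs <- setNames(c(pos, rep(neg, 99)), sprintf("s%03d", 1:100))
  res <- scan_database(seqs)
  expect_equal(unname(res$fractions["FANZOR_LIKE"]), 0.01)
  expect_equal(unname(res$fractions["INCOMPLETE"]), 0.99)
  expect_equal(sum(res$fractions), 1)
  expect_setequal(names(res$fractions),
                  c("FANZOR_LIKE", "E_ALT_DPHIG", "CANONICAL",
                    "AMBIGUOUS", "INCOMPLETE"))
  expect_error(scan_database(setNames(c(pos, pos), c("a", "a"))),
               "unique")
})
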