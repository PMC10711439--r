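test_that("log-odds follow the closed form on identical rows without pseudocount", {
  p <- build_profile(c("ACD", "ACD", "ACD", "ACD"), pseudocount = 0)
  expect_equal(unname(p$log_odds["A", 1]), log2(20))
  expect_equal(unname(p$log_odds["C", 2]), log2(20))
  expect_equal(unname(p$log_odds["D", 3]), log2(20))
  expect_equal(p$column_map, 1:3)
})

test_that("low-occupancy and all-gap columns are masked", {
  p <- build_profile(c("A-C", "A-C", "A-C"))
  expect_equal(p$column_map, c(1L, 3L))
  p2 <- build_profile(c("AAC", "A-C", "A-C", "A-C"), occupancy_min = 0.5)
  expect_equal(p2$column_map, c(1L, 3L))  # 1/4 occupancy below cutoff
  expect_error(build_profile(c("--", "--")), "occupancy")
  expect_error(build_profile(c("AC", "ACD")), "ragged")
})

test_that("log-odds equal the formula evaluated cell by cell", {
  set.seed(9)
  aln <- c(a = "ACDE-", b = "ACDEF", c = "AC-EF", d = "GCDEF")
  beta <- 0.7
  p <- build_profile(aln, pseudocount = beta)
  mat <- do.call(rbind, strsplit(aln, ""))
  q <- 1 / 20
  for (jj in seq_along(p$column_map)) {
    j <- p$column_map[jj]
    col <- mat[, j]; col <- col[col != "-"]
    for (a in c("A", "C", "D", "E", "F", "G", "W")) {
      c_ia <- sum(col == a)
      want <- log2((c_ia + beta * q) / (length(col) + beta) / q)
      expect_equal(unname(p$log_odds[a, jj]), want, tolerance = 1e-12)
    }
  }
})

test_that("searching the consensus attains the per-column maximum bound", {
  set.seed(10)
  rows <- replicate(5, mutate_seq(random_protein(25), 0.05))
  p <- build_profile(rows)
  hit <- search_profile(p, p$consensus)
  expect_equal(hit$score, sum(apply(p$log_odds, 2, max)), tolerance = 1e-9)
  expect_equal(hit$profile_interval, c(1L, ncol(p$log_odds)))
  expect_equal(hit$aligned, p$consensus)
})

test_that("unrelated sequences yield no hit (score floor at zero)", {
  p <- build_profile(c("AAAAAAAA", "AAAAAAAA", "AAAAAAAA"))
  h <- search_profile(p, "WWWWWWWW")
  expect_equal(h$score, 0)
  expect_null(h$seq_interval)
})

test_that("alignment scores equal the exhaustive segment-chain oracle", {
  set.seed(2024)
  for (case in 1:20) {
    m <- sample(4:10, 1)
    n <- sample(8:30, 1)
    rows <- replicate(3, mutate_seq(random_protein(m), 0.1))
    p <- build_profile(rows)
    seq <- if (runif(1) < 0.5) random_protein(n) else
      paste0(random_protein(sample(0:8, 1)),
             mutate_seq(p$consensus, 0.3),
             random_protein(sample(0:8, 1)))
    enc <- match(strsplit(seq, "")[[1]], fanzortrace:::AA_ALPHABET,
                 nomatch = 0L)
    want <- oracle_local_align(p$log_odds, enc, gap_open = -8,
                               gap_extend = -1)
    got <- search_profile(p, seq)$score
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("null calibration at quantile 1 returns the decoy maximum", {
  set.seed(5)
  rows <- replicate(4, mutate_seq(random_protein(30), 0.05))
  p <- build_profile(rows)
  thr_max <- calibrate_threshold(p, n_shuffles = 100, quantile = 1,
                                 seed = 3)
  thr_999 <- calibrate_threshold(p, n_shuffles = 100, quantile = 0.999,
                                 seed = 3)
  expect_gte(thr_max, thr_999)
  # deterministic given the seed
  expect_identical(thr_max,
                   calibrate_threshold(p, n_shuffles = 100, quantile = 1,
                                       seed = 3))
  # few decoys clear the calibrated threshold by construction
  set.seed(77)
  cleared <- sum(vapply(1:200, function(i) {
    d <- paste(sample(strsplit(p$rows[[1]], "")[[1]]), collapse = "")
    search_profile(p, d)$score >= thr_999
  }, logical(1)))
  expect_lte(cleared, 10L)
})

test_that("the multi-domain filter requires every profile to hit", {
  set.seed(21)
  regions <- lapply(1:3, function(i) random_protein(25))
  names(regions) <- c("ZF", "RuvC2", "RuvC3")
  profiles <- lapply(regions, function(r)
    build_profile(vapply(1:5, function(i) mutate_seq(r, 0.05), "")))
  thresholds <- vapply(names(profiles), function(nm)
    calibrate_threshold(profiles[[nm]], 100, seed = 1), numeric(1))
  pos <- paste0(random_protein(10), regions$RuvC2, random_protein(5),
                regions$ZF, random_protein(5), regions$RuvC3,
                random_protein(10))
  res <- multi_profile_filter(pos, profiles, thresholds)
  expect_true(res$pass)
  expect_equal(res$hit_order, c("RuvC2", "ZF", "RuvC3"))
  scrambled <- paste0(random_protein(10), regions$RuvC2, random_protein(5),
                      regions$ZF, random_protein(5),
                      paste(sample(strsplit(regions$RuvC3, "")[[1]]),
                            collapse = ""), random_protein(10))
  expect_false(multi_profile_filter(scrambled, profiles, thresholds)$pass)
})

test_that("searching the seed set itself is a round-1 fixed point", {
  set.seed(3)
  rows <- vapply(1:6, function(i) mutate_seq(random_protein(40), 0.05), "")
  names(rows) <- sprintf("seed_%d", 1:6)
  db <- rows
  names(db) <- sprintf("db_%d", 1:6)
  res <- iterative_search(rows, db, rounds = 5, seed = 2)
  expect_setequal(res$hit_ids_by_round[[1]], names(db))
  expect_equal(res$history$n_new, c(6, 0, 0, 0, 0))
  expect_equal(length(res$alignment), 12L)
})

test_that("hit sets grow monotonically and augmentation reaches further", {
  lad <- gen_homolog_ladder(ladder_config(n_per_rung = 25, seed = 19))
  res <- iterative_search(lad$seed_alignment, lad$database, rounds = 5,
                          seed = 7)
  sizes <- vapply(res$hit_ids_by_round, length, integer(1))
  expect_true(all(diff(sizes) >= 0))
  for (r in 2:5)
    expect_true(all(res$hit_ids_by_round[[r - 1]] %in%
                      res$hit_ids_by_round[[r]]))
  ids40 <- lad$truth$id[!is.na(lad$truth$rung) & lad$truth$rung == 0.4]
  rec <- vapply(res$hit_ids_by_round, function(h)
    mean(ids40 %in% h), numeric(1))
  expect_gte(rec[5], rec[1])
  # no unrelated decoys swept in
  expect_length(grep("decoy", res$hit_ids), 0L)
})
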