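## Iterative PSSM homology search. A position-specific log-odds profile is
## built from a seed alignment of a conserved subdomain, searched against a
## database by affine-gap local alignment, and hit segments are added back
## to the alignment (in profile coordinates) for the next round -- the
## PSI-BLAST-style augmentation loop used to pull in progressively more
## divergent homologs over a fixed number of rounds (default 5).

#' Build a position-specific scoring matrix from an alignment block
#'
#' Per-column, per-residue log-odds in bits:
#' `log2( (c_ia + beta * q_a) / (N_i + beta) / q_a )` with residue counts
#' `c_ia` over non-gap rows, non-gap count `N_i`, pseudocount weight `beta`
#' and background `q_a`. Columns with occupancy (non-gap fraction) below
#' `occupancy_min` are masked out and take no part in scoring.
#'
#' @param alignment named character vector of equal-width gapped rows
#'   (>= 2 rows; `-` and `.` are gaps).
#' @param pseudocount pseudocount weight beta, default 1.
#' @param background named residue frequencies summing to 1; default
#'   uniform 1/20.
#' @param occupancy_min retained-column occupancy cutoff, default 0.5.
#' @return an object of class `pssm_profile`: `log_odds` (residues x
#'   retained columns, bits), `column_map` (retained column -> original
#'   alignment column), `width` (original alignment width), `background`,
#'   `pseudocount`, `consensus` (highest-scoring residue per retained
#'   column) and `rows` (the ungapped source sequences, used for
#'   empirical-null calibration).
#' @export
build_profile <- function(alignment, pseudocount = 1, background = NULL,
                          occupancy_min = 0.5) {
  if (length(alignment) < 2L) stop("alignment needs at least 2 rows")
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L) stop("ragged alignment")
  if (is.null(background))
    background <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  stopifnot(abs(sum(background) - 1) < 1e-9)

  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  mat[mat == "."] <- "-"
  nongap <- mat != "-"
  occupancy <- colMeans(nongap)
  keep <- which(occupancy >= occupancy_min)
  if (length(keep) == 0L) stop("all columns fall below the occupancy cutoff")

  q <- background[AA_ALPHABET]
  beta <- pseudocount
  log_odds <- vapply(keep, function(j) {
    col <- mat[nongap[, j], j]
    counts <- table(factor(col, levels = AA_ALPHABET))
    n <- sum(counts)
    as.numeric(log2((as.numeric(counts) + beta * q) / (n + beta) / q))
  }, numeric(20))
  log_odds <- matrix(log_odds, nrow = 20,
                     dimnames = list(AA_ALPHABET, NULL))
  consensus <- AA_ALPHABET[apply(log_odds, 2, which.max)]
  ungapped <- vapply(seq_len(nrow(mat)),
                     function(i) paste(mat[i, nongap[i, ]], collapse = ""),
                     "")
  structure(list(log_odds = log_odds, column_map = keep,
                 width = widths[1], background = q, pseudocount = beta,
                 occupancy_min = occupancy_min,
                 consensus = paste(consensus, collapse = ""),
                 rows = ungapped),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("PSSM profile:", ncol(x$log_odds), "retained of", x$width,
      "columns,", length(x$rows), "rows\n")
  cat("consensus:", x$consensus, "\n")
  invisible(x)
}

#' Search a sequence with a profile (affine-gap local alignment)
#'
#' @param profile a [build_profile()] object.
#' @param seq protein sequence string.
#' @param gap_open,gap_extend affine gap penalties in bits (negative).
#' @return a list of class `profile_hit`: `score` (bits), `seq_interval`
#'   and `profile_interval` (1-based inclusive; profile interval indexes
#'   retained columns), and `aligned` (the hit segment in profile
#'   coordinates, `-` for deleted columns). `score` is 0 with `NULL`
#'   intervals when no positive-scoring alignment exists.
#' @export
search_profile <- function(profile, seq, gap_open = -8, gap_extend = -1) {
  stopifnot(inherits(profile, "pssm_profile"),
            gap_open < 0, gap_extend < 0)
  seq <- toupper(seq)
  enc <- match(seq_chars(seq), AA_ALPHABET, nomatch = 0L)
  res <- align_profile_cpp(profile$log_odds, enc, seq, gap_open, gap_extend)
  if (res$score <= 0)
    return(structure(list(score = 0, seq_interval = NULL,
                          profile_interval = NULL, aligned = NULL),
                     class = "profile_hit"))
  structure(list(score = res$score,
                 seq_interval = c(res$seq_start, res$seq_end),
                 profile_interval = c(res$prof_start, res$prof_end),
                 aligned = res$aligned),
            class = "profile_hit")
}

#' Calibrate a bit-score threshold on an empirical null
#'
#' Shuffled decoys of matched length and composition (residue shuffles of
#' the profile's source rows, cycled) are searched with the profile; the
#' threshold is the stated quantile of the best-hit score distribution
#' (inverse-ECDF quantile, so `quantile = 1` returns the decoy maximum).
#'
#' @param profile a [build_profile()] object.
#' @param n_shuffles number of decoys (>= 100).
#' @param quantile null quantile for the threshold, default 0.999.
#' @param seed RNG seed; calibration is deterministic given it.
#' @param gap_open,gap_extend passed to [search_profile()].
#' @return threshold in bits.
#' @export
calibrate_threshold <- function(profile, n_shuffles = 200L, quantile = 0.999,
                                seed = 1L, gap_open = -8, gap_extend = -1) {
  stopifnot(n_shuffles >= 100)
  scores <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      src <- profile$rows[[(i - 1L) %% length(profile$rows) + 1L]]
      decoy <- chars_seq(sample(seq_chars(src)))
      search_profile(profile, decoy, gap_open, gap_extend)$score
    }, numeric(1))
  })
  as.numeric(stats::quantile(scores, probs = quantile, type = 1, names = FALSE))
}

#' Require hits to several subdomain profiles at once
#'
#' A sequence is accepted only when every profile (e.g. ZF, RuvC2, RuvC3)
#' hits above its own threshold -- the multi-domain requirement used to call
#' putative Fanzors.
#'
#' @param seq protein sequence string.
#' @param profiles named list of [build_profile()] objects.
#' @param thresholds named numeric vector of bit thresholds (same names).
#' @param ... passed to [search_profile()].
#' @return list with `pass` (logical), `hits` (named list of
#'   `profile_hit`s) and `hit_order` (profile names ordered by hit start
#'   along the sequence, for the passing profiles).
#' @export
multi_profile_filter <- function(seq, profiles, thresholds, ...) {
  stopifnot(all(names(profiles) %in% names(thresholds)))
  hits <- lapply(profiles, search_profile, seq = seq, ...)
  above <- vapply(names(profiles),
                  function(nm) hits[[nm]]$score >= thresholds[[nm]],
                  logical(1))
  starts <- vapply(hits, function(h)
    if (is.null(h$seq_interval)) NA_real_ else h$seq_interval[1], numeric(1))
  ord <- names(profiles)[above][order(starts[above])]
  list(pass = all(above), hits = hits, hit_order = ord)
}

#' Iterative profile search with alignment augmentation
#'
#' Per round: build a profile from the current alignment, calibrate an
#' empirical-null threshold, search every database sequence not yet a hit,
#' and add each new hit's aligned segment (in profile coordinates, lifted
#' back to alignment columns) as a new alignment row. Hit sets therefore
#' grow monotonically; a row cap guards runaway augmentation.
#'
#' @param seed_alignment named character vector, the seed alignment.
#' @param database named character vector of candidate sequences.
#' @param rounds number of search rounds, default 5.
#' @param pseudocount,background,occupancy_min passed to [build_profile()].
#' @param gap_open,gap_extend passed to [search_profile()].
#' @param n_shuffles,quantile passed to [calibrate_threshold()].
#' @param row_cap maximum alignment rows, default 10000.
#' @param seed master seed for the per-round calibrations.
#' @return an object of class `iter_search`: `history` (data.frame with one
#'   row per round: threshold, cumulative hits, new hits), `hit_ids_by_round`
#'   (list of cumulative hit-id sets), `alignment` (final augmented
#'   alignment) and `hit_ids`.
#' @export
iterative_search <- function(seed_alignment, database, rounds = 5L,
                             pseudocount = 1, background = NULL,
                             occupancy_min = 0.5,
                             gap_open = -8, gap_extend = -1,
                             n_shuffles = 200L, quantile = 0.999,
                             row_cap = 10000L, seed = 1L) {
  stopifnot(rounds >= 1, length(database) > 0,
            !is.null(names(database)), !anyDuplicated(names(database)))
  alignment <- seed_alignment
  hit_ids <- character()
  history <- vector("list", rounds)
  hits_by_round <- vector("list", rounds)

  for (r in seq_len(rounds)) {
    if (length(alignment) > row_cap)
      stop("alignment exceeded the row cap (", row_cap, ") in round ", r)
    profile <- build_profile(alignment, pseudocount, background,
                             occupancy_min)
    thr <- calibrate_threshold(profile, n_shuffles, quantile,
                               seed = child_seed(seed, r),
                               gap_open = gap_open, gap_extend = gap_extend)
    todo <- setdiff(names(database), hit_ids)
    new_rows <- list()
    for (id in todo) {
      hit <- search_profile(profile, database[[id]], gap_open, gap_extend)
      if (hit$score >= thr && hit$score > 0) {
        row <- rep("-", profile$width)
        span <- hit$profile_interval[1]:hit$profile_interval[2]
        row[profile$column_map[span]] <- seq_chars(hit$aligned)
        new_rows[[id]] <- chars_seq(row)
        hit_ids <- c(hit_ids, id)
      }
    }
    if (length(new_rows) > 0)
      alignment <- c(alignment, unlist(new_rows))
    hits_by_round[[r]] <- hit_ids
    history[[r]] <- data.frame(round = r, threshold = thr,
                               n_hits = length(hit_ids),
                               n_new = length(new_rows))
  }
  structure(list(history = do.call(rbind, history),
                 hit_ids_by_round = hits_by_round,
                 alignment = alignment, hit_ids = hit_ids),
            class = "iter_search")
}

#' @export
print.iter_search <- function(x, ...) {
  cat("iterative profile search:", nrow(x$history), "rounds,",
      length(x$hit_ids), "hits,", length(x$alignment),
      "alignment rows\n")
  print(x$history, row.names = FALSE)
  invisible(x)
}
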