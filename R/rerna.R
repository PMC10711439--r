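## reRNA (right-end RNA) analysis: map merged small-RNA reads onto the
## transposon-containing locus, call the expressed reRNA's boundaries from
## the coverage profile, measure how far it extends past a transposon
## feature (the right end or the TSD), and check pseudoknot complementarity
## between the nucleotides flanking the guide region and the apical loop of
## the scaffold. Coordinates are 1-based inclusive.

#' Map reads onto a locus by exact seed and mismatch-tolerant extension
#'
#' Each read is placed by exact match of its first `seed_k` nucleotides,
#' then scored over its full length allowing up to `max_mismatch`
#' substitutions. A unique best placement is required; ties are discarded
#' as ambiguous. Forward strand only (reads are assumed pre-oriented).
#'
#' @param reads character vector of read sequences.
#' @param locus locus nucleotide string (length >= `seed_k`).
#' @param seed_k exact seed length, default 12.
#' @param max_mismatch substitution budget per read, default 2.
#' @param locus_id optional identifier carried into the profile.
#' @return an object of class `rerna_profile`: `coverage` (integer depth
#'   per locus position), `plateau` (median of non-zero coverage),
#'   `n_mapped`, `n_unmapped`, `n_ties`, `locus_id`.
#' @export
map_reads <- function(reads, locus, seed_k = 12L, max_mismatch = 2L,
                      locus_id = "locus") {
  locus <- toupper(locus)
  L <- nchar(locus)
  stopifnot(L >= seed_k)
  lchars <- seq_chars(locus)
  cov <- integer(L)
  n_mapped <- 0L; n_unmapped <- 0L; n_ties <- 0L
  for (read in toupper(reads)) {
    rl <- nchar(read)
    if (rl < seed_k) { n_unmapped <- n_unmapped + 1L; next }
    seed <- substr(read, 1L, seed_k)
    starts <- gregexpr(seed, locus, fixed = TRUE)[[1]]
    if (starts[1] == -1L) { n_unmapped <- n_unmapped + 1L; next }
    starts <- as.integer(starts)
    starts <- starts[starts + rl - 1L <= L]
    if (length(starts) == 0L) { n_unmapped <- n_unmapped + 1L; next }
    rchars <- seq_chars(read)
    mm <- vapply(starts, function(s)
      sum(rchars != lchars[s:(s + rl - 1L)]), integer(1))
    ok <- mm <= max_mismatch
    if (!any(ok)) { n_unmapped <- n_unmapped + 1L; next }
    best <- min(mm[ok])
    cand <- starts[ok][mm[ok] == best]
    if (length(cand) > 1L) { n_ties <- n_ties + 1L; next }
    span <- cand:(cand + rl - 1L)
    cov[span] <- cov[span] + 1L
    n_mapped <- n_mapped + 1L
  }
  nz <- cov[cov > 0]
  structure(list(coverage = cov,
                 plateau = if (length(nz)) median(nz) else 0,
                 n_mapped = n_mapped, n_unmapped = n_unmapped,
                 n_ties = n_ties, locus_id = locus_id),
            class = "rerna_profile")
}

#' @export
print.rerna_profile <- function(x, ...) {
  cat("reRNA coverage profile for", x$locus_id, "--",
      x$n_mapped, "mapped,", x$n_unmapped, "unmapped,",
      x$n_ties, "ambiguous; plateau depth", x$plateau, "\n")
  invisible(x)
}

#' Call reRNA boundaries from a coverage profile
#'
#' The called interval is the maximal contiguous run of positions with
#' coverage at or above `frac` times the plateau (median non-zero coverage)
#' that contains the coverage maximum. Other qualifying runs are reported
#' as secondary.
#'
#' @param profile an `rerna_profile`.
#' @param frac plateau fraction defining the boundary, default 0.5.
#' @return list with `interval` (1-based inclusive), `length`, and
#'   `secondary` (list of other qualifying intervals, possibly empty).
#' @export
call_boundaries <- function(profile, frac = 0.5) {
  cov <- profile$coverage
  if (all(cov == 0)) stop("coverage is zero everywhere; nothing to call")
  thr <- frac * profile$plateau
  above <- cov >= thr & cov > 0
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  peak <- which.max(cov)
  main <- which(runs$start <= peak & runs$end >= peak)
  stopifnot(length(main) == 1L)
  secondary <- lapply(setdiff(seq_len(nrow(runs)), main),
                      function(i) c(runs$start[i], runs$end[i]))
  interval <- c(runs$start[main], runs$end[main])
  list(interval = interval, length = diff(interval) + 1L,
       secondary = secondary)
}

#' Signed extension of a called boundary past a transposon feature
#'
#' Positive values mean the reRNA extends past the feature, away from the
#' element; negative values mean the boundary falls inside it.
#'
#' @param called_interval 1-based inclusive called reRNA interval.
#' @param feature_coord locus coordinate of the feature boundary (e.g. the
#'   last position of the transposon right end or of the TSD).
#' @param side `"right"` (default) or `"left"`: which called boundary to
#'   compare.
#' @return signed distance in nt.
#' @export
extension_beyond <- function(called_interval, feature_coord,
                             side = c("right", "left")) {
  side <- match.arg(side)
  if (side == "right") called_interval[2] - feature_coord
  else feature_coord - called_interval[1]
}

#' Check pseudoknot complementarity between two annotated regions
#'
#' The five nucleotides flanking the guide region are tested against the
#' apical-loop segment in antiparallel register: region A position i pairs
#' with region B position n + 1 - i. Each couple is classed Watson-Crick
#' (A:U, G:C), GU wobble, or unpaired.
#'
#' @param seq locus or transcript sequence (DNA or RNA alphabet; T and U
#'   are equivalent).
#' @param regionA,regionB 1-based inclusive (start, end) intervals of equal
#'   length; must not overlap.
#' @return list of class `pk_annotation`: `pairs` (data.frame: pos_a,
#'   pos_b, base_a, base_b, class), `n_wc`, `n_gu`, `n_none`.
#' @export
pk_check <- function(seq, regionA, regionB) {
  la <- regionA[2] - regionA[1] + 1L
  lb <- regionB[2] - regionB[1] + 1L
  if (la != lb) stop("regions must have equal length")
  if (max(regionA[1], regionB[1]) <= min(regionA[2], regionB[2]))
    stop("regions overlap")
  rna <- chartr("Tt", "Uu", toupper(seq))
  a <- seq_chars(substr(rna, regionA[1], regionA[2]))
  b <- seq_chars(substr(rna, regionB[1], regionB[2]))
  b_rev <- rev(b)
  cls <- vapply(seq_len(la), function(i) {
    pair <- paste0(a[i], b_rev[i])
    if (pair %in% c("AU", "UA", "GC", "CG")) "WC"
    else if (pair %in% c("GU", "UG")) "GU"
    else "none"
  }, "")
  pairs <- data.frame(pos_a = regionA[1]:regionA[2],
                      pos_b = regionB[2]:regionB[1],
                      base_a = a, base_b = b_rev, class = cls)
  structure(list(pairs = pairs,
                 n_wc = sum(cls == "WC"), n_gu = sum(cls == "GU"),
                 n_none = sum(cls == "none")),
            class = "pk_annotation")
}

#' @export
print.pk_annotation <- function(x, ...) {
  cat("pseudoknot register:", x$n_wc, "WC,", x$n_gu, "GU,",
      x$n_none, "unpaired\n")
  invisible(x)
}

#' Apply a point mutation given in guide-relative notation
#'
#' Mutation specs follow the `U-130A` convention: reference base, signed
#' position, replacement base. Position -k means k nucleotides 5' of the
#' first guide nucleotide (so -1 abuts the guide and the scaffold is
#' negatively indexed); position +k is the k-th guide nucleotide. The
#' reference base is checked against the sequence before substitution,
#' guarding against coordinate misreads.
#'
#' @param seq nucleotide string (DNA or RNA alphabet; the replacement is
#'   written in the sequence's own alphabet, or verbatim when the sequence
#'   contains neither T nor U to tell the two apart).
#' @param spec mutation string, e.g. `"U-130A"` or `"A-3U"`.
#' @param guide_start 1-based position of the first guide nucleotide.
#' @return the mutated sequence string.
#' @export
apply_mutation <- function(seq, spec, guide_start) {
  m <- regmatches(spec,
                  regexec("^([ACGTUacgtu])(-?[0-9]+)([ACGTUacgtu])$", spec))[[1]]
  if (length(m) != 4L) stop("cannot parse mutation spec '", spec, "'")
  ref <- toupper(m[2]); k <- as.integer(m[3]); new <- toupper(m[4])
  idx <- if (k < 0) guide_start + k else guide_start + k - 1L
  if (idx < 1L || idx > nchar(seq))
    stop("mutation position ", k, " falls outside the sequence")
  up <- toupper(seq)
  has_u <- grepl("U", up, fixed = TRUE)
  has_t <- grepl("T", up, fixed = TRUE)
  to_alpha <- function(b) {
    if (has_u && !has_t) chartr("T", "U", b)
    else if (has_t && !has_u) chartr("U", "T", b)
    else b  # alphabet ambiguous: keep the spec's own letter
  }
  found <- toupper(substr(seq, idx, idx))
  if (chartr("T", "U", found) != chartr("T", "U", ref))
    stop("reference base mismatch at position ", k, ": expected ", ref,
         ", found ", found)
  substr(seq, idx, idx) <- to_alpha(new)
  seq
}
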