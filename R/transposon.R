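## Transposon locus curation: target-site duplications (TSD), terminal
## inverted repeats (TIR), IS607 GG crossover boundaries, IS-family
## assignment from neighbour-gene domain labels, and genome-wide element
## copy search. Coordinates are 1-based inclusive.

## Domain-label sets used to assign TnpBs to an insertion-sequence family
## from the annotations of their neighbouring transposase gene. Labels are
## normalised to lower case with spaces collapsed to underscores; both names
## and database accessions are accepted.
IS200_605_LABELS <- c("y1_tnp", "pfam01797", "y1_tnp_superfamily", "cl00848",
                      "transpos_is200", "nf033573")
IS607_LABELS <- c("transpos_is607", "nf033518", "transpos_is607_superfamily",
                  "cl41297", "resolvase", "cl02788", "recombinase", "cl06512")

normalise_label <- function(x) gsub("[[:space:]]+", "_", tolower(trimws(x)))

#' Assign an insertion-sequence family from neighbour-gene domain labels
#'
#' TnpBs are assigned to the IS200/605 or IS607 family by the domain
#' annotations of their co-encoded transposase (TnpA): Y1 tyrosine
#' transposase labels mark IS200/605, serine-recombinase/resolvase labels
#' mark IS607. Elements whose neighbours match neither set are left
#' `UNCLASSIFIED`; matches to both sets yield `CONFLICT`.
#'
#' @param labels character vector (or set) of domain labels for the
#'   neighbouring genes; names or accessions, case-insensitive.
#' @return list with `family` (one of `IS200_605`, `IS607`, `UNCLASSIFIED`,
#'   `CONFLICT`) and `evidence` (the matched labels as supplied).
#' @export
classify_is_family <- function(labels) {
  norm <- normalise_label(labels)
  hit200 <- norm %in% IS200_605_LABELS
  hit607 <- norm %in% IS607_LABELS
  family <- if (any(hit200) && any(hit607)) "CONFLICT"
  else if (any(hit200)) "IS200_605"
  else if (any(hit607)) "IS607"
  else "UNCLASSIFIED"
  list(family = family, evidence = labels[hit200 | hit607])
}

#' Detect a target-site duplication at an element's junctions
#'
#' Returns the longest k in `[k_min, k_max]` such that the k-mer immediately
#' 5' of the element equals the k-mer immediately 3' of it (exact match
#' only -- curated TSDs are expected to be clean duplications).
#'
#' @param insertion_allele nucleotide string containing the element.
#' @param element_interval 1-based inclusive (start, end) of the element.
#' @param k_min,k_max TSD length bounds; eukaryotic TSDs of this lineage can
#'   reach 12 nt, so the default upper bound of 15 leaves headroom.
#' @return the TSD string, or `NULL` when no duplication exists.
#' @export
detect_tsd <- function(insertion_allele, element_interval,
                       k_min = 2L, k_max = 15L) {
  start <- element_interval[1]; end <- element_interval[2]
  n <- nchar(insertion_allele)
  if (start - 1L < k_max || n - end < k_max)
    stop("flanks shorter than k_max on at least one side")
  for (k in seq(k_max, k_min)) {
    left <- substr(insertion_allele, start - k, start - 1L)
    right <- substr(insertion_allele, end + 1L, end + k)
    if (left == right) return(left)
  }
  NULL
}

#' Verify an insertion against its empty (pre-integration) allele
#'
#' True iff removing the element plus one TSD copy from the insertion allele
#' reconstructs the empty allele exactly; both choices of which TSD copy to
#' remove are tested.
#'
#' @param insertion_allele,empty_allele nucleotide strings.
#' @param element_interval 1-based inclusive element interval.
#' @param tsd the detected TSD string (may be `""` for TSD-less elements).
#' @return logical.
#' @export
verify_empty_site <- function(insertion_allele, element_interval, tsd,
                              empty_allele) {
  start <- element_interval[1]; end <- element_interval[2]
  n <- nchar(insertion_allele)
  k <- nchar(tsd)
  drop_right <- paste0(substr(insertion_allele, 1L, start - 1L),
                       substr(insertion_allele, end + k + 1L, n))
  drop_left <- paste0(substr(insertion_allele, 1L, start - k - 1L),
                      substr(insertion_allele, end + 1L, n))
  drop_right == empty_allele || drop_left == empty_allele
}

#' Detect (degenerate) terminal inverted repeats
#'
#' Scans the first and last `window` nt of the element for the segment pair
#' maximising `matches - mismatches` between the left segment and the
#' reverse complement of the right segment, requiring length >= `min_len`
#' and a mismatch fraction <= `max_mismatch_frac`. The balanced score keeps
#' chance-complementary bases beyond a repeat's true end from dragging the
#' boundary outward; ties prefer the more compact placement, then segments
#' closer to the element termini.
#'
#' @param element_seq element nucleotide string (length >= 2 * window).
#' @param window terminal window size, default 50 nt.
#' @param min_len minimum TIR length, default 8 nt.
#' @param max_mismatch_frac mismatch tolerance, default 0.2.
#' @return list with `left`, `right` (1-based inclusive intervals in element
#'   coordinates) and `mismatches`, or `NULL` when no repeat qualifies.
#' @export
detect_tir <- function(element_seq, window = 50L, min_len = 8L,
                       max_mismatch_frac = 0.2) {
  stopifnot(nchar(element_seq) >= 2L * window)
  hit <- tir_scan_cpp(toupper(element_seq), as.integer(window),
                      as.integer(min_len), max_mismatch_frac)
  if (length(hit) == 0L) return(NULL)
  list(left = c(hit[1], hit[2]), right = c(hit[3], hit[4]),
       mismatches = hit[5])
}

#' Check IS607 GG crossover boundaries
#'
#' IS607 elements mobilise by recombination between GG dinucleotides, so a
#' curated IS607 element is expected to begin and end with GG (the terminal
#' dinucleotides of the element carry the crossover motif at both the
#' left-end and right-end boundary).
#'
#' @param sequence the allele (or element) nucleotide string.
#' @param element_interval 1-based inclusive element interval within
#'   `sequence`.
#' @return named logical vector `c(LE = , RE = )`.
#' @export
check_is607_boundaries <- function(sequence, element_interval) {
  start <- element_interval[1]; end <- element_interval[2]
  c(LE = substr(sequence, start, start + 1L) == "GG",
    RE = substr(sequence, end - 1L, end) == "GG")
}

#' Find copies of an element in a genome by ungapped seed-and-extend
#'
#' Exact `seed_k`-mers sampled along the element vote for candidate
#' placements; each candidate is evaluated by full-length ungapped identity
#' and kept at `min_identity` or above. Hits are reported with flanking
#' context of `flank` nt on each side, clipped at the contig ends.
#'
#' @param genome contig nucleotide string.
#' @param element_seq element nucleotide string.
#' @param min_identity minimum ungapped identity, default 0.9.
#' @param seed_k exact seed length, default 16.
#' @param flank flank extension, default 2000 nt.
#' @return data.frame with columns `start`, `end`, `identity`,
#'   `flank_start`, `flank_end`; zero rows when no copy qualifies.
#' @export
find_element_copies <- function(genome, element_seq, min_identity = 0.9,
                                seed_k = 16L, flank = 2000L) {
  gl <- nchar(genome); el <- nchar(element_seq)
  stopifnot(gl >= el, el >= seed_k)
  offsets <- seq(1L, el - seed_k + 1L, by = seed_k)
  cand <- integer()
  for (off in offsets) {
    seed <- substr(element_seq, off, off + seed_k - 1L)
    hits <- gregexpr(seed, genome, fixed = TRUE)[[1]]
    if (hits[1] != -1L) cand <- c(cand, as.integer(hits) - off + 1L)
  }
  cand <- sort(unique(cand))
  cand <- cand[cand >= 1L & cand + el - 1L <= gl]
  if (length(cand) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      identity = numeric(), flank_start = integer(),
                      flank_end = integer()))
  echars <- seq_chars(element_seq)
  rows <- lapply(cand, function(s) {
    gchars <- seq_chars(substr(genome, s, s + el - 1L))
    ident <- mean(gchars == echars)
    if (ident < min_identity) return(NULL)
    data.frame(start = s, end = s + el - 1L, identity = ident,
               flank_start = max(1L, s - flank),
               flank_end = min(gl, s + el - 1L + flank))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(),
                      identity = numeric(), flank_start = integer(),
                      flank_end = integer())
  out
}

#' Curate one locus end to end
#'
#' Convenience wrapper: detects the TSD, verifies the empty site, scans for
#' TIRs and checks GG boundaries; returns everything in one record.
#'
#' @param insertion_allele,empty_allele nucleotide strings.
#' @param element_interval 1-based inclusive element interval.
#' @param ... passed to [detect_tir()].
#' @return list with `tsd`, `empty_site_ok`, `tirs`, `gg_boundaries`.
#' @export
annotate_locus <- function(insertion_allele, element_interval,
                           empty_allele = NULL, ...) {
  tsd <- detect_tsd(insertion_allele, element_interval)
  ok <- if (!is.null(empty_allele))
    verify_empty_site(insertion_allele, element_interval,
                      if (is.null(tsd)) "" else tsd, empty_allele)
  else NA
  element <- substr(insertion_allele, element_interval[1],
                    element_interval[2])
  tirs <- if (nchar(element) >= 100L) detect_tir(element, ...) else NULL
  list(tsd = tsd, empty_site_ok = ok, tirs = tirs,
       gg_boundaries = check_is607_boundaries(insertion_allele,
                                              element_interval))
}
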