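## RuvC/zinc-finger fingerprint classification of TnpB-family proteins.
##
## The Fanzor lineage is marked by two features of the RuvC nuclease domain:
## a DPG motif at RuvC1 (other TnpBs carry D-phi-G, phi in {I,L,F,W,Y,M}) and
## a rearranged RuvC2 catalytic glutamate sitting six residues upstream of the
## first zinc-finger cysteine (the "alternative" placement, E_alt) instead of
## ~50 residues upstream (the "canonical" placement, E_can). The full
## fingerprint is the gap-constrained pattern
##   D P G x(120,160) E x{6} C x x C x(12,18) C x x C x(4,8) D
## All coordinates reported here are 1-based and inclusive.

FINGERPRINT_CATEGORIES <- c("FANZOR_LIKE", "E_ALT_DPHIG", "CANONICAL",
                            "AMBIGUOUS", "INCOMPLETE")

#' Find all C-terminal zinc-finger motifs
#'
#' Enumerates every placement of the pattern `CxxC x(s1) CxxC x(s2) D` where
#' the inter-block spacer `s1` defaults to 12--18 residues and the distance
#' from the fourth cysteine to the terminal aspartate (`s2`) defaults to
#' 4--8 residues. Overlapping placements are all reported. `X` (unknown
#' residue) matches wildcard positions but never the literal C/D anchors.
#'
#' @param seq protein sequence string.
#' @param spacer1 length-2 integer vector: residues strictly between the two
#'   CxxC blocks.
#' @param spacer2 length-2 integer vector: residues strictly between the
#'   fourth cysteine and the terminal aspartate.
#' @return a data.frame with one row per motif, columns `c1, c2, c3, c4,
#'   d_end` (residue indices of the four cysteines and the aspartate) and
#'   `spacer1, spacer2`; zero rows when the pattern is absent. Ordered by
#'   `c1`, then `c3`, then `d_end`.
#' @export
find_zf_motifs <- function(seq, spacer1 = c(12L, 18L), spacer2 = c(4L, 8L)) {
  ch <- seq_chars(seq)
  n <- length(ch)
  cpos <- which(ch == "C")
  dpos <- which(ch == "D")
  empty <- data.frame(c1 = integer(), c2 = integer(), c3 = integer(),
                      c4 = integer(), d_end = integer(),
                      spacer1 = integer(), spacer2 = integer())
  if (length(cpos) < 4L || length(dpos) < 1L) return(empty)
  cxxc <- cpos[(cpos + 3L) %in% cpos]   # first C of each CxxC block
  if (length(cxxc) < 2L) return(empty)
  out <- empty
  for (c1 in cxxc) {
    c2 <- c1 + 3L
    c3s <- cxxc[cxxc >= c2 + spacer1[1] + 1L & cxxc <= c2 + spacer1[2] + 1L]
    for (c3 in c3s) {
      c4 <- c3 + 3L
      ds <- dpos[dpos >= c4 + spacer2[1] + 1L & dpos <= c4 + spacer2[2] + 1L]
      for (d_end in ds) {
        out <- rbind(out, data.frame(
          c1 = c1, c2 = c2, c3 = c3, c4 = c4, d_end = d_end,
          spacer1 = c3 - c2 - 1L, spacer2 = d_end - c4 - 1L))
      }
    }
  }
  out[order(out$c1, out$c3, out$d_end), , drop = FALSE]
}

#' Find all RuvC1 catalytic-aspartate motifs
#'
#' Reports every `DPG` and `D-phi-G` occurrence (phi in I, L, F, W, Y, M).
#' Other middle residues (e.g. `DKG`) are not RuvC1 motifs.
#'
#' @param seq protein sequence string.
#' @return data.frame with columns `d_index`, `g_index`, `middle`,
#'   `motif_class` (`"DPG"` or `"DPhiG"`); zero rows when absent.
#' @export
find_ruvc1 <- function(seq) {
  ch <- seq_chars(seq)
  n <- length(ch)
  empty <- data.frame(d_index = integer(), g_index = integer(),
                      middle = character(), motif_class = character())
  if (n < 3L) return(empty)
  i <- which(ch == "D")
  i <- i[i + 2L <= n]
  i <- i[ch[i + 2L] == "G"]
  mid <- ch[i + 1L]
  keep <- mid == "P" | mid %in% PHI_SET
  i <- i[keep]; mid <- mid[keep]
  if (length(i) == 0L) return(empty)
  data.frame(d_index = i, g_index = i + 2L, middle = mid,
             motif_class = ifelse(mid == "P", "DPG", "DPhiG"))
}

#' Classify a protein by its RuvC/zinc-finger fingerprint
#'
#' Evaluates all combinations of RuvC1 motif, glutamate placement and
#' zinc-finger motif and reports the best category under the order
#' `FANZOR_LIKE > E_ALT_DPHIG > CANONICAL > AMBIGUOUS > INCOMPLETE`:
#' \describe{
#'   \item{FANZOR_LIKE}{a DPG RuvC1, a glutamate exactly 7 residues before
#'     the first ZF cysteine (E_alt: E + 6 arbitrary residues + C), a ZF
#'     motif, and 120--160 residues strictly between the RuvC1 glycine and
#'     that glutamate.}
#'   \item{E_ALT_DPHIG}{the same arrangement with a D-phi-G RuvC1.}
#'   \item{CANONICAL}{a ZF motif with a glutamate in the canonical window
#'     (by default 35--65 residues upstream of the first ZF cysteine, never
#'     the E_alt offset itself) and no E_alt placement on any ZF motif.}
#'   \item{AMBIGUOUS}{both an E_alt and a canonical-window glutamate exist
#'     but no spacer-complete Fanzor arrangement does.}
#'   \item{INCOMPLETE}{anything else (a component is missing).}
#' }
#'
#' @param seq protein sequence string (length >= 50 recommended).
#' @param ecan_window length-2 vector: allowed distances (in residues) from
#'   the canonical glutamate to the first ZF cysteine.
#' @param spacer_range length-2 vector: residues strictly between the RuvC1
#'   glycine and the RuvC2 glutamate.
#' @param spacer1,spacer2 passed to [find_zf_motifs()].
#' @return a list of class `fingerprint_call`: `category`, plus (when
#'   defined) `ruvc1` and `zf` one-row data.frames of the reported
#'   combination, `e_alt_index`, `e_can_index`, and `spacer_ok`.
#' @export
classify_fingerprint <- function(seq, ecan_window = c(35L, 65L),
                                 spacer_range = c(120L, 160L),
                                 spacer1 = c(12L, 18L), spacer2 = c(4L, 8L)) {
  ch <- seq_chars(seq)
  zf <- find_zf_motifs(seq, spacer1, spacer2)
  ruv <- find_ruvc1(seq)

  call <- structure(list(category = "INCOMPLETE", ruvc1 = NULL, zf = NULL,
                         e_alt_index = NA_integer_, e_can_index = NA_integer_,
                         spacer_ok = FALSE),
                    class = "fingerprint_call")
  if (nrow(zf) == 0L) return(call)

  ealt_pos <- zf$c1 - 7L
  zf$has_ealt <- ealt_pos >= 1L & ch[pmax(ealt_pos, 1L)] == "E"

  ecan_of <- function(c1) {
    p <- c1 - seq.int(ecan_window[1], ecan_window[2])
    p <- p[p >= 1L & p != c1 - 7L]
    p[ch[p] == "E"]
  }

  spacer_ok <- function(g_index, e_index) {
    between <- e_index - g_index - 1L
    between >= spacer_range[1] && between <= spacer_range[2]
  }

  ## full Fanzor-pattern arrangements, by RuvC1 class
  best_arrangement <- function(class) {
    rows <- ruv[ruv$motif_class == class, , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    for (zi in which(zf$has_ealt)) {
      e <- zf$c1[zi] - 7L
      for (ri in seq_len(nrow(rows))) {
        if (spacer_ok(rows$g_index[ri], e)) {
          return(list(ruvc1 = rows[ri, , drop = FALSE],
                      zf = zf[zi, setdiff(names(zf), "has_ealt"), drop = FALSE],
                      e_alt = e))
        }
      }
    }
    NULL
  }

  arr <- best_arrangement("DPG")
  if (!is.null(arr)) {
    call$category <- "FANZOR_LIKE"
  } else {
    arr <- best_arrangement("DPhiG")
    if (!is.null(arr)) call$category <- "E_ALT_DPHIG"
  }
  if (!is.null(arr)) {
    call$ruvc1 <- arr$ruvc1
    call$zf <- arr$zf
    call$e_alt_index <- arr$e_alt
    call$spacer_ok <- TRUE
    return(call)
  }

  ecan_hits <- lapply(zf$c1, ecan_of)
  any_ecan <- any(lengths(ecan_hits) > 0L)
  any_ealt <- any(zf$has_ealt)

  if (any_ecan && !any_ealt) {
    zi <- which(lengths(ecan_hits) > 0L)[1L]
    call$category <- "CANONICAL"
    call$zf <- zf[zi, setdiff(names(zf), "has_ealt"), drop = FALSE]
    call$e_can_index <- max(ecan_hits[[zi]])
    if (nrow(ruv) > 0L) call$ruvc1 <- ruv[1L, , drop = FALSE]
  } else if (any_ecan && any_ealt) {
    call$category <- "AMBIGUOUS"
    zi <- which(zf$has_ealt)[1L]
    call$zf <- zf[zi, setdiff(names(zf), "has_ealt"), drop = FALSE]
    call$e_alt_index <- zf$c1[zi] - 7L
    call$e_can_index <- max(unlist(ecan_hits))
  }
  call
}

#' @export
print.fingerprint_call <- function(x, ...) {
  cat("fingerprint call:", x$category, "\n")
  if (!is.null(x$ruvc1))
    cat("  RuvC1", x$ruvc1$motif_class, "at", x$ruvc1$d_index, "\n")
  if (!is.null(x$zf))
    cat("  ZF C1..D at", x$zf$c1, "-", x$zf$d_end, "\n")
  if (!is.na(x$e_alt_index)) cat("  E_alt at", x$e_alt_index, "\n")
  if (!is.na(x$e_can_index)) cat("  E_can at", x$e_can_index, "\n")
  invisible(x)
}

#' Classify a set of proteins and tabulate category prevalence
#'
#' @param seqs named character vector of protein sequences; names are
#'   sequence identifiers and must be unique.
#' @param ... passed to [classify_fingerprint()].
#' @return a list: `calls` (data.frame: id, category, motif coordinates) and
#'   `fractions` (named numeric over all five categories, summing to 1;
#'   empty categories report 0).
#' @export
scan_database <- function(seqs, ...) {
  if (length(seqs) == 0L) stop("no sequences supplied")
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must carry unique identifiers")
  rows <- lapply(seq_along(seqs), function(i) {
    fc <- classify_fingerprint(seqs[[i]], ...)
    data.frame(
      id = ids[i],
      category = fc$category,
      ruvc1_class = if (is.null(fc$ruvc1)) NA_character_ else fc$ruvc1$motif_class,
      ruvc1_d = if (is.null(fc$ruvc1)) NA_integer_ else fc$ruvc1$d_index,
      e_alt = fc$e_alt_index,
      e_can = fc$e_can_index,
      zf_c1 = if (is.null(fc$zf)) NA_integer_ else fc$zf$c1,
      zf_d = if (is.null(fc$zf)) NA_integer_ else fc$zf$d_end,
      spacer_ok = fc$spacer_ok)
  })
  calls <- do.call(rbind, rows)
  counts <- table(factor(calls$category, levels = FINGERPRINT_CATEGORIES))
  fractions <- as.numeric(counts) / length(seqs)
  names(fractions) <- FINGERPRINT_CATEGORIES
  list(calls = calls, fractions = fractions)
}
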