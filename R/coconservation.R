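## TnpA-TnpB co-conservation. If a TnpB (or Fanzor2) has co-resided with its
## TnpA transposase since their common ancestor, the pairwise identities of
## TnpA-TnpA and TnpB-TnpB comparisons across elements co-vary; independent
## reassortment destroys the correlation. Identities are computed on
## user-supplied alignments, optionally column-trimmed by occupancy first.

#' Percent identity between two aligned rows
#'
#' `100 * identical positions / columns where both rows are non-gap`.
#' Columns where either row is gapped count toward neither numerator nor
#' denominator; two rows sharing no non-gap column score 0 (with a warning).
#'
#' @param row_i,row_j gapped strings of equal length (`-` or `.` gaps).
#' @return percent identity in [0, 100].
#' @export
percent_identity <- function(row_i, row_j) {
  if (nchar(row_i) != nchar(row_j)) stop("rows have different widths")
  a <- seq_chars(toupper(row_i)); b <- seq_chars(toupper(row_j))
  a[a == "."] <- "-"; b[b == "."] <- "-"
  both <- a != "-" & b != "-"
  if (!any(both)) {
    warning("rows share no non-gap columns; identity set to 0")
    return(0)
  }
  100 * sum(a[both] == b[both]) / sum(both)
}

#' Pairwise percent-identity matrix for an alignment
#'
#' @param msa named character vector of equal-width gapped rows.
#' @return symmetric matrix in [0, 100] with unit diagonal of exactly 100,
#'   dimnames from the row names.
#' @export
identity_matrix <- function(msa) {
  n <- length(msa)
  m <- matrix(100, n, n, dimnames = list(names(msa), names(msa)))
  if (n < 2L) return(m)
  chars <- strsplit(toupper(msa), "", fixed = TRUE)
  chars <- lapply(chars, function(x) { x[x == "."] <- "-"; x })
  for (i in seq_len(n - 1L)) {
    ai <- chars[[i]]; gi <- ai != "-"
    for (j in (i + 1L):n) {
      bj <- chars[[j]]
      both <- gi & bj != "-"
      m[i, j] <- m[j, i] <-
        if (any(both)) 100 * sum(ai[both] == bj[both]) / sum(both) else 0
    }
  }
  m
}

#' Trim alignment columns by occupancy
#'
#' Keeps exactly the columns whose non-gap fraction is at or above the
#' cutoff (the stringent gap-threshold filter used before tree building);
#' idempotent by construction.
#'
#' @param msa named character vector of equal-width gapped rows (>= 2).
#' @param occupancy minimum non-gap fraction, default 0.9.
#' @return list with `msa` (trimmed rows) and `kept` (original column
#'   indices of the surviving columns, for coordinate lift-over).
#' @export
trim_columns <- function(msa, occupancy = 0.9) {
  if (length(msa) < 2L) stop("alignment needs at least 2 rows")
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L) stop("ragged alignment")
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  mat[mat == "."] <- "-"
  keep <- which(colMeans(mat != "-") >= occupancy)
  if (length(keep) == 0L) stop("no columns survive the occupancy cutoff")
  trimmed <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  names(trimmed) <- names(msa)
  list(msa = trimmed, kept = keep)
}

#' Co-conservation of paired TnpA/TnpB identities across elements
#'
#' For every unordered pair of elements (i1, i2) emits the TnpA-TnpA and
#' TnpB-TnpB percent identities, then summarises their association with
#' Pearson and Spearman correlations and a fixed-bin 2D histogram.
#'
#' @param msa_a,msa_b named character vectors: the TnpA and TnpB/Fanzor
#'   alignments.
#' @param pairing data.frame with columns `element_id`, `row_a`, `row_b`
#'   mapping each element to one row of each alignment.
#' @param bins histogram bins per axis over [0, 100], default 20.
#' @return list of class `coconservation_result`: `pairs` (data.frame:
#'   element_i, element_j, id_a, id_b), `pearson_r`, `spearman_rho`,
#'   `histogram2d` (`bins` x `bins` counts, TnpA on rows).
#' @export
paired_identities <- function(msa_a, msa_b, pairing, bins = 20L) {
  need <- c("element_id", "row_a", "row_b")
  stopifnot(all(need %in% names(pairing)))
  if (!all(pairing$row_a %in% names(msa_a)) ||
      !all(pairing$row_b %in% names(msa_b)))
    stop("pairing refers to rows absent from the alignments")
  n <- nrow(pairing)
  if (n < 3L) stop("need at least 3 paired elements")

  ma <- identity_matrix(msa_a[pairing$row_a])
  mb <- identity_matrix(msa_b[pairing$row_b])
  idx <- which(upper.tri(ma), arr.ind = TRUE)
  pairs <- data.frame(element_i = pairing$element_id[idx[, 1]],
                      element_j = pairing$element_id[idx[, 2]],
                      id_a = ma[idx], id_b = mb[idx])
  breaks <- seq(0, 100, length.out = bins + 1L)
  h <- table(cut(pairs$id_a, breaks, include.lowest = TRUE),
             cut(pairs$id_b, breaks, include.lowest = TRUE))
  structure(list(pairs = pairs,
                 pearson_r = cor(pairs$id_a, pairs$id_b),
                 spearman_rho = cor(pairs$id_a, pairs$id_b,
                                    method = "spearman"),
                 histogram2d = unclass(h)),
            class = "coconservation_result")
}

#' @export
print.coconservation_result <- function(x, ...) {
  cat("co-conservation over", nrow(x$pairs), "element pairs\n")
  cat(sprintf("  Pearson r = %.3f, Spearman rho = %.3f\n",
              x$pearson_r, x$spearman_rho))
  invisible(x)
}
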