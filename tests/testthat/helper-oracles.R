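# Independent oracles used to cross-check the implementation. Each takes a
# deliberately different route from the code it validates: regular
# expressions instead of component enumeration for the fingerprint,
# substring scans for motif placement, explicit segment-pair enumeration
# with geometric gap accounting for the local aligner.

PHI <- c("I", "L", "F", "W", "Y", "M")

# Fingerprint category by direct regex evaluation of the two printed-style
# patterns plus the canonical-window rule.
oracle_fingerprint <- function(seq, ecan_window = c(35, 65)) {
  fz <- "DPG.{120,160}E.{6}C..C.{12,18}C..C.{4,8}D"
  alt <- sprintf("D[%s]G.{120,160}E.{6}C..C.{12,18}C..C.{4,8}D",
                 paste(PHI, collapse = ""))
  if (grepl(fz, seq, perl = TRUE)) return("FANZOR_LIKE")
  if (grepl(alt, seq, perl = TRUE)) return("E_ALT_DPHIG")
  zf_starts <- oracle_zf_starts(seq)
  if (length(zf_starts) == 0) return("INCOMPLETE")
  ch <- strsplit(seq, "")[[1]]
  has_ealt <- any(zf_starts > 7 & ch[pmax(zf_starts - 7, 1)] == "E")
  has_ecan <- any(vapply(zf_starts, function(c1) {
    p <- c1 - seq(ecan_window[1], ecan_window[2])
    p <- p[p >= 1 & p != c1 - 7]
    any(ch[p] == "E")
  }, logical(1)))
  if (has_ecan && !has_ealt) "CANONICAL"
  else if (has_ecan && has_ealt) "AMBIGUOUS"
  else "INCOMPLETE"
}

# All ZF motif start positions via a lookahead regex (overlaps included).
oracle_zf_starts <- function(seq) {
  m <- gregexpr("(?=C..C.{12,18}C..C.{4,8}D)", seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

# Full ZF motif placements by testing every substring against an anchored
# pattern -- independent of the component-based enumeration in the package.
oracle_zf_motifs <- function(seq) {
  n <- nchar(seq)
  out <- list()
  for (s in seq_len(n)) {
    for (len in 25:40) {  # 4+12+4+4+1 .. 4+18+4+8+1 residues
      e <- s + len - 1
      if (e > n) break
      sub <- substr(seq, s, e)
      if (grepl("^C..C.{12,18}C..C.{4,8}D$", sub, perl = TRUE)) {
        ch <- strsplit(sub, "")[[1]]
        cpos <- which(ch == "C")
        # the anchored match fixes c1 = 1 and d_end = len; recover c3 as any
        # C with C at +3 in the allowed band (all such give distinct rows)
        for (c3 in cpos[cpos >= 17 & cpos <= 23]) {
          if (ch[c3 + 3] == "C" && len - (c3 + 3) - 1 >= 4 &&
              len - (c3 + 3) - 1 <= 8)
            out[[length(out) + 1]] <- c(s, s + 3, s + c3 - 1, s + c3 + 2,
                                        s + len - 1)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(c1 = integer(), c3 = integer(), d_end = integer()))
  m <- unique(do.call(rbind, out))
  df <- data.frame(c1 = m[, 1], c2 = m[, 2], c3 = m[, 3], c4 = m[, 4],
                   d_end = m[, 5])
  df[order(df$c1, df$c3, df$d_end), , drop = FALSE]
}

# Exhaustive local-alignment oracle for alignments with at most two gap
# runs: enumerate every ungapped diagonal segment, then every compatible
# segment pair and pair-of-pairs, charging gap penalties from the geometry
# of the joint. Returns the best score (0 when nothing positive exists).
oracle_local_align <- function(pssm, enc, gap_open, gap_extend) {
  n <- length(enc); m <- ncol(pssm)
  colmin <- apply(pssm, 2, min)
  S <- matrix(0, n, m)
  for (i in seq_len(n))
    for (j in seq_len(m))
      S[i, j] <- if (enc[i] > 0) pssm[enc[i], j] else colmin[j]

  segs <- list()
  for (i0 in seq_len(n)) {
    for (j0 in seq_len(m)) {
      sc <- 0
      l <- 0
      while (i0 + l <= n && j0 + l <= m) {
        sc <- sc + S[i0 + l, j0 + l]
        segs[[length(segs) + 1]] <- c(i0, j0, i0 + l, j0 + l, sc)
        l <- l + 1
      }
    }
  }
  sg <- do.call(rbind, segs)
  colnames(sg) <- c("i0", "j0", "i1", "j1", "sc")
  best <- max(0, max(sg[, "sc"]))

  # score of the best chain ending in each segment after one more gap run
  chain_scores <- function(prev_best_at_seg) {
    k <- nrow(sg)
    out <- rep(-Inf, k)
    for (b in seq_len(k)) {
      i0 <- sg[b, "i0"]; j0 <- sg[b, "j0"]
      # gap in profile (columns skipped): predecessor ends at row i0-1,
      # column < j0-1; gap in sequence: ends at column j0-1, row < i0-1
      gx <- which(sg[, "i1"] == i0 - 1 & sg[, "j1"] < j0 - 1)
      gy <- which(sg[, "j1"] == j0 - 1 & sg[, "i1"] < i0 - 1)
      cand <- -Inf
      if (length(gx))
        cand <- max(cand, max(prev_best_at_seg[gx] + gap_open +
                                gap_extend * (j0 - sg[gx, "j1"] - 2)))
      if (length(gy))
        cand <- max(cand, max(prev_best_at_seg[gy] + gap_open +
                                gap_extend * (i0 - sg[gy, "i1"] - 2)))
      out[b] <- cand + sg[b, "sc"]
    }
    out
  }

  seg_self <- sg[, "sc"]
  one_gap <- chain_scores(seg_self)
  best <- max(best, one_gap, 0)
  two_gap <- chain_scores(one_gap)
  max(best, two_gap, 0)
}

# Brute-force column census for occupancy trimming.
oracle_trim_keep <- function(msa, occupancy) {
  mat <- do.call(rbind, strsplit(msa, ""))
  mat[mat == "."] <- "-"
  which(apply(mat, 2, function(col) mean(col != "-")) >= occupancy)
}

# Does any terminal inverted repeat satisfying the constraints exist?
oracle_tir_exists <- function(element, window = 50, min_len = 8,
                              frac = 0.2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(element, "")[[1]]
  L <- length(ch)
  for (i in 1:window) {
    for (j in L:(L - window + 1)) {
      lmax <- min(window - i + 1, j - (L - window))
      if (lmax < min_len) next
      for (l in min_len:lmax) {
        left <- ch[i:(i + l - 1)]
        right <- rev(comp[ch[(j - l + 1):j]])
        if (mean(left != right) <= frac) return(TRUE)
      }
    }
  }
  FALSE
}
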