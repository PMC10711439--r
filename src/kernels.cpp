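#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment of an integer-encoded sequence against a PSSM
// (Gotoh three-state recursion, Smith-Waterman 0 floor on the match state).
//
// States: M = residue aligned to column, X = profile column deleted,
// Y = sequence residue inserted. Local alignments start and end in M.
// Traceback ties break diagonal (M) > up (X) > left (Y), deterministic.
//
// pssm: residues x columns matrix of per-column log-odds (bits).
// seq:  1-based residue indices into the pssm rows; 0 marks an unscorable
//       letter, which receives the column minimum.
// seq_str: the sequence letters, used to emit the aligned segment.
//
// Returns list(score, seq_start, seq_end, prof_start, prof_end, aligned);
// `aligned` holds one character per profile column of the hit ('-' for a
// deleted column; inserted residues are dropped), i.e. the hit written in
// profile coordinates. score = 0 means no positive-scoring alignment.
// [[Rcpp::export]]
List align_profile_cpp(NumericMatrix pssm, IntegerVector seq,
                       std::string seq_str,
                       double gap_open, double gap_extend) {
  const int n = seq.size();
  const int m = pssm.ncol();
  const double NEG = -1e30;

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);
  // tb codes give the predecessor state: 1 = M, 2 = X, 3 = Y

  std::vector<double> colmin(m);
  for (int j = 0; j < m; ++j) {
    double mn = pssm(0, j);
    for (int a = 1; a < pssm.nrow(); ++a) mn = std::min(mn, pssm(a, j));
    colmin[j] = mn;
  }

  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = 0; X(i, j) = NEG; Y(i, j) = NEG; }

  double best = 0; int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int a = seq[i - 1];
      const double s = (a > 0) ? pssm(a - 1, j - 1) : colmin[j - 1];

      // X: consume profile column j without a residue
      double xo = M(i, j - 1) + gap_open;
      double xe = X(i, j - 1) + gap_extend;
      if (xo >= xe) { X(i, j) = xo; tbX(i, j) = 1; }
      else          { X(i, j) = xe; tbX(i, j) = 2; }

      // Y: consume residue i without a profile column
      double yo = M(i - 1, j) + gap_open;
      double ye = Y(i - 1, j) + gap_extend;
      if (yo >= ye) { Y(i, j) = yo; tbY(i, j) = 1; }
      else          { Y(i, j) = ye; tbY(i, j) = 3; }

      // M: residue i aligned to column j (M(i-1,j-1) >= 0 covers the
      // fresh-start case; the 0 floor terminates local alignments)
      double d = M(i - 1, j - 1); int code = 1;
      if (X(i - 1, j - 1) > d) { d = X(i - 1, j - 1); code = 2; }
      if (Y(i - 1, j - 1) > d) { d = Y(i - 1, j - 1); code = 3; }
      double val = d + s;
      if (val < 0) val = 0;
      M(i, j) = val; tbM(i, j) = code;
      if (val > best) { best = val; bi = i; bj = j; }
    }
  }

  if (best <= 0 || bi < 0)
    return List::create(_["score"] = 0.0);

  int i = bi, j = bj, state = 1;
  std::vector<char> prof_cols;  // built backwards, one entry per column used
  int seq_start = bi, prof_start = bj;
  while (true) {
    if (state == 1) {
      if (M(i, j) <= 0) break;          // local start reached
      int code = tbM(i, j);
      prof_cols.push_back(seq_str[i - 1]);
      seq_start = i; prof_start = j;
      --i; --j;
      state = code;
    } else if (state == 2) {
      int code = tbX(i, j);
      prof_cols.push_back('-');
      prof_start = j;
      --j;
      state = code;
    } else {
      int code = tbY(i, j);
      seq_start = i;
      --i;
      state = code;
    }
  }
  std::reverse(prof_cols.begin(), prof_cols.end());
  std::string aligned(prof_cols.begin(), prof_cols.end());
  return List::create(_["score"] = best,
                      _["seq_start"] = seq_start, _["seq_end"] = bi,
                      _["prof_start"] = prof_start, _["prof_end"] = bj,
                      _["aligned"] = aligned);
}

static inline char complement(char b) {
  switch (b) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

// Scan the terminal windows of an element for (degenerate) terminal
// inverted repeats: the left segment element[i..i+l-1] is compared against
// the reverse complement of the right segment element[j-l+1..j] (0-based
// internally). Candidate placements need length >= min_len and a mismatch
// fraction <= max_mismatch_frac; among them the placement maximising
// matches - mismatches wins, so chance-complementary single bases beyond a
// repeat's true end cannot drag the boundary outward. Ties prefer the more
// compact (shorter) placement, then a left segment closer to the element
// start, then a right segment closer to the element end.
// Output is 1-based inclusive: (left_start, left_end, right_start,
// right_end, mismatches); empty vector when nothing qualifies.
// [[Rcpp::export]]
IntegerVector tir_scan_cpp(std::string element, int window, int min_len,
                           double max_mismatch_frac) {
  const int L = element.size();
  if (L < 2 * window) return IntegerVector(0);
  const int NONE = -2000000000;
  int best_score = NONE, best_len = 0, best_i = -1, best_j = -1, best_mm = 0;
  for (int i = 0; i < window; ++i) {            // left segment start
    for (int j = L - 1; j >= L - window; --j) { // right segment end
      int lmax = std::min(window - i, j - (L - window) + 1);
      int matches = 0;
      for (int l = 1; l <= lmax; ++l) {
        if (element[i + l - 1] == complement(element[j - l + 1])) ++matches;
        if (l < min_len) continue;
        int mism = l - matches;
        if ((double)mism / l > max_mismatch_frac) continue;
        int score = matches - mism;
        bool better = score > best_score ||
          (score == best_score && (l < best_len ||
            (l == best_len && (i < best_i ||
              (i == best_i && j > best_j)))));
        if (better) {
          best_score = score; best_len = l; best_i = i; best_j = j;
          best_mm = mism;
        }
      }
    }
  }
  if (best_score == NONE) return IntegerVector(0);
  return IntegerVector::create(best_i + 1, best_i + best_len,
                               best_j - best_len + 2, best_j + 1,
                               best_mm);
}
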