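#include <Rcpp.h>
using namespace Rcpp;

// Glocal (global-in-profile, local-in-query) alignment of a query against a
// column-wise log-odds profile with affine gap costs.
//
// lo        : L x 20 matrix of per-column log-odds scores (bits)
// qidx      : query residue indices, 0..19, or -1 for 'X' (scores 0 everywhere)
// gap_open  : cost charged once per gap run (bits, positive)
// gap_extend: cost charged per gapped position (bits, positive)
//
// A gap run of length k costs gap_open + k * gap_extend. Every profile column
// must be consumed (matched or deleted); query residues before the first and
// after the last column event are free overhangs. Insertions are query
// residues consumed strictly between column events. All state transitions are
// allowed; moving between a deletion run and an insertion run opens a new gap.
//
// Traceback tie-break: match > deletion > insertion at equal score, and at the
// terminal cell smaller consumed-query prefixes are preferred, so output is
// bit-reproducible.

static const double NEG = -1e30;

// [[Rcpp::export]]
List glocal_align_cpp(NumericMatrix lo, IntegerVector qidx,
                      double gap_open, double gap_extend) {
  const int L = lo.nrow();
  const int n = qidx.size();
  if (L < 1) stop("profile must have at least one match column");

  // score matrices, (n+1) rows (query prefix consumed) x L cols (1-based col j
  // stored at j-1)
  NumericMatrix M(n + 1, L), D(n + 1, L), I(n + 1, L);
  // traceback: predecessor state 0=M 1=D 2=I 3=start
  IntegerMatrix tM(n + 1, L), tD(n + 1, L), tI(n + 1, L);

  const double gop = gap_open + gap_extend; // cost of first gapped position

  for (int j = 0; j < L; ++j) {
    for (int i = 0; i <= n; ++i) {
      // M: query residue i aligned to column j (requires i >= 1)
      double m = NEG; int tm = -1;
      if (i >= 1) {
        double sub = (qidx[i - 1] < 0) ? 0.0 : lo(j, qidx[i - 1]);
        double best; int tb;
        if (j == 0) { best = 0.0; tb = 3; } // leading overhang of i-1 residues
        else {
          best = M(i - 1, j - 1); tb = 0;
          if (D(i - 1, j - 1) > best) { best = D(i - 1, j - 1); tb = 1; }
          if (I(i - 1, j - 1) > best) { best = I(i - 1, j - 1); tb = 2; }
        }
        if (best > NEG / 2) { m = best + sub; tm = tb; }
      }
      M(i, j) = m; tM(i, j) = tm;

      // D: column j deleted, i residues consumed so far
      double d; int td;
      if (j == 0) { d = -gop; td = 3; } // leading overhang of i residues
      else {
        d = M(i, j - 1) - gop; td = 0;
        if (D(i, j - 1) - gap_extend > d) { d = D(i, j - 1) - gap_extend; td = 1; }
        if (I(i, j - 1) - gop > d) { d = I(i, j - 1) - gop; td = 2; }
      }
      D(i, j) = d; tD(i, j) = td;

      // I: query residue i inserted after column j (requires i >= 1); an
      // insertion after the final column would be a free overhang, exclude.
      double ins = NEG; int ti = -1;
      if (i >= 1 && j < L - 1) {
        ins = M(i - 1, j) - gop; ti = 0;
        if (D(i - 1, j) - gop > ins) { ins = D(i - 1, j) - gop; ti = 1; }
        if (I(i - 1, j) - gap_extend > ins) { ins = I(i - 1, j) - gap_extend; ti = 2; }
      }
      I(i, j) = ins; tI(i, j) = ti;
    }
  }

  // terminal: any trailing overhang is free
  double best = NEG; int bi = 0, bs = 0;
  for (int i = 0; i <= n; ++i) {
    if (M(i, L - 1) > best) { best = M(i, L - 1); bi = i; bs = 0; }
  }
  for (int i = 0; i <= n; ++i) {
    if (D(i, L - 1) > best) { best = D(i, L - 1); bi = i; bs = 1; }
  }

  // traceback
  std::vector<int> qpos, col;
  int i = bi, j = L - 1, s = bs;
  int lead = 0;
  while (true) {
    int prev;
    if (s == 0) {
      prev = tM(i, j); qpos.push_back(i); col.push_back(j + 1);
      if (prev == 3) { lead = i - 1; break; }
      --i; --j;
    } else if (s == 1) {
      prev = tD(i, j);
      if (prev == 3) { lead = i; break; }
      --j;
    } else {
      prev = tI(i, j);
      --i;
    }
    s = prev;
  }
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(col.begin(), col.end());

  IntegerMatrix path(qpos.size(), 2);
  for (size_t r = 0; r < qpos.size(); ++r) {
    path(r, 0) = qpos[r];
    path(r, 1) = col[r];
  }

  return List::create(_["score"] = best,
                      _["path"] = path,
                      _["lead"] = lead,
                      _["trail"] = n - bi);
}
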