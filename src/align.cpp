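#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps, Gotoh recursion.
// The substitution matrix arrives as a 26x26 lookup indexed by 'A'..'Z'.
// A gap of length L costs open + ext * L (BLAST convention: open=11, ext=1
// means a length-1 gap costs 12).
//
// DP buffers are reused across the batch; only the top/left borders need
// initialization because interior cells are written in scan order before
// they are read.

namespace {

struct AlnResult {
  int score, nmatch, mismatches, gap_opens, aln_len;
  int q_start, q_end, s_start, s_end;
};

const int NEG = -1000000000;

struct Workspace {
  std::vector<int> M, X, Y;
  std::vector<unsigned char> tbM, tbX, tbY;
  void ensure(size_t cells) {
    if (M.size() < cells) {
      M.resize(cells); X.resize(cells); Y.resize(cells);
      tbM.resize(cells); tbX.resize(cells); tbY.resize(cells);
    }
  }
};

AlnResult sw_one(const std::string &a, const std::string &b,
                 const int sub[26][26], int open, int ext, Workspace &ws) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = m + 1;
  ws.ensure((size_t)(n + 1) * W);
  int *M = ws.M.data(), *X = ws.X.data(), *Y = ws.Y.data();
  unsigned char *tbM = ws.tbM.data(), *tbX = ws.tbX.data(),
                *tbY = ws.tbY.data();
  for (int j = 0; j <= m; ++j) { M[j] = 0; X[j] = NEG; Y[j] = NEG; tbM[j] = 0; }
  for (int i = 0; i <= n; ++i) {
    M[i * W] = 0; X[i * W] = NEG; Y[i * W] = NEG; tbM[i * W] = 0;
  }

  int best = 0, bi = 0, bj = 0;
  const int oe = open + ext;
  for (int i = 1; i <= n; ++i) {
    const int *srow = sub[a[i - 1] - 'A'];
    int *Mr = M + i * W, *Mu = M + (i - 1) * W;
    int *Xr = X + i * W, *Xu = X + (i - 1) * W;
    int *Yr = Y + i * W;
    unsigned char *tMr = tbM + i * W, *tXr = tbX + i * W, *tYr = tbY + i * W;
    for (int j = 1; j <= m; ++j) {
      int x_open = Mu[j] - oe, x_ext = Xu[j] - ext;
      int xv; unsigned char xo;
      if (x_open >= x_ext) { xv = x_open; xo = 1; } else { xv = x_ext; xo = 0; }
      Xr[j] = xv; tXr[j] = xo;
      int y_open = Mr[j - 1] - oe, y_ext = Yr[j - 1] - ext;
      int yv; unsigned char yo;
      if (y_open >= y_ext) { yv = y_open; yo = 1; } else { yv = y_ext; yo = 0; }
      Yr[j] = yv; tYr[j] = yo;
      int v = Mu[j - 1] + srow[b[j - 1] - 'A'];
      unsigned char t = 1;
      if (xv > v) { v = xv; t = 2; }
      if (yv > v) { v = yv; t = 3; }
      if (v <= 0) { v = 0; t = 0; }
      Mr[j] = v; tMr[j] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }

  AlnResult r; r.score = best;
  r.nmatch = 0; r.mismatches = 0; r.gap_opens = 0; r.aln_len = 0;
  r.q_start = r.q_end = r.s_start = r.s_end = 0;
  if (best <= 0) return r;
  r.q_end = bi; r.s_end = bj;
  int i = bi, j = bj, state = 1; // 1=M, 2=X, 3=Y
  while (i > 0 && j > 0) {
    const size_t idx = (size_t)i * W + j;
    if (state == 1) {
      const unsigned char t = tbM[idx];
      if (M[idx] <= 0 || t == 0) break;
      if (t == 1) {
        ++r.aln_len;
        if (a[i - 1] == b[j - 1]) ++r.nmatch; else ++r.mismatches;
        --i; --j;
      } else {
        state = t; // switch to the gap matrix at this same cell
      }
    } else if (state == 2) {
      ++r.aln_len; // a[i] against a gap in b
      const unsigned char opened = tbX[idx];
      --i;
      if (opened) { ++r.gap_opens; state = 1; }
    } else {
      ++r.aln_len; // b[j] against a gap in a
      const unsigned char opened = tbY[idx];
      --j;
      if (opened) { ++r.gap_opens; state = 1; }
    }
  }
  r.q_start = i + 1; r.s_start = j + 1;
  return r;
}

} // namespace

// [[Rcpp::export(name = ".sw_align_batch")]]
DataFrame sw_align_batch(CharacterVector qseq, CharacterVector sseq,
                         IntegerMatrix sub, int gap_open, int gap_ext) {
  const int k = qseq.size();
  if (sseq.size() != k) stop("qseq and sseq must have equal length");
  int subc[26][26];
  for (int i = 0; i < 26; ++i)
    for (int j = 0; j < 26; ++j) subc[i][j] = sub(i, j);
  Workspace ws;
  IntegerVector score(k), nmatch(k), mism(k), gapo(k), alen(k),
      qs(k), qe(k), ss(k), se(k);
  for (int t = 0; t < k; ++t) {
    std::string a = as<std::string>(qseq[t]);
    std::string b = as<std::string>(sseq[t]);
    AlnResult r = sw_one(a, b, subc, gap_open, gap_ext, ws);
    score[t] = r.score; nmatch[t] = r.nmatch; mism[t] = r.mismatches;
    gapo[t] = r.gap_opens; alen[t] = r.aln_len;
    qs[t] = r.q_start; qe[t] = r.q_end; ss[t] = r.s_start; se[t] = r.s_end;
  }
  return DataFrame::create(
      _["raw_score"] = score, _["nmatch"] = nmatch, _["mismatches"] = mism,
      _["gap_opens"] = gapo, _["aln_len"] = alen,
      _["q_start"] = qs, _["q_end"] = qe,
      _["s_start"] = ss, _["s_end"] = se);
}
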