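#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Gotoh affine-gap global alignment, score-maximising.
// Gap of length L costs gap_open + (L-1)*gap_extend (the first gapped
// residue pays the opening penalty only).
// Deterministic tie-break, applied both in the cell maximisation and the
// traceback: diagonal (substitution) > gap-in-A > gap-in-B, where
// "gap-in-A" means a gap character placed in sequence A (a column that
// consumes a residue of B only).
//
// Scores are kept in two rolling rows per state; the traceback is a full
// byte matrix (2 bits per state), so memory is (n+1)*(m+1) bytes.

namespace {

const double NEG_INF = -1e30;

enum State { SM = 0, SX = 1, SY = 2 }; // M diagonal, X gap-in-A, Y gap-in-B

inline int argmax3(double m, double x, double y) {
  double best = m; int arg = SM;          // tie preference M > X > Y
  if (x > best) { best = x; arg = SX; }
  if (y > best) { best = y; arg = SY; }
  return arg;
}

inline double pick3(int arg, double m, double x, double y) {
  return arg == SM ? m : arg == SX ? x : y;
}

} // namespace

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b,
                 NumericMatrix submat, std::string alphabet,
                 double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if ((double)(n + 1) * (double)(m + 1) > 4.0e8)
    stop("sequences too long for full dynamic-programming alignment");

  int lut[256];
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    lut[(unsigned char)alphabet[i]] = (int)i;
  for (int i = 0; i < n; ++i)
    if (lut[(unsigned char)a[i]] < 0) stop("character not in scoring alphabet");
  for (int j = 0; j < m; ++j)
    if (lut[(unsigned char)b[j]] < 0) stop("character not in scoring alphabet");

  // substitution scores as flat C array for speed
  const int K = submat.nrow();
  std::vector<double> sub((size_t)K * K);
  for (int r = 0; r < K; ++r)
    for (int c = 0; c < K; ++c) sub[(size_t)r * K + c] = submat(r, c);

  const int w = m + 1;
  std::vector<double> Mprev(w), Xprev(w), Yprev(w), Mcur(w), Xcur(w), Ycur(w);
  std::vector<unsigned char> tb((size_t)(n + 1) * w, 0);

  // row 0: only X (leading gap in A) reachable past the origin
  Mprev[0] = 0.0; Xprev[0] = NEG_INF; Yprev[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG_INF; Yprev[j] = NEG_INF;
    Xprev[j] = gap_open + (j - 1) * gap_extend;
    tb[j] |= (unsigned char)((j == 1 ? SM : SX) << 2);
  }

  std::vector<int> bidx(m);
  for (int j = 0; j < m; ++j) bidx[j] = lut[(unsigned char)b[j]];

  for (int i = 1; i <= n; ++i) {
    const int ai = lut[(unsigned char)a[i - 1]];
    const double *srow = &sub[(size_t)ai * K];
    unsigned char *trow = &tb[(size_t)i * w];
    Mcur[0] = NEG_INF; Xcur[0] = NEG_INF;
    Ycur[0] = gap_open + (i - 1) * gap_extend;
    trow[0] |= (unsigned char)((i == 1 ? SM : SY) << 4);
    for (int j = 1; j <= m; ++j) {
      const double s = srow[bidx[j - 1]];
      // M from diagonal predecessors
      {
        int arg = argmax3(Mprev[j - 1], Xprev[j - 1], Yprev[j - 1]);
        double best = pick3(arg, Mprev[j - 1], Xprev[j - 1], Yprev[j - 1]);
        Mcur[j] = (best > NEG_INF / 2) ? best + s : NEG_INF;
        trow[j] |= (unsigned char)arg;
      }
      // X: gap in A, horizontal
      {
        double fm = Mcur[j - 1] + gap_open;
        double fx = Xcur[j - 1] + gap_extend;
        double fy = Ycur[j - 1] + gap_open;
        int arg = argmax3(fm, fx, fy);
        Xcur[j] = pick3(arg, fm, fx, fy);
        trow[j] |= (unsigned char)(arg << 2);
      }
      // Y: gap in B, vertical
      {
        double fm = Mprev[j] + gap_open;
        double fx = Xprev[j] + gap_open;
        double fy = Yprev[j] + gap_extend;
        int arg = argmax3(fm, fx, fy);
        Ycur[j] = pick3(arg, fm, fx, fy);
        trow[j] |= (unsigned char)(arg << 4);
      }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  int state = argmax3(Mprev[m], Xprev[m], Yprev[m]);
  double score = pick3(state, Mprev[m], Xprev[m], Yprev[m]);

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t k = (size_t)i * w + j;
    int prev = (tb[k] >> (2 * state)) & 3;
    if (state == SM) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (state == SX) {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    } else {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    }
    state = prev;
    if (i == 0 && j > 0) state = SX;
    if (j == 0 && i > 0) state = SY;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}
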