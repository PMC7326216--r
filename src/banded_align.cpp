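#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// Banded global alignment with affine gaps (Gotoh). A gap of length L costs
// gap_open + L * gap_extend. Cells with |i - j| > band are unreachable.

namespace {
const double NEG = -1e30;
enum State { MAT = 0, INS = 1, DEL = 2 };  // INS consumes A only, DEL consumes B only
}

// [[Rcpp::export(name = ".banded_align_cpp")]]
List banded_align_cpp(std::string a, std::string b, int band,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  if (std::abs(n - m) >= band)
    stop("length difference (%d) exceeds band width (%d)", std::abs(n - m), band);
  int W = 2 * band + 1;

  // traceback: 0/1/2 = predecessor state, per cell per state
  std::vector<signed char> tb((size_t)(n + 1) * W * 3, -1);
  std::vector<double> Mrow(W, NEG), Irow(W, NEG), Drow(W, NEG);
  std::vector<double> Mprev(W, NEG), Iprev(W, NEG), Dprev(W, NEG);

  auto col = [&](int i, int j) { return j - i + band; };  // band-local index

  // row 0: leading gaps in A (DEL consumes B)
  Mprev[col(0, 0)] = 0.0;
  for (int j = 1; j <= std::min(m, band); ++j) {
    int c = col(0, j);
    Dprev[c] = gap_open + j * gap_extend;
    tb[(size_t)(0 * W + c) * 3 + DEL] = j == 1 ? MAT : DEL;
  }

  for (int i = 1; i <= n; ++i) {
    std::fill(Mrow.begin(), Mrow.end(), NEG);
    std::fill(Irow.begin(), Irow.end(), NEG);
    std::fill(Drow.begin(), Drow.end(), NEG);
    int jlo = std::max(0, i - band), jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int c = col(i, j);
      size_t base = ((size_t)i * W + c) * 3;
      // INS: consume a[i-1], from row i-1 same j (band index shifts by +1)
      if (j - (i - 1) + band < W) {
        int cu = j - (i - 1) + band;
        double open = std::max(Mprev[cu], Dprev[cu]) + gap_open + gap_extend;
        double ext = Iprev[cu] + gap_extend;
        if (open >= ext && open > NEG / 2) {
          Irow[c] = open;
          tb[base + INS] = Mprev[cu] >= Dprev[cu] ? MAT : DEL;
        } else if (ext > NEG / 2) {
          Irow[c] = ext;
          tb[base + INS] = INS;
        }
      }
      // DEL: consume b[j-1], from same row j-1 (band index c-1)
      if (j > jlo) {
        double open = std::max(Mrow[c - 1], Irow[c - 1]) + gap_open + gap_extend;
        double ext = Drow[c - 1] + gap_extend;
        if (open >= ext && open > NEG / 2) {
          Drow[c] = open;
          tb[base + DEL] = Mrow[c - 1] >= Irow[c - 1] ? MAT : INS;
        } else if (ext > NEG / 2) {
          Drow[c] = ext;
          tb[base + DEL] = DEL;
        }
      }
      // MAT: consume both, from row i-1, j-1 (same band index)
      if (j > 0) {
        double s = (a[i - 1] == b[j - 1] &&
                    (a[i - 1] == 'A' || a[i - 1] == 'C' ||
                     a[i - 1] == 'G' || a[i - 1] == 'T'))
                       ? match
                       : mismatch;
        double best = Mprev[c];
        signed char from = MAT;
        if (Iprev[c] > best) { best = Iprev[c]; from = INS; }
        if (Dprev[c] > best) { best = Dprev[c]; from = DEL; }
        if (best > NEG / 2) {
          Mrow[c] = best + s;
          tb[base + MAT] = from;
        }
      }
    }
    std::swap(Mrow, Mprev);
    std::swap(Irow, Iprev);
    std::swap(Drow, Dprev);
  }

  int cend = col(n, m);
  double sc = Mprev[cend];
  int state = MAT;
  if (Iprev[cend] > sc) { sc = Iprev[cend]; state = INS; }
  if (Dprev[cend] > sc) { sc = Dprev[cend]; state = DEL; }
  if (sc < NEG / 2) stop("no alignment within band; widen band_width");

  // traceback
  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int c = col(i, j);
    signed char prev = tb[((size_t)i * W + c) * 3 + state];
    if (state == MAT) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i; --j;
    } else if (state == INS) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
    }
    state = prev;
  }
  std::string fa(ra.rbegin(), ra.rend()), fb(rb.rbegin(), rb.rend());
  return List::create(_["aligned_a"] = fa, _["aligned_b"] = fb, _["score"] = sc);
}
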