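#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

// 2-bit packed nucleotide comparison. Each base occupies two bits in a
// uint64 lattice; ambiguous bases (anything outside ACGT) are flagged in a
// parallel mask and always count as mismatches.

namespace {

const uint64_t LO_BITS = 0x5555555555555555ULL;

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct Packed {
  std::vector<uint64_t> bits;  // 2 bits per base
  std::vector<uint64_t> amb;   // 01 at ambiguous base slots
  int len;
};

Packed pack_str(const char* s, int start, int len) {
  Packed p;
  int nw = (len + 31) / 32;
  p.bits.assign(nw, 0);
  p.amb.assign(nw, 0);
  p.len = len;
  for (int i = 0; i < len; ++i) {
    int c = base_code(s[start + i]);
    int w = i >> 5, off = (i & 31) << 1;
    if (c < 0)
      p.amb[w] |= 1ULL << off;
    else
      p.bits[w] |= static_cast<uint64_t>(c) << off;
  }
  return p;
}

// mismatches over the first `len` bases of two packed sequences
inline int mismatches(const std::vector<uint64_t>& a_bits,
                      const std::vector<uint64_t>& a_amb,
                      const std::vector<uint64_t>& b_bits,
                      const std::vector<uint64_t>& b_amb,
                      int len) {
  int nw = (len + 31) / 32;
  int m = 0;
  for (int w = 0; w < nw; ++w) {
    uint64_t x = a_bits[w] ^ b_bits[w];
    uint64_t bad = ((x | (x >> 1)) & LO_BITS) | a_amb[w] | b_amb[w];
    if (w == nw - 1 && (len & 31))
      bad &= (1ULL << ((len & 31) << 1)) - 1;
    m += __builtin_popcountll(bad);
  }
  return m;
}

// shift a packed sequence left by `off` bases (drop the first `off`)
inline void shift_words(const std::vector<uint64_t>& in, std::vector<uint64_t>& out,
                        int off) {
  int nw = in.size();
  int wshift = off >> 5, bshift = (off & 31) << 1;
  for (int w = 0; w < nw; ++w) {
    uint64_t lo = (w + wshift < nw) ? in[w + wshift] : 0ULL;
    uint64_t hi = (w + wshift + 1 < nw) ? in[w + wshift + 1] : 0ULL;
    out[w] = bshift ? ((lo >> bshift) | (hi << (64 - bshift))) : lo;
  }
}

std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': case 'a': c = 'T'; break;
      case 'C': case 'c': c = 'G'; break;
      case 'G': case 'g': c = 'C'; break;
      case 'T': case 't': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

}  // namespace

// [[Rcpp::export(name = ".bait_identity_cpp")]]
NumericVector bait_identity_cpp(CharacterVector fragments, CharacterVector baits) {
  int nb = baits.size();
  if (nb == 0) stop("empty bait set");
  int B = LENGTH(STRING_ELT(baits, 0));
  std::vector<Packed> pb(nb);
  for (int k = 0; k < nb; ++k) {
    const char* s = CHAR(STRING_ELT(baits, k));
    if ((int)strlen(s) != B) stop("baits must all have equal length");
    pb[k] = pack_str(s, 0, B);
  }

  int nf = fragments.size();
  NumericVector out(nf);
  std::vector<uint64_t> sb((B + 31) / 32), sa((B + 31) / 32);

  for (int fi = 0; fi < nf; ++fi) {
    std::string fwd = as<std::string>(fragments[fi]);
    int f = fwd.size();
    if (f == 0) stop("empty fragment");
    std::string rev = revcomp_str(fwd);
    int cmp_len = std::min(f, B);
    int best_mism = cmp_len + 1;

    for (int ori = 0; ori < 2 && best_mism > 0; ++ori) {
      const std::string& seq = ori == 0 ? fwd : rev;
      if (f >= B) {
        // slide the fragment: windows of length B vs whole baits
        int nwin = f - B + 1;
        std::vector<Packed> win(nwin);
        for (int o = 0; o < nwin; ++o) win[o] = pack_str(seq.c_str(), o, B);
        for (int k = 0; k < nb && best_mism > 0; ++k)
          for (int o = 0; o < nwin; ++o) {
            int m = mismatches(win[o].bits, win[o].amb, pb[k].bits, pb[k].amb, B);
            if (m < best_mism) best_mism = m;
          }
      } else {
        // slide each bait: windows of length f vs whole fragment
        Packed pf = pack_str(seq.c_str(), 0, f);
        int noff = B - f + 1;
        for (int k = 0; k < nb && best_mism > 0; ++k)
          for (int o = 0; o < noff; ++o) {
            shift_words(pb[k].bits, sb, o);
            shift_words(pb[k].amb, sa, o);
            int m = mismatches(pf.bits, pf.amb, sb, sa, f);
            if (m < best_mism) best_mism = m;
          }
      }
    }
    out[fi] = 1.0 - static_cast<double>(best_mism) / cmp_len;
  }
  return out;
}
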