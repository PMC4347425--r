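#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps and traceback.
// A gap of length L costs gap_open + (L - 1) * gap_ext (both supplied
// negative). Result coordinates are 0-based half-open on query and target.
// [[Rcpp::export]]
List cpp_sw(std::string q, std::string t, double match, double mismatch,
            double gap_open, double gap_ext) {
  const int n = q.size(), m = t.size();
  const double NEG = -1e18;
  // Rolling score rows; full byte traceback matrices.
  // H: best score ending at (i,j); E: ending with gap in query (consumes a
  // target char); F: ending with gap in target (consumes a query char).
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Fprev(m + 1, NEG), Fcur(m + 1, NEG);
  std::vector<double> Ecur(m + 1, NEG);
  // ptrH codes: 0 stop, 1 diagonal, 2 from E, 3 from F
  // ptrE/ptrF: 1 if gap extended, 0 if gap opened from H
  std::vector<uint8_t> ptrH((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> ptrE((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> ptrF((size_t)(n + 1) * (m + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0; Ecur[0] = NEG;
    const char qc = q[i - 1];
    size_t row = (size_t)i * (m + 1);
    for (int j = 1; j <= m; ++j) {
      size_t idx = row + j;
      double e_open = Hcur[j - 1] + gap_open, e_ext = Ecur[j - 1] + gap_ext;
      if (e_ext > e_open) { Ecur[j] = e_ext; ptrE[idx] = 1; }
      else                { Ecur[j] = e_open; ptrE[idx] = 0; }
      double f_open = Hprev[j] + gap_open, f_ext = Fprev[j] + gap_ext;
      if (f_ext > f_open) { Fcur[j] = f_ext; ptrF[idx] = 1; }
      else                { Fcur[j] = f_open; ptrF[idx] = 0; }
      double s = (qc == t[j - 1]) ? match : mismatch;
      double diag = Hprev[j - 1] + s;
      double h = 0.0; uint8_t p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; p = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; p = 3; }
      Hcur[j] = h; ptrH[idx] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["t_start"] = NA_INTEGER,
                        _["t_end"] = NA_INTEGER, _["matches"] = 0,
                        _["aligned_cols"] = 0, _["gap_cols"] = 0);
  }

  // traceback from the best cell
  int i = bi, j = bj;
  int matches = 0, cols = 0, gaps = 0;
  int state = 0; // 0 = H, 2 = E, 3 = F
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      uint8_t p = ptrH[idx];
      if (p == 0) break;
      if (p == 1) {
        ++cols;
        if (q[i - 1] == t[j - 1]) ++matches;
        --i; --j;
      } else {
        state = p;
      }
    } else if (state == 2) { // gap in query, consume target char
      ++cols; ++gaps;
      uint8_t ext = ptrE[idx];
      --j;
      if (!ext) state = 0;
    } else {                 // gap in target, consume query char
      ++cols; ++gaps;
      uint8_t ext = ptrF[idx];
      --i;
      if (!ext) state = 0;
    }
  }
  return List::create(_["score"] = best, _["q_start"] = i, _["q_end"] = bi,
                      _["t_start"] = j, _["t_end"] = bj,
                      _["matches"] = matches, _["aligned_cols"] = cols,
                      _["gap_cols"] = gaps);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Exact k-mer seed matches between query and target (forward orientation),
// 2-bit encoded; k-mers containing non-ACGT characters are skipped.
// Returns a two-column matrix of 0-based (qpos, tpos).
// [[Rcpp::export]]
IntegerMatrix cpp_seed_hits(std::string q, std::string t, int k) {
  const int n = q.size(), m = t.size();
  std::vector<int> qpos_out, tpos_out;
  if (k < 1 || k > 15 || n < k || m < k) {
    IntegerMatrix empty(0, 2);
    colnames(empty) = CharacterVector::create("qpos", "tpos");
    return empty;
  }
  const uint32_t mask = (1u << (2 * k)) - 1u;
  std::unordered_map<uint32_t, std::vector<int> > index;
  {
    uint32_t w = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = base_code(q[i]);
      if (c < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint32_t)c) & mask;
      if (++run >= k) index[w].push_back(i - k + 1);
    }
  }
  {
    uint32_t w = 0; int run = 0;
    for (int j = 0; j < m; ++j) {
      int c = base_code(t[j]);
      if (c < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint32_t)c) & mask;
      if (++run >= k) {
        auto it = index.find(w);
        if (it != index.end()) {
          for (int qp : it->second) {
            qpos_out.push_back(qp);
            tpos_out.push_back(j - k + 1);
          }
        }
      }
    }
  }
  IntegerMatrix out(qpos_out.size(), 2);
  for (size_t r = 0; r < qpos_out.size(); ++r) {
    out(r, 0) = qpos_out[r];
    out(r, 1) = tpos_out[r];
  }
  colnames(out) = CharacterVector::create("qpos", "tpos");
  return out;
}
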