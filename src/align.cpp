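#include <Rcpp.h>
#include <climits>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps, Gotoh recurrences.
// A gap of length L costs gapOpen + L * gapExt, matching the convention of
// Biostrings::pairwiseAlignment so the two can be compared cell for cell.
// Traceback ties are broken deterministically: diagonal > up (gap in the
// subject) > left (gap in the query); the best cell is the first maximal
// cell in row-major scan order.
//
// Traceback state is packed into one byte per cell:
//   bits 0-1: H origin (0 stop, 1 diagonal, 2 vertical F, 3 horizontal E)
//   bit 2   : E extends a previous E (else opens from H)
//   bit 3   : F extends a previous F (else opens from H)

static inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // ambiguous bases mismatch everything
  }
}

struct AlnResult {
  int score, qstart, qend, sstart, send, matches, mismatches, gaps;
  std::vector<int> qpos, spos;
};

struct AlnBuffers {
  std::vector<int> H, Hup, F;
  std::vector<uint8_t> tb;
  std::vector<int8_t> scode;
};

static void alignOne(const std::string& q, const std::string& s,
                     int match, int mismatch, int gapOpen, int gapExt,
                     bool keepPath, AlnBuffers& buf, AlnResult& res) {
  const int m = (int)q.size(), n = (int)s.size();
  const int NEG = INT_MIN / 4;
  const int go = gapOpen + gapExt;

  buf.H.assign(n + 1, 0);
  buf.Hup.assign(n + 1, 0);
  buf.F.assign(n + 1, NEG);
  buf.tb.assign((size_t)m * n, 0);
  if ((int)buf.scode.size() != n) {
    buf.scode.resize(n);
    for (int j = 0; j < n; ++j) buf.scode[j] = (int8_t)baseCode(s[j]);
  }

  int* H = buf.H.data();
  int* Hup = buf.Hup.data();
  int* F = buf.F.data();
  uint8_t* tb = buf.tb.data();
  const int8_t* scode = buf.scode.data();

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int E = NEG;
    H[0] = 0;
    const int qc = baseCode(q[i - 1]);
    uint8_t* tbrow = tb + (size_t)(i - 1) * n;
    for (int j = 1; j <= n; ++j) {
      uint8_t t;
      const int eOpen = H[j - 1] - go, eExt = E - gapExt;
      if (eOpen >= eExt) { E = eOpen; t = 0; }
      else               { E = eExt;  t = 4; }
      const int fOpen = Hup[j] - go, fExt = F[j] - gapExt;
      if (fOpen >= fExt) { F[j] = fOpen; }
      else               { F[j] = fExt;  t |= 8; }
      const int diag = Hup[j - 1] + ((qc >= 0 && qc == scode[j - 1])
                                       ? match : mismatch);
      int h = diag; uint8_t o = 1;
      if (F[j] > h) { h = F[j]; o = 2; }
      if (E > h)    { h = E;    o = 3; }
      if (h <= 0)   { h = 0;    o = 0; }
      H[j] = h; tbrow[j - 1] = t | o;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(H, Hup);
  }

  res.score = best;
  res.matches = res.mismatches = res.gaps = 0;
  res.qstart = res.qend = res.sstart = res.send = 0;
  res.qpos.clear(); res.spos.clear();

  if (best > 0) {
    res.qend = bi; res.send = bj;
    int i = bi, j = bj, state = 0;
    while (i >= 1 && j >= 1) {
      const uint8_t t = tb[(size_t)(i - 1) * n + (j - 1)];
      if (state == 0) {
        const uint8_t o = t & 3;
        if (o == 0) break;
        if (o == 1) {
          const int qc = baseCode(q[i - 1]);
          if (qc >= 0 && qc == scode[j - 1]) ++res.matches;
          else ++res.mismatches;
          if (keepPath) { res.qpos.push_back(i); res.spos.push_back(j); }
          --i; --j;
        } else {
          state = o;  // 2 = F, 3 = E
        }
      } else if (state == 2) {  // gap in subject: consume query base i
        ++res.gaps;
        if (keepPath) { res.qpos.push_back(i); res.spos.push_back(NA_INTEGER); }
        state = (t & 8) ? 2 : 0;
        --i;
      } else {  // gap in query: consume subject base j
        ++res.gaps;
        if (keepPath) { res.qpos.push_back(NA_INTEGER); res.spos.push_back(j); }
        state = (t & 4) ? 3 : 0;
        --j;
      }
    }
    res.qstart = i + 1; res.sstart = j + 1;
    std::reverse(res.qpos.begin(), res.qpos.end());
    std::reverse(res.spos.begin(), res.spos.end());
  }
}

// [[Rcpp::export]]
List alignLocalCpp(CharacterVector queries, std::string subject,
                   int match, int mismatch, int gapOpen, int gapExt,
                   bool keepPath) {
  if (subject.empty()) stop("empty subject sequence");
  const int nq = queries.size();
  IntegerMatrix stats(nq, 8);
  colnames(stats) = CharacterVector::create(
    "score", "qstart", "qend", "sstart", "send",
    "matches", "mismatches", "gaps");
  List paths(keepPath ? nq : 0);
  AlnBuffers buf;
  AlnResult res;
  for (int i = 0; i < nq; ++i) {
    const std::string q = as<std::string>(queries[i]);
    if (q.empty()) stop("empty query sequence");
    alignOne(q, subject, match, mismatch, gapOpen, gapExt, keepPath,
             buf, res);
    stats(i, 0) = res.score;
    stats(i, 1) = res.qstart; stats(i, 2) = res.qend;
    stats(i, 3) = res.sstart; stats(i, 4) = res.send;
    stats(i, 5) = res.matches; stats(i, 6) = res.mismatches;
    stats(i, 7) = res.gaps;
    if (keepPath)
      paths[i] = List::create(
        _["qpos"] = IntegerVector(res.qpos.begin(), res.qpos.end()),
        _["spos"] = IntegerVector(res.spos.begin(), res.spos.end()));
  }
  if (keepPath) return List::create(_["stats"] = stats, _["paths"] = paths);
  return List::create(_["stats"] = stats);
}
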