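#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Affine-gap Smith-Waterman with full traceback.
//
// Scoring: substitution matrix indexed by 'A'..'Z' (26 x 26); a gap of
// length L costs gap_open + L * gap_ext (the first gapped residue pays
// gap_open + gap_ext, each further residue gap_ext), matching the usual
// protein-BLAST convention for "open 11, extend 1".
//
// Determinism: the optimal local alignment never ends in a gap, so the best
// cell is sought over the match state only. Among equal-score end cells
// (scanned in (i, j) order, capped at MAX_TIES) each candidate is traced
// back with a fixed state preference (match > gap-in-target > gap-in-query)
// and the winner is the alignment with the smallest query start, then the
// smallest target start, then smallest query/target end.

static const int NEG_INF = -1000000000;
static const int MAX_TIES = 64;

struct Traced {
  int qs, qe, ts, te, nid, ncol;
};

static Traced traceback(const std::vector<int>& M, const std::vector<int>& X,
                        const std::vector<int>& Y, int cols,
                        const std::string& a, const std::string& b,
                        const IntegerMatrix& sub, int go, int ge,
                        int i, int j) {
  Traced tr;
  tr.qe = i;
  tr.te = j;
  tr.nid = 0;
  tr.ncol = 0;
  int state = 0; // 0 = M, 1 = X (gap in target, consume query), 2 = Y
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * cols + j;
    if (state == 0) {
      int s = sub(a[i - 1] - 'A', b[j - 1] - 'A');
      if (a[i - 1] == b[j - 1]) tr.nid++;
      tr.ncol++;
      size_t d = (size_t)(i - 1) * cols + (j - 1);
      int prev = M[idx] - s;
      i--; j--;
      // a zero-score prefix is not part of the alignment: start here
      if (prev <= 0) break;
      if (M[d] == prev) state = 0;
      else if (X[d] == prev) state = 1;
      else state = 2;
    } else if (state == 1) {
      // gap in target: consumed a[i-1]
      tr.ncol++;
      size_t u = (size_t)(i - 1) * cols + j;
      if (M[u] - (go + ge) == X[idx]) state = 0;
      else state = 1;
      i--;
    } else {
      tr.ncol++;
      size_t l = (size_t)i * cols + (j - 1);
      if (M[l] - (go + ge) == Y[idx]) state = 0;
      else state = 2;
      j--;
    }
  }
  tr.qs = i + 1;
  tr.ts = j + 1;
  return tr;
}

// [[Rcpp::export]]
List cpp_sw_align(std::string a, std::string b, IntegerMatrix sub,
                  int gap_open, int gap_ext) {
  int n = (int)a.size(), m = (int)b.size();
  int cols = m + 1;
  std::vector<int> M((size_t)(n + 1) * cols, 0);
  std::vector<int> X((size_t)(n + 1) * cols, NEG_INF);
  std::vector<int> Y((size_t)(n + 1) * cols, NEG_INF);

  int best = 0;
  std::vector<std::pair<int, int> > ends;
  for (int i = 1; i <= n; i++) {
    int ai = a[i - 1] - 'A';
    size_t row = (size_t)i * cols;
    size_t prow = (size_t)(i - 1) * cols;
    for (int j = 1; j <= m; j++) {
      int x = std::max(M[prow + j] - (gap_open + gap_ext),
                       X[prow + j] == NEG_INF ? NEG_INF : X[prow + j] - gap_ext);
      int y = std::max(M[row + j - 1] - (gap_open + gap_ext),
                       Y[row + j - 1] == NEG_INF ? NEG_INF : Y[row + j - 1] - gap_ext);
      int diag = std::max(std::max(M[prow + j - 1], X[prow + j - 1]),
                          Y[prow + j - 1]);
      int mm = diag + sub(ai, b[j - 1] - 'A');
      if (mm < 0) mm = 0;
      M[row + j] = mm;
      X[row + j] = x;
      Y[row + j] = y;
      if (mm > best) {
        best = mm;
        ends.clear();
        ends.push_back(std::make_pair(i, j));
      } else if (mm == best && best > 0 && (int)ends.size() < MAX_TIES) {
        ends.push_back(std::make_pair(i, j));
      }
    }
  }

  if (best <= 0) {
    return List::create(_["score"] = 0, _["found"] = false);
  }

  Traced bt;
  bool have = false;
  for (size_t k = 0; k < ends.size(); k++) {
    Traced tr = traceback(M, X, Y, cols, a, b, sub, gap_open, gap_ext,
                          ends[k].first, ends[k].second);
    if (!have ||
        tr.qs < bt.qs ||
        (tr.qs == bt.qs && (tr.ts < bt.ts ||
          (tr.ts == bt.ts && (tr.qe < bt.qe ||
            (tr.qe == bt.qe && tr.te < bt.te)))))) {
      bt = tr;
      have = true;
    }
  }

  return List::create(
    _["score"] = best, _["found"] = true,
    _["qstart"] = bt.qs, _["qend"] = bt.qe,
    _["tstart"] = bt.ts, _["tend"] = bt.te,
    _["nident"] = bt.nid, _["ncols"] = bt.ncol);
}

// 64-bit FNV-1a hash, reported as 16 hex digits. Used for stable,
// dependency-free sequence identifiers.
// [[Rcpp::export]]
CharacterVector cpp_fnv1a64(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  char buf[17];
  for (int i = 0; i < n; i++) {
    if (CharacterVector::is_na(x[i])) {
      out[i] = NA_STRING;
      continue;
    }
    const char* s = CHAR(STRING_ELT(x, i));
    uint64_t h = 14695981039346656037ULL;
    for (const char* p = s; *p; p++) {
      h ^= (uint64_t)(unsigned char)(*p);
      h *= 1099511628211ULL;
    }
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
    out[i] = buf;
  }
  return out;
}
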