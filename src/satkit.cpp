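#include <Rcpp.h>
#include <cfloat>
#include <string>
#include <vector>
using namespace Rcpp;

// N never matches anything (conservative toward the divergence ceiling).
static inline bool base_mismatch(char a, char b) {
  return a != b || a == 'N';
}

// Exhaustive wraparound scan of one sequence against one consensus.
//
// A monomer copy starting at s with rotation r reads C[(r+i) mod L] at
// genome position x = s + i, i.e. consensus index j = (x - d) mod L with
// diagonal d = (s - r) mod L. For each of the L diagonals we build the
// per-base mismatch indicator and slide a window of one monomer length;
// every window with at most max_mismatch mismatches is reported. This is
// the all-positions x all-rotations (ungapped) search, so recall on
// substitution-only truth within the divergence ceiling is exhaustive.
//
// [[Rcpp::export(name = ".scan_diagonals_cpp")]]
List scan_diagonals_cpp(std::string genome, std::string consensus,
                        int max_mismatch) {
  const int G = (int)genome.size();
  const int L = (int)consensus.size();
  std::vector<int> starts, diags, mism;
  if (G >= L && L > 0) {
    std::vector<unsigned char> mm(G);
    for (int d = 0; d < L; ++d) {
      // mismatch indicator along this diagonal
      int j = ((0 - d) % L + L) % L;
      for (int x = 0; x < G; ++x) {
        mm[x] = base_mismatch(genome[x], consensus[j]) ? 1 : 0;
        if (++j == L) j = 0;
      }
      // sliding window of length L
      int s = 0;
      int cnt = 0;
      for (int x = 0; x < L; ++x) cnt += mm[x];
      while (true) {
        if (cnt <= max_mismatch) {
          starts.push_back(s);
          diags.push_back(d);
          mism.push_back(cnt);
        }
        if (s + L >= G) break;
        cnt += mm[s + L] - mm[s];
        ++s;
      }
    }
  }
  return List::create(_["start"] = wrap(starts),
                      _["diag"] = wrap(diags),
                      _["mismatch"] = wrap(mism));
}

// Per-base mismatch indicator along one diagonal over [from, to) (0-based),
// used for array boundary refinement.
//
// [[Rcpp::export(name = ".diag_mismatch_cpp")]]
IntegerVector diag_mismatch_cpp(std::string genome, std::string consensus,
                                int d, int from, int to) {
  const int L = (int)consensus.size();
  const int G = (int)genome.size();
  if (from < 0) from = 0;
  if (to > G) to = G;
  if (to < from) to = from;
  IntegerVector out(to - from);
  int j = ((from - d) % L + L) % L;
  for (int x = from; x < to; ++x) {
    out[x - from] = base_mismatch(genome[x], consensus[j]) ? 1 : 0;
    if (++j == L) j = 0;
  }
  return out;
}

// Ungapped end-to-end matching of reads against a dimer reference.
// A read matches if at some offset of `dimer` or `dimer_rc` it aligns
// end-to-end with at most `limit` mismatches. Reads longer than the dimer
// never match (callers count and log them).
//
// [[Rcpp::export(name = ".read_matches_cpp")]]
LogicalVector read_matches_cpp(std::vector<std::string> reads,
                               std::string dimer, std::string dimer_rc,
                               int limit) {
  const int n = (int)reads.size();
  const int D = (int)dimer.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    const std::string &r = reads[i];
    const int m = (int)r.size();
    bool hit = false;
    if (m <= D && m > 0) {
      for (int strand = 0; strand < 2 && !hit; ++strand) {
        const std::string &ref = strand == 0 ? dimer : dimer_rc;
        for (int off = 0; off + m <= D && !hit; ++off) {
          int mmc = 0;
          for (int k = 0; k < m; ++k) {
            if (base_mismatch(r[k], ref[off + k])) {
              if (++mmc > limit) break;
            }
          }
          if (mmc <= limit) hit = true;
        }
      }
    }
    out[i] = hit;
  }
  return out;
}

// Maximal admissible qualifying runs for the landscape peak rule.
// Qualification: every bin (or the run maximum, rule_every_bin = false) of
// [i..j] >= factor * both outside neighbours (out-of-range = 0), at least
// one neighbour positive, run not all-zero. Admissibility: no internal
// valley whose flanking run maxima both strictly exceed it and reach
// factor * its value. Returns 1-based [from, to] rows of the maximal runs,
// overlaps resolved leftmost-first.
//
// [[Rcpp::export(name = ".peak_runs_cpp")]]
IntegerMatrix peak_runs_cpp(NumericVector v, double factor,
                            bool rule_every_bin) {
  const int K = v.size();
  const bool strict_f = factor > 1.0;
  std::vector<int> bj(K, -1);
  for (int i = 0; i < K; ++i) {
    double stat = rule_every_bin ? R_PosInf : R_NegInf;
    bool nonzero = false;
    const double ln = i > 0 ? v[i - 1] : 0.0;
    const double fl = factor * ln;
    double pm = R_NegInf;
    double min_thr = R_PosInf;
    for (int j = i; j < K; ++j) {
      const double vj = v[j];
      const bool split = strict_f ? (vj >= min_thr) : (vj > min_thr);
      if (split) break;
      const bool left_ready = pm > vj && pm >= factor * vj;
      stat = rule_every_bin ? std::min(stat, vj) : std::max(stat, vj);
      nonzero = nonzero || vj > 0;
      if (pm < vj) pm = vj;
      if (left_ready) {
        double thr = strict_f ? (vj > 0 ? factor * vj : DBL_MIN) : vj;
        if (thr < min_thr) min_thr = thr;
      }
      if (rule_every_bin && stat < fl) break;
      const double rn = j < K - 1 ? v[j + 1] : 0.0;
      if (nonzero && (ln > 0 || rn > 0) && stat >= fl && stat >= factor * rn) {
        bj[i] = j;
      }
    }
  }
  std::vector<int> from, to;
  int max_bj_seen = -1, last_end = -1;
  for (int i = 0; i < K; ++i) {
    if (bj[i] >= 0) {
      if (bj[i] > max_bj_seen && i > last_end) {
        from.push_back(i + 1);
        to.push_back(bj[i] + 1);
        last_end = bj[i];
      }
      if (bj[i] > max_bj_seen) max_bj_seen = bj[i];
    }
  }
  IntegerMatrix out(from.size(), 2);
  for (int r = 0; r < (int)from.size(); ++r) {
    out(r, 0) = from[r];
    out(r, 1) = to[r];
  }
  return out;
}

// Pairwise counts of transitions / transversions / compared sites between
// equal-length aligned rows, for distance-matrix construction.
//
// [[Rcpp::export(name = ".pairwise_ptq_cpp")]]
List pairwise_ptq_cpp(std::vector<std::string> seqs) {
  const int n = (int)seqs.size();
  NumericMatrix P(n, n), Q(n, n);
  IntegerMatrix S(n, n);
  auto is_base = [](char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T';
  };
  auto purine = [](char c) { return c == 'A' || c == 'G'; };
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const std::string &a = seqs[i], &b = seqs[j];
      int m = (int)std::min(a.size(), b.size());
      int ns = 0, ts = 0, tv = 0;
      for (int k = 0; k < m; ++k) {
        if (!is_base(a[k]) || !is_base(b[k])) continue;
        ++ns;
        if (a[k] != b[k]) {
          if (purine(a[k]) == purine(b[k])) ++ts; else ++tv;
        }
      }
      S(i, j) = S(j, i) = ns;
      P(i, j) = P(j, i) = ns > 0 ? (double)ts / ns : NA_REAL;
      Q(i, j) = Q(j, i) = ns > 0 ? (double)tv / ns : NA_REAL;
    }
  }
  return List::create(_["P"] = P, _["Q"] = Q, _["sites"] = S);
}
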