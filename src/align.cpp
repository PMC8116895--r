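#include <Rcpp.h>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Merge one read pair by best ungapped overlap of the forward read against
// the reverse-complemented mate. Qualities are Phred+33 strings. Agreements
// get q1+q2 (capped), disagreements keep the higher-quality base with
// quality |q1-q2| floored at 2.
// [[Rcpp::export(name = ".cpp_merge_pairs")]]
List cpp_merge_pairs(CharacterVector fwd, CharacterVector fwd_q,
                     CharacterVector rev_rc, CharacterVector rev_rc_q,
                     int min_overlap, double max_mismatch_frac,
                     int q_cap, int q_floor, int offset) {
  int n = fwd.size();
  CharacterVector out_seq(n), out_qual(n), status(n);
  IntegerVector out_overlap(n), out_mism(n);
  for (int i = 0; i < n; ++i) {
    std::string f = as<std::string>(fwd[i]);
    std::string fq = as<std::string>(fwd_q[i]);
    std::string r = as<std::string>(rev_rc[i]);
    std::string rq = as<std::string>(rev_rc_q[i]);
    int lf = f.size(), lr = r.size();
    int omax = std::min(lf, lr);
    int best_o = -1, best_mm = 0, best_score = INT_MIN;
    for (int o = min_overlap; o <= omax; ++o) {
      int allowed = (int)std::floor(max_mismatch_frac * o);
      int mm = 0, match = 0;
      bool ok = true;
      const char *ft = f.data() + (lf - o);
      for (int j = 0; j < o; ++j) {
        if (ft[j] == r[j]) ++match; else if (++mm > allowed) { ok = false; break; }
      }
      if (!ok) continue;
      int score = match - 4 * mm;
      if (score > best_score) { best_score = score; best_o = o; best_mm = mm; }
    }
    if (best_o < 0) {
      out_seq[i] = NA_STRING; out_qual[i] = NA_STRING;
      out_overlap[i] = NA_INTEGER; out_mism[i] = NA_INTEGER;
      status[i] = "no_overlap";
      continue;
    }
    int o = best_o;
    std::string ms; ms.reserve(lf + lr - o);
    std::string mq; mq.reserve(lf + lr - o);
    ms.append(f, 0, lf - o);
    mq.append(fq, 0, lf - o);
    for (int j = 0; j < o; ++j) {
      char bf = f[lf - o + j], br = r[j];
      int q1 = fq[lf - o + j] - offset, q2 = rq[j] - offset;
      if (bf == br) {
        ms.push_back(bf);
        mq.push_back((char)(std::min(q_cap, q1 + q2) + offset));
      } else {
        int qd = std::max(q_floor, std::abs(q1 - q2));
        ms.push_back(q1 >= q2 ? bf : br);
        mq.push_back((char)(qd + offset));
      }
    }
    ms.append(r, o, lr - o);
    mq.append(rq, o, lr - o);
    out_seq[i] = ms; out_qual[i] = mq;
    out_overlap[i] = o; out_mism[i] = best_mm;
    status[i] = "merged";
  }
  return List::create(_["seq"] = out_seq, _["qual"] = out_qual,
                      _["status"] = status, _["overlap"] = out_overlap,
                      _["mismatches"] = out_mism);
}

static int bounded_edit(const std::string &a, const std::string &b, int band) {
  int n = a.size(), m = b.size();
  if (std::abs(n - m) > band) return -1;
  // Ukkonen band around the diagonal.
  const int INF = band + 1;
  std::vector<int> prev(2 * band + 1, INF), cur(2 * band + 1, INF);
  // prev[k] = D(i, j) with j = i + (k - band) for row i.
  for (int k = band; k <= 2 * band; ++k) {
    int j = k - band;
    if (j <= m) prev[k] = j;
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int best_row = INF;
    for (int k = 0; k <= 2 * band; ++k) {
      int j = i + (k - band);
      if (j < 0 || j > m) continue;
      int v = INF;
      if (j == 0) v = i;
      else {
        int sub = (k >= 0 && prev[k] < INF) ? prev[k] + (a[i - 1] == b[j - 1] ? 0 : 1) : INF;
        int del = (k + 1 <= 2 * band && prev[k + 1] < INF) ? prev[k + 1] + 1 : INF; // skip a[i-1]
        int ins = (k - 1 >= 0 && cur[k - 1] < INF) ? cur[k - 1] + 1 : INF;           // skip b[j-1]
        v = std::min(sub, std::min(del, ins));
      }
      cur[k] = v;
      if (v < best_row) best_row = v;
    }
    if (best_row > band) return -1;
    std::swap(prev, cur);
  }
  int res = prev[m - n + band];
  return res > band ? -1 : res;
}

// Banded Levenshtein distance of one query against a set of references.
// Returns -1 where the distance exceeds the band.
// [[Rcpp::export(name = ".cpp_edit_many")]]
IntegerVector cpp_edit_many(std::string query, CharacterVector refs, int band) {
  int n = refs.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = bounded_edit(query, as<std::string>(refs[i]), band);
  return out;
}

// [[Rcpp::export(name = ".cpp_edit_one")]]
int cpp_edit_one(std::string a, std::string b, int band) {
  return bounded_edit(a, b, band);
}

// Expected errors from Phred+33 quality strings: sum of 10^(-Q/10).
// [[Rcpp::export(name = ".cpp_expected_errors")]]
NumericVector cpp_expected_errors(CharacterVector quals, int offset) {
  int n = quals.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (quals[i] == NA_STRING) { out[i] = NA_REAL; continue; }
    std::string q = as<std::string>(quals[i]);
    double ee = 0.0;
    for (size_t j = 0; j < q.size(); ++j)
      ee += std::pow(10.0, -((double)(q[j] - offset)) / 10.0);
    out[i] = ee;
  }
  return out;
}

// Longest common prefix / suffix lengths of a query against references
// (used by the two-parent chimera reconstruction check).
// [[Rcpp::export(name = ".cpp_lcp_many")]]
IntegerVector cpp_lcp_many(std::string query, CharacterVector refs) {
  int n = refs.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(refs[i]);
    size_t lim = std::min(query.size(), r.size()), j = 0;
    while (j < lim && query[j] == r[j]) ++j;
    out[i] = (int)j;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_lcs_many")]]
IntegerVector cpp_lcs_many(std::string query, CharacterVector refs) {
  int n = refs.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(refs[i]);
    size_t lim = std::min(query.size(), r.size()), j = 0;
    while (j < lim && query[query.size() - 1 - j] == r[r.size() - 1 - j]) ++j;
    out[i] = (int)j;
  }
  return out;
}
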