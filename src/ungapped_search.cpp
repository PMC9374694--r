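#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Exhaustive ungapped diagonal search of a peptide/protein query against a
// database of short peptides. Sequences arrive as 0-based integer encodings
// (index into the 20-letter amino-acid alphabet); coordinates leave 1-based.
//
// A window qualifies when length >= min_len and 100*matches/length >= min_id.
// Identity threshold comparison uses a small epsilon so that exact boundary
// cases (e.g. 8/10 = 80.0%) are included, matching a ">=" contract.

namespace {

struct Hit {
  int subject;   // 0-based index into db
  int q_start;   // 0-based
  int s_start;   // 0-based
  int len;
  int matches;
  int raw;       // summed substitution score
};

inline bool qualifies(int matches, int len, double min_id) {
  return matches * 100.0 >= min_id * len - 1e-9;
}

// Enumerate qualifying windows on one diagonal, keep only maximal ones
// (a qualifying window contained in another qualifying window is suppressed).
void diagonal_hits(const int* q, int n, const int* s, int m, int subject_idx,
                   int min_len, double min_id, const IntegerMatrix& mat,
                   std::vector<Hit>& out) {
  std::vector<int> pm, praw;
  for (int d = -(m - 1); d <= n - 1; ++d) {
    int qs = d > 0 ? d : 0;
    int ss = qs - d;
    int L = std::min(n - qs, m - ss);
    if (L < min_len) continue;
    pm.assign(L + 1, 0);
    praw.assign(L + 1, 0);
    for (int i = 0; i < L; ++i) {
      int a = q[qs + i], b = s[ss + i];
      pm[i + 1] = pm[i] + (a == b ? 1 : 0);
      praw[i + 1] = praw[i] + mat(a, b);
    }
    // collect qualifying windows (start, end) 0-based inclusive on diagonal
    std::vector<std::pair<int, int> > win;
    for (int a = 0; a + min_len <= L; ++a) {
      for (int len = min_len; a + len <= L; ++len) {
        if (qualifies(pm[a + len] - pm[a], len, min_id))
          win.push_back(std::make_pair(a, a + len - 1));
      }
    }
    if (win.empty()) continue;
    std::sort(win.begin(), win.end(),
              [](const std::pair<int, int>& x, const std::pair<int, int>& y) {
                if (x.first != y.first) return x.first < y.first;
                return x.second > y.second;
              });
    int max_end = -1;
    for (size_t k = 0; k < win.size(); ++k) {
      if (win[k].second > max_end) {
        max_end = win[k].second;
        Hit h;
        h.subject = subject_idx;
        h.q_start = qs + win[k].first;
        h.s_start = ss + win[k].first;
        h.len = win[k].second - win[k].first + 1;
        h.matches = pm[win[k].second + 1] - pm[win[k].first];
        h.raw = praw[win[k].second + 1] - praw[win[k].first];
        out.push_back(h);
      }
    }
  }
}

// Early-exit existence test: does any qualifying window exist on any diagonal?
bool pair_has_hit(const int* q, int n, const int* s, int m,
                  int min_len, double min_id) {
  std::vector<int> pm;
  for (int d = -(m - 1); d <= n - 1; ++d) {
    int qs = d > 0 ? d : 0;
    int ss = qs - d;
    int L = std::min(n - qs, m - ss);
    if (L < min_len) continue;
    pm.assign(L + 1, 0);
    for (int i = 0; i < L; ++i)
      pm[i + 1] = pm[i] + (q[qs + i] == s[ss + i] ? 1 : 0);
    for (int a = 0; a + min_len <= L; ++a)
      for (int len = min_len; a + len <= L; ++len)
        if (qualifies(pm[a + len] - pm[a], len, min_id)) return true;
  }
  return false;
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_ungapped_hits(IntegerVector query, List subjects,
                            int min_len, double min_id, bool best_only,
                            IntegerMatrix score_matrix) {
  int n = query.size();
  const int* q = INTEGER(query);
  std::vector<Hit> hits;
  for (int j = 0; j < subjects.size(); ++j) {
    IntegerVector sv = subjects[j];
    std::vector<Hit> sub_hits;
    diagonal_hits(q, n, INTEGER(sv), sv.size(), j, min_len, min_id,
                  score_matrix, sub_hits);
    if (sub_hits.empty()) continue;
    if (best_only) {
      // highest raw score; ties: longest, then smallest query start
      size_t best = 0;
      for (size_t k = 1; k < sub_hits.size(); ++k) {
        const Hit& a = sub_hits[k];
        const Hit& b = sub_hits[best];
        if (a.raw > b.raw ||
            (a.raw == b.raw && (a.len > b.len ||
             (a.len == b.len && a.q_start < b.q_start))))
          best = k;
      }
      hits.push_back(sub_hits[best]);
    } else {
      hits.insert(hits.end(), sub_hits.begin(), sub_hits.end());
    }
  }
  int nh = (int)hits.size();
  IntegerVector subject(nh), q_start(nh), q_end(nh), s_start(nh), s_end(nh),
      length(nh), matches(nh), raw(nh);
  for (int k = 0; k < nh; ++k) {
    subject[k] = hits[k].subject + 1;
    q_start[k] = hits[k].q_start + 1;
    q_end[k] = hits[k].q_start + hits[k].len;
    s_start[k] = hits[k].s_start + 1;
    s_end[k] = hits[k].s_start + hits[k].len;
    length[k] = hits[k].len;
    matches[k] = hits[k].matches;
    raw[k] = hits[k].raw;
  }
  return DataFrame::create(
      _["subject"] = subject, _["query_start"] = q_start,
      _["query_end"] = q_end, _["subject_start"] = s_start,
      _["subject_end"] = s_end, _["length"] = length,
      _["matches"] = matches, _["raw_score"] = raw);
}

// [[Rcpp::export]]
bool cpp_any_hit(IntegerVector query, List subjects, int min_len,
                 double min_id) {
  int n = query.size();
  const int* q = INTEGER(query);
  for (int j = 0; j < subjects.size(); ++j) {
    IntegerVector sv = subjects[j];
    if (pair_has_hit(q, n, INTEGER(sv), sv.size(), min_len, min_id))
      return true;
  }
  return false;
}

// [[Rcpp::export]]
LogicalVector cpp_classify_batch(List queries, List subjects, int min_len,
                                 double min_id) {
  int nq = queries.size();
  LogicalVector out(nq);
  for (int i = 0; i < nq; ++i) {
    IntegerVector qv = queries[i];
    out[i] = cpp_any_hit(qv, subjects, min_len, min_id);
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
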