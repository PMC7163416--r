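#include <Rcpp.h>
using namespace Rcpp;

// Optimal-matching edit distance between two state sequences (1-based
// integer codes) under a substitution-cost matrix and a single indel cost.
// Standard (|a|+1) x (|b|+1) dynamic program.
static double om_dp(const IntegerVector& a, const IntegerVector& b,
                    const NumericMatrix& sub, double indel) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j * indel;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * indel;
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const int bj = b[j - 1] - 1;
      double best = prev[j - 1] + sub(ai, bj);
      best = std::min(best, prev[j] + indel);
      best = std::min(best, cur[j - 1] + indel);
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double om_cost_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                   double indel) {
  return om_dp(a, b, sub, indel);
}

// [[Rcpp::export]]
NumericMatrix om_pairwise_cpp(List seqs, NumericMatrix sub, double indel) {
  const int n = seqs.size();
  NumericMatrix d(n, n);
  std::vector<IntegerVector> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<IntegerVector>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double v = om_dp(s[i], s[j], sub, indel);
      d(i, j) = v;
      d(j, i) = v;
    }
  }
  return d;
}

// Greedy forward linking of repeat measurements. Input is sorted by
// (patient, day). Within each patient the first measurement anchors the
// chain; each later one is retained iff its gap from the last RETAINED
// measurement is short- or long-term follow-up. Returns per row:
// 0 = first retained, 1 = SHORT, 2 = LONG, -1 = discarded (unrelated).
// [[Rcpp::export]]
IntegerVector greedy_link_cpp(IntegerVector group, IntegerVector day,
                              int short_min, int short_max, int long_max) {
  const int n = group.size();
  IntegerVector code(n);
  int anchor_day = 0;
  int cur_group = NA_INTEGER;
  for (int i = 0; i < n; ++i) {
    if (cur_group == NA_INTEGER || group[i] != cur_group) {
      cur_group = group[i];
      anchor_day = day[i];
      code[i] = 0;
      continue;
    }
    const int delta = day[i] - anchor_day;
    if (delta >= short_min && delta <= short_max) {
      code[i] = 1;
      anchor_day = day[i];
    } else if (delta > short_max && delta <= long_max) {
      code[i] = 2;
      anchor_day = day[i];
    } else {
      code[i] = -1;
    }
  }
  return code;
}
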