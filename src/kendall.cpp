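#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Pair bookkeeping for Kendall's tau via Knight's O(n log n) algorithm:
// sort by (x, y), count ties in x / y / both, then count strict inversions
// of y with a merge sort; inversions are exactly the discordant pairs.

static long long merge_count(std::vector<double> &y, std::vector<double> &buf,
                             size_t lo, size_t hi) {
  if (hi - lo < 2) return 0;
  size_t mid = lo + (hi - lo) / 2;
  long long inv = merge_count(y, buf, lo, mid) + merge_count(y, buf, mid, hi);
  size_t i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (y[j] < y[i]) {            // strict: ties are not inversions
      inv += (long long)(mid - i);
      buf[k++] = y[j++];
    } else {
      buf[k++] = y[i++];
    }
  }
  while (i < mid) buf[k++] = y[i++];
  while (j < hi) buf[k++] = y[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
  return inv;
}

static long long tie_pairs(const std::vector<double> &v) {
  long long t = 0, run = 1;
  for (size_t i = 1; i < v.size(); ++i) {
    if (v[i] == v[i - 1]) {
      ++run;
    } else {
      t += run * (run - 1) / 2;
      run = 1;
    }
  }
  t += run * (run - 1) / 2;
  return t;
}

// [[Rcpp::export]]
Rcpp::List kendall_pair_counts(Rcpp::NumericVector x, Rcpp::NumericVector y) {
  size_t n = x.size();
  std::vector<size_t> ord(n);
  for (size_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  std::vector<double> xs(n), ys(n);
  for (size_t i = 0; i < n; ++i) {
    xs[i] = x[ord[i]];
    ys[i] = y[ord[i]];
  }

  long long n1 = tie_pairs(xs);   // pairs tied in x
  long long n3 = 0;               // pairs tied in both
  {
    long long run = 1;
    for (size_t i = 1; i < n; ++i) {
      if (xs[i] == xs[i - 1] && ys[i] == ys[i - 1]) {
        ++run;
      } else {
        n3 += run * (run - 1) / 2;
        run = 1;
      }
    }
    n3 += run * (run - 1) / 2;
  }

  std::vector<double> buf(n);
  long long discordant = merge_count(ys, buf, 0, n);

  std::sort(ys.begin(), ys.end());
  long long n2 = tie_pairs(ys);   // pairs tied in y

  long long n0 = (long long)n * ((long long)n - 1) / 2;
  long long concordant = n0 - n1 - n2 + n3 - discordant;

  return Rcpp::List::create(
      Rcpp::Named("concordant") = (double)concordant,
      Rcpp::Named("discordant") = (double)discordant,
      Rcpp::Named("ties_x") = (double)n1,
      Rcpp::Named("ties_y") = (double)n2,
      Rcpp::Named("ties_xy") = (double)n3,
      Rcpp::Named("n_pairs") = (double)n0);
}
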