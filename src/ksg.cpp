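#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger (algorithm 1) mutual information between
// two continuous scalars. For each point the Chebyshev distance to its
// k-th nearest neighbour in the joint space sets eps_i; n_x and n_y count
// the points strictly within eps_i in each marginal (self included, which
// matches the digamma(n+1) convention). Returns nats, floored at 0.
// O(n^2) joint k-NN with an O(log n) sorted-marginal count.

// [[Rcpp::export]]
double ksg_mi(NumericVector x, NumericVector y, int k) {
  int n = x.size();
  if (y.size() != n) stop("x and y lengths differ");
  if (n <= k + 1) stop("need more points than the neighbour count k");

  std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end());
  std::sort(xs.begin(), xs.end());
  std::sort(ys.begin(), ys.end());

  std::vector<double> knn(k);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    // k smallest joint Chebyshev distances to other points
    int filled = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d = std::max(std::fabs(x[j] - x[i]), std::fabs(y[j] - y[i]));
      if (filled < k) {
        knn[filled++] = d;
        if (filled == k) std::make_heap(knn.begin(), knn.end());
      } else if (d < knn[0]) {
        std::pop_heap(knn.begin(), knn.end());
        knn[k - 1] = d;
        std::push_heap(knn.begin(), knn.end());
      }
    }
    double eps = knn[0];
    // strict marginal counts within eps (self counts once in each)
    int nx = std::lower_bound(xs.begin(), xs.end(), x[i] + eps) -
             std::upper_bound(xs.begin(), xs.end(), x[i] - eps);
    int ny = std::lower_bound(ys.begin(), ys.end(), y[i] + eps) -
             std::upper_bound(ys.begin(), ys.end(), y[i] - eps);
    acc += R::digamma((double)nx) + R::digamma((double)ny);
  }
  double mi = R::digamma((double)k) + R::digamma((double)n) - acc / n;
  return mi > 0.0 ? mi : 0.0;
}
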