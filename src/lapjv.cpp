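#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Balanced linear assignment by shortest augmenting paths with dual
// potentials (Jonker-Volgenant family, O(n^3)). Rows are augmented one at a
// time; each augmentation is a Dijkstra-like scan over columns on reduced
// costs, after which the duals (u, v) are updated so that
//   cost(i, j) - u[i] - v[j] >= 0  for all i, j
// with equality on matched edges. Ties are resolved deterministically by
// column scan order, so results are reproducible for a fixed input.
//
// [[Rcpp::export]]
List lap_solve_cpp(NumericMatrix cost) {
    const int n = cost.nrow();
    if (cost.ncol() != n) stop("cost matrix must be square");
    for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i)
            if (!R_finite(cost(i, j))) stop("non-finite cost entry");

    const double INF = std::numeric_limits<double>::infinity();
    // 1-based with sentinel slot 0 (e-maxx formulation).
    std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0), minv(n + 1);
    std::vector<int> p(n + 1, 0), way(n + 1, 0);
    std::vector<char> used(n + 1);

    for (int i = 1; i <= n; ++i) {
        p[0] = i;
        int j0 = 0;
        std::fill(minv.begin(), minv.end(), INF);
        std::fill(used.begin(), used.end(), 0);
        do {
            used[j0] = 1;
            int i0 = p[j0], j1 = 0;
            double delta = INF;
            for (int j = 1; j <= n; ++j) {
                if (used[j]) continue;
                double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
                if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
                if (minv[j] < delta) { delta = minv[j]; j1 = j; }
            }
            for (int j = 0; j <= n; ++j) {
                if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
                else minv[j] -= delta;
            }
            j0 = j1;
        } while (p[j0] != 0);
        do {
            int j1 = way[j0];
            p[j0] = p[j1];
            j0 = j1;
        } while (j0);
    }

    IntegerVector perm(n);           // perm[k] = column assigned to row k
    for (int j = 1; j <= n; ++j) perm[p[j] - 1] = j;
    double total = 0.0;
    for (int k = 0; k < n; ++k) total += cost(k, perm[k] - 1);

    NumericVector uu(n), vv(n);
    for (int i = 1; i <= n; ++i) uu[i - 1] = u[i];
    for (int j = 1; j <= n; ++j) vv[j - 1] = v[j];

    return List::create(_["perm"] = perm, _["u"] = uu, _["v"] = vv,
                        _["total_cost"] = total);
}
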