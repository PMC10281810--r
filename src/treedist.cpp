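// Split-based tree comparison statistics.
//
// Trees are reduced in R to matrices of non-trivial splits (rows = splits,
// columns = leaves, entries 0/1, canonicalized so column 1 is 0). The
// clustering-information distance matches splits one-to-one to maximize
// shared clustering information; the Nye similarity matches them to maximize
// a Jaccard-type side-overlap score. Both use an exact O(n^3) Hungarian
// assignment, never a greedy matching.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Exact maximum-weight assignment on a (possibly rectangular) non-negative
// weight matrix; unmatched rows/columns score 0 (valid because weights >= 0).
// Classic potentials formulation of the Hungarian algorithm, minimizing -w.
double assignMax(const std::vector<std::vector<double> >& w,
                 int nr, int nc) {
    if (nr == 0 || nc == 0) return 0.0;
    int n = std::max(nr, nc);
    // cost matrix, 1-based, padded with zeros
    std::vector<std::vector<double> > a(n + 1, std::vector<double>(n + 1, 0.0));
    for (int i = 0; i < nr; ++i)
        for (int j = 0; j < nc; ++j)
            a[i + 1][j + 1] = -w[i][j];
    std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
    std::vector<int> p(n + 1, 0), way(n + 1, 0);
    for (int i = 1; i <= n; ++i) {
        p[0] = i;
        int j0 = 0;
        std::vector<double> minv(n + 1, INF);
        std::vector<char> used(n + 1, 0);
        do {
            used[j0] = 1;
            int i0 = p[j0], j1 = 0;
            double delta = INF;
            for (int j = 1; j <= n; ++j) {
                if (used[j]) continue;
                double cur = a[i0][j] - u[i0] - v[j];
                if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
                if (minv[j] < delta) { delta = minv[j]; j1 = j; }
            }
            for (int j = 0; j <= n; ++j) {
                if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
                else minv[j] -= delta;
            }
            j0 = j1;
        } while (p[j0] != 0);
        do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
    }
    double total = 0.0;
    for (int j = 1; j <= n; ++j) {
        int i = p[j];
        if (i >= 1 && i <= nr && j <= nc) total += w[i - 1][j - 1];
    }
    return total;
}

static inline double xlog2x(double x) {
    return (x <= 0.0) ? 0.0 : x * std::log2(x);
}

// entropy (bits) of a bipartition with one side of size a out of n
static inline double splitEntropy(int a, int n) {
    double p = (double)a / n;
    return -xlog2x(p) - xlog2x(1.0 - p);
}

// mutual clustering information (bits) between two splits from the 2x2
// joint leaf-membership table
static inline double mutualInfo(int n11, int n10, int n01, int n00, int n) {
    double mi = 0.0;
    int r1 = n11 + n10, r0 = n01 + n00;
    int c1 = n11 + n01, c0 = n10 + n00;
    const int cell[4] = { n11, n10, n01, n00 };
    const int rm[4] = { r1, r1, r0, r0 };
    const int cm[4] = { c1, c0, c1, c0 };
    for (int k = 0; k < 4; ++k) {
        if (cell[k] == 0) continue;
        double pj = (double)cell[k] / n;
        mi += pj * std::log2((double)cell[k] * n / ((double)rm[k] * cm[k]));
    }
    return mi;
}

static inline double jaccard(int inter, int uni) {
    return uni == 0 ? 0.0 : (double)inter / uni;
}

// Nye pair score between split (A|A') and (B|B'):
// max over the two side pairings of min(J(A,B), J(A',B')).
static double nyePairScore(int n11, int n10, int n01, int n00) {
    double s1 = std::min(jaccard(n11, n11 + n10 + n01),
                         jaccard(n00, n00 + n10 + n01));
    double s2 = std::min(jaccard(n10, n10 + n11 + n00),
                         jaccard(n01, n01 + n11 + n00));
    return std::max(s1, s2);
}

// Statistic between split matrices A (k1 x L) and B (k2 x L) with leaf i of
// A corresponding to leaf perm[i] of B. method: 0 = clustering information
// distance (bits), 1 = Nye unnormalized matched score.
static double splitStat(const IntegerMatrix& A, const IntegerMatrix& B,
                        const std::vector<int>& perm, int method) {
    int k1 = A.nrow(), k2 = B.nrow(), L = A.ncol();
    std::vector<std::vector<double> > w(k1, std::vector<double>(k2, 0.0));
    for (int r = 0; r < k1; ++r) {
        for (int q = 0; q < k2; ++q) {
            int n11 = 0, n10 = 0, n01 = 0, n00 = 0;
            for (int i = 0; i < L; ++i) {
                int a = A(r, i), b = B(q, perm[i]);
                if (a && b) ++n11;
                else if (a && !b) ++n10;
                else if (!a && b) ++n01;
                else ++n00;
            }
            w[r][q] = (method == 0) ? mutualInfo(n11, n10, n01, n00, L)
                                    : nyePairScore(n11, n10, n01, n00);
        }
    }
    double matched = assignMax(w, k1, k2);
    if (method == 1) return matched;
    double h1 = 0.0, h2 = 0.0;
    for (int r = 0; r < k1; ++r) {
        int a = 0;
        for (int i = 0; i < L; ++i) a += A(r, i);
        h1 += splitEntropy(a, L);
    }
    for (int q = 0; q < k2; ++q) {
        int b = 0;
        for (int i = 0; i < L; ++i) b += B(q, i);
        h2 += splitEntropy(b, L);
    }
    double d = h1 + h2 - 2.0 * matched;
    return d < 0.0 ? 0.0 : d;
}

// [[Rcpp::export]]
double cpp_split_stat(IntegerMatrix A, IntegerMatrix B, int method) {
    if (A.ncol() != B.ncol()) stop("split matrices disagree on leaf count");
    std::vector<int> id(A.ncol());
    for (int i = 0; i < (int)id.size(); ++i) id[i] = i;
    return splitStat(A, B, id, method);
}

// Permutation test core: observed statistic with the identity
// correspondence, then nperm random permutations of the leaf
// correspondence (the shuffled symbiont-to-host assignment). Counts
// permutations at least as congruent as the observation. Uses R's RNG.
// [[Rcpp::export]]
List cpp_perm_test_splits(IntegerMatrix A, IntegerMatrix B, int nperm,
                          int method, bool largeIsCongruent) {
    if (A.ncol() != B.ncol()) stop("split matrices disagree on leaf count");
    int L = A.ncol();
    std::vector<int> perm(L);
    for (int i = 0; i < L; ++i) perm[i] = i;
    double obs = splitStat(A, B, perm, method);
    const double eps = 1e-12;
    int extreme = 0;
    NumericVector null(nperm);
    for (int b = 0; b < nperm; ++b) {
        // Fisher-Yates with R's RNG
        for (int i = L - 1; i > 0; --i) {
            int j = (int)(unif_rand() * (i + 1));
            if (j > i) j = i;
            std::swap(perm[i], perm[j]);
        }
        double s = splitStat(A, B, perm, method);
        null[b] = s;
        if (largeIsCongruent ? (s >= obs - eps) : (s <= obs + eps)) ++extreme;
    }
    return List::create(_["observed"] = obs, _["extreme"] = extreme,
                        _["null"] = null);
}

// [[Rcpp::export]]
NumericMatrix cpp_split_score_matrix(IntegerMatrix A, IntegerMatrix B,
                                     int method) {
    // pairwise split scores with identity correspondence (used by tests)
    int k1 = A.nrow(), k2 = B.nrow(), L = A.ncol();
    NumericMatrix out(k1, k2);
    for (int r = 0; r < k1; ++r)
        for (int q = 0; q < k2; ++q) {
            int n11 = 0, n10 = 0, n01 = 0, n00 = 0;
            for (int i = 0; i < L; ++i) {
                int a = A(r, i), b = B(q, i);
                if (a && b) ++n11;
                else if (a && !b) ++n10;
                else if (!a && b) ++n01;
                else ++n00;
            }
            out(r, q) = (method == 0) ? mutualInfo(n11, n10, n01, n00, L)
                                      : nyePairScore(n11, n10, n01, n00);
        }
    return out;
}

// [[Rcpp::export]]
double cpp_assign_max(NumericMatrix w) {
    int nr = w.nrow(), nc = w.ncol();
    std::vector<std::vector<double> > ww(nr, std::vector<double>(nc));
    for (int i = 0; i < nr; ++i)
        for (int j = 0; j < nc; ++j) ww[i][j] = w(i, j);
    return assignMax(ww, nr, nc);
}
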