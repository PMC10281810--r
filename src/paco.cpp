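// Procrustean cophylogeny core: residual m^2 of the least-squares
// superimposition of the link-expanded symbiont configuration onto the
// link-expanded host configuration (translation + orthogonal map +
// one-directional scaling), and the permutation loop with the backtracking
// randomization that conserves row and column totals of the association.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// m^2 for link-expanded coordinate matrices (rows = links), centered here.
// min over orthogonal Q (rotations and reflections) and scale c of
// ||Hc - c * Sc * Q||^2 = tr(Hc'Hc) - (sum sv(Sc'Hc))^2 / tr(Sc'Sc).
static double m2_links(const arma::mat& H, const arma::mat& S) {
    arma::mat Hc = H.each_row() - arma::mean(H, 0);
    arma::mat Sc = S.each_row() - arma::mean(S, 0);
    double trH = arma::accu(Hc % Hc);
    double trS = arma::accu(Sc % Sc);
    if (trS < 1e-300) return trH;  // degenerate symbiont configuration
    arma::vec sv = arma::svd(Sc.t() * Hc);
    double num = arma::accu(sv);
    double m2 = trH - num * num / trS;
    return m2 < 0.0 ? 0.0 : m2;
}

// [[Rcpp::export]]
double cpp_paco_m2(const arma::mat& H, const arma::mat& S) {
    if (H.n_rows != S.n_rows) stop("link-expanded matrices disagree on rows");
    return m2_links(H, S);
}

// One backtracking fill of a binary matrix with the given margins: links are
// placed one at a time on a uniformly chosen feasible free cell; a deadlock
// (margins not yet met but no feasible cell) restarts the fill from scratch.
// Returns true on success, filling hostIdx/symbIdx (0-based) with the links.
static bool fill_once(const arma::ivec& rs, const arma::ivec& cs,
                      std::vector<int>& hostIdx, std::vector<int>& symbIdx) {
    int nr = rs.n_elem, nc = cs.n_elem;
    arma::ivec r = rs, c = cs;
    std::vector<char> used(nr * nc, 0);
    int L = arma::accu(rs);
    hostIdx.clear(); symbIdx.clear();
    for (int k = 0; k < L; ++k) {
        // collect feasible free cells
        int nf = 0;
        static thread_local std::vector<int> cells;
        cells.clear();
        for (int i = 0; i < nr; ++i) {
            if (r[i] <= 0) continue;
            for (int j = 0; j < nc; ++j) {
                if (c[j] <= 0 || used[i * nc + j]) continue;
                cells.push_back(i * nc + j);
                ++nf;
            }
        }
        if (nf == 0) return false;  // deadlock -> caller restarts
        int pick = (int)(unif_rand() * nf);
        if (pick >= nf) pick = nf - 1;
        int cell = cells[pick];
        int i = cell / nc, j = cell % nc;
        used[cell] = 1;
        --r[i]; --c[j];
        hostIdx.push_back(i);
        symbIdx.push_back(j);
    }
    return true;
}

// [[Rcpp::export]]
IntegerMatrix cpp_fill_margins(IntegerVector rowSums, IntegerVector colSums,
                               int maxRestarts) {
    arma::ivec rs(rowSums.size()), cs(colSums.size());
    for (int i = 0; i < rowSums.size(); ++i) rs[i] = rowSums[i];
    for (int j = 0; j < colSums.size(); ++j) cs[j] = colSums[j];
    if (arma::accu(rs) != arma::accu(cs))
        stop("row and column totals disagree");
    std::vector<int> hi, si;
    for (int t = 0; t < maxRestarts; ++t) {
        if (fill_once(rs, cs, hi, si)) {
            IntegerMatrix M(rs.n_elem, cs.n_elem);
            for (size_t k = 0; k < hi.size(); ++k) M(hi[k], si[k]) = 1;
            return M;
        }
    }
    stop("backtracking fill failed after %d restarts", maxRestarts);
}

// Permutation loop for the PACo test: nperm backtracking randomizations of
// the association, each scored by m^2 on the link-expanded coordinates.
// [[Rcpp::export]]
List cpp_paco_perm(const arma::mat& hostCoords, const arma::mat& symbCoords,
                   IntegerVector rowSums, IntegerVector colSums,
                   double observed, int nperm, int maxRestarts) {
    arma::ivec rs(rowSums.size()), cs(colSums.size());
    for (int i = 0; i < rowSums.size(); ++i) rs[i] = rowSums[i];
    for (int j = 0; j < colSums.size(); ++j) cs[j] = colSums[j];
    int extreme = 0;
    const double eps = 1e-12;
    NumericVector null(nperm);
    std::vector<int> hi, si;
    for (int b = 0; b < nperm; ++b) {
        bool ok = false;
        for (int t = 0; t < maxRestarts && !ok; ++t)
            ok = fill_once(rs, cs, hi, si);
        if (!ok)
            stop("backtracking fill failed after %d restarts "
                 "(permutation %d of %d)", maxRestarts, b + 1, nperm);
        int L = hi.size();
        arma::mat H(L, hostCoords.n_cols), S(L, symbCoords.n_cols);
        for (int k = 0; k < L; ++k) {
            H.row(k) = hostCoords.row(hi[k]);
            S.row(k) = symbCoords.row(si[k]);
        }
        double s = m2_links(H, S);
        null[b] = s;
        if (s <= observed + eps) ++extreme;
    }
    return List::create(_["extreme"] = extreme, _["null"] = null);
}
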