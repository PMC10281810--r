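// Undated duplication-transfer-loss likelihood.
//
// Each species-tree branch (one per node, the root carrying a stem branch)
// hosts a gene lineage that draws one event with probabilities
// pS = 1/q, pD = delta/q, pT = tau/q, pL = lambda/q, q = 1 + delta + tau + lambda.
// Transfers move a copy to a branch drawn uniformly among branches not
// ancestral to the donor (self excluded, descendants allowed). Extinction
// probabilities are solved by fixed-point iteration; the self-referential
// propagation terms of the inside probabilities (speciation-loss,
// duplication-loss, transfer-loss) are resolved by a fixed number of
// Gauss-Seidel sweeps. The likelihood sums the gene-root inside probability
// over all species branches under a uniform root-placement prior.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_dtl_loglik(IntegerVector spParent, IntegerVector spLeft,
                    IntegerVector spRight, IntegerVector spPostorder,
                    IntegerVector gLeft, IntegerVector gRight,
                    IntegerVector gPostorder, IntegerVector leafMap,
                    double delta, double tau, double lambda,
                    int insideRounds, double extTol, int extMaxIter) {
    const int S = spParent.size();
    const int G = gLeft.size();
    const double q = 1.0 + delta + tau + lambda;
    const double pS = 1.0 / q, pD = delta / q, pT = tau / q, pL = lambda / q;

    // strict ancestors of each branch; recipient set R(e) = all branches
    // except e and its strict ancestors
    std::vector<std::vector<int> > anc(S);
    for (int e = 0; e < S; ++e) {
        int a = spParent[e];
        while (a >= 0) { anc[e].push_back(a); a = spParent[a]; }
    }
    std::vector<double> nR(S);
    for (int e = 0; e < S; ++e) nR[e] = S - 1.0 - anc[e].size();

    // extinction probabilities, Jacobi iteration from 0 (converges to the
    // minimal non-negative solution)
    std::vector<double> E(S, 0.0), En(S, 0.0);
    double resid = 0.0;
    bool converged = false;
    for (int it = 0; it < extMaxIter; ++it) {
        double sumE = 0.0;
        for (int e = 0; e < S; ++e) sumE += E[e];
        resid = 0.0;
        for (int e = 0; e < S; ++e) {
            double excl = sumE - E[e];
            for (size_t k = 0; k < anc[e].size(); ++k) excl -= E[anc[e][k]];
            double Ebar = nR[e] > 0 ? excl / nR[e] : 0.0;
            double v = pL + pD * E[e] * E[e] + pT * E[e] * Ebar;
            if (spLeft[e] >= 0) v += pS * E[spLeft[e]] * E[spRight[e]];
            // at a sampled leaf the speciation (sampling) event contributes 0
            En[e] = v;
            double d = std::fabs(En[e] - E[e]);
            if (d > resid) resid = d;
        }
        E.swap(En);
        if (resid < extTol) { converged = true; break; }
    }
    if (!converged)
        return List::create(_["loglik"] = NA_REAL, _["converged"] = false,
                            _["residual"] = resid);

    std::vector<double> sumAncE(S), Ebar(S);
    double sumE = 0.0;
    for (int e = 0; e < S; ++e) sumE += E[e];
    for (int e = 0; e < S; ++e) {
        double excl = sumE - E[e];
        for (size_t k = 0; k < anc[e].size(); ++k) excl -= E[anc[e][k]];
        Ebar[e] = nR[e] > 0 ? excl / nR[e] : 0.0;
    }

    // inside probabilities P[u][e]; rows are renormalized when they get
    // tiny, with the log correction accumulated per gene node (every term
    // of a parent's base is degree 1 in each child's row, so corrections
    // add along the gene tree) -- this keeps big incongruent gene trees
    // clear of double underflow
    std::vector<std::vector<double> > P(G, std::vector<double>(S, 0.0));
    std::vector<double> base(S), sums(G, 0.0), logScale(G, 0.0);

    // recipient-average of a row given its total
    auto rowBar = [&](const std::vector<double>& row, double total, int e) {
        if (nR[e] <= 0) return 0.0;
        double excl = total - row[e];
        for (size_t k = 0; k < anc[e].size(); ++k) excl -= row[anc[e][k]];
        return excl / nR[e];
    };

    bool numericTrouble = false;
    for (int gi = 0; gi < G; ++gi) {
        int u = gPostorder[gi];
        int a = gLeft[u], b = gRight[u];
        if (a < 0) {
            for (int e = 0; e < S; ++e) base[e] = 0.0;
            if (leafMap[u] >= 0) base[leafMap[u]] = pS;
        } else {
            for (int si = 0; si < S; ++si) {
                int e = si;
                double v = 2.0 * pD * P[a][e] * P[b][e];
                if (spLeft[e] >= 0) {
                    int f = spLeft[e], g = spRight[e];
                    v += pS * (P[a][f] * P[b][g] + P[a][g] * P[b][f]);
                }
                v += pT * (P[a][e] * rowBar(P[b], sums[b], e) +
                           P[b][e] * rowBar(P[a], sums[a], e));
                base[e] = v;
            }
        }
        std::vector<double>& Pu = P[u];
        for (int e = 0; e < S; ++e) Pu[e] = base[e];
        double total = 0.0;
        for (int e = 0; e < S; ++e) total += Pu[e];
        for (int r = 0; r < insideRounds; ++r) {
            for (int si = 0; si < S; ++si) {
                int e = spPostorder[si];
                double v = base[e];
                if (spLeft[e] >= 0) {
                    int f = spLeft[e], g = spRight[e];
                    v += pS * (Pu[f] * E[g] + Pu[g] * E[f]);
                }
                double pbar = rowBar(Pu, total, e);
                v += 2.0 * pD * E[e] * Pu[e] +
                     pT * (Pu[e] * Ebar[e] + pbar * E[e]);
                total += v - Pu[e];
                Pu[e] = v;
            }
        }
        double rowMax = 0.0;
        for (int e = 0; e < S; ++e) {
            if (!(Pu[e] >= 0.0)) numericTrouble = true;
            if (Pu[e] > rowMax) rowMax = Pu[e];
        }
        logScale[u] = (a < 0) ? 0.0 : logScale[a] + logScale[b];
        if (rowMax > 1.0 + 1e-9) numericTrouble = true;
        if (rowMax > 0.0 && rowMax < 1e-50) {
            for (int e = 0; e < S; ++e) Pu[e] /= rowMax;
            logScale[u] += std::log(rowMax);
            total /= rowMax;
        }
        sums[u] = total;
    }

    int groot = gPostorder[G - 1];
    double lik = 0.0;
    for (int e = 0; e < S; ++e) lik += P[groot][e];
    lik /= S;  // uniform prior over root placements
    double ll;
    if (numericTrouble || !(lik > 0.0))
        ll = R_NegInf;  // outside the model's valid numeric regime
    else {
        ll = std::log(lik) + logScale[groot];
        if (ll > 1e-9) ll = R_NegInf;  // not a probability: invalid regime
    }
    return List::create(_["loglik"] = ll, _["converged"] = true,
                        _["residual"] = resid);
}
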