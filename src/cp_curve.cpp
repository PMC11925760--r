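#include <Rcpp.h>
using namespace Rcpp;

// Clustering-coefficient curve along a nested edge ranking.
//
// edges: kmax x 2 matrix of 1-based node pairs sorted by descending
// connection strength; w: the strengths in the same order; kvec: cumulative
// edge counts (non-decreasing) at which the mean clustering coefficient is
// reported -- one per sparsity level. Because the graphs are nested, each
// edge is inserted once and its triangle contributions updated
// incrementally, so a whole 22-level schedule costs O(kmax * n).
//
// weighted = true uses the Onnela coefficient: geometric mean of triangle
// weights, each normalized by the maximum weight, which for a nested
// ranking is w[0] at every level. weighted = false is the Watts-Strogatz
// triangle fraction. Nodes with degree < 2 contribute 0; the mean is over
// all n nodes.
static NumericVector cp_curve_impl(const std::vector<int> &ei,
                                   const std::vector<int> &ej,
                                   const std::vector<double> &w, int n,
                                   IntegerVector kvec, bool weighted,
                                   double wmax) {
    const int kmax = (int)ei.size();
    std::vector<double> A((size_t)n * n, 0.0);
    std::vector<double> tri(n, 0.0);
    std::vector<int> deg(n, 0);
    NumericVector out(kvec.size());
    int e = 0;
    for (int s = 0; s < kvec.size(); ++s) {
        const int k = kvec[s];
        if (k > kmax) stop("kvec exceeds available edges");
        for (; e < k; ++e) {
            const int u = ei[e], v = ej[e];
            const double x = weighted ? std::cbrt(w[e] / wmax) : 1.0;
            double *Au = &A[(size_t)u * n], *Av = &A[(size_t)v * n];
            for (int h = 0; h < n; ++h) {
                if (Au[h] > 0.0 && Av[h] > 0.0) {
                    const double t = x * Au[h] * Av[h];
                    tri[u] += t;
                    tri[v] += t;
                    tri[h] += t;
                }
            }
            Au[v] = x;
            Av[u] = x;
            ++deg[u];
            ++deg[v];
        }
        double cp = 0.0;
        for (int i = 0; i < n; ++i)
            if (deg[i] >= 2)
                cp += 2.0 * tri[i] / ((double)deg[i] * (deg[i] - 1));
        out[s] = cp / n;
    }
    return out;
}

// [[Rcpp::export]]
NumericVector cp_curve_cpp(IntegerMatrix edges, NumericVector w, int n,
                           IntegerVector kvec, bool weighted) {
    const int kmax = edges.nrow();
    std::vector<int> ei(kmax), ej(kmax);
    std::vector<double> ww(kmax);
    for (int e = 0; e < kmax; ++e) {
        ei[e] = edges(e, 0) - 1;
        ej[e] = edges(e, 1) - 1;
        ww[e] = w[e];
    }
    const double wmax = (weighted && kmax > 0)
        ? *std::max_element(ww.begin(), ww.end()) : 1.0;
    return cp_curve_impl(ei, ej, ww, n, kvec, weighted, wmax);
}

// Cp curve straight from a correlation matrix: ranks the upper-triangle
// entries by connection strength (|r|, or signed r with absolute = false),
// ties broken on ascending (i, j) as in applySparsity, then runs the
// incremental curve. One call covers a whole sparsity schedule; this is the
// permutation-loop hot path.
// [[Rcpp::export]]
NumericVector cp_curve_cor_cpp(NumericMatrix r, IntegerVector kvec,
                               bool weighted, bool absolute) {
    const int n = r.nrow();
    const int m = n * (n - 1) / 2;
    int kmax = 0;
    for (int s = 0; s < kvec.size(); ++s) kmax = std::max(kmax, kvec[s]);
    if (kmax > m) stop("requested more edges than node pairs");
    std::vector<int> ii(m), jj(m), ord(m);
    std::vector<double> st(m);
    int e = 0;
    for (int j = 1; j < n; ++j)
        for (int i = 0; i < j; ++i, ++e) {
            ii[e] = i;
            jj[e] = j;
            double v = r(i, j);
            st[e] = absolute ? std::fabs(v) : v;
            ord[e] = e;
        }
    auto cmp = [&](int a, int b) {
        if (st[a] != st[b]) return st[a] > st[b];
        if (ii[a] != ii[b]) return ii[a] < ii[b];
        return jj[a] < jj[b];
    };
    std::nth_element(ord.begin(), ord.begin() + kmax - 1, ord.end(), cmp);
    std::sort(ord.begin(), ord.begin() + kmax, cmp);
    std::vector<int> ei(kmax), ej(kmax);
    std::vector<double> ww(kmax);
    for (e = 0; e < kmax; ++e) {
        ei[e] = ii[ord[e]];
        ej[e] = jj[ord[e]];
        ww[e] = std::min(st[ord[e]], 1.0);
        if (st[ord[e]] <= 0.0)
            stop("cannot rank edges: non-positive strengths reached");
    }
    // edges are sorted by descending strength, so ww[0] is the maximum
    // weight of the graph at every nested threshold
    const double wmax = (weighted && kmax > 0) ? ww[0] : 1.0;
    return cp_curve_impl(ei, ej, ww, n, kvec, weighted, wmax);
}
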