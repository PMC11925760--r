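#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// All-pairs shortest-path distances with edge length = 1/weight.
// edges: E x 2 (1-based, i < j); unreachable pairs are +Inf.
// [[Rcpp::export]]
NumericMatrix dijkstra_edges_cpp(IntegerMatrix edges, NumericVector w,
                                 int n) {
    const int E = edges.nrow();
    std::vector<std::vector<std::pair<int, double>>> adj(n);
    for (int e = 0; e < E; ++e) {
        const int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
        if (w[e] <= 0) stop("edge weights must be positive");
        const double len = 1.0 / w[e];
        adj[u].push_back(std::make_pair(v, len));
        adj[v].push_back(std::make_pair(u, len));
    }
    NumericMatrix D(n, n);
    std::vector<double> dist(n);
    std::vector<char> done(n);
    typedef std::pair<double, int> QE;
    for (int s = 0; s < n; ++s) {
        std::fill(dist.begin(), dist.end(), R_PosInf);
        std::fill(done.begin(), done.end(), 0);
        dist[s] = 0.0;
        std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
        pq.push(std::make_pair(0.0, s));
        while (!pq.empty()) {
            const QE top = pq.top();
            pq.pop();
            const int u = top.second;
            if (done[u]) continue;
            done[u] = 1;
            for (size_t k = 0; k < adj[u].size(); ++k) {
                const int v = adj[u][k].first;
                const double nd = dist[u] + adj[u][k].second;
                if (nd < dist[v]) {
                    dist[v] = nd;
                    pq.push(std::make_pair(nd, v));
                }
            }
        }
        for (int j = 0; j < n; ++j) D(s, j) = dist[j];
    }
    return D;
}

// Maslov-Sneppen degree-preserving rewiring: `niter` attempted double-edge
// swaps (u,v),(x,y) -> (u,y),(x,v), rejecting self-loops and multi-edges.
// Uses R's RNG, so results are reproducible under set.seed(). Returns the
// rewired edge list, rows normalized to i < j.
// [[Rcpp::export]]
IntegerMatrix rewire_ms_cpp(IntegerMatrix edges, int n, int niter) {
    const int E = edges.nrow();
    if (E < 2) stop("need at least 2 edges to rewire");
    std::vector<int> a(E), b(E);
    std::vector<char> adjm((size_t)n * n, 0);
    for (int e = 0; e < E; ++e) {
        a[e] = edges(e, 0) - 1;
        b[e] = edges(e, 1) - 1;
        adjm[(size_t)a[e] * n + b[e]] = 1;
        adjm[(size_t)b[e] * n + a[e]] = 1;
    }
    for (int it = 0; it < niter; ++it) {
        const int e1 = (int)(unif_rand() * E);
        const int e2 = (int)(unif_rand() * E);
        if (e1 == e2) continue;
        int u = a[e1], v = b[e1], x = a[e2], y = b[e2];
        if (unif_rand() < 0.5) std::swap(x, y);
        if (u == x || u == y || v == x || v == y) continue;
        if (adjm[(size_t)u * n + y] || adjm[(size_t)x * n + v]) continue;
        adjm[(size_t)u * n + v] = adjm[(size_t)v * n + u] = 0;
        adjm[(size_t)x * n + y] = adjm[(size_t)y * n + x] = 0;
        adjm[(size_t)u * n + y] = adjm[(size_t)y * n + u] = 1;
        adjm[(size_t)x * n + v] = adjm[(size_t)v * n + x] = 1;
        b[e1] = y;
        b[e2] = v;
        a[e2] = x;
    }
    IntegerMatrix out(E, 2);
    for (int e = 0; e < E; ++e) {
        out(e, 0) = std::min(a[e], b[e]) + 1;
        out(e, 1) = std::max(a[e], b[e]) + 1;
    }
    return out;
}
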