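# Independent brute-force implementations used as oracles. These are written
# as literal loops over the defining formulas and share no code with the
# package internals.

# Onnela / Watts-Strogatz clustering by explicit triple loop.
oracleClustering <- function(A, weighted) {
    n <- nrow(A)
    M <- if (weighted && max(A) > 0) (A / max(A))^(1 / 3) else (A > 0) * 1
    cc <- numeric(n)
    for (i in seq_len(n)) {
        k <- sum(A[i, ] > 0)
        if (k < 2) next
        s <- 0
        for (j in seq_len(n)) {
            for (h in seq_len(n)) {
                if (j != i && h != i && j != h)
                    s <- s + M[i, j] * M[i, h] * M[j, h]
            }
        }
        cc[i] <- s / (k * (k - 1))
    }
    list(node = cc, mean = mean(cc))
}

# Floyd-Warshall all-pairs shortest paths on lengths 1/w.
oracleDistances <- function(A) {
    n <- nrow(A)
    d <- matrix(Inf, n, n)
    d[A > 0] <- 1 / A[A > 0]
    diag(d) <- 0
    for (k in seq_len(n))
        d <- pmin(d, outer(d[, k], d[k, ], "+"))
    d
}

oracleLp <- function(d) {
    n <- nrow(d)
    inv <- 1 / d
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    n * (n - 1) / sum(inv)
}

oracleEglob <- function(d) {
    n <- nrow(d)
    inv <- 1 / d
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    sum(inv) / (n * (n - 1))
}

# Local efficiency by explicit neighborhood subgraph loop.
oracleEloc <- function(A) {
    n <- nrow(A)
    vals <- numeric(n)
    for (i in seq_len(n)) {
        nb <- which(A[i, ] > 0)
        if (length(nb) < 2) next
        vals[i] <- oracleEglob(oracleDistances(A[nb, nb, drop = FALSE]))
    }
    mean(vals)
}

# Random test graph with distinct weights (no ties at the sparsity cut).
randomTestGraph <- function(n, nEdges, weighted = TRUE, seed = 1) {
    set.seed(seed)
    pairs <- which(upper.tri(matrix(0, n, n)))
    pick <- sort(sample(pairs, nEdges))
    i <- ((pick - 1L) %% n) + 1L
    j <- ((pick - 1L) %/% n) + 1L
    w <- if (weighted) runif(nEdges, 0.05, 1) else rep(1, nEdges)
    thresholdedGraph(cbind(i, j), w, nodes = n,
                     mode = if (weighted) "weighted" else "binary")
}

# Correlation matrix of random Gaussian data (valid correlation structure).
randomCorMatrix <- function(R, nSubj = 40, seed = 1) {
    set.seed(seed)
    cor(matrix(rnorm(nSubj * R), nSubj, R))
}

corNetwork <- function(r, group = "test") {
    new("CovarianceNetwork", r = r,
        regions = sprintf("r%03d", seq_len(nrow(r))),
        nSubjects = NA_integer_, group = group)
}

# Ring lattice: each node connected to its k nearest neighbors (k even).
ringLattice <- function(n, k, weighted = FALSE) {
    stopifnot(k %% 2 == 0)
    e <- NULL
    for (step in seq_len(k / 2)) {
        a <- seq_len(n)
        b <- ((a - 1 + step) %% n) + 1
        e <- rbind(e, cbind(pmin(a, b), pmax(a, b)))
    }
    e <- unique(e)
    thresholdedGraph(e, if (weighted) runif(nrow(e), 0.5, 1) else NULL,
                     nodes = n,
                     mode = if (weighted) "weighted" else "binary")
}
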