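# Internal fast path used by the permutation machinery: operates on plain
# matrices so that rebuilding both group networks in every permutation stays
# cheap. The user-facing route (residualizeCBF -> correlationNetwork ->
# applySparsity -> clusteringCoefficient) computes the same quantities;
# tests assert the two routes agree.

#' @useDynLib cbfnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# OLS residuals of Y (subjects x regions) on design X, then Pearson
# correlations across subjects. Normal equations are fine here: the design
# is an intercept plus a couple of well-scaled covariates.
.residCor <- function(Y, X) {
    B <- solve(crossprod(X), crossprod(X, Y))
    cor(Y - X %*% B)
}

# Ranked upper-triangle edges of a correlation matrix, as used by
# applySparsity: list(edges = kmax x 2, w = strengths descending). Partial
# selection narrows the candidate set before the full (strength desc, i, j)
# ordering, which matters inside the permutation loop.
.rankedEdges <- function(r, kmax, rank) {
    R <- nrow(r)
    ut <- .upperTriCached(R)
    strength <- if (rank == "absolute") abs(r[ut$idx]) else r[ut$idx]
    m <- length(strength)
    cand <- seq_len(m)
    if (kmax < m) {
        thr <- sort(strength, partial = m - kmax + 1L)[m - kmax + 1L]
        cand <- which(strength >= thr)
    }
    ord <- cand[order(-strength[cand], ut$i[cand], ut$j[cand])][seq_len(kmax)]
    w <- strength[ord]
    if (any(w <= 0))
        .stopf("cannot rank %d edges: non-positive strengths reached", kmax)
    list(edges = cbind(ut$i[ord], ut$j[ord]), w = pmin(w, 1))
}

# Cp at every sparsity in the schedule, via the incremental C++ kernel.
.cpCurveFromCor <- function(r, schedule, mode, rank) {
    R <- nrow(r)
    kvec <- as.integer(round(schedule * R * (R - 1) / 2))
    cp_curve_cor_cpp(r, kvec, mode == "weighted", rank == "absolute")
}

# Per-sparsity values of one metric from a correlation matrix. Normalized
# metrics draw nRandom degree-preserving references per threshold, seeded
# from `seed`.
.metricValuesFromCor <- function(r, schedule, metric, mode, rank,
                                 nRandom, seed, regions = NULL) {
    if (metric == "Cp")
        return(.cpCurveFromCor(r, schedule, mode, rank))
    if (is.null(regions)) regions <- sprintf("r%03d", seq_len(nrow(r)))
    net <- new("CovarianceNetwork", r = r, regions = regions,
               nSubjects = NA_integer_, group = "internal")
    needRefs <- metric %in% c("gamma", "lambda", "sigma")
    seeds <- if (needRefs) .deriveSeeds(seed, length(schedule))
    weighted <- mode == "weighted"
    vapply(seq_along(schedule), function(k) {
        g <- applySparsity(net, schedule[k], mode = mode, rank = rank)
        if (!needRefs) {
            return(switch(metric,
                Lp = characteristicPathLength(shortestDistances(g)),
                Eglob = globalEfficiency(shortestDistances(g)),
                Eloc = localEfficiency(g),
                .stopf("unknown metric '%s'", metric)))
        }
        # reference Cp/Lp computed on plain edge lists: same rewiring and
        # weight-shuffle null as randomReferences(), minus object overhead
        E <- nrow(g@edges)
        nn <- length(g@nodes)
        needCp <- metric %in% c("gamma", "sigma")
        needLp <- metric %in% c("lambda", "sigma")
        ref <- .withSeed(seeds[k], vapply(seq_len(nRandom), function(q) {
            e2 <- rewire_ms_cpp(g@edges, nn, ceiling(10 * E))
            w2 <- if (weighted) sample(g@weights) else g@weights
            c(if (needCp) cp_curve_cpp(e2, w2, nn, E, weighted) else NA_real_,
              if (needLp) characteristicPathLength(
                  dijkstra_edges_cpp(e2, w2, nn)) else NA_real_)
        }, numeric(2)))
        gamma <- if (needCp)
            cp_curve_cpp(g@edges, g@weights, nn, E, weighted) /
                mean(ref[1, ])
        lambda <- if (needLp)
            characteristicPathLength(
                dijkstra_edges_cpp(g@edges, g@weights, nn)) / mean(ref[2, ])
        switch(metric, gamma = gamma, lambda = lambda,
               sigma = gamma / lambda)
    }, numeric(1))
}

# Group statistic (per-sparsity vector or AUC scalar) for one index set.
.groupStat <- function(Y, X, idx, schedule, metric, mode, rank, level,
                       nRandom, seed) {
    r <- .residCor(Y[idx, , drop = FALSE], X[idx, , drop = FALSE])
    v <- .metricValuesFromCor(r, schedule, metric, mode, rank, nRandom, seed)
    if (level == "auc") {
        if (length(schedule) == 1L) v else .trapz(schedule, v)
    } else v
}
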