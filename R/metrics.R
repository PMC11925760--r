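#' Nodewise and mean clustering coefficient
#'
#' Binary graphs use the Watts-Strogatz triangle fraction. Weighted graphs
#' use the Onnela coefficient: for node i,
#' `C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w~_ij w~_ih w~_jh)^{1/3}`
#' over ordered neighbor pairs, with every weight normalized by the maximum
#' weight in the graph; it reduces to Watts-Strogatz on unit weights. Nodes
#' of degree < 2 contribute 0, and the mean is taken over all N nodes so
#' denominators are comparable across groups.
#'
#' @param graph a [ThresholdedGraph-class].
#' @return list with `node` (per-node values) and `mean` (Cp).
#' @export
clusteringCoefficient <- function(graph) {
    stopifnot(is(graph, "ThresholdedGraph"))
    A <- adjacencyMatrix(graph)
    deg <- colSums(A > 0)
    M <- if (graph@mode == "weighted" && any(A > 0)) (A / max(A))^(1/3)
         else (A > 0) * 1
    paths <- diag(M %*% M %*% M)
    cc <- ifelse(deg >= 2, paths / pmax(deg * (deg - 1), 1), 0)
    list(node = setNames(cc, graph@nodes), mean = mean(cc))
}

# Shortest-path distances from a weight matrix (0 = no edge); edge length is
# the reciprocal weight, so stronger coupling means shorter distance.
.distancesFromWeights <- function(W) {
    n <- nrow(W)
    if (n == 0L) return(matrix(numeric(0), 0, 0))
    keep <- which(upper.tri(W) & W > 0)
    if (!length(keep)) {
        d <- matrix(Inf, n, n)
        diag(d) <- 0
        return(d)
    }
    i <- ((keep - 1L) %% n) + 1L
    j <- ((keep - 1L) %/% n) + 1L
    dijkstra_edges_cpp(cbind(i, j), W[keep], n)
}

#' All-pairs shortest-path distances
#'
#' Edge length is `1/weight` (1 on binary graphs): stronger coupling means
#' shorter distance. Pairs in different components are `Inf`.
#'
#' @param graph a [ThresholdedGraph-class].
#' @return an N x N numeric matrix with zero diagonal.
#' @export
shortestDistances <- function(graph) {
    stopifnot(is(graph, "ThresholdedGraph"))
    d <- .distancesFromWeights(adjacencyMatrix(graph))
    dimnames(d) <- list(graph@nodes, graph@nodes)
    d
}

#' Characteristic path length (harmonic mean distance)
#'
#' `Lp = N (N - 1) / sum_{i != j} 1 / d_ij`, the harmonic mean of pairwise
#' distances. Unreachable pairs contribute 0 to the reciprocal sum, so Lp is
#' finite whenever at least one pair is connected — the point of using the
#' harmonic mean on possibly disconnected thresholded networks. Identically,
#' `Lp = 1 / Eglob`.
#'
#' @param d distance matrix from [shortestDistances()].
#' @return Lp (scalar).
#' @export
characteristicPathLength <- function(d) {
    n <- nrow(d)
    if (n < 2L) .stopf("need at least 2 nodes")
    inv <- 1 / d
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    s <- sum(inv)
    if (s == 0) .stopf("no connected node pair; path length undefined")
    n * (n - 1) / s
}

#' Global efficiency
#'
#' `Eglob = mean over ordered pairs of 1 / d_ij`; unreachable pairs
#' contribute 0.
#'
#' @param d distance matrix from [shortestDistances()].
#' @return Eglob (scalar).
#' @export
globalEfficiency <- function(d) {
    n <- nrow(d)
    if (n < 2L) .stopf("need at least 2 nodes")
    inv <- 1 / d
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of each node's neighborhood
#' subgraph (the node itself removed). Nodes with fewer than two neighbors
#' contribute 0.
#'
#' @param graph a [ThresholdedGraph-class].
#' @return Eloc (scalar).
#' @export
localEfficiency <- function(graph) {
    stopifnot(is(graph, "ThresholdedGraph"))
    A <- adjacencyMatrix(graph)
    n <- nrow(A)
    eff <- vapply(seq_len(n), function(i) {
        nb <- which(A[i, ] > 0)
        if (length(nb) < 2L) return(0)
        sub <- A[nb, nb, drop = FALSE]
        globalEfficiency(.distancesFromWeights(sub))
    }, numeric(1))
    mean(eff)
}

#' Degree-preserving random reference networks
#'
#' Generates `n` references by Maslov-Sneppen double-edge-swap rewiring
#' (10 x E attempted swaps by default), which preserves every node's degree
#' and the edge count exactly. In weighted mode the original multiset of
#' edge weights is randomly reassigned to the rewired edges, preserving the
#' weight distribution. Deterministic given `seed`.
#'
#' @param graph a [ThresholdedGraph-class] with at least 2 edges.
#' @param n number of references.
#' @param seed RNG seed.
#' @param nSwapFactor attempted swaps per edge.
#' @return list of [ThresholdedGraph-class] references.
#' @export
randomReferences <- function(graph, n = 100, seed = 1L, nSwapFactor = 10) {
    stopifnot(is(graph, "ThresholdedGraph"))
    E <- nrow(graph@edges)
    if (E < 2L) .stopf("need at least 2 edges to rewire")
    nNodes <- length(graph@nodes)
    .withSeed(seed, lapply(seq_len(n), function(k) {
        e <- rewire_ms_cpp(graph@edges, nNodes, ceiling(nSwapFactor * E))
        w <- if (graph@mode == "weighted") sample(graph@weights)
             else rep(1, E)
        new("ThresholdedGraph", nodes = graph@nodes, edges = e,
            weights = w, sparsity = graph@sparsity, mode = graph@mode)
    }))
}

#' All seven global metrics, normalized against random references
#'
#' Computes Cp, Lp, Eloc and Eglob on the graph, Cp and Lp on every
#' reference, and reports `gamma = Cp / mean(Cp_ref)`,
#' `lambda = Lp / mean(Lp_ref)` and the small-worldness
#' `sigma = gamma / lambda`.
#'
#' @param graph a [ThresholdedGraph-class].
#' @param references list of reference graphs from [randomReferences()].
#' @return one-row data.frame with columns `Cp, Lp, gamma, lambda, sigma,
#'   Eloc, Eglob, nRandom`.
#' @export
normalizedMetrics <- function(graph, references) {
    stopifnot(is(graph, "ThresholdedGraph"))
    if (!length(references)) .stopf("need at least one reference network")
    d <- shortestDistances(graph)
    Cp <- clusteringCoefficient(graph)$mean
    Lp <- characteristicPathLength(d)
    refCp <- mean(vapply(references, function(g)
        clusteringCoefficient(g)$mean, numeric(1)))
    refLp <- mean(vapply(references, function(g)
        characteristicPathLength(shortestDistances(g)), numeric(1)))
    if (refCp == 0) .stopf("mean reference clustering is zero")
    if (refLp == 0) .stopf("mean reference path length is zero")
    gamma <- Cp / refCp
    lambda <- Lp / refLp
    data.frame(Cp = Cp, Lp = Lp, gamma = gamma, lambda = lambda,
               sigma = gamma / lambda, Eloc = localEfficiency(graph),
               Eglob = globalEfficiency(d), nRandom = length(references))
}

#' Global metric trajectories over a sparsity schedule
#'
#' Thresholds the covariance network at every sparsity in the schedule,
#' computes the seven global measures (with `nRandom` degree-preserving
#' references per threshold for gamma/lambda/sigma), and summarizes each
#' metric by its trapezoidal area under the curve over the schedule. A
#' single-point schedule reports the raw value with `aucWidth = 0`.
#'
#' @param net a [CovarianceNetwork-class].
#' @param schedule sparsity values from [sparsitySchedule()].
#' @param mode `"weighted"` or `"binary"`.
#' @param nRandom random references per threshold.
#' @param seed RNG seed for the references.
#' @param rank edge ranking passed to [applySparsity()].
#' @return a [MetricCurve-class].
#' @export
metricCurve <- function(net, schedule = sparsitySchedule(),
                        mode = c("weighted", "binary"), nRandom = 100,
                        seed = 1L, rank = c("absolute", "positive")) {
    stopifnot(is(net, "CovarianceNetwork"))
    mode <- match.arg(mode)
    rank <- match.arg(rank)
    if (!length(schedule) || any(diff(schedule) <= 0))
        .stopf("schedule must be strictly increasing and non-empty")
    seeds <- .deriveSeeds(seed, length(schedule))
    rows <- lapply(seq_along(schedule), function(k) {
        g <- applySparsity(net, schedule[k], mode = mode, rank = rank)
        refs <- randomReferences(g, n = nRandom, seed = seeds[k])
        cbind(sparsity = schedule[k], normalizedMetrics(g, refs))
    })
    tab <- do.call(rbind, rows)
    width <- max(schedule) - min(schedule)
    metricNames <- c("Cp", "Lp", "gamma", "lambda", "sigma", "Eloc", "Eglob")
    auc <- vapply(metricNames, function(m)
        if (length(schedule) == 1L) tab[[m]] else .trapz(schedule, tab[[m]]),
        numeric(1))
    new("MetricCurve", metrics = tab, auc = auc, aucWidth = width,
        mode = mode, nRandom = as.integer(nRandom), seed = as.integer(seed))
}

#' @describeIn MetricCurve per-sparsity metrics table.
#' @export
setMethod("metricsTable", "MetricCurve", function(x) x@metrics)

#' @describeIn MetricCurve named AUC vector (raw value for single-point
#'   schedules).
#' @export
setMethod("aucValues", "MetricCurve", function(x) x@auc)

setMethod("show", "MetricCurve", function(object) {
    s <- object@metrics$sparsity
    cat(sprintf("MetricCurve (%s): %d sparsity levels in [%.2f, %.2f], %d references\n",
                object@mode, length(s), min(s), max(s), object@nRandom))
    cat("  AUC:", paste(sprintf("%s=%.4g", names(object@auc), object@auc),
                        collapse = ", "), "\n")
})

#' Write a metric curve as tidy TSV
#'
#' Columns: `group, mode, sparsity, metric, value`; AUC rows carry
#' `sparsity = NA` and metric names suffixed `_auc`.
#'
#' @param x a [MetricCurve-class].
#' @param path output file.
#' @param group group tag recorded in the first column.
#' @return `path`, invisibly.
#' @export
writeMetricsTSV <- function(x, path, group = "all") {
    stopifnot(is(x, "MetricCurve"))
    tab <- x@metrics
    metricNames <- c("Cp", "Lp", "gamma", "lambda", "sigma", "Eloc", "Eglob")
    long <- do.call(rbind, lapply(metricNames, function(m)
        data.frame(group = group, mode = x@mode, sparsity = tab$sparsity,
                   metric = m, value = tab[[m]])))
    aucRows <- data.frame(group = group, mode = x@mode, sparsity = NA,
                          metric = paste0(names(x@auc), "_auc"),
                          value = unname(x@auc))
    write.table(rbind(long, aucRows), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' @rdname writeMetricsTSV
#' @export
writeMetricsJSON <- function(x, path, group = "all") {
    stopifnot(is(x, "MetricCurve"))
    jsonlite::write_json(
        list(group = group, mode = x@mode, n_random = x@nRandom,
             seed = x@seed, schedule = x@metrics$sparsity,
             auc = as.list(x@auc), auc_width = x@aucWidth,
             metrics = x@metrics),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
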