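#' Regress covariates out of regional CBF values
#'
#' Fits, at every region, an ordinary least squares model of the regional
#' value on an intercept plus the named covariates, and replaces the values
#' by the residuals. Residuals have zero mean and zero sample correlation
#' with each covariate, which is what the covariance network is computed
#' over.
#'
#' @param x a [RegionalCBF-class].
#' @param covariates covariate column names in `subjectInfo(x)`
#'   (default age and sex).
#' @return a [RegionalCBF-class] of residuals (`isResidualized()` is TRUE).
#' @export
residualizeCBF <- function(x, covariates = c("age", "sex")) {
    stopifnot(is(x, "RegionalCBF"))
    info <- subjectInfo(x)
    miss <- setdiff(covariates, colnames(info))
    if (length(miss))
        .stopf("unknown covariate(s): %s", paste(miss, collapse = ", "))
    X <- cbind(`(Intercept)` = 1,
               as.matrix(info[, covariates, drop = FALSE]))
    if (nrow(X) <= ncol(X))
        .stopf("need more than %d subjects to residualize %d covariates",
               ncol(X), length(covariates))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        drop <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
        .stopf("rank-deficient design: covariate(s) %s carry no information",
               paste(drop, collapse = ", "))
    }
    res <- qr.resid(qrX, cbfMatrix(x))
    RegionalCBF(res, info, regions = regionNames(x), residualized = TRUE)
}

#' Across-subject Pearson covariance network
#'
#' Correlates every pair of regions across the subjects of one group,
#' producing the group-level R x R covariance network. This is a group
#' construct: there are no per-subject networks.
#'
#' @param x a [RegionalCBF-class], typically residualized.
#' @param group optional group label to subset to; by default all subjects
#'   in `x` are used.
#' @return a [CovarianceNetwork-class].
#' @export
correlationNetwork <- function(x, group = NULL) {
    stopifnot(is(x, "RegionalCBF"))
    if (!is.null(group)) x <- .subsetGroup(x, group)
    vals <- cbfMatrix(x)
    if (nrow(vals) < 4L)
        .stopf("need at least 4 subjects, got %d", nrow(vals))
    sds <- apply(vals, 2, sd)
    if (any(sds == 0))
        .stopf("constant region(s): %s",
               paste(colnames(vals)[sds == 0], collapse = ", "))
    r <- cor(vals)
    diag(r) <- 1
    r <- (r + t(r)) / 2
    new("CovarianceNetwork", r = r, regions = colnames(vals),
        nSubjects = nrow(vals),
        group = if (is.null(group)) "all" else group)
}

#' @describeIn CovarianceNetwork the correlation matrix.
#' @export
setMethod("corMatrix", "CovarianceNetwork", function(x) x@r)

setMethod("show", "CovarianceNetwork", function(object) {
    cat(sprintf("CovarianceNetwork: %d regions, %d subjects (group %s)\n",
                nrow(object@r), object@nSubjects, object@group))
    off <- object@r[upper.tri(object@r)]
    cat(sprintf("  off-diagonal r: median %.3f, range [%.3f, %.3f]\n",
                stats::median(off), min(off), max(off)))
})

#' Sparsity schedule for proportional thresholding
#'
#' The default schedule, 0.09 to 0.30 in steps of 0.01 (22 levels), keeps the
#' mean node degree of a 116-node network above 2 ln(N) at the lower end
#' while staying sparse at the upper end.
#'
#' @param min,max schedule endpoints (inclusive), in (0, 1).
#' @param step increment.
#' @return numeric vector of sparsity values, rounded to the step's decimal
#'   precision.
#' @examples
#' sparsitySchedule()              # 22 values, 0.09 .. 0.30
#' sparsitySchedule(0.05, 0.2, 0.05)
#' @export
sparsitySchedule <- function(min = 0.09, max = 0.30, step = 0.01) {
    if (!(min > 0 && max < 1 && min <= max))
        .stopf("need 0 < min <= max < 1 (got %g, %g)", min, max)
    if (step <= 0) .stopf("step must be positive")
    frac <- sub("^[^.]*\\.?", "", format(step, digits = 15, scientific = FALSE))
    digits <- nchar(frac)
    s <- round(seq(min, max + step / 2, by = step), digits)
    s <- s[s <= max + 1e-12]
    unique(s)
}

#' Threshold a covariance network at a sparsity level
#'
#' Keeps the top `round(S * R * (R - 1) / 2)` edges ranked by connection
#' strength. By default strength is the absolute correlation `|r|` (the
#' usual covariance-network convention, keeping weights in (0, 1]);
#' `rank = "positive"` ranks on signed r and drops non-positive edges from
#' eligibility. Ties are broken deterministically on ascending node-index
#' pairs. Edge weights are the strengths, unrescaled; binary mode sets all
#' weights to 1.
#'
#' @param net a [CovarianceNetwork-class].
#' @param S sparsity in (0, 1]; `S = 1` gives the complete graph.
#' @param mode `"weighted"` or `"binary"`.
#' @param rank `"absolute"` or `"positive"`.
#' @return a [ThresholdedGraph-class].
#' @export
applySparsity <- function(net, S, mode = c("weighted", "binary"),
                          rank = c("absolute", "positive")) {
    stopifnot(is(net, "CovarianceNetwork"))
    mode <- match.arg(mode)
    rank <- match.arg(rank)
    if (!(S > 0 && S <= 1)) .stopf("sparsity must lie in (0, 1]")
    R <- nrow(net@r)
    ut <- .upperTri(R)
    strength <- if (rank == "absolute") abs(net@r[ut]) else net@r[ut]
    k <- round(S * R * (R - 1) / 2)
    if (k < 1L) .stopf("sparsity %g yields an empty graph on %d nodes", S, R)
    ord <- order(-strength, ut[, "i"], ut[, "j"])[seq_len(k)]
    w <- strength[ord]
    if (rank == "positive" && any(w <= 0))
        .stopf("fewer than %d positive correlations available", k)
    if (any(w == 0))
        .stopf("cannot rank zero-strength edges at sparsity %g", S)
    w <- pmin(w, 1)
    new("ThresholdedGraph", nodes = net@regions,
        edges = cbind(ut[ord, "i"], ut[ord, "j"]),
        weights = if (mode == "binary") rep(1, k) else w,
        sparsity = S, mode = mode)
}

#' Construct a thresholded graph directly from an edge list
#'
#' Mainly for tests and toy examples; `sparsity` defaults to the achieved
#' edge density.
#'
#' @param edges two-column matrix of 1-based node index pairs (i < j).
#' @param weights edge weights in (0, 1].
#' @param nodes node labels (or an integer node count).
#' @param mode `"weighted"` or `"binary"`.
#' @return a [ThresholdedGraph-class].
#' @export
thresholdedGraph <- function(edges, weights = NULL, nodes,
                             mode = c("weighted", "binary")) {
    mode <- match.arg(mode)
    if (length(nodes) == 1L && is.numeric(nodes))
        nodes <- sprintf("n%02d", seq_len(nodes))
    edges <- matrix(as.integer(edges), ncol = 2)
    flip <- edges[, 1] > edges[, 2]
    edges[flip, ] <- edges[flip, 2:1]
    if (is.null(weights) || mode == "binary") weights <- rep(1, nrow(edges))
    n <- length(nodes)
    new("ThresholdedGraph", nodes = nodes, edges = edges,
        weights = as.numeric(weights),
        sparsity = nrow(edges) / (n * (n - 1) / 2), mode = mode)
}

#' @describeIn ThresholdedGraph edge index matrix (i < j).
#' @export
setMethod("graphEdges", "ThresholdedGraph", function(x) x@edges)

#' @describeIn ThresholdedGraph edge weights.
#' @export
setMethod("edgeWeights", "ThresholdedGraph", function(x) x@weights)

#' @describeIn ThresholdedGraph achieved sparsity.
#' @export
setMethod("sparsityLevel", "ThresholdedGraph", function(x) x@sparsity)

#' @describeIn ThresholdedGraph `"weighted"` or `"binary"`.
#' @export
setMethod("graphMode", "ThresholdedGraph", function(x) x@mode)

#' @describeIn ThresholdedGraph dense symmetric adjacency (weight) matrix.
#' @export
setMethod("adjacencyMatrix", "ThresholdedGraph", function(x) {
    n <- length(x@nodes)
    A <- matrix(0, n, n, dimnames = list(x@nodes, x@nodes))
    A[x@edges] <- x@weights
    A[x@edges[, 2:1, drop = FALSE]] <- x@weights
    A
})

#' @describeIn ThresholdedGraph convert to an igraph object; with
#'   `distance = TRUE` edge attribute `weight` is the length 1/w used for
#'   shortest paths.
#' @export
setMethod("asIgraph", "ThresholdedGraph", function(x, distance = FALSE) {
    g <- igraph::make_empty_graph(n = length(x@nodes), directed = FALSE)
    g <- igraph::add_edges(g, t(x@edges))
    igraph::V(g)$name <- x@nodes
    igraph::E(g)$weight <- if (distance) 1 / x@weights else x@weights
    g
})

setMethod("show", "ThresholdedGraph", function(object) {
    cat(sprintf("ThresholdedGraph: %d nodes, %d edges (S = %.3f, %s)\n",
                length(object@nodes), nrow(object@edges), object@sparsity,
                object@mode))
})

#' Mean-degree criterion for threshold admissibility
#'
#' A sparsity level is admissible when the mean node degree 2E/N exceeds
#' 2 log(N); the natural logarithm is the default, as is standard in the
#' small-world estimation literature, with the base configurable.
#'
#' @param graph a [ThresholdedGraph-class].
#' @param base logarithm base (default `exp(1)`).
#' @return list with `pass` (logical), `meanDegree` and `threshold`.
#' @export
checkDegreeCriterion <- function(graph, base = exp(1)) {
    stopifnot(is(graph, "ThresholdedGraph"))
    n <- length(graph@nodes)
    meanDegree <- 2 * nrow(graph@edges) / n
    threshold <- 2 * log(n, base = base)
    list(pass = meanDegree > threshold, meanDegree = meanDegree,
         threshold = threshold)
}

#' Export a covariance network or thresholded graph as TSV
#'
#' `writeNetworkTSV` writes the square correlation matrix with a region-label
#' header; `writeEdgeListTSV` writes `region_a, region_b, weight` rows.
#'
#' @param x a [CovarianceNetwork-class] or [ThresholdedGraph-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNetworkTSV <- function(x, path) {
    stopifnot(is(x, "CovarianceNetwork"))
    m <- x@r
    dimnames(m) <- list(x@regions, x@regions)
    write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
    invisible(path)
}

#' @rdname writeNetworkTSV
#' @export
writeEdgeListTSV <- function(x, path) {
    df <- if (is(x, "ThresholdedGraph")) {
        data.frame(region_a = x@nodes[x@edges[, 1]],
                   region_b = x@nodes[x@edges[, 2]],
                   weight = x@weights)
    } else if (is(x, "CovarianceNetwork")) {
        ut <- .upperTri(nrow(x@r))
        data.frame(region_a = x@regions[ut[, "i"]],
                   region_b = x@regions[ut[, "j"]],
                   weight = x@r[ut])
    } else .stopf("unsupported class: %s", class(x)[1])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
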