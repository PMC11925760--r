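# internal helpers shared across modules

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is restored afterwards so seeded helpers do not perturb it.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Derive a child seed stream from a master seed (values < 2^31).
.deriveSeeds <- function(seed, n) {
    .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Trapezoidal integral of y over x.
.trapz <- function(x, y) {
    n <- length(x)
    if (n == 1L) return(y)
    sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Row/column indices of the strict upper triangle of an R x R matrix,
# column-major, as used to vectorize symmetric matrices consistently.
.upperTri <- function(R) {
    j <- rep.int(seq_len(R), seq_len(R) - 1L)
    i <- sequence(seq_len(R) - 1L)
    cbind(i = i, j = j)
}

# Cached variant for the permutation loop: i/j vectors plus the linear
# index of the strict upper triangle in an R x R matrix.
.utCache <- new.env(parent = emptyenv())
.upperTriCached <- function(R) {
    key <- as.character(R)
    got <- .utCache[[key]]
    if (!is.null(got)) return(got)
    ut <- .upperTri(R)
    out <- list(i = ut[, "i"], j = ut[, "j"],
                idx = (ut[, "j"] - 1L) * R + ut[, "i"])
    .utCache[[key]] <- out
    out
}

# Block-constant correlation matrix: nRegions split into nModules contiguous
# modules as evenly as possible; rhoWithin inside a module, rhoBetween across.
.blockCorrelation <- function(nRegions, nModules, rhoWithin, rhoBetween) {
    module <- sort(rep_len(seq_len(nModules), nRegions))
    same <- outer(module, module, "==")
    R <- ifelse(same, rhoWithin, rhoBetween)
    diag(R) <- 1
    R
}

# Shrink a signal correlation matrix for independent additive noise of
# standard deviation noiseSd (signal has unit SD).
.noisyCorrelation <- function(R, noiseSd) {
    out <- R / (1 + noiseSd^2)
    diag(out) <- 1
    out
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
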