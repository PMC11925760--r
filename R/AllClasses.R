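#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor sd rnorm runif rbinom quantile setNames
#' @importFrom utils read.delim write.table head
NULL

#' Subjects-by-regions regional CBF container
#'
#' `RegionalCBF` extends \linkS4class{SummarizedExperiment}: rows are atlas
#' regions, columns are subjects. The single assay `"cbf"` holds mean regional
#' CBF (normalized or raw); `colData` carries the subject covariates
#' (`group`, `age`, `sex`) used for residualization and group comparison.
#'
#' @slot residualized logical flag; `TRUE` after [residualizeCBF()].
#' @export
setClass("RegionalCBF",
    contains = "SummarizedExperiment",
    representation(residualized = "logical"),
    prototype(residualized = FALSE)
)

setValidity("RegionalCBF", function(object) {
    msg <- character()
    if (!"cbf" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'cbf' is required")
    else if (anyNA(SummarizedExperiment::assay(object, "cbf")))
        msg <- c(msg, "assay 'cbf' contains missing values")
    cd <- SummarizedExperiment::colData(object)
    need <- c("group", "age", "sex")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks covariate(s): ",
                             paste(miss, collapse = ", ")))
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate subject ids")
    if (is.null(rownames(object)))
        msg <- c(msg, "region labels (rownames) are required")
    if (length(msg)) msg else TRUE
})

#' Specification of a two-group synthetic CBF cohort
#'
#' Region values are drawn per group from a multivariate normal with
#' block-modular correlation: `rhoWithin` inside each of `nModules`
#' contiguous region modules, `rhoBetween` across modules. Independent
#' Gaussian noise with standard deviation `noiseSd` (relative to the unit
#' signal SD) and linear age/sex effects are added on top, so the implied
#' region-region correlation is the block matrix shrunk by
#' `1 / (1 + noiseSd^2)` off the diagonal.
#'
#' @slot nGroupA,nGroupB group sizes (subjects).
#' @slot nRegions number of atlas regions (nodes).
#' @slot nModules number of correlation modules.
#' @slot rhoWithinA,rhoWithinB within-module correlation per group, in [0, 1).
#' @slot rhoBetween between-module correlation, in [0, 1).
#' @slot noiseSd independent noise SD (signal has unit SD).
#' @slot ageEffect,sexEffect linear covariate slopes per region (length 1 or
#'   `nRegions`).
#' @slot meanCBF baseline regional CBF level.
#' @slot ageRange uniform sampling interval for age, in years.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortSpec", representation(
    nGroupA = "integer", nGroupB = "integer",
    nRegions = "integer", nModules = "integer",
    rhoWithinA = "numeric", rhoWithinB = "numeric", rhoBetween = "numeric",
    noiseSd = "numeric",
    ageEffect = "numeric", sexEffect = "numeric",
    meanCBF = "numeric", ageRange = "numeric",
    seed = "integer"
))

setValidity("CohortSpec", function(object) {
    msg <- character()
    if (object@nGroupA < 3L || object@nGroupB < 3L)
        msg <- c(msg, "group sizes must be >= 3")
    if (!(object@nRegions >= object@nModules && object@nModules >= 1L))
        msg <- c(msg, "need nRegions >= nModules >= 1")
    for (nm in c("rhoWithinA", "rhoWithinB", "rhoBetween")) {
        r <- slot(object, nm)
        if (!is.finite(r) || r < 0 || r >= 1)
            msg <- c(msg, paste0(nm, " must lie in [0, 1)"))
    }
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@meanCBF <= 0) msg <- c(msg, "meanCBF must be positive")
    if (length(object@ageRange) != 2L || diff(object@ageRange) < 0)
        msg <- c(msg, "ageRange must be an increasing pair")
    for (nm in c("ageEffect", "sexEffect")) {
        le <- length(slot(object, nm))
        if (!le %in% c(1L, object@nRegions))
            msg <- c(msg, paste0(nm, " must have length 1 or nRegions"))
    }
    if (!length(msg)) {
        for (grp in c("A", "B")) {
            R <- .blockCorrelation(object@nRegions, object@nModules,
                if (grp == "A") object@rhoWithinA else object@rhoWithinB,
                object@rhoBetween)
            ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
            if (min(ev) < -1e-8)
                msg <- c(msg, paste0("implied correlation matrix for group ",
                                     grp, " is not positive semi-definite"))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Synthetic two-group cohort with known generating structure
#'
#' @slot data a [RegionalCBF-class] holding both groups (column `group` in
#'   `colData` is `"A"` or `"B"`).
#' @slot truth list with the implied (noise-shrunk) region-region correlation
#'   matrix per group, named `A` and `B`.
#' @slot spec the generating [CohortSpec-class].
#' @slot seed the seed actually used.
#' @export
setClass("SyntheticCohort", representation(
    data = "RegionalCBF", truth = "list", spec = "CohortSpec",
    seed = "integer"
))

setValidity("SyntheticCohort", function(object) {
    msg <- character()
    sp <- object@spec
    if (ncol(object@data) != sp@nGroupA + sp@nGroupB)
        msg <- c(msg, "subject count does not match spec")
    if (nrow(object@data) != sp@nRegions)
        msg <- c(msg, "region count does not match spec")
    if (!identical(sort(names(object@truth)), c("A", "B")))
        msg <- c(msg, "truth must hold matrices named A and B")
    for (tm in object@truth) {
        if (!isSymmetric(unname(tm)) || max(abs(diag(tm) - 1)) > 1e-12)
            msg <- c(msg, "truth matrices must be symmetric with unit diagonal")
    }
    if (length(msg)) msg else TRUE
})

#' A CBF volume with brain mask
#'
#' @slot voxels numeric 3-D array of CBF values.
#' @slot affine 4x4 voxel-to-world transform.
#' @slot mask logical array, same shape as `voxels`.
#' @slot normalized `TRUE` once divided by the whole-brain (in-mask) mean.
#' @export
setClass("CBFVolume", representation(
    voxels = "array", affine = "matrix", mask = "array",
    normalized = "logical"
))

setValidity("CBFVolume", function(object) {
    msg <- character()
    if (!identical(dim(object@voxels), dim(object@mask)))
        msg <- c(msg, "voxel grid and mask shapes differ")
    if (!any(object@mask))
        msg <- c(msg, "brain mask is empty")
    if (!identical(dim(object@affine), c(4L, 4L)))
        msg <- c(msg, "affine must be 4x4")
    if (isTRUE(object@normalized) && any(object@mask)) {
        m <- mean(object@voxels[object@mask])
        if (abs(m - 1) > 1e-9)
            msg <- c(msg, "normalized flag set but in-mask mean is not 1")
    }
    if (length(msg)) msg else TRUE
})

#' Integer-labeled atlas volume
#'
#' @slot labels integer 3-D array; 0 is background, 1..R are regions.
#' @slot regionTable data.frame with columns `id` (integer) and `name`.
#' @export
setClass("AtlasLabelVolume", representation(
    labels = "array", regionTable = "data.frame"
))

setValidity("AtlasLabelVolume", function(object) {
    msg <- character()
    lab <- object@labels
    if (any(lab < 0) || any(lab != round(lab)))
        msg <- c(msg, "labels must be non-negative integers")
    rt <- object@regionTable
    if (!all(c("id", "name") %in% colnames(rt)))
        msg <- c(msg, "regionTable needs columns id and name")
    else {
        present <- sort(unique(as.integer(lab[lab > 0])))
        if (!all(rt$id %in% present))
            msg <- c(msg, "regionTable lists ids absent from the label grid")
    }
    if (length(msg)) msg else TRUE
})

#' Group-level CBF covariance network
#'
#' R x R Pearson correlations of region residuals across the subjects of one
#' group.
#'
#' @slot r symmetric correlation matrix with unit diagonal.
#' @slot regions region labels.
#' @slot nSubjects number of subjects the correlations were computed over.
#' @slot group group tag (free text).
#' @export
setClass("CovarianceNetwork", representation(
    r = "matrix", regions = "character", nSubjects = "integer",
    group = "character"
))

setValidity("CovarianceNetwork", function(object) {
    msg <- character()
    r <- object@r
    if (nrow(r) != ncol(r)) msg <- c(msg, "matrix not square")
    else {
        if (max(abs(r - t(r))) > 1e-12) msg <- c(msg, "matrix not symmetric")
        if (max(abs(diag(r) - 1)) > 1e-12) msg <- c(msg, "diagonal must be 1")
        if (min(r) < -1 - 1e-12 || max(r) > 1 + 1e-12)
            msg <- c(msg, "entries outside [-1, 1]")
        if (length(object@regions) != nrow(r))
            msg <- c(msg, "region labels do not match matrix dimension")
    }
    if (length(msg)) msg else TRUE
})

#' Sparsity-thresholded undirected graph
#'
#' Produced by [applySparsity()]: the strongest edges of a covariance
#' network, as many as `round(S * R * (R - 1) / 2)`.
#'
#' @slot nodes node (region) labels.
#' @slot edges integer matrix, two columns, each row an undirected edge
#'   `i < j` (1-based node indices).
#' @slot weights edge weights in (0, 1]; all 1 in binary mode.
#' @slot sparsity achieved sparsity S.
#' @slot mode `"weighted"` or `"binary"`.
#' @export
setClass("ThresholdedGraph", representation(
    nodes = "character", edges = "matrix", weights = "numeric",
    sparsity = "numeric", mode = "character"
))

setValidity("ThresholdedGraph", function(object) {
    msg <- character()
    e <- object@edges
    n <- length(object@nodes)
    if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
    else if (nrow(e)) {
        if (any(e[, 1] >= e[, 2])) msg <- c(msg, "edges must satisfy i < j (no self-loops)")
        if (min(e) < 1 || max(e) > n) msg <- c(msg, "edge indices out of range")
    }
    if (length(object@weights) != nrow(e))
        msg <- c(msg, "one weight per edge required")
    if (!object@mode %in% c("weighted", "binary"))
        msg <- c(msg, "mode must be 'weighted' or 'binary'")
    if (object@mode == "binary" && length(object@weights) &&
        any(object@weights != 1))
        msg <- c(msg, "binary mode requires unit weights")
    if (object@mode == "weighted" && length(object@weights) &&
        (min(object@weights) <= 0 || max(object@weights) > 1 + 1e-12))
        msg <- c(msg, "weighted mode requires weights in (0, 1]")
    maxE <- n * (n - 1) / 2
    if (maxE > 0 && nrow(e) != round(object@sparsity * maxE))
        msg <- c(msg, "edge count inconsistent with sparsity")
    if (length(msg)) msg else TRUE
})

#' Global network metrics along a sparsity schedule
#'
#' @slot metrics data.frame with one row per sparsity and columns
#'   `sparsity, Cp, Lp, gamma, lambda, sigma, Eloc, Eglob`.
#' @slot auc named trapezoidal area under each metric curve over the
#'   schedule; for a single-point schedule the raw value is reported and
#'   `aucWidth` is 0.
#' @slot aucWidth width (max - min) of the schedule.
#' @slot mode `"weighted"` or `"binary"`.
#' @slot nRandom number of random reference networks per threshold.
#' @slot seed seed used for the references.
#' @export
setClass("MetricCurve", representation(
    metrics = "data.frame", auc = "numeric", aucWidth = "numeric",
    mode = "character", nRandom = "integer", seed = "integer"
))

setValidity("MetricCurve", function(object) {
    msg <- character()
    need <- c("sparsity", "Cp", "Lp", "gamma", "lambda", "sigma",
              "Eloc", "Eglob")
    if (!all(need %in% colnames(object@metrics)))
        msg <- c(msg, "metrics table lacks required columns")
    if (!all(is.finite(object@auc)))
        msg <- c(msg, "AUC values must be finite")
    if (length(msg)) msg else TRUE
})

#' Result of a group-relabeling permutation test
#'
#' @slot metric metric name.
#' @slot mode `"weighted"` or `"binary"`.
#' @slot level `"auc"` or `"per-sparsity"`.
#' @slot sparsity sparsity values (per-sparsity level) or NA (AUC level).
#' @slot observed real group difference (A - B); scalar for AUC level.
#' @slot null matrix of permuted differences, `nPerm` rows.
#' @slot pValue p-value(s), same length as `observed`.
#' @slot nPerm,seed,nGroupA,nGroupB test settings.
#' @slot settings list of pipeline settings (schedule, nRandom, sidedness,
#'   p-value formula).
#' @export
setClass("PermutationResult", representation(
    metric = "character", mode = "character", level = "character",
    sparsity = "numeric", observed = "numeric", null = "matrix",
    pValue = "numeric", nPerm = "integer", seed = "integer",
    nGroupA = "integer", nGroupB = "integer", settings = "list"
))

setValidity("PermutationResult", function(object) {
    msg <- character()
    if (any(object@pValue < 0 | object@pValue > 1))
        msg <- c(msg, "p-values must lie in [0, 1]")
    if (nrow(object@null) != object@nPerm)
        msg <- c(msg, "null distribution length must equal nPerm")
    if (ncol(object@null) != length(object@observed))
        msg <- c(msg, "null and observed dimensions differ")
    if (length(object@pValue) != length(object@observed))
        msg <- c(msg, "one p-value per observed difference required")
    if (length(msg)) msg else TRUE
})
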