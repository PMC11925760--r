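#' Construct a RegionalCBF object
#'
#' @param values numeric matrix, subjects x regions.
#' @param subjects data.frame with one row per subject and columns
#'   `subject_id`, `group`, `age`, `sex` (sex coded 0/1).
#' @param regions character vector of region labels; defaults to the column
#'   names of `values`.
#' @param residualized logical; set by [residualizeCBF()].
#' @return a [RegionalCBF-class] object (regions x subjects internally).
#' @examples
#' vals <- matrix(rnorm(12, 50), nrow = 3,
#'                dimnames = list(NULL, paste0("R", 1:4)))
#' subj <- data.frame(subject_id = paste0("s", 1:3), group = "A",
#'                    age = c(50, 60, 70), sex = c(0, 1, 0))
#' RegionalCBF(vals, subj)
#' @export
RegionalCBF <- function(values, subjects, regions = colnames(values),
                        residualized = FALSE) {
    values <- as.matrix(values)
    if (is.null(regions))
        regions <- paste0("region_", seq_len(ncol(values)))
    if (length(regions) != ncol(values))
        .stopf("got %d region labels for %d regions",
               length(regions), ncol(values))
    need <- c("subject_id", "group", "age", "sex")
    miss <- setdiff(need, colnames(subjects))
    if (length(miss))
        .stopf("subject table lacks column(s): %s", paste(miss, collapse = ", "))
    if (nrow(subjects) != nrow(values))
        .stopf("%d subject rows for %d data rows", nrow(subjects), nrow(values))
    bad <- subjects$subject_id[!stats::complete.cases(
        subjects[, c("group", "age", "sex")])]
    if (length(bad))
        .stopf("missing covariates for subject(s): %s",
               paste(bad, collapse = ", "))
    dup <- subjects$subject_id[duplicated(subjects$subject_id)]
    if (length(dup))
        .stopf("duplicate subject id(s): %s", paste(unique(dup), collapse = ", "))
    if (anyNA(values))
        .stopf("CBF values contain missing entries")
    a <- t(values)
    dimnames(a) <- list(regions, subjects$subject_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(cbf = a),
        colData = S4Vectors::DataFrame(
            group = as.character(subjects$group),
            age = as.numeric(subjects$age),
            sex = as.numeric(subjects$sex),
            row.names = subjects$subject_id))
    new("RegionalCBF", se, residualized = residualized)
}

#' @describeIn RegionalCBF subjects x regions value matrix.
#' @export
setMethod("cbfMatrix", "RegionalCBF", function(x)
    t(SummarizedExperiment::assay(x, "cbf")))

#' @describeIn RegionalCBF subject covariate data.frame
#'   (subject_id, group, age, sex).
#' @export
setMethod("subjectInfo", "RegionalCBF", function(x) {
    cd <- SummarizedExperiment::colData(x)
    data.frame(subject_id = rownames(cd), group = cd$group, age = cd$age,
               sex = cd$sex, row.names = NULL,
               stringsAsFactors = FALSE)
})

#' @describeIn RegionalCBF region labels.
#' @export
setMethod("regionNames", "RegionalCBF", function(x) rownames(x))

#' @describeIn RegionalCBF whether covariates have been regressed out.
#' @export
setMethod("isResidualized", "RegionalCBF", function(x) x@residualized)

setMethod("show", "RegionalCBF", function(object) {
    cat(sprintf("RegionalCBF: %d regions x %d subjects%s\n",
                nrow(object), ncol(object),
                if (object@residualized) " (residualized)" else ""))
    g <- table(SummarizedExperiment::colData(object)$group)
    cat("  groups:", paste(sprintf("%s=%d", names(g), g), collapse = ", "),
        "\n")
})

#' Read and write regional CBF tables as TSV
#'
#' The on-disk layout has one row per subject and a header of
#' `subject_id, group, age, sex` followed by one column per region.
#'
#' @param x a [RegionalCBF-class] object.
#' @param path file path.
#' @return `readRegionalTSV` returns a [RegionalCBF-class];
#'   `writeRegionalTSV` returns `path` invisibly.
#' @export
writeRegionalTSV <- function(x, path) {
    stopifnot(is(x, "RegionalCBF"))
    df <- cbind(subjectInfo(x), as.data.frame(cbfMatrix(x)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeRegionalTSV
#' @export
readRegionalTSV <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("subject_id", "group", "age", "sex")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        .stopf("regional TSV lacks column(s): %s", paste(miss, collapse = ", "))
    regions <- setdiff(colnames(df), need)
    if (!length(regions)) .stopf("regional TSV has no region columns")
    RegionalCBF(as.matrix(df[, regions, drop = FALSE]),
                df[, need, drop = FALSE], regions = regions)
}

# Internal: subset a RegionalCBF to one group, preserving flags.
.subsetGroup <- function(x, group) {
    keep <- SummarizedExperiment::colData(x)$group == group
    if (!any(keep)) .stopf("no subjects in group '%s'", group)
    out <- x[, keep]
    out@residualized <- x@residualized
    out
}
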