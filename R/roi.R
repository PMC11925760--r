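#' Read a CBF volume from NIfTI
#'
#' The brain mask defaults to finite, strictly positive voxels — the weakest
#' sensible constraint for a perfusion map — unless an explicit mask file
#' (non-zero voxels) is supplied.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param maskPath optional NIfTI mask on the same grid.
#' @return a [CBFVolume-class].
#' @export
readCBFVolume <- function(path, maskPath = NULL) {
    if (!file.exists(path)) .stopf("CBF volume not found: %s", path)
    img <- RNifti::readNifti(path)
    vox <- array(as.numeric(img), dim(img))
    affine <- structure(as.matrix(RNifti::xform(img)), dim = c(4L, 4L))
    if (!is.null(maskPath)) {
        if (!file.exists(maskPath)) .stopf("mask not found: %s", maskPath)
        mimg <- RNifti::readNifti(maskPath)
        if (!identical(dim(mimg), dim(img)))
            .stopf("mask grid %s does not match volume grid %s",
                   paste(dim(mimg), collapse = "x"),
                   paste(dim(img), collapse = "x"))
        mask <- array(as.numeric(mimg) != 0, dim(img))
    } else {
        mask <- array(is.finite(vox) & vox > 0, dim(img))
    }
    if (!any(mask)) .stopf("empty brain mask for %s", path)
    new("CBFVolume", voxels = vox, affine = affine, mask = mask,
        normalized = FALSE)
}

#' Construct a CBF volume in memory
#'
#' @param voxels numeric 3-D array.
#' @param mask optional logical array; defaults to finite positive voxels.
#' @param affine optional 4x4 transform; defaults to identity.
#' @param normalized whether the volume is already global-mean normalized.
#' @return a [CBFVolume-class].
#' @export
cbfVolume <- function(voxels, mask = NULL, affine = diag(4),
                      normalized = FALSE) {
    voxels <- as.array(voxels)
    if (is.null(mask)) mask <- array(is.finite(voxels) & voxels > 0,
                                     dim(voxels))
    if (!any(mask)) .stopf("empty brain mask")
    new("CBFVolume", voxels = voxels, affine = affine,
        mask = array(as.logical(mask), dim(voxels)), normalized = normalized)
}

setMethod("show", "CBFVolume", function(object) {
    cat(sprintf("CBFVolume: %s grid, %d in-mask voxels%s\n",
                paste(dim(object@voxels), collapse = "x"),
                sum(object@mask),
                if (object@normalized) ", normalized" else ""))
})

#' Normalize a CBF volume by its whole-brain mean
#'
#' Divides every in-mask voxel by the in-mask mean, so the normalized
#' volume has in-mask mean exactly 1. Out-of-mask voxels are untouched.
#' Normalizing an already-normalized volume is an error: values must be
#' divided by the global mean exactly once.
#'
#' @param vol a [CBFVolume-class].
#' @return the normalized [CBFVolume-class].
#' @export
normalizeByGlobalMean <- function(vol) {
    stopifnot(is(vol, "CBFVolume"))
    if (vol@normalized)
        .stopf("volume is already normalized by its global mean")
    m <- mean(vol@voxels[vol@mask])
    if (!is.finite(m) || m <= 0)
        .stopf("in-mask mean is %s; cannot normalize", format(m))
    vox <- vol@voxels
    vox[vol@mask] <- vox[vol@mask] / m
    new("CBFVolume", voxels = vox, affine = vol@affine, mask = vol@mask,
        normalized = TRUE)
}

#' Read an integer-labeled atlas volume
#'
#' @param path NIfTI label volume (0 = background).
#' @param labelsPath optional TSV with columns `id`, `name`; defaults to
#'   `region_<id>` names.
#' @return an [AtlasLabelVolume-class].
#' @export
readAtlas <- function(path, labelsPath = NULL) {
    if (!file.exists(path)) .stopf("atlas not found: %s", path)
    img <- RNifti::readNifti(path)
    lab <- array(as.integer(round(as.numeric(img))), dim(img))
    if (is.null(labelsPath)) {
        ids <- sort(unique(lab[lab > 0]))
        rt <- data.frame(id = ids, name = sprintf("region_%03d", ids),
                         stringsAsFactors = FALSE)
    } else {
        rt <- read.delim(labelsPath, stringsAsFactors = FALSE)
        if (!all(c("id", "name") %in% colnames(rt)))
            .stopf("label table must have columns id and name")
    }
    new("AtlasLabelVolume", labels = lab, regionTable = rt)
}

#' @rdname readAtlas
#' @param labels integer 3-D array of region labels.
#' @param regionTable data.frame with columns `id`, `name`.
#' @export
atlasVolume <- function(labels, regionTable = NULL) {
    labels <- array(as.integer(labels), dim(as.array(labels)))
    if (is.null(regionTable)) {
        ids <- sort(unique(labels[labels > 0]))
        regionTable <- data.frame(id = ids, name = sprintf("region_%03d", ids),
                                  stringsAsFactors = FALSE)
    }
    new("AtlasLabelVolume", labels = labels, regionTable = regionTable)
}

setMethod("show", "AtlasLabelVolume", function(object) {
    cat(sprintf("AtlasLabelVolume: %s grid, %d regions\n",
                paste(dim(object@labels), collapse = "x"),
                nrow(object@regionTable)))
})

#' Extract per-region mean CBF from a volume
#'
#' For each atlas region, the mean over in-mask voxels carrying that label.
#' Regions with no in-mask voxel are an error by default (silent NaNs would
#' propagate into the covariance network); set `onEmpty = "nan"` to get NaN
#' with a warning instead.
#'
#' @param vol a [CBFVolume-class].
#' @param atlas an [AtlasLabelVolume-class] on the same grid.
#' @param onEmpty `"error"` or `"nan"`.
#' @return named numeric vector of regional means, in atlas label order.
#' @export
extractRegionalMeans <- function(vol, atlas, onEmpty = c("error", "nan")) {
    stopifnot(is(vol, "CBFVolume"), is(atlas, "AtlasLabelVolume"))
    onEmpty <- match.arg(onEmpty)
    if (!identical(dim(vol@voxels), dim(atlas@labels)))
        .stopf("volume grid %s does not match atlas grid %s",
               paste(dim(vol@voxels), collapse = "x"),
               paste(dim(atlas@labels), collapse = "x"))
    ids <- atlas@regionTable$id
    lab <- atlas@labels
    keep <- vol@mask & lab > 0
    sums <- rowsum(vol@voxels[keep], group = lab[keep])
    counts <- rowsum(rep(1, sum(keep)), group = lab[keep])
    out <- setNames(rep(NaN, length(ids)), atlas@regionTable$name)
    hit <- match(as.integer(rownames(sums)), ids)
    out[hit[!is.na(hit)]] <- (sums / counts)[!is.na(hit)]
    empty <- atlas@regionTable$name[is.nan(out)]
    if (length(empty)) {
        if (onEmpty == "error")
            .stopf("region(s) with no in-mask voxels: %s",
                   paste(empty, collapse = ", "))
        warning("region(s) with no in-mask voxels: ",
                paste(empty, collapse = ", "), call. = FALSE)
    }
    out
}

#' Assemble per-subject regional vectors into a RegionalCBF matrix
#'
#' @param vectors list of named numeric vectors (one per subject), all with
#'   the same region order.
#' @param subjects data.frame with columns `subject_id`, `group`, `age`,
#'   `sex`, one row per vector.
#' @return a [RegionalCBF-class] with rows ordered by `subject_id`.
#' @export
assembleRegionalCBF <- function(vectors, subjects) {
    if (length(vectors) != nrow(subjects))
        .stopf("%d vectors for %d subjects", length(vectors), nrow(subjects))
    lens <- lengths(vectors)
    if (length(unique(lens)) != 1L)
        .stopf("inconsistent region counts across subjects: %s",
               paste(unique(lens), collapse = ", "))
    ref <- names(vectors[[1]])
    for (k in seq_along(vectors))
        if (!is.null(ref) && !identical(names(vectors[[k]]), ref))
            .stopf("region order differs for subject %s",
                   subjects$subject_id[k])
    values <- do.call(rbind, vectors)
    colnames(values) <- ref
    ord <- order(subjects$subject_id)
    RegionalCBF(values[ord, , drop = FALSE],
                subjects[ord, , drop = FALSE], regions = ref)
}
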