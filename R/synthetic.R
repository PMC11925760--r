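#' Specify a synthetic two-group CBF cohort
#'
#' Defaults mirror a two-group perfusion study design: 44 vs 50 subjects,
#' 116 atlas regions, ages uniform on 35-75 years, sex balanced 0/1.
#' Regional values for each subject are
#' `meanCBF + z + noiseSd * e + ageEffect * age + sexEffect * sex`, with
#' `z` multivariate normal (unit variance, block-modular correlation) and
#' `e` standard normal, so the implied region-region correlation is the
#' block matrix shrunk by `1/(1 + noiseSd^2)`.
#'
#' @param nGroupA,nGroupB subjects per group.
#' @param nRegions number of regions (network nodes).
#' @param nModules number of contiguous correlation modules.
#' @param rhoWithinA,rhoWithinB within-module signal correlation per group.
#' @param rhoBetween between-module signal correlation.
#' @param noiseSd independent noise SD relative to unit signal SD.
#' @param ageEffect,sexEffect linear covariate slopes (length 1 or
#'   `nRegions`); units: CBF per year and CBF per sex category.
#' @param meanCBF baseline level (mL/100 g/min scale by default).
#' @param ageRange age sampling interval in years.
#' @param seed integer RNG seed.
#' @return a validated [CohortSpec-class].
#' @examples
#' cohortSpec(nGroupA = 10, nGroupB = 10, nRegions = 20, nModules = 4,
#'            seed = 1)
#' @export
cohortSpec <- function(nGroupA = 44, nGroupB = 50, nRegions = 116,
                       nModules = 8, rhoWithinA = 0.30, rhoWithinB = 0.30,
                       rhoBetween = 0.10, noiseSd = 0.5,
                       ageEffect = -0.05, sexEffect = 0.5,
                       meanCBF = 50, ageRange = c(35, 75), seed = 1L) {
    new("CohortSpec",
        nGroupA = as.integer(nGroupA), nGroupB = as.integer(nGroupB),
        nRegions = as.integer(nRegions), nModules = as.integer(nModules),
        rhoWithinA = rhoWithinA, rhoWithinB = rhoWithinB,
        rhoBetween = rhoBetween, noiseSd = noiseSd,
        ageEffect = as.numeric(ageEffect), sexEffect = as.numeric(sexEffect),
        meanCBF = meanCBF, ageRange = as.numeric(ageRange),
        seed = as.integer(seed))
}

#' Generate a synthetic cohort from a specification
#'
#' Subjects of each group are drawn independently from the group's
#' multivariate normal signal model; age and sex are sampled per subject and
#' added as linear effects, so downstream residualization can remove them
#' exactly. Output is deterministic given `spec@seed` (or the `seed`
#' override).
#'
#' @param spec a [CohortSpec-class].
#' @param seed optional override of `spec@seed`.
#' @return a [SyntheticCohort-class].
#' @examples
#' ch <- generateCohort(cohortSpec(nGroupA = 6, nGroupB = 6, nRegions = 10,
#'                                 nModules = 2, seed = 7))
#' cohortGroup(ch, "A")
#' @export
generateCohort <- function(spec, seed = NULL) {
    stopifnot(is(spec, "CohortSpec"))
    validObject(spec)
    seed <- as.integer(if (is.null(seed)) spec@seed else seed)
    sizes <- c(A = spec@nGroupA, B = spec@nGroupB)
    ageEff <- rep_len(spec@ageEffect, spec@nRegions)
    sexEff <- rep_len(spec@sexEffect, spec@nRegions)
    truth <- list()
    parts <- .withSeed(seed, lapply(names(sizes), function(grp) {
        n <- sizes[[grp]]
        rhoW <- if (grp == "A") spec@rhoWithinA else spec@rhoWithinB
        R <- .blockCorrelation(spec@nRegions, spec@nModules, rhoW,
                               spec@rhoBetween)
        z <- MASS::mvrnorm(n, mu = rep(0, spec@nRegions), Sigma = R)
        z <- matrix(z, nrow = n)                 # mvrnorm drops dim at n = 1
        age <- runif(n, spec@ageRange[1], spec@ageRange[2])
        sex <- rbinom(n, 1L, 0.5)
        noise <- matrix(rnorm(n * spec@nRegions, sd = spec@noiseSd), n)
        vals <- spec@meanCBF + z + noise +
            outer(age, ageEff) + outer(sex, sexEff)
        list(group = grp, vals = vals, age = age, sex = sex,
             truth = .noisyCorrelation(R, spec@noiseSd))
    }))
    values <- do.call(rbind, lapply(parts, `[[`, "vals"))
    subjects <- data.frame(
        subject_id = sprintf("sub%03d", seq_len(sum(sizes))),
        group = rep(names(sizes), sizes),
        age = unlist(lapply(parts, `[[`, "age")),
        sex = unlist(lapply(parts, `[[`, "sex")),
        stringsAsFactors = FALSE)
    regions <- sprintf("region_%03d", seq_len(spec@nRegions))
    truth <- setNames(lapply(parts, `[[`, "truth"), names(sizes))
    new("SyntheticCohort",
        data = RegionalCBF(values, subjects, regions),
        truth = truth, spec = spec, seed = seed)
}

#' @describeIn SyntheticCohort extract one group's data as a
#'   [RegionalCBF-class].
#' @param group `"A"` or `"B"`.
#' @export
setMethod("cohortGroup", "SyntheticCohort", function(x, group) {
    stopifnot(group %in% c("A", "B"))
    .subsetGroup(x@data, group)
})

#' @describeIn SyntheticCohort the generating (noise-shrunk) correlation
#'   matrices, a list named `A`, `B`.
#' @export
setMethod("truthMatrices", "SyntheticCohort", function(x) x@truth)

setMethod("show", "SyntheticCohort", function(object) {
    sp <- object@spec
    cat(sprintf(
        "SyntheticCohort: %d + %d subjects, %d regions (%d modules), seed %d\n",
        sp@nGroupA, sp@nGroupB, sp@nRegions, sp@nModules, object@seed))
    cat(sprintf("  rho within A/B = %.2f/%.2f, between = %.2f, noise SD = %.2f\n",
                sp@rhoWithinA, sp@rhoWithinB, sp@rhoBetween, sp@noiseSd))
})

#' Write toy NIfTI volumes realizing a synthetic cohort
#'
#' Lays the regions out as disjoint patches of `voxelsPerRegion` voxels on a
#' 3-D grid and writes, for every subject, a volume whose mean inside each
#' patch equals that subject's regional CBF value (exactly at `jitter = 0`;
#' with `jitter > 0`, independent Gaussian voxel noise of that SD is added).
#' A matching integer atlas volume, a label sidecar TSV, and a subject
#' manifest TSV are written alongside, so [runExtract()] can recover the
#' regional matrix.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @param gridShape integer length-3 grid dimensions.
#' @param voxelsPerRegion voxels per region patch (>= 8).
#' @param jitter within-region voxel noise SD.
#' @param seed RNG seed for the jitter.
#' @return invisibly, a list with `manifest` (data.frame with subject
#'   metadata and volume paths), `atlas` and `labels` file paths.
#' @export
generateToyVolumes <- function(cohort, dir, gridShape = c(12, 12, 12),
                               voxelsPerRegion = 8L, jitter = 0,
                               seed = cohort@seed) {
    stopifnot(is(cohort, "SyntheticCohort"))
    gridShape <- as.integer(gridShape)
    stopifnot(length(gridShape) == 3L)
    voxelsPerRegion <- as.integer(voxelsPerRegion)
    if (voxelsPerRegion < 8L) .stopf("need >= 8 voxels per region")
    R <- nrow(cohort@data)
    nvox <- prod(gridShape)
    if (nvox < R * voxelsPerRegion)
        .stopf("grid of %d voxels cannot host %d regions of %d voxels",
               nvox, R, voxelsPerRegion)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    lab <- integer(nvox)
    lab[seq_len(R * voxelsPerRegion)] <- rep(seq_len(R),
                                             each = voxelsPerRegion)
    lab <- array(lab, gridShape)
    atlasPath <- file.path(dir, "atlas.nii.gz")
    RNifti::writeNifti(lab, atlasPath, datatype = "int32")
    labelsPath <- file.path(dir, "atlas_labels.tsv")
    write.table(data.frame(id = seq_len(R), name = regionNames(cohort@data)),
                labelsPath, sep = "\t", quote = FALSE, row.names = FALSE)

    vals <- cbfMatrix(cohort@data)
    info <- subjectInfo(cohort@data)
    paths <- .withSeed(seed, vapply(seq_len(nrow(info)), function(s) {
        vox <- numeric(nvox)
        idx <- seq_len(R * voxelsPerRegion)
        vox[idx] <- rep(vals[s, ], each = voxelsPerRegion)
        if (jitter > 0) {
            noise <- rnorm(length(idx), sd = jitter)
            # keep patch means exact in expectation; noise is not demeaned so
            # recovered means carry O(jitter/sqrt(voxels)) sampling error
            vox[idx] <- vox[idx] + noise
        }
        p <- file.path(dir, paste0(info$subject_id[s], "_cbf.nii.gz"))
        RNifti::writeNifti(array(vox, gridShape), p, datatype = "double")
        p
    }, character(1)))
    manifest <- cbind(info, path = paths, stringsAsFactors = FALSE)
    manifestPath <- file.path(dir, "manifest.tsv")
    write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(list(manifest = manifest, manifestPath = manifestPath,
                   atlas = atlasPath, labels = labelsPath))
}
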