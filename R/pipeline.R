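# Configuration-driven pipeline entry points. A single YAML file drives the
# three stages; every output embeds the config hash and seed so a run can be
# reproduced from its own artifacts.

.configSchema <- list(
    top = c("seed", "output_dir", "simulate", "extract", "compare"),
    simulate = c("n_group_a", "n_group_b", "n_regions", "n_modules",
                 "rho_within_a", "rho_within_b", "rho_between", "noise_sd",
                 "age_effect", "sex_effect", "mean_cbf", "age_range",
                 "write_volumes", "grid_shape", "voxels_per_region",
                 "jitter"),
    extract = c("manifest", "atlas", "labels", "normalize", "mask"),
    compare = c("input", "group_a", "group_b", "covariates", "sparsity",
                "modes", "metrics", "level", "n_random", "n_perm", "rank",
                "alternative", "p_formula", "write_curves",
                "write_null"))

.checkKeys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
        .stopf("unknown config key(s) in %s: %s", where,
               paste(unknown, collapse = ", "))
}

#' Read and validate a pipeline run configuration
#'
#' The YAML file may contain `seed`, `output_dir` and the sections
#' `simulate`, `extract` and `compare`; unknown keys anywhere are rejected
#' before any computation runs.
#'
#' @param path YAML file, or a list already in config shape.
#' @return validated config list with a `hash` attribute (MD5 of the
#'   canonicalized YAML).
#' @export
readRunConfig <- function(path) {
    cfg <- if (is.character(path)) {
        if (!file.exists(path)) .stopf("config not found: %s", path)
        yaml::read_yaml(path)
    } else path
    if (!is.list(cfg)) .stopf("config must be a YAML mapping")
    .checkKeys(cfg, .configSchema$top, "top level")
    for (sec in c("simulate", "extract", "compare"))
        if (!is.null(cfg[[sec]]))
            .checkKeys(cfg[[sec]], .configSchema[[sec]], sec)
    if (is.null(cfg$seed)) cfg$seed <- 1L
    cfg$seed <- as.integer(cfg$seed)
    if (is.null(cfg$output_dir)) cfg$output_dir <- "."
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(cfg[order(names(cfg))], tmp)
    attr(cfg, "hash") <- unname(tools::md5sum(tmp))
    cfg
}

.runMeta <- function(cfg) {
    list(config_hash = attr(cfg, "hash"), seed = cfg$seed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Simulate a synthetic cohort from a config
#'
#' Wraps [generateCohort()] (and optionally [generateToyVolumes()]): writes
#' `cohort.tsv` (one row per subject: subject_id, group, age, sex, then the
#' regions) plus a `simulate_meta.json` with the config hash and seed.
#'
#' @param config path to a YAML config or a config list (see
#'   [readRunConfig()]).
#' @return invisibly, list with `cohort` ([SyntheticCohort-class]) and
#'   output paths.
#' @export
runSimulate <- function(config) {
    cfg <- readRunConfig(config)
    sc <- cfg$simulate
    args <- list(
        nGroupA = sc$n_group_a %||% 44, nGroupB = sc$n_group_b %||% 50,
        nRegions = sc$n_regions %||% 116, nModules = sc$n_modules %||% 8,
        rhoWithinA = sc$rho_within_a %||% 0.30,
        rhoWithinB = sc$rho_within_b %||% 0.30,
        rhoBetween = sc$rho_between %||% 0.10,
        noiseSd = sc$noise_sd %||% 0.5,
        ageEffect = sc$age_effect %||% -0.05,
        sexEffect = sc$sex_effect %||% 0.5,
        meanCBF = sc$mean_cbf %||% 50,
        ageRange = unlist(sc$age_range %||% c(35, 75)),
        seed = cfg$seed)
    spec <- do.call(cohortSpec, args)
    cohort <- generateCohort(spec)
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    cohortPath <- file.path(cfg$output_dir, "cohort.tsv")
    writeRegionalTSV(cohort@data, cohortPath)
    out <- list(cohort = cohort, cohortPath = cohortPath)
    if (isTRUE(sc$write_volumes)) {
        volDir <- file.path(cfg$output_dir, "volumes")
        out$volumes <- generateToyVolumes(
            cohort, volDir,
            gridShape = unlist(sc$grid_shape %||% c(12, 12, 12)),
            voxelsPerRegion = sc$voxels_per_region %||% 8L,
            jitter = sc$jitter %||% 0, seed = cfg$seed)
    }
    meta <- .runMeta(cfg)
    meta$n_subjects <- ncol(cohort@data)
    meta$n_regions <- nrow(cohort@data)
    jsonlite::write_json(meta, file.path(cfg$output_dir,
                                         "simulate_meta.json"),
                         auto_unbox = TRUE, digits = NA)
    message(sprintf("[simulate] wrote %d subjects x %d regions to %s",
                    meta$n_subjects, meta$n_regions, cohortPath))
    invisible(out)
}

#' Extract a regional CBF matrix from NIfTI volumes listed in a manifest
#'
#' The manifest TSV must have columns `subject_id, group, age, sex, path`.
#' Each volume is read, optionally normalized by its whole-brain mean, and
#' reduced to atlas-region means; rows are ordered by `subject_id`, so the
#' manifest order does not matter.
#'
#' @param config path to a YAML config or a config list; the `extract`
#'   section must name `manifest` and `atlas` (optionally `labels`,
#'   `normalize`, `mask`).
#' @return invisibly, list with the [RegionalCBF-class] and the output path.
#' @export
runExtract <- function(config) {
    cfg <- readRunConfig(config)
    ex <- cfg$extract
    if (is.null(ex$manifest) || is.null(ex$atlas))
        .stopf("extract config must name 'manifest' and 'atlas'")
    man <- read.delim(ex$manifest, stringsAsFactors = FALSE)
    need <- c("subject_id", "group", "age", "sex", "path")
    miss <- setdiff(need, colnames(man))
    if (length(miss))
        .stopf("manifest lacks column(s): %s", paste(miss, collapse = ", "))
    atlas <- readAtlas(ex$atlas, ex$labels)
    normalize <- isTRUE(ex$normalize)
    vecs <- lapply(seq_len(nrow(man)), function(s) {
        p <- man$path[s]
        if (!file.exists(p))
            .stopf("volume for subject %s not found: %s",
                   man$subject_id[s], p)
        vol <- tryCatch(readCBFVolume(p, maskPath = ex$mask),
                        error = function(e)
                            .stopf("subject %s: %s", man$subject_id[s],
                                   conditionMessage(e)))
        if (normalize) vol <- normalizeByGlobalMean(vol)
        extractRegionalMeans(vol, atlas)
    })
    mat <- assembleRegionalCBF(vecs, man[, setdiff(need, "path")])
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    outPath <- file.path(cfg$output_dir, "regional.tsv")
    writeRegionalTSV(mat, outPath)
    meta <- .runMeta(cfg)
    meta$n_subjects <- ncol(mat)
    meta$n_regions <- nrow(mat)
    meta$normalized <- normalize
    jsonlite::write_json(meta, file.path(cfg$output_dir,
                                         "extract_meta.json"),
                         auto_unbox = TRUE, digits = NA)
    message(sprintf("[extract] wrote %d subjects x %d regions to %s",
                    meta$n_subjects, meta$n_regions, outPath))
    invisible(list(data = mat, path = outPath))
}

#' Run the full group comparison from a config
#'
#' Reads the regional TSV, splits it into the two groups, and runs
#' residualization, covariance-network construction, sparsity thresholding,
#' global metrics and the relabeling permutation test for the requested
#' metrics and modes. Writes `compare_report.json` (observed differences,
#' p-values, settings, config hash, seed), optional per-group metric-curve
#' TSVs, and optional null-distribution TSVs.
#'
#' @param config path to a YAML config or a config list; `compare$input`
#'   names the regional TSV (defaults to `cohort.tsv` under `output_dir`).
#' @return invisibly, the [compareAll()] result list.
#' @export
runCompare <- function(config) {
    cfg <- readRunConfig(config)
    cp <- cfg$compare
    input <- cp$input %||% file.path(cfg$output_dir, "cohort.tsv")
    if (!file.exists(input)) .stopf("regional input not found: %s", input)
    tab <- readRegionalTSV(input)
    groups <- sort(unique(subjectInfo(tab)$group))
    gA <- cp$group_a %||% groups[1]
    gB <- cp$group_b %||% groups[2]
    if (length(groups) < 2L || !all(c(gA, gB) %in% groups))
        .stopf("input must contain the two groups '%s' and '%s'", gA, gB)
    dataA <- .subsetGroup(tab, gA)
    dataB <- .subsetGroup(tab, gB)
    sp <- cp$sparsity %||% list()
    schedule <- sparsitySchedule(sp$min %||% 0.09, sp$max %||% 0.30,
                                 sp$step %||% 0.01)
    modes <- unlist(cp$modes %||% c("weighted", "binary"))
    metrics <- unlist(cp$metrics %||% .metricChoices)
    nRandom <- cp$n_random %||% 100
    nPerm <- cp$n_perm %||% 1000
    covariates <- unlist(cp$covariates %||% c("age", "sex"))
    message(sprintf(
        "[compare] %s (n=%d) vs %s (n=%d); %d metrics x %d modes, %d permutations",
        gA, ncol(dataA), gB, ncol(dataB), length(metrics), length(modes),
        nPerm))
    t0 <- Sys.time()
    res <- compareAll(dataA, dataB, metrics = metrics, modes = modes,
                      level = cp$level %||% "auc", schedule = schedule,
                      nPerm = nPerm, seed = cfg$seed, nRandom = nRandom,
                      covariates = covariates,
                      rank = cp$rank %||% "absolute",
                      alternative = cp$alternative %||% "two.sided",
                      pFormula = cp$p_formula %||% "count")
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    if (isTRUE(cp$write_curves)) {
        curveSeeds <- .deriveSeeds(cfg$seed, 2L * length(modes))
        k <- 0L
        for (mode in modes) for (grp in c(gA, gB)) {
            k <- k + 1L
            net <- correlationNetwork(
                residualizeCBF(if (grp == gA) dataA else dataB, covariates))
            crv <- metricCurve(net, schedule, mode = mode,
                               nRandom = nRandom, seed = curveSeeds[k])
            writeMetricsTSV(crv, file.path(
                cfg$output_dir,
                sprintf("metrics_%s_%s.tsv", grp, mode)), group = grp)
        }
    }
    if (isTRUE(cp$write_null)) {
        for (nm in names(res$results)) {
            nd <- nullDistribution(res$results[[nm]])
            write.table(nd, file.path(cfg$output_dir,
                                      sprintf("null_%s.tsv", nm)),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        }
    }
    report <- .runMeta(cfg)
    report$groups <- list(a = gA, b = gB,
                          n_a = ncol(dataA), n_b = ncol(dataB))
    report$settings <- list(schedule = schedule, modes = modes,
                            metrics = metrics, n_random = nRandom,
                            n_perm = nPerm, covariates = covariates)
    report$results <- lapply(res$results, function(r) list(
        metric = r@metric, mode = r@mode, level = r@level,
        observed = r@observed, p_value = r@pValue, n_perm = r@nPerm))
    jsonlite::write_json(report,
                         file.path(cfg$output_dir, "compare_report.json"),
                         auto_unbox = TRUE, digits = NA)
    message(sprintf("[compare] done in %.1f s; report in %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    file.path(cfg$output_dir, "compare_report.json")))
    invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
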