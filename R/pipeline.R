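#' Direct age standardization within a five-year group
#'
#' Weights single-age (or other stratum) rates by a standard
#' population's age distribution: rate = sum(w_a r_a) with the weights
#' normalized to sum to 1 over the group's strata, and
#' SE^2 = sum(w_a^2 SE_a^2), the standard direct-method variance. When
#' per-stratum SEs are not supplied they are derived as r_a / sqrt(n_a)
#' from the case counts.
#'
#' @param rates numeric stratum rates.
#' @param weights non-negative standard-population weights (normalized
#'   internally).
#' @param se per-stratum standard errors; derived from `counts` when
#'   `NULL`.
#' @param counts per-stratum case counts (used only when `se` is
#'   `NULL`).
#' @return Named numeric `c(rate = , se = )`.
#' @examples
#' ageStandardize(c(10, 20), weights = c(0.25, 0.75), se = c(2, 4))
#' @export
ageStandardize <- function(rates, weights, se = NULL, counts = NULL) {
    if (!length(rates)) stop("empty age group", call. = FALSE)
    stopifnot(length(weights) == length(rates))
    if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
    if (sum(weights) == 0) stop("all weights are zero", call. = FALSE)
    w <- weights / sum(weights)
    if (is.null(se)) {
        if (is.null(counts))
            stop("supply either per-stratum SEs or case counts", call. = FALSE)
        se <- rates / sqrt(counts)
    }
    c(rate = sum(w * rates), se = sqrt(sum(w^2 * se^2)))
}

#' Configuration for an end-to-end run
#'
#' Bundles and validates the choices [runPipeline()] needs. The
#' defaults mirror the SEER lung-cancer setup: strict case-count
#' threshold 15, usable ages from the grid's own layout, anchors at the
#' last period and cohort 8, outlier flagging at |z| > 2 against the
#' weighted mean.
#'
#' @param input path to a long-format incidence CSV (see
#'   [readIncidenceGrids()]) holding every category.
#' @param reference integer code of the reference category.
#' @param anchorPeriod,anchorCohort anchors (NULL = defaults of
#'   [estimateEffects()]).
#' @param minCount,usableFrom cell filters (see [applyFilters()];
#'   `usableFrom = NULL` uses the age layout's own value).
#' @param outlierMode,zThreshold outlier rule (see [flagOutliers()]).
#' @param outDir output directory, created on success.
#' @param seed integer seed recorded in the run log.
#' @param ages,periods layouts for reading the input.
#' @return A validated list of class `"RunConfig"`.
#' @export
runConfig <- function(input, reference = 0L, anchorPeriod = NULL,
                      anchorCohort = NULL, minCount = 15L, usableFrom = NULL,
                      outlierMode = "mean", zThreshold = 2, outDir = tempdir(),
                      seed = 1L, ages = standardAgeGrid(),
                      periods = standardPeriodGrid()) {
    stopifnot(zThreshold > 0, minCount >= 0)
    cfg <- list(input = input, reference = as.integer(reference),
                anchorPeriod = anchorPeriod, anchorCohort = anchorCohort,
                minCount = as.integer(minCount), usableFrom = usableFrom,
                outlierMode = match.arg(outlierMode, c("mean", "trend")),
                zThreshold = zThreshold, outDir = outDir,
                seed = as.integer(seed), ages = ages, periods = periods)
    class(cfg) <- "RunConfig"
    cfg
}

#' Run the full estimation pipeline
#'
#' Reads the incidence grids, applies the cell filters, estimates (per
#' category) the period/cohort coefficients, corrects the rates,
#' estimates the hazard curves, and compares every non-reference
#' category with the reference: relative-hazard series with outlier
#' flags, averaged relative hazard with SE, slopes with and without
#' flagged points, and the adjusted curve. All results are computed
#' first and written only on success (no partial outputs): per-category
#' effects and hazard CSVs, per-comparison series CSVs, a
#' `summary.json`, and a `run.log` recording the filters, dropped
#' cells, flagged outliers and package version.
#'
#' @param config a `"RunConfig"` from [runConfig()].
#' @return Invisibly, a list with components `grids`, `effects`,
#'   `curves`, `comparisons`, `summary`.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    set.seed(config$seed)
    grids <- readIncidenceGrids(config$input, ages = config$ages,
                                periods = config$periods)
    if (!as.character(config$reference) %in% names(grids))
        stop(sprintf("reference category %d not among inputs (%s)",
                     config$reference, paste(names(grids), collapse = ", ")),
             call. = FALSE)
    usableFrom <- if (is.null(config$usableFrom)) config$ages@usableFrom
                  else config$usableFrom
    grids <- lapply(grids, applyFilters, minCount = config$minCount,
                    usableFrom = usableFrom)
    if (all(vapply(grids, function(g) all(is.na(rates(g))), logical(1L))))
        stop("no usable cells after filtering", call. = FALSE)
    effects <- lapply(grids, function(g) {
        ap <- if (is.null(config$anchorPeriod)) periodGrid(g)@mPeriods
              else config$anchorPeriod
        if (is.null(config$anchorCohort)) estimateEffects(g, anchorPeriod = ap)
        else estimateEffects(g, anchorPeriod = ap,
                             anchorCohort = config$anchorCohort)
    })
    curves <- mapply(function(g, e) estimateHazard(correctRates(g, e)),
                     grids, effects, SIMPLIFY = FALSE)
    refNm <- as.character(config$reference)
    comparisons <- compareHazards(curves, reference = refNm,
                                  mode = config$outlierMode,
                                  zThreshold = config$zThreshold)
    comparisons <- lapply(comparisons, function(cmp) {
        cmp$adjusted <- adjustCurve(curves[[as.character(cmp$series@category)]],
                                    cmp$averaged)
        cmp
    })
    summary <- list(
        schema_version = "1.0",
        package_version = as.character(utils::packageVersion("llapc")),
        reference = config$reference, seed = config$seed,
        filters = list(min_count = config$minCount, usable_from = usableFrom),
        outlier_rule = list(mode = config$outlierMode,
                            z_threshold = config$zThreshold),
        averaged_relative_hazards = lapply(comparisons, function(cmp) list(
            category = cmp$series@category,
            R = cmp$averaged@R, se = cmp$averaged@se,
            excluded_ages = cmp$averaged@excluded,
            slope_all = unname(cmp$slopeAll[["slope"]]),
            slope_all_se = unname(cmp$slopeAll[["se"]]),
            slope_kept = unname(cmp$slopeKept[["slope"]]),
            slope_kept_se = unname(cmp$slopeKept[["se"]]))))
    # all computed; write outputs
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(effects))
        writeEffects(effects[[nm]], file.path(config$outDir,
                                              sprintf("effects_c%s.csv", nm)))
    for (nm in names(curves))
        writeHazardCurve(curves[[nm]], file.path(config$outDir,
                                                 sprintf("hazard_c%s.csv", nm)))
    for (nm in names(comparisons)) {
        df <- comparisons[[nm]]$series@series
        for (col in c("r", "se", "ci_low", "ci_high"))
            df[[col]] <- fmtNum(df[[col]])
        utils::write.csv(df, file.path(config$outDir,
                                       sprintf("relhazard_c%s.csv", nm)),
                         row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(summary,
                         file.path(config$outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    log <- c(sprintf("llapc %s", summary$package_version),
             sprintf("seed: %d", config$seed),
             sprintf("filters: count > %d, ages from group %d",
                     config$minCount, usableFrom),
             vapply(names(grids), function(nm) sprintf(
                 "category %s: %d cells dropped by filters, %d usable",
                 nm, metadata(grids[[nm]])$filters$nDropped,
                 sum(!is.na(rates(grids[[nm]])))), character(1L)),
             sprintf("outlier rule: |z| > %g against weighted %s fit",
                     config$zThreshold, config$outlierMode),
             vapply(names(comparisons), function(nm) sprintf(
                 "category %s vs %s: R = %.4f +- %.4f, excluded ages [%s]",
                 nm, refNm, comparisons[[nm]]$averaged@R,
                 comparisons[[nm]]$averaged@se,
                 paste(comparisons[[nm]]$averaged@excluded, collapse = ", ")),
                 character(1L)))
    writeLines(log, file.path(config$outDir, "run.log"))
    invisible(list(grids = grids, effects = effects, curves = curves,
                   comparisons = comparisons, summary = summary))
}
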