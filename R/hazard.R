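#' Correct observed rates for period and cohort effects
#'
#' Divides each present cell by the product of its period and cohort
#' coefficients, I* = I / (v_j u_l), and propagates the standard error
#' to first order:
#' SE^2(I*) = (1/(v u))^2 SE_I^2 + (I/(v^2 u))^2 SE_v^2 +
#' (I/(v u^2))^2 SE_u^2. Cells whose cohort coefficient is absent (a
#' cohort unreachable from the anchor) become absent; their number is
#' recorded in the result's metadata. The coefficients are typically
#' estimated from the same grid being corrected; the correlation this
#' induces between cells is ignored, a deliberate first-order
#' approximation (see the methods vignette).
#'
#' @param grid a filtered \linkS4class{IncidenceGrid}.
#' @param eff an \linkS4class{EffectEstimates} with matching dimensions.
#' @return A \linkS4class{CorrectedGrid}.
#' @export
correctRates <- function(grid, eff) {
    stopifnot(is(grid, "IncidenceGrid"), is(eff, "EffectEstimates"))
    layout <- cohortLayout(grid)
    if (nrow(eff@period) != periodGrid(grid)@mPeriods)
        stop("period coefficient count disagrees with the grid", call. = FALSE)
    if (nrow(eff@cohort) != layout@kCohorts)
        stop("cohort coefficient count disagrees with the grid", call. = FALSE)
    bad <- c(eff@period$value, eff@cohort$value)
    if (any(!is.na(bad) & bad <= 0))
        stop("effect coefficients must be strictly positive", call. = FALSE)
    rate <- assay(grid, "rate"); se <- assay(grid, "se")
    n <- nrow(rate); m <- ncol(rate)
    L <- outer(-seq_len(n), seq_len(m), "+") + layout@offset
    inRange <- L >= 1L & L <= layout@kCohorts
    Lsafe <- ifelse(inRange, L, 1L)
    u <- ifelse(inRange, eff@cohort$value[Lsafe], NA_real_)
    uSE <- ifelse(inRange, eff@cohort$se[Lsafe], NA_real_)
    v <- matrix(eff@period$value, n, m, byrow = TRUE)
    vSE <- matrix(eff@period$se, n, m, byrow = TRUE)
    value <- rate / (v * u)
    sev <- sqrt((1 / (v * u))^2 * se^2 +
                (rate / (v^2 * u))^2 * vSE^2 +
                (rate / (v * u^2))^2 * uSE^2)
    dropped <- sum(!is.na(rate) & is.na(value))
    sev[is.na(value)] <- NA_real_
    dimnames(value) <- dimnames(sev) <- dimnames(rate)
    out <- SummarizedExperiment(
        assays = list(value = value, se = sev),
        rowData = rowData(grid), colData = colData(grid),
        metadata = c(metadata(grid),
                     list(anchorPeriod = eff@anchorPeriod,
                          anchorCohort = eff@anchorCohort,
                          effectProvenance = eff@provenance,
                          nDroppedCoef = dropped)))
    new("CorrectedGrid", out)
}

#' Estimate the age-specific hazard function
#'
#' For each age group, the hazard h*(t_i) is the inverse-variance
#' weighted mean of the corrected rates across periods, with weights
#' w = 1/SE^2, and SE(h*) = (sum of weights)^(-1/2). Age groups with no
#' present cells are absent from the curve. A present cell with SE 0
#' alongside cells with positive SE is rejected (it would take infinite
#' weight); set `seFloor` to impose a minimum SE instead. When every
#' cell of a row has SE 0 the data are exact and the common value is
#' returned with SE 0.
#'
#' @param corr a \linkS4class{CorrectedGrid}.
#' @param seFloor optional minimum SE applied to all cells before
#'   weighting.
#' @return A \linkS4class{HazardCurve}.
#' @examples
#' # two corrected cells (10 +- 1, 20 +- 2) pool to 12 +- 0.894
#' @export
estimateHazard <- function(corr, seFloor = NULL) {
    stopifnot(is(corr, "CorrectedGrid"))
    value <- assay(corr, "value"); se <- assay(corr, "se")
    if (!is.null(seFloor)) se[!is.na(se)] <- pmax(se[!is.na(se)], seFloor)
    md <- metadata(corr)
    ages <- md$ages
    rows <- lapply(seq_len(nrow(value)), function(i) {
        cells <- which(!is.na(value[i, ]))
        if (!length(cells)) return(NULL)
        p <- ivPool(value[i, cells], se[i, cells],
                    context = sprintf("hazard at age group %d", i))
        data.frame(age_index = i, age_midpoint = ages@midpoints[i],
                   hazard = p$value, se = p$se, n_cells = p$n)
    })
    est <- do.call(rbind, rows)
    if (is.null(est)) stop("no usable cells: the corrected grid is empty",
                           call. = FALSE)
    rownames(est) <- NULL
    new("HazardCurve", estimates = est,
        category = md$category, label = md$label,
        anchorPeriod = md$anchorPeriod, anchorCohort = md$anchorCohort)
}

#' Construct a hazard curve from per-age estimates
#'
#' Used for externally supplied curves (published estimates, fixtures);
#' curves produced by the pipeline come from [estimateHazard()].
#'
#' @param age_index,age_midpoint,hazard,se per-age vectors.
#' @param n_cells contributing periods per age (NA when unknown).
#' @param category integer category code.
#' @param label free-text label.
#' @param anchorPeriod,anchorCohort the anchors the estimates are tied to.
#' @return A \linkS4class{HazardCurve}.
#' @export
HazardCurve <- function(age_index, age_midpoint, hazard, se,
                        n_cells = NA_integer_, category = 0L, label = "",
                        anchorPeriod = NA_integer_, anchorCohort = NA_integer_) {
    est <- data.frame(age_index = as.integer(age_index),
                      age_midpoint = as.numeric(age_midpoint),
                      hazard = as.numeric(hazard), se = as.numeric(se),
                      n_cells = as.integer(n_cells))
    new("HazardCurve", estimates = est, category = as.integer(category),
        label = as.character(label), anchorPeriod = as.integer(anchorPeriod),
        anchorCohort = as.integer(anchorCohort))
}

#' Read and write hazard curves as CSV
#'
#' Columns: `age_index`, `age_midpoint`, `hazard`, `se`, `n_cells`;
#' category, label and anchors are carried in commented header lines so
#' a write/read round trip preserves the full object.
#'
#' @param curve a \linkS4class{HazardCurve}.
#' @param path CSV file path.
#' @return `readHazardCurve()` a \linkS4class{HazardCurve};
#'   `writeHazardCurve()` `path`, invisibly.
#' @export
writeHazardCurve <- function(curve, path) {
    stopifnot(is(curve, "HazardCurve"))
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c(sprintf("# category=%d", curve@category),
                 sprintf("# label=%s", curve@label),
                 sprintf("# anchor_period=%d", curve@anchorPeriod),
                 sprintf("# anchor_cohort=%d", curve@anchorCohort)), con)
    df <- curve@estimates
    df$age_midpoint <- fmtNum(df$age_midpoint)
    df$hazard <- fmtNum(df$hazard); df$se <- fmtNum(df$se)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeHazardCurve
#' @export
readHazardCurve <- function(path) {
    hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
    meta <- c(category = NA, label = "", anchor_period = NA, anchor_cohort = NA)
    for (line in hdr) {
        kv <- sub("^#\\s*", "", line)
        key <- sub("=.*$", "", kv)
        if (key %in% names(meta)) meta[key] <- sub("^[^=]*=", "", kv)
    }
    df <- utils::read.csv(path, comment.char = "#")
    toInt <- function(x) suppressWarnings(as.integer(x))
    HazardCurve(df$age_index, df$age_midpoint, df$hazard, df$se, df$n_cells,
                category = toInt(meta[["category"]]),
                label = meta[["label"]],
                anchorPeriod = toInt(meta[["anchor_period"]]),
                anchorCohort = toInt(meta[["anchor_cohort"]]))
}
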