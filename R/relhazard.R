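#' Age-specific relative hazards of two curves
#'
#' Ratios r(t_i) = h_c(t_i) / h_0(t_i) over the common age support, with
#' first-order propagated SEs, SE(r) = r sqrt((SE_c/h_c)^2 +
#' (SE_0/h_0)^2), and 95% confidence limits r -/+ 1.96 SE. The two
#' curves are hazards of different populations, so their errors are
#' treated as independent. Because effect coefficients are identified
#' only up to the anchors, curves are comparable only under identical
#' anchors; a mismatch is refused.
#'
#' @param numerator,reference \linkS4class{HazardCurve} objects sharing
#'   anchors.
#' @return A \linkS4class{RelativeHazardSeries} with all outlier flags
#'   `FALSE`.
#' @export
ratioSeries <- function(numerator, reference) {
    stopifnot(is(numerator, "HazardCurve"), is(reference, "HazardCurve"))
    if (!identical(anchors(numerator), anchors(reference)))
        stop(sprintf(
            "anchor mismatch: numerator (period %s, cohort %s) vs reference (period %s, cohort %s)",
            numerator@anchorPeriod, numerator@anchorCohort,
            reference@anchorPeriod, reference@anchorCohort), call. = FALSE)
    a <- numerator@estimates; b <- reference@estimates
    common <- intersect(a$age_index, b$age_index)
    if (!length(common))
        stop("the two curves share no age groups", call. = FALSE)
    a <- a[match(common, a$age_index), ]; b <- b[match(common, b$age_index), ]
    r <- a$hazard / b$hazard
    se <- ratioSE(a$hazard, a$se, b$hazard, b$se)
    df <- data.frame(age_index = common, age_midpoint = a$age_midpoint,
                     r = r, se = se, ci_low = r - 1.96 * se,
                     ci_high = r + 1.96 * se, outlier = FALSE)
    rownames(df) <- NULL
    new("RelativeHazardSeries", series = df,
        category = numerator@category, refCategory = reference@category,
        anchorPeriod = numerator@anchorPeriod,
        anchorCohort = numerator@anchorCohort)
}

#' Flag outlying ages in a relative-hazard series
#'
#' Fits either the inverse-variance weighted mean (`mode = "mean"`) or a
#' weighted least-squares line against age midpoint (`mode = "trend"`)
#' and flags every point whose standardized residual
#' |r_i - fit_i| / SE(r_i) exceeds `zThreshold`. By default a single
#' pass over all points; with `iterate = TRUE` the fit is recomputed on
#' the unflagged points until the flag set stabilises.
#'
#' @param series a \linkS4class{RelativeHazardSeries} with at least 3
#'   points.
#' @param mode fit against which residuals are standardized.
#' @param zThreshold flagging threshold on |z| (default 2).
#' @param iterate refit on unflagged points to a fixpoint.
#' @return The series with its `outlier` column updated.
#' @export
flagOutliers <- function(series, mode = c("mean", "trend"), zThreshold = 2,
                         iterate = FALSE) {
    stopifnot(is(series, "RelativeHazardSeries"))
    mode <- match.arg(mode)
    df <- series@series
    if (nrow(df) < 3L) stop("need at least 3 points", call. = FALSE)
    if (any(df$se == 0) && !all(df$se == 0))
        stop("mix of zero and positive SEs; supply an SE floor", call. = FALSE)
    # exact series (all SEs zero) get equal weights; a nonzero residual
    # against an exact value is then an outlier by definition
    exact <- all(df$se == 0)
    w <- if (exact) rep(1, nrow(df)) else 1 / df$se^2
    zscore <- function(resid) ifelse(resid == 0, 0, abs(resid) / df$se)
    flag <- rep(FALSE, nrow(df))
    repeat {
        keep <- !flag
        if (sum(keep) < 3L)
            stop("fewer than 3 unflagged points remain", call. = FALSE)
        fitv <- if (mode == "mean") {
            rep(sum((w * df$r)[keep]) / sum(w[keep]), nrow(df))
        } else {
            ln <- wlsLine(df$age_midpoint[keep], df$r[keep], w[keep])
            ln$intercept + ln$slope * df$age_midpoint
        }
        newflag <- zscore(df$r - fitv) > zThreshold
        if (!iterate || identical(newflag, flag)) { flag <- newflag; break }
        flag <- newflag
    }
    if (sum(!flag) < 3L)
        stop("fewer than 3 unflagged points remain", call. = FALSE)
    df$outlier <- flag
    series@series <- df
    series
}

#' Averaged relative hazard
#'
#' The inverse-variance weighted mean R of the unflagged relative
#' hazards, with SE (sum of weights)^(-1/2); flagged points are excluded
#' from both the mean and the weights. The all-points weighted slope
#' against age is attached as a constancy diagnostic.
#'
#' @param series a \linkS4class{RelativeHazardSeries} (typically after
#'   [flagOutliers()]).
#' @return An \linkS4class{AveragedRelativeHazard}.
#' @export
averagedRelativeHazard <- function(series) {
    stopifnot(is(series, "RelativeHazardSeries"))
    df <- series@series
    keep <- !df$outlier
    if (!any(keep)) stop("no unflagged points", call. = FALSE)
    p <- ivPool(df$r[keep], df$se[keep], context = "averaged relative hazard")
    w <- if (all(df$se[keep] == 0)) rep(NA_real_, sum(keep))
         else 1 / df$se[keep]^2
    names(w) <- df$age_index[keep]
    sl <- if (nrow(df) >= 3L && length(unique(df$age_midpoint)) >= 2L)
        weightedSlope(series, useFlagged = TRUE)
    else c(slope = NA_real_, se = NA_real_)
    new("AveragedRelativeHazard", R = p$value, se = p$se,
        excluded = as.integer(df$age_index[!keep]),
        slope = unname(sl[[1L]]), slopeSE = unname(sl[[2L]]), weights = w)
}

#' Weighted least-squares slope of a relative-hazard series
#'
#' Fits r = a + b t by weighted least squares with weights 1/SE^2 and
#' returns the slope b with its (residual-scaled) standard error. Near-
#' zero slopes indicate that the relative hazard is constant in age,
#' i.e. that the exposure scales the whole hazard curve uniformly.
#'
#' @param series a \linkS4class{RelativeHazardSeries}.
#' @param useFlagged include points flagged as outliers (default TRUE,
#'   the all-points fit).
#' @return Named numeric `c(slope = , se = )`.
#' @export
weightedSlope <- function(series, useFlagged = TRUE) {
    stopifnot(is(series, "RelativeHazardSeries"))
    df <- series@series
    if (!useFlagged) df <- df[!df$outlier, ]
    if (nrow(df) < 3L) stop("need at least 3 points", call. = FALSE)
    w <- if (all(df$se == 0)) rep(1, nrow(df)) else 1 / df$se^2
    ln <- wlsLine(df$age_midpoint, df$r, w)
    c(slope = ln$slope, se = ln$slopeSE)
}

#' Rescale a hazard curve by an averaged relative hazard
#'
#' Divides the hazard values and their SEs by R, superimposing the curve
#' on the reference category's scale. The uncertainty of R itself is
#' not propagated — this is a display adjustment, matching how adjusted
#' curves are conventionally overlaid on the reference.
#'
#' @param curve a \linkS4class{HazardCurve}.
#' @param R an \linkS4class{AveragedRelativeHazard} or a positive
#'   number.
#' @return The rescaled \linkS4class{HazardCurve}.
#' @export
adjustCurve <- function(curve, R) {
    stopifnot(is(curve, "HazardCurve"))
    if (is(R, "AveragedRelativeHazard")) R <- R@R
    stopifnot(is.numeric(R), length(R) == 1L, R > 0)
    curve@estimates$hazard <- curve@estimates$hazard / R
    curve@estimates$se <- curve@estimates$se / R
    curve
}

#' Compare a set of hazard curves against a reference
#'
#' Convenience wrapper running [ratioSeries()], [flagOutliers()],
#' [averagedRelativeHazard()] and [weightedSlope()] (with and without
#' flagged points) for each non-reference curve.
#'
#' @param curves named list of \linkS4class{HazardCurve} objects.
#' @param reference name or index of the reference curve.
#' @param mode,zThreshold,iterate passed to [flagOutliers()].
#' @return Named list (one element per non-reference curve) of lists
#'   with components `series`, `averaged`, `slopeAll`, `slopeKept`.
#' @export
compareHazards <- function(curves, reference = 1L, mode = "mean",
                           zThreshold = 2, iterate = FALSE) {
    ref <- curves[[reference]]
    others <- if (is.character(reference)) setdiff(names(curves), reference)
              else setdiff(seq_along(curves), reference)
    out <- lapply(others, function(nm) {
        ser <- flagOutliers(ratioSeries(curves[[nm]], ref), mode = mode,
                            zThreshold = zThreshold, iterate = iterate)
        list(series = ser,
             averaged = averagedRelativeHazard(ser),
             slopeAll = weightedSlope(ser, useFlagged = TRUE),
             slopeKept = weightedSlope(ser, useFlagged = FALSE))
    })
    names(out) <- if (is.character(reference)) others else names(curves)[others]
    out
}
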