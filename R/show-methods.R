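#' @describeIn AgeGrid-class compact display
#' @param object an object of the class.
#' @export
setMethod("show", "AgeGrid", function(object) {
    cat(sprintf("AgeGrid: %d five-year groups, midpoints %g-%g, usable from group %d\n",
                object@nAge, min(object@midpoints), max(object@midpoints),
                object@usableFrom))
})

#' @describeIn PeriodGrid-class compact display
#' @param object an object of the class.
#' @export
setMethod("show", "PeriodGrid", function(object) {
    cat(sprintf("PeriodGrid: %d periods (%s ... %s)\n", object@mPeriods,
                object@labels[1L], object@labels[object@mPeriods]))
})

#' @describeIn CohortLayout-class compact display
#' @param object an object of the class.
#' @export
setMethod("show", "CohortLayout", function(object) {
    cat(sprintf("CohortLayout: %d cohorts, l = j - i + %d\n",
                object@kCohorts, object@offset))
})

#' @describeIn IncidenceGrid-class compact display
#' @param object an object of the class.
#' @export
setMethod("show", "IncidenceGrid", function(object) {
    md <- metadata(object)
    cat(sprintf("IncidenceGrid: category %d (%s), %d age groups x %d periods, %d present cells\n",
                md$category, md$label, nrow(object), ncol(object),
                sum(!is.na(assay(object, "rate")))))
    if (!is.null(md$filters))
        cat(sprintf("  filters: count > %d, ages from group %d (%d cells dropped)\n",
                    md$filters$minCount, md$filters$usableFrom,
                    md$filters$nDropped))
})

#' @describeIn EffectEstimates-class compact display
#' @param object an object of the class.
#' @export
setMethod("show", "EffectEstimates", function(object) {
    cat(sprintf("EffectEstimates (%s): %d period and %d cohort coefficients\n",
                object@provenance, nrow(object@period), nrow(object@cohort)))
    cat(sprintf("  anchors: v = 1 at period %d, u = 1 at cohort %d\n",
                object@anchorPeriod, object@anchorCohort))
    if (anyNA(object@cohort$value))
        cat(sprintf("  %d cohort(s) unreachable from the anchor (NA)\n",
                    sum(is.na(object@cohort$value))))
})

#' @describeIn HazardCurve-class compact display
#' @param object an object of the class.
#' @export
setMethod("show", "HazardCurve", function(object) {
    cat(sprintf("HazardCurve: category %d (%s), %d age groups, anchors (period %s, cohort %s)\n",
                object@category, object@label, nrow(object@estimates),
                object@anchorPeriod, object@anchorCohort))
    print(utils::head(object@estimates, 3L))
    if (nrow(object@estimates) > 3L) cat("  ...\n")
})

#' @describeIn RelativeHazardSeries-class compact display
#' @param object an object of the class.
#' @export
setMethod("show", "RelativeHazardSeries", function(object) {
    cat(sprintf("RelativeHazardSeries: category %d vs %d, %d ages, %d flagged\n",
                object@category, object@refCategory, nrow(object@series),
                sum(object@series$outlier)))
})

#' @describeIn AveragedRelativeHazard-class compact display
#' @param object an object of the class.
#' @export
setMethod("show", "AveragedRelativeHazard", function(object) {
    cat(sprintf("AveragedRelativeHazard: R = %.4f +- %.4f (%d age(s) excluded)\n",
                object@R, object@se, length(object@excluded)))
    if (is.finite(object@slope))
        cat(sprintf("  all-points slope vs age: %.4f (SE %.4f)\n",
                    object@slope, object@slopeSE))
})

#' @describeIn TruthSpec-class compact display
#' @param object an object of the class.
#' @export
setMethod("show", "TruthSpec", function(object) {
    cat(sprintf("TruthSpec: %d ages x %d periods, %d cohorts, cv = %g, seed = %d\n",
                object@ages@nAge, object@periods@mPeriods,
                object@layout@kCohorts, object@cv, object@seed))
})

#' Plot a hazard curve or relative-hazard series
#'
#' Base-graphics convenience displays: a hazard curve with one-SE error
#' bars, or a relative-hazard series with 95% CI bars, outliers drawn as
#' open circles and the averaged relative hazard as a horizontal line.
#'
#' @param x a \linkS4class{HazardCurve} or
#'   \linkS4class{RelativeHazardSeries}.
#' @param y for a series, an optional \linkS4class{AveragedRelativeHazard}
#'   drawn as the horizontal reference line.
#' @param ... passed to [graphics::plot()].
#' @return `invisible(NULL)`.
#' @importFrom graphics plot arrows abline points
#' @export
setMethod("plot", signature("HazardCurve", "missing"), function(x, y, ...) {
    df <- x@estimates
    plot(df$age_midpoint, df$hazard, pch = 19,
         xlab = "age (years)", ylab = "hazard (per 100,000 person-years)",
         main = x@label, ...)
    arrows(df$age_midpoint, df$hazard - df$se, df$age_midpoint,
           df$hazard + df$se, angle = 90, code = 3, length = 0.03)
    invisible(NULL)
})

#' @rdname plot-HazardCurve-missing-method
#' @export
setMethod("plot", signature("RelativeHazardSeries", "ANY"), function(x, y, ...) {
    df <- x@series
    plot(df$age_midpoint, df$r, pch = ifelse(df$outlier, 1, 19),
         ylim = range(df$ci_low, df$ci_high),
         xlab = "age (years)", ylab = "relative hazard",
         main = sprintf("category %d vs %d", x@category, x@refCategory), ...)
    arrows(df$age_midpoint, df$ci_low, df$age_midpoint, df$ci_high,
           angle = 90, code = 3, length = 0.03)
    if (!missing(y) && is(y, "AveragedRelativeHazard"))
        abline(h = y@R, lty = 2)
    invisible(NULL)
})
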