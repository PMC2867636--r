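#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assays<- rowData colData
NULL

#' Five-year age-group layout
#'
#' Describes the age axis of an incidence grid: the number of (five-year)
#' age groups, their midpoints in years, display labels, and the first
#' age group considered usable for estimation (younger groups typically
#' carry too few cases for rate SEs to be meaningful).
#'
#' @slot nAge integer, number of age groups.
#' @slot midpoints numeric, strictly increasing age midpoints in years.
#' @slot labels character, one display label per group.
#' @slot usableFrom integer, index of the first usable age group.
#' @seealso [AgeGrid()], [standardAgeGrid()]
#' @export
setClass("AgeGrid", representation(
    nAge = "integer", midpoints = "numeric",
    labels = "character", usableFrom = "integer"
))

setValidity("AgeGrid", function(object) {
    msg <- NULL
    if (length(object@nAge) != 1L || object@nAge < 1L)
        msg <- c(msg, "nAge must be a single positive integer")
    if (length(object@midpoints) != object@nAge)
        msg <- c(msg, "midpoints length must equal nAge")
    if (any(diff(object@midpoints) <= 0))
        msg <- c(msg, "midpoints must be strictly increasing")
    if (length(object@labels) != object@nAge)
        msg <- c(msg, "labels length must equal nAge")
    if (object@usableFrom < 1L || object@usableFrom > object@nAge)
        msg <- c(msg, "usableFrom must lie in [1, nAge]")
    if (is.null(msg)) TRUE else msg
})

#' Calendar-period layout
#'
#' Describes the period axis: the number of (five-year) cross-sectional
#' calendar periods and their display labels. At least two periods are
#' required for any period-effect estimation.
#'
#' @slot mPeriods integer, number of periods.
#' @slot labels character, one label per period (e.g. \code{"1975-79"}).
#' @seealso [PeriodGrid()], [standardPeriodGrid()]
#' @export
setClass("PeriodGrid", representation(mPeriods = "integer", labels = "character"))

setValidity("PeriodGrid", function(object) {
    msg <- NULL
    if (length(object@mPeriods) != 1L || object@mPeriods < 2L)
        msg <- c(msg, "mPeriods must be at least 2")
    if (length(object@labels) != object@mPeriods)
        msg <- c(msg, "labels length must equal mPeriods")
    if (is.null(msg)) TRUE else msg
})

#' Diagonal birth-cohort indexing of an age-period grid
#'
#' Maps a cell (age group i, period j) to its birth cohort l along the
#' Lexis diagonal, l = j - i + offset. A five-year age group crossed with
#' a five-year period spans about nine birth years; the single-diagonal
#' convention assigns each cell to one synthetic five-year cohort, which
#' is the convention under which an 11-age x 6-period usable grid yields
#' exactly 16 cohorts.
#'
#' @slot kCohorts integer, number of cohorts spanned by usable cells.
#' @slot offset integer, the additive offset in l = j - i + offset.
#' @slot nAge,mPeriods,usableFrom integer, dimensions of the grid the
#'   layout indexes (used for bound checks).
#' @slot labels character, birth-year range per cohort (may be empty).
#' @seealso [CohortLayout()], [cohortIndex()]
#' @export
setClass("CohortLayout", representation(
    kCohorts = "integer", offset = "integer",
    nAge = "integer", mPeriods = "integer", usableFrom = "integer",
    labels = "character"
))

setValidity("CohortLayout", function(object) {
    msg <- NULL
    if (object@kCohorts < 1L) msg <- c(msg, "kCohorts must be positive")
    i <- rep(seq.int(object@usableFrom, object@nAge), times = object@mPeriods)
    j <- rep(seq_len(object@mPeriods), each = object@nAge - object@usableFrom + 1L)
    l <- j - i + object@offset
    if (any(l < 1L | l > object@kCohorts))
        msg <- c(msg, "some usable (i, j) cells map outside [1, kCohorts]")
    if (length(object@labels) && length(object@labels) != object@kCohorts)
        msg <- c(msg, "labels, when given, must have length kCohorts")
    if (is.null(msg)) TRUE else msg
})

#' Age x period incidence-rate grid for one exposure category
#'
#' A \linkS4class{SummarizedExperiment} whose rows are age groups and
#' whose columns are calendar periods, with assays \code{rate} (cases per
#' 100,000 person-years), \code{se} (standard error, same units) and
#' \code{count} (raw case count). Absent cells are \code{NA} in the
#' \code{rate} assay and are skipped, never zero-filled, by every
#' downstream estimator. The age, period and cohort layouts plus the
#' exposure-category code live in \code{metadata()}.
#'
#' @seealso [IncidenceGrid()], [applyFilters()], [readIncidenceGrids()]
#' @export
setClass("IncidenceGrid", contains = "SummarizedExperiment")

setValidity("IncidenceGrid", function(object) {
    msg <- NULL
    need <- c("rate", "se", "count")
    if (!all(need %in% names(assays(object))))
        return(sprintf("assays must include %s", paste(need, collapse = ", ")))
    md <- metadata(object)
    for (nm in c("ages", "periods", "layout", "category"))
        if (is.null(md[[nm]])) msg <- c(msg, sprintf("metadata$%s missing", nm))
    if (!is.null(md$ages) && nrow(object) != md$ages@nAge)
        msg <- c(msg, "row count disagrees with age layout")
    if (!is.null(md$periods) && ncol(object) != md$periods@mPeriods)
        msg <- c(msg, "column count disagrees with period layout")
    r <- assay(object, "rate"); s <- assay(object, "se"); k <- assay(object, "count")
    if (any(!is.na(r) & r <= 0)) msg <- c(msg, "present rates must be > 0")
    if (any(!is.na(s) & s < 0)) msg <- c(msg, "SEs must be >= 0")
    if (any(!is.na(k) & (k < 0 | k != round(k))))
        msg <- c(msg, "counts must be non-negative integers")
    if (any(is.na(r) & !is.na(s)))
        msg <- c(msg, "SE present where rate is absent")
    if (is.null(msg)) TRUE else msg
})

#' Period- and cohort-effect coefficient estimates
#'
#' Multiplicative period coefficients v_j and cohort coefficients u_l
#' with standard errors, anchored so that v equals 1 at one period and
#' u equals 1 at one cohort (the identifiability constraint: age, period
#' and cohort are linearly dependent, so the effects are determined only
#' up to these anchors). Cohorts that cannot be connected to the anchor
#' through the data are reported as \code{NA}, never guessed.
#'
#' @slot period data.frame with columns index, label, value, se, is_anchor.
#' @slot cohort data.frame, same columns, one row per cohort.
#' @slot anchorPeriod,anchorCohort integer anchor indices.
#' @slot provenance \code{"estimated"} or \code{"supplied"}.
#' @seealso [estimateEffects()], [EffectEstimates()], [correctRates()]
#' @export
setClass("EffectEstimates", representation(
    period = "data.frame", cohort = "data.frame",
    anchorPeriod = "integer", anchorCohort = "integer",
    provenance = "character"
))

setValidity("EffectEstimates", function(object) {
    msg <- NULL
    chk <- function(df, anchor, what) {
        m <- NULL
        if (!all(c("index", "label", "value", "se", "is_anchor") %in% names(df)))
            return(sprintf("%s table lacks required columns", what))
        if (anchor < 1L || anchor > nrow(df))
            m <- c(m, sprintf("%s anchor out of range", what))
        else {
            a <- df[df$index == anchor, ]
            if (nrow(a) != 1L || is.na(a$value) || a$value != 1 || a$se != 0)
                m <- c(m, sprintf("%s anchor must have value 1 and se 0", what))
        }
        if (any(!is.na(df$value) & df$value <= 0))
            m <- c(m, sprintf("%s values must be strictly positive", what))
        if (any(!is.na(df$se) & df$se < 0))
            m <- c(m, sprintf("%s SEs must be non-negative", what))
        m
    }
    msg <- c(msg, chk(object@period, object@anchorPeriod, "period"),
             chk(object@cohort, object@anchorCohort, "cohort"))
    if (!object@provenance %in% c("estimated", "supplied"))
        msg <- c(msg, "provenance must be 'estimated' or 'supplied'")
    if (is.null(msg)) TRUE else msg
})

#' Effect-corrected incidence grid
#'
#' A \linkS4class{SummarizedExperiment} holding the corrected rates
#' I* = I / (v_j u_l) in assay \code{value} and their propagated standard
#' errors in assay \code{se}. Cells are present exactly where the source
#' cell was present and both coefficients were available.
#'
#' @seealso [correctRates()], [estimateHazard()]
#' @export
setClass("CorrectedGrid", contains = "SummarizedExperiment")

setValidity("CorrectedGrid", function(object) {
    msg <- NULL
    if (!all(c("value", "se") %in% names(assays(object))))
        return("assays must include value and se")
    v <- assay(object, "value"); s <- assay(object, "se")
    if (any(!is.na(v) & v <= 0)) msg <- c(msg, "corrected values must be > 0")
    if (any(!is.na(s) & s < 0)) msg <- c(msg, "SEs must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Age-specific hazard curve
#'
#' The estimated hazard h*(t_i) per age group with its standard error and
#' the number of period cells that contributed to each inverse-variance
#' weighted mean. Carries the anchors its coefficients were estimated
#' under; curves may be compared only when their anchors agree.
#'
#' @slot estimates data.frame with columns age_index, age_midpoint,
#'   hazard, se, n_cells (n_cells may be NA for externally supplied
#'   curves whose pooling breadth is unknown).
#' @slot category integer exposure-category code (0 = reference).
#' @slot label free-text population label.
#' @slot anchorPeriod,anchorCohort integer anchors inherited from the
#'   effect estimates.
#' @seealso [estimateHazard()], [ratioSeries()], [adjustCurve()]
#' @export
setClass("HazardCurve", representation(
    estimates = "data.frame", category = "integer", label = "character",
    anchorPeriod = "integer", anchorCohort = "integer"
))

setValidity("HazardCurve", function(object) {
    msg <- NULL
    df <- object@estimates
    need <- c("age_index", "age_midpoint", "hazard", "se", "n_cells")
    if (!all(need %in% names(df)))
        return(sprintf("estimates must have columns %s", paste(need, collapse = ", ")))
    if (any(df$hazard <= 0)) msg <- c(msg, "hazard values must be > 0")
    if (any(df$se < 0)) msg <- c(msg, "SEs must be >= 0")
    if (any(!is.na(df$n_cells) & df$n_cells < 1))
        msg <- c(msg, "n_cells must be >= 1 where known")
    if (is.unsorted(df$age_index, strictly = TRUE))
        msg <- c(msg, "age_index must be strictly increasing")
    if (is.null(msg)) TRUE else msg
})

#' Age-specific relative-hazard series
#'
#' Ratios r(t_i) of two hazard curves (category c over the reference)
#' with first-order propagated SEs, 95% confidence limits and outlier
#' flags set by [flagOutliers()].
#'
#' @slot series data.frame with columns age_index, age_midpoint, r, se,
#'   ci_low, ci_high, outlier.
#' @slot category,refCategory integer category codes of the pair.
#' @slot anchorPeriod,anchorCohort the shared anchors.
#' @seealso [ratioSeries()], [averagedRelativeHazard()], [weightedSlope()]
#' @export
setClass("RelativeHazardSeries", representation(
    series = "data.frame", category = "integer", refCategory = "integer",
    anchorPeriod = "integer", anchorCohort = "integer"
))

setValidity("RelativeHazardSeries", function(object) {
    df <- object@series
    need <- c("age_index", "age_midpoint", "r", "se", "ci_low", "ci_high", "outlier")
    if (!all(need %in% names(df)))
        return(sprintf("series must have columns %s", paste(need, collapse = ", ")))
    msg <- NULL
    if (any(df$r <= 0)) msg <- c(msg, "ratios must be > 0")
    if (any(abs(df$ci_low - (df$r - 1.96 * df$se)) > 1e-8) ||
        any(abs(df$ci_high - (df$r + 1.96 * df$se)) > 1e-8))
        msg <- c(msg, "confidence limits must equal r -/+ 1.96*se")
    if (!is.logical(df$outlier)) msg <- c(msg, "outlier must be logical")
    if (is.null(msg)) TRUE else msg
})

#' Averaged relative hazard
#'
#' The inverse-variance weighted mean R of a relative-hazard series over
#' its unflagged ages, its SE, the excluded ages, the weights used, and
#' the all-points weighted-regression slope against age as a constancy
#' diagnostic.
#'
#' @slot R,se numeric, the weighted mean and its standard error.
#' @slot excluded integer age indices omitted as outliers.
#' @slot slope,slopeSE numeric, all-points weighted LS slope vs age
#'   midpoint and its standard error.
#' @slot weights numeric, the 1/SE^2 weights of the included ages
#'   (named by age index).
#' @seealso [averagedRelativeHazard()], [adjustCurve()]
#' @export
setClass("AveragedRelativeHazard", representation(
    R = "numeric", se = "numeric", excluded = "integer",
    slope = "numeric", slopeSE = "numeric", weights = "numeric"
))

setValidity("AveragedRelativeHazard", function(object) {
    msg <- NULL
    if (object@R <= 0) msg <- c(msg, "R must be > 0")
    if (object@se < 0) msg <- c(msg, "se must be >= 0")
    if (length(object@weights) && all(is.finite(object@weights)) &&
        object@se > 0 &&
        abs(object@se - 1 / sqrt(sum(object@weights))) > 1e-8)
        msg <- c(msg, "se must equal (sum of weights)^-1/2")
    if (is.null(msg)) TRUE else msg
})

#' Ground truth for synthetic incidence grids
#'
#' Defines a multiplicative age-period-cohort truth I = v_j u_l h(t_i)
#' (with a constant hazard multiplier per non-reference category) plus a
#' relative noise level, from which [generateGrid()] draws observed
#' grids with multiplicative normal noise.
#'
#' @slot ages,periods,layout the grid layouts.
#' @slot vTrue,uTrue,hTrue numeric truth vectors (per period, cohort and
#'   age group respectively; hTrue may be NA below the usable range).
#' @slot RTrue named numeric, hazard multiplier per category code
#'   (category "0" is implicitly 1).
#' @slot cv numeric, relative (coefficient-of-variation) noise level.
#' @slot seed integer, default random seed.
#' @seealso [TruthSpec()], [generateGrid()]
#' @export
setClass("TruthSpec", representation(
    ages = "AgeGrid", periods = "PeriodGrid", layout = "CohortLayout",
    vTrue = "numeric", uTrue = "numeric", hTrue = "numeric",
    RTrue = "numeric", cv = "numeric", seed = "integer"
))

setValidity("TruthSpec", function(object) {
    msg <- NULL
    if (length(object@vTrue) != object@periods@mPeriods)
        msg <- c(msg, "vTrue length must equal the number of periods")
    if (length(object@uTrue) != object@layout@kCohorts)
        msg <- c(msg, "uTrue length must equal the number of cohorts")
    if (length(object@hTrue) != object@ages@nAge)
        msg <- c(msg, "hTrue length must equal the number of age groups")
    if (any(object@vTrue <= 0) || any(object@uTrue <= 0) ||
        any(!is.na(object@hTrue) & object@hTrue <= 0))
        msg <- c(msg, "all truth values must be strictly positive")
    usable <- seq.int(object@ages@usableFrom, object@ages@nAge)
    if (any(is.na(object@hTrue[usable])))
        msg <- c(msg, "hTrue must be present for all usable age groups")
    if (any(object@RTrue <= 0)) msg <- c(msg, "RTrue must be strictly positive")
    if (object@cv < 0) msg <- c(msg, "cv must be non-negative")
    if (is.null(msg)) TRUE else msg
})
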