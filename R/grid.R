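#' Construct an age-group layout
#'
#' @param midpoints numeric, strictly increasing age midpoints in years.
#' @param labels character labels, one per group; derived from the
#'   midpoints when omitted.
#' @param usableFrom index of the first age group used in estimation.
#' @return An \linkS4class{AgeGrid}.
#' @examples
#' AgeGrid(seq(37.5, 87.5, by = 5))
#' @export
AgeGrid <- function(midpoints, labels = NULL, usableFrom = 1L) {
    midpoints <- as.numeric(midpoints)
    if (is.null(labels))
        labels <- sprintf("%g-%g", midpoints - 2.5, midpoints + 2.5)
    new("AgeGrid", nAge = length(midpoints), midpoints = midpoints,
        labels = as.character(labels), usableFrom = as.integer(usableFrom))
}

#' Construct a calendar-period layout
#'
#' @param labels character, one label per five-year period.
#' @return A \linkS4class{PeriodGrid}.
#' @examples
#' PeriodGrid(c("1975-79", "1980-84"))
#' @export
PeriodGrid <- function(labels) {
    labels <- as.character(labels)
    new("PeriodGrid", mPeriods = length(labels), labels = labels)
}

#' The SEER-style layout: 18 five-year age groups and 6 periods
#'
#' Eighteen age groups 0-4 through 85+ (midpoints 2.5 to 87.5), with the
#' groups over age 35 (indices 8 to 18) usable; six periods 1975-79
#' through 2000-04. Under the default cohort offset this usable window
#' spans exactly 16 five-year birth cohorts, 1890-94 through 1965-69.
#'
#' @return `standardAgeGrid()` an \linkS4class{AgeGrid};
#'   `standardPeriodGrid()` a \linkS4class{PeriodGrid};
#'   `standardCohortLayout()` a \linkS4class{CohortLayout}.
#' @examples
#' standardCohortLayout()@kCohorts  # 16
#' @export
standardAgeGrid <- function() {
    labs <- c(sprintf("%d-%d", seq(0L, 80L, 5L), seq(4L, 84L, 5L)), "85+")
    AgeGrid(midpoints = seq(2.5, 87.5, by = 5), labels = labs, usableFrom = 8L)
}

#' @rdname standardAgeGrid
#' @export
standardPeriodGrid <- function() {
    PeriodGrid(sprintf("%d-%02d", seq(1975L, 2000L, 5L), seq(79L, 104L, 5L) %% 100L))
}

#' @rdname standardAgeGrid
#' @export
standardCohortLayout <- function() {
    labs <- sprintf("%d-%02d", seq(1890L, 1965L, 5L), seq(94L, 169L, 5L) %% 100L)
    CohortLayout(standardAgeGrid(), standardPeriodGrid(), labels = labs)
}

#' Construct a cohort layout for an age/period grid
#'
#' Cohort index along the Lexis diagonal: l = j - i + offset. The default
#' offset equals the number of age groups, which places the oldest usable
#' group of the earliest period in cohort 1.
#'
#' @param ages an \linkS4class{AgeGrid}.
#' @param periods a \linkS4class{PeriodGrid}.
#' @param offset integer offset; defaults to `ages@nAge`.
#' @param labels optional birth-year-range labels, one per cohort.
#' @return A \linkS4class{CohortLayout}.
#' @examples
#' CohortLayout(standardAgeGrid(), standardPeriodGrid())
#' @export
CohortLayout <- function(ages, periods, offset = ages@nAge, labels = character()) {
    k <- (ages@nAge - ages@usableFrom + 1L) + periods@mPeriods - 1L
    new("CohortLayout", kCohorts = k, offset = as.integer(offset),
        nAge = ages@nAge, mPeriods = periods@mPeriods,
        usableFrom = ages@usableFrom, labels = as.character(labels))
}

#' Cohort index of a grid cell
#'
#' Returns the birth-cohort index l = j - i + offset for age-group index
#' i and period index j; cells on the same (j - i) diagonal always share
#' a cohort. Vectorized over `i` and `j`.
#'
#' @param i,j age-group and period indices (1-based).
#' @param layout a \linkS4class{CohortLayout}.
#' @return Integer cohort indices.
#' @examples
#' layout <- standardCohortLayout()
#' cohortIndex(8, 1, layout)   # 11: ages 35-39 in 1975-79, cohort 1940-44
#' cohortIndex(18, 1, layout)  # 1: oldest group, earliest period
#' @export
cohortIndex <- function(i, j, layout) {
    stopifnot(is(layout, "CohortLayout"))
    i <- as.integer(i); j <- as.integer(j)
    bad <- i < 1L | i > layout@nAge | j < 1L | j > layout@mPeriods
    if (any(bad))
        stop(sprintf("cell (i=%d, j=%d) is outside the %d x %d grid",
                     i[bad][1L], j[bad][1L], layout@nAge, layout@mPeriods),
             call. = FALSE)
    l <- j - i + layout@offset
    out <- l < 1L | l > layout@kCohorts
    if (any(out))
        stop(sprintf("cell (i=%d, j=%d) maps to cohort %d outside [1, %d]",
                     i[out][1L], j[out][1L], l[out][1L], layout@kCohorts),
             call. = FALSE)
    l
}

#' Construct an incidence grid
#'
#' @param rate,se,count numeric matrices (age groups x periods); `NA` in
#'   `rate` marks an absent cell. `count` may be omitted.
#' @param ages,periods,layout the grid layouts.
#' @param category integer exposure-category code (0 = reference).
#' @param label free-text population label (e.g. sex and area).
#' @return An \linkS4class{IncidenceGrid}.
#' @examples
#' ages <- AgeGrid(c(52.5, 57.5)); periods <- PeriodGrid(c("a", "b"))
#' IncidenceGrid(rate = matrix(c(10, 20, 12, 24), 2), se = matrix(1, 2, 2),
#'               ages = ages, periods = periods)
#' @export
IncidenceGrid <- function(rate, se, count = NULL, ages, periods,
                          layout = CohortLayout(ages, periods),
                          category = 0L, label = "") {
    rate <- as.matrix(rate); se <- as.matrix(se)
    if (is.null(count)) count <- matrix(NA_real_, nrow(rate), ncol(rate))
    count <- as.matrix(count)
    dimnames(rate) <- dimnames(se) <- dimnames(count) <-
        list(ages@labels, periods@labels)
    se[is.na(rate)] <- NA_real_
    count[is.na(rate)] <- NA_real_
    se0 <- SummarizedExperiment(
        assays = list(rate = rate, se = se, count = count),
        rowData = DataFrame(age_index = seq_len(ages@nAge),
                            age_midpoint = ages@midpoints,
                            age_label = ages@labels),
        colData = DataFrame(period_index = seq_len(periods@mPeriods),
                            period_label = periods@labels),
        metadata = list(ages = ages, periods = periods, layout = layout,
                        category = as.integer(category),
                        label = as.character(label), filters = NULL)
    )
    new("IncidenceGrid", se0)
}

#' Accessors for llapc objects
#'
#' `rates()`, `rateSE()` and `caseCounts()` return the assay matrices of
#' an \linkS4class{IncidenceGrid}; `category()`, `ageGrid()`,
#' `periodGrid()` and `cohortLayout()` return grid metadata;
#' `periodEffects()`, `cohortEffects()`, `anchors()` and `provenance()`
#' inspect \linkS4class{EffectEstimates}; `hazardTable()` and
#' `seriesTable()` return the per-age data.frames of a
#' \linkS4class{HazardCurve} and \linkS4class{RelativeHazardSeries}.
#'
#' @param x an llapc object.
#' @return The matrix, data.frame or scalar named above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("rates", "IncidenceGrid", function(x) assay(x, "rate"))

#' @rdname accessors
#' @export
setMethod("rateSE", "IncidenceGrid", function(x) assay(x, "se"))

#' @rdname accessors
#' @export
setMethod("caseCounts", "IncidenceGrid", function(x) assay(x, "count"))

#' @rdname accessors
#' @export
setMethod("category", "IncidenceGrid", function(x) metadata(x)$category)

#' @rdname accessors
#' @export
setMethod("category", "HazardCurve", function(x) x@category)

#' @rdname accessors
#' @export
setMethod("ageGrid", "IncidenceGrid", function(x) metadata(x)$ages)

#' @rdname accessors
#' @export
setMethod("periodGrid", "IncidenceGrid", function(x) metadata(x)$periods)

#' @rdname accessors
#' @export
setMethod("cohortLayout", "IncidenceGrid", function(x) metadata(x)$layout)

#' @rdname accessors
#' @export
setMethod("hazardTable", "HazardCurve", function(x) x@estimates)

#' @rdname accessors
#' @export
setMethod("seriesTable", "RelativeHazardSeries", function(x) x@series)

#' Apply the cell-inclusion filters
#'
#' Marks absent every cell whose case count is at most `minCount`
#' (strictly-greater-than retention, so a count equal to the threshold is
#' dropped) and every cell below the first usable age group. Cells with
#' no recorded count are retained by the count filter. Idempotent; the
#' filters applied and the number of cells dropped are recorded in
#' `metadata(grid)$filters`.
#'
#' @param grid an \linkS4class{IncidenceGrid}.
#' @param minCount retain cells only when count > `minCount`.
#' @param usableFrom first usable age-group index; defaults to the
#'   grid's age layout.
#' @return The filtered \linkS4class{IncidenceGrid}.
#' @export
applyFilters <- function(grid, minCount = 15L,
                         usableFrom = ageGrid(grid)@usableFrom) {
    stopifnot(is(grid, "IncidenceGrid"))
    rate <- assay(grid, "rate"); se <- assay(grid, "se")
    count <- assay(grid, "count")
    present <- !is.na(rate)
    drop <- (!is.na(count) & count <= minCount) |
        row(rate) < as.integer(usableFrom)
    drop <- drop & present
    rate[drop] <- NA_real_; se[drop] <- NA_real_; count[drop] <- NA_real_
    assays(grid) <- list(rate = rate, se = se, count = count)
    metadata(grid)$filters <- list(minCount = as.integer(minCount),
                                   usableFrom = as.integer(usableFrom),
                                   nDropped = sum(drop))
    grid
}

#' Read and write incidence grids as long-format CSV
#'
#' One row per present cell with columns `category`, `sex`, `age_index`,
#' `age_midpoint`, `period_index`, `rate`, `se`, `count`. Numbers are
#' written with 17 significant digits so a write/read round trip is
#' bit-exact.
#'
#' @param path CSV file path.
#' @param ages,periods layouts the rows are indexed against.
#' @param layout optional \linkS4class{CohortLayout}.
#' @return `readIncidenceGrids()` returns a named list of
#'   \linkS4class{IncidenceGrid}, one per category code found in the
#'   file; `writeIncidenceGrids()` returns `path` invisibly.
#' @export
readIncidenceGrids <- function(path, ages = standardAgeGrid(),
                               periods = standardPeriodGrid(),
                               layout = CohortLayout(ages, periods)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("category", "sex", "age_index", "age_midpoint", "period_index",
              "rate", "se", "count")
    if (!all(need %in% names(df)))
        stop("incidence CSV must have columns ", paste(need, collapse = ", "),
             call. = FALSE)
    if (any(df$age_index < 1L | df$age_index > ages@nAge) ||
        any(df$period_index < 1L | df$period_index > periods@mPeriods))
        stop("age_index or period_index outside the supplied layouts", call. = FALSE)
    out <- lapply(split(df, df$category), function(d) {
        rate <- se <- count <- matrix(NA_real_, ages@nAge, periods@mPeriods)
        idx <- cbind(d$age_index, d$period_index)
        rate[idx] <- d$rate; se[idx] <- d$se; count[idx] <- d$count
        IncidenceGrid(rate, se, count, ages = ages, periods = periods,
                      layout = layout, category = d$category[[1L]],
                      label = as.character(d$sex[[1L]]))
    })
    out[order(as.integer(names(out)))]
}

#' @rdname readIncidenceGrids
#' @param grids an \linkS4class{IncidenceGrid} or list of them.
#' @export
writeIncidenceGrids <- function(grids, path) {
    if (is(grids, "IncidenceGrid")) grids <- list(grids)
    rows <- lapply(grids, function(g) {
        rate <- assay(g, "rate"); present <- which(!is.na(rate), arr.ind = TRUE)
        data.frame(
            category = metadata(g)$category,
            sex = metadata(g)$label,
            age_index = present[, 1L],
            age_midpoint = ageGrid(g)@midpoints[present[, 1L]],
            period_index = present[, 2L],
            rate = fmtNum(rate[present]),
            se = fmtNum(assay(g, "se")[present]),
            count = fmtNum(assay(g, "count")[present]),
            stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df <- df[order(df$category, df$period_index, df$age_index), ]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
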