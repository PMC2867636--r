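#' Define ground truth for synthetic grids
#'
#' @param vTrue,uTrue,hTrue positive truth vectors per period, cohort
#'   and age group; `hTrue` may be `NA` below the usable age range.
#' @param RTrue named numeric of hazard multipliers per non-reference
#'   category code (e.g. `c("1" = 1.5)`); the reference category 0 is
#'   always 1.
#' @param cv relative noise level (coefficient of variation of a cell
#'   rate around its model value).
#' @param seed default random seed for [generateGrid()].
#' @param ages,periods,layout grid layouts.
#' @return A \linkS4class{TruthSpec}.
#' @examples
#' ages <- AgeGrid(seq(37.5, 87.5, 5))
#' periods <- PeriodGrid(as.character(1:6))
#' TruthSpec(vTrue = rep(1, 6), uTrue = rep(1, 16),
#'           hTrue = seq(5, 300, length.out = 11), cv = 0.03,
#'           ages = ages, periods = periods)
#' @export
TruthSpec <- function(vTrue, uTrue, hTrue, RTrue = numeric(), cv = 0.03,
                      seed = 1L, ages, periods,
                      layout = CohortLayout(ages, periods)) {
    new("TruthSpec", ages = ages, periods = periods, layout = layout,
        vTrue = as.numeric(vTrue), uTrue = as.numeric(uTrue),
        hTrue = as.numeric(hTrue), RTrue = RTrue, cv = cv,
        seed = as.integer(seed))
}

#' Generate a synthetic incidence grid
#'
#' Draws an observed grid from the multiplicative truth
#' rate(i, j) = v_j u_l (R_c h(t_i)) (1 + eps), with eps normal with
#' mean 0 and standard deviation `cv`, redrawn while any eps <= -0.9 so
#' rates stay positive. The SE assay is set to the oracle value
#' cv x (noise-free product) — the error scale of the generating
#' process, not the realized rate — so that error-propagation formulas
#' have a clean target. Counts are set to 1000 so the default case-count
#' filter retains every cell. Cells outside the usable age range, or
#' whose diagonal falls outside the cohort layout, are absent. With
#' `cv = 0`, rates equal the model product exactly and SEs are 0.
#'
#' @param spec a \linkS4class{TruthSpec}.
#' @param category integer category code; its hazard is
#'   `RTrue[as.character(category)] * hTrue` (multiplier 1 when absent).
#' @param seed random seed; identical seed and spec give bit-identical
#'   grids. With equal `RTrue` and the same seed, two categories are
#'   identical.
#' @return An \linkS4class{IncidenceGrid}.
#' @export
generateGrid <- function(spec, category = 0L, seed = spec@seed) {
    stopifnot(is(spec, "TruthSpec"))
    ages <- spec@ages; periods <- spec@periods; layout <- spec@layout
    n <- ages@nAge; m <- periods@mPeriods
    Rc <- 1
    nm <- as.character(category)
    if (nm %in% names(spec@RTrue)) Rc <- spec@RTrue[[nm]]
    prod <- matrix(NA_real_, n, m)
    for (j in seq_len(m)) for (i in seq.int(ages@usableFrom, n)) {
        l <- j - i + layout@offset
        if (l < 1L || l > layout@kCohorts || is.na(spec@hTrue[i])) next
        prod[i, j] <- spec@vTrue[j] * spec@uTrue[l] * Rc * spec@hTrue[i]
    }
    present <- which(!is.na(prod))
    set.seed(seed)
    eps <- stats::rnorm(length(present), 0, spec@cv)
    while (any(eps <= -0.9))
        eps[eps <= -0.9] <- stats::rnorm(sum(eps <= -0.9), 0, spec@cv)
    rate <- se <- matrix(NA_real_, n, m)
    rate[present] <- prod[present] * (1 + eps)
    se[present] <- spec@cv * prod[present]
    count <- matrix(NA_real_, n, m); count[present] <- 1000
    IncidenceGrid(rate, se, count, ages = ages, periods = periods,
                  layout = layout, category = category,
                  label = sprintf("synthetic category %s", nm))
}

#' Published SEER 9 lung-cancer hazard estimates
#'
#' Age-specific hazard-function estimates (and SEs) of first primary,
#' microscopically confirmed lung cancer in white men and women for
#' three SEER 9 geographical areas — San Francisco-Oakland (category 0),
#' Connecticut (1) and Detroit (2) — derived from age-adjusted incidence
#' rates collected 1975-2004, corrected for period and cohort effects
#' anchored at period 2000-04 (j = 6) and cohort 1925-29 (l = 8). Ages
#' 37.5 to 87.5 (groups 8 to 18). These previously published estimates
#' ship with the package as plain CSV and serve as the reference input
#' for relative-hazard analysis without any data download.
#'
#' @param sex `"men"` or `"women"`.
#' @return Named list of three \linkS4class{HazardCurve} objects:
#'   `"San Francisco-Oakland"`, `"Connecticut"`, `"Detroit"`.
#' @examples
#' curves <- lungHazardCurves("men")
#' hazardTable(curves[["Connecticut"]])
#' @export
lungHazardCurves <- function(sex = c("men", "women")) {
    sex <- match.arg(sex)
    path <- system.file("extdata", sprintf("seer9_lung_hazard_%s.csv", sex),
                        package = "llapc", mustWork = TRUE)
    df <- utils::read.csv(path)
    areas <- c("San Francisco-Oakland", "Connecticut", "Detroit")
    out <- lapply(seq_along(areas) - 1L, function(cc) {
        d <- df[df$category == cc, ]
        HazardCurve(d$age_index, d$age_midpoint, d$hazard, d$se,
                    category = cc, label = sprintf("white %s, %s", sex, areas[cc + 1L]),
                    anchorPeriod = 6L, anchorCohort = 8L)
    })
    names(out) <- areas
    out
}
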