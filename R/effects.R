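#' Adjacent-period rate ratios
#'
#' For each pair of neighbouring periods (j, j+1), forms the per-age
#' ratios I(i, j+1) / I(i, j) over all age groups present in both
#' periods, with first-order propagated SEs, and pools them by inverse
#' variance. Under the multiplicative model each ratio equals
#' (v_{j+1}/v_j)(u_{l+1}/u_l); under the neighbour-cohort assumption
#' (adjacent five-year birth cohorts have nearly equal coefficients) the
#' pooled ratio estimates the period-effect ratio v_{j+1}/v_j. When the
#' cohort effects drift geometrically with per-cohort ratio rho, the
#' estimator is biased by exactly that factor — see the methods vignette.
#'
#' This estimator, like [estimateCohortEffects()], is a reconstruction
#' from the neighbour-cohort assumption by ratio chaining; externally
#' computed coefficients can be used instead via [EffectEstimates()] or
#' [readEffects()].
#'
#' @param grid a filtered \linkS4class{IncidenceGrid}.
#' @return data.frame with one row per adjacent pair: `j` (the left
#'   period), `value`, `se`, `n_cells`.
#' @export
estimatePeriodRatios <- function(grid) {
    stopifnot(is(grid, "IncidenceGrid"))
    rate <- assay(grid, "rate"); se <- assay(grid, "se")
    m <- ncol(rate)
    if (m < 2L) stop("need at least two periods", call. = FALSE)
    out <- lapply(seq_len(m - 1L), function(j) {
        both <- which(!is.na(rate[, j]) & !is.na(rate[, j + 1L]))
        if (!length(both))
            stop(sprintf("no shared present cells between periods %d and %d",
                         j, j + 1L), call. = FALSE)
        r <- rate[both, j + 1L] / rate[both, j]
        s <- ratioSE(rate[both, j + 1L], se[both, j + 1L],
                     rate[both, j], se[both, j])
        p <- ivPool(r, s, context = sprintf("period pair %d/%d", j + 1L, j))
        data.frame(j = j, value = p$value, se = p$se, n_cells = p$n)
    })
    do.call(rbind, out)
}

#' Chain adjacent ratios into anchored coefficients
#'
#' Multiplies the adjacent-index ratios into a coefficient series and
#' rescales it so the anchor index equals exactly 1 with SE 0. Chaining
#' is done on the log scale; the SE of each coefficient accumulates the
#' squared relative errors of the ratios between it and the anchor
#' (ratios are treated as independent).
#'
#' @param ratios data.frame with columns `value` and `se`, row r giving
#'   the ratio of coefficient r+1 to coefficient r (as returned by
#'   [estimatePeriodRatios()]).
#' @param anchor index at which the chained coefficient is fixed to 1.
#' @param labels optional labels for the coefficient table.
#' @return data.frame with columns `index`, `label`, `value`, `se`,
#'   `is_anchor`.
#' @examples
#' chainAndAnchor(data.frame(value = c(2, 2), se = 0), anchor = 3)
#' @export
chainAndAnchor <- function(ratios, anchor, labels = NULL) {
    if (any(is.na(ratios$value)))
        stop("missing ratio in the chain", call. = FALSE)
    n <- nrow(ratios) + 1L
    anchor <- as.integer(anchor)
    stopifnot(anchor >= 1L, anchor <= n)
    logv <- c(0, cumsum(log(ratios$value)))
    value <- exp(logv - logv[anchor])
    relvar <- c(0, cumsum((ratios$se / ratios$value)^2))
    se <- value * sqrt(abs(relvar - relvar[anchor]))
    if (is.null(labels)) labels <- as.character(seq_len(n))
    data.frame(index = seq_len(n), label = labels, value = value, se = se,
               is_anchor = seq_len(n) == anchor)
}

#' Birth-cohort effect coefficients
#'
#' Removes the period effects (dividing each cell by v_j, with SEs
#' propagated), so that each cell estimates u_l h(t_i). Ratios of
#' period-adjacent cells at the same age then estimate the adjacent-
#' cohort ratios u_{l+1}/u_l; these are pooled by inverse variance per
#' cohort pair and chained from the anchor outward on the log scale.
#' Cohorts that cannot be reached from the anchor through observed
#' adjacent ratios are reported as `NA`.
#'
#' @param grid a filtered \linkS4class{IncidenceGrid}.
#' @param v period coefficients: the data.frame returned by
#'   [chainAndAnchor()] (columns `value`, `se`).
#' @param anchorCohort cohort index fixed to 1.
#' @return data.frame with columns `index`, `label`, `value`, `se`,
#'   `is_anchor`, one row per cohort.
#' @export
estimateCohortEffects <- function(grid, v, anchorCohort) {
    stopifnot(is(grid, "IncidenceGrid"))
    layout <- cohortLayout(grid)
    k <- layout@kCohorts
    anchorCohort <- as.integer(anchorCohort)
    stopifnot(anchorCohort >= 1L, anchorCohort <= k)
    rate <- assay(grid, "rate"); se <- assay(grid, "se")
    m <- ncol(rate)
    vv <- v$value; vs <- v$se
    # period-corrected cells: A = I / v_j, relative variances add
    A <- sweep(rate, 2L, vv, "/")
    Ase <- A * sqrt(sweep((se / rate)^2, 2L, (vs / vv)^2, "+"))
    # pooled adjacent-cohort ratios u_{l+1}/u_l
    pair <- vector("list", k - 1L)
    for (j in seq_len(m - 1L)) {
        ii <- which(!is.na(A[, j]) & !is.na(A[, j + 1L]))
        for (i in ii) {
            l <- j - i + layout@offset  # cell (i, j+1) is cohort l+1
            if (l < 1L || l >= k) next
            r <- A[i, j + 1L] / A[i, j]
            s <- ratioSE(A[i, j + 1L], Ase[i, j + 1L], A[i, j], Ase[i, j])
            pair[[l]] <- rbind(pair[[l]], c(r, s))
        }
    }
    ratio <- rep(NA_real_, k - 1L); rse <- rep(NA_real_, k - 1L)
    for (l in seq_len(k - 1L)) {
        if (is.null(pair[[l]])) next
        p <- ivPool(pair[[l]][, 1L], pair[[l]][, 2L],
                    context = sprintf("cohort pair %d/%d", l + 1L, l))
        ratio[l] <- p$value; rse[l] <- p$se
    }
    # chain outward from the anchor; stop at the first missing ratio
    value <- rep(NA_real_, k); sev <- rep(NA_real_, k)
    value[anchorCohort] <- 1; sev[anchorCohort] <- 0
    logu <- 0; relvar <- 0
    for (l in seq.int(anchorCohort, k - 1L)) {
        if (is.na(ratio[l])) break
        logu <- logu + log(ratio[l]); relvar <- relvar + (rse[l] / ratio[l])^2
        value[l + 1L] <- exp(logu); sev[l + 1L] <- exp(logu) * sqrt(relvar)
    }
    logu <- 0; relvar <- 0
    for (l in seq.int(anchorCohort - 1L, 1L)) {
        if (anchorCohort == 1L) break
        if (is.na(ratio[l])) break
        logu <- logu - log(ratio[l]); relvar <- relvar + (rse[l] / ratio[l])^2
        value[l] <- exp(logu); sev[l] <- exp(logu) * sqrt(relvar)
    }
    labels <- if (length(layout@labels)) layout@labels else as.character(seq_len(k))
    data.frame(index = seq_len(k), label = labels, value = value, se = sev,
               is_anchor = seq_len(k) == anchorCohort)
}

#' Estimate anchored period and cohort coefficients from a grid
#'
#' Runs [estimatePeriodRatios()], [chainAndAnchor()] and
#' [estimateCohortEffects()] and assembles the result. Default anchors
#' follow the SEER lung-cancer configuration: the last period and, when
#' the layout has at least eight cohorts, cohort 8 (1925-29 under the
#' standard layout).
#'
#' @param grid a filtered \linkS4class{IncidenceGrid}.
#' @param anchorPeriod period index anchored at v = 1.
#' @param anchorCohort cohort index anchored at u = 1.
#' @return An \linkS4class{EffectEstimates} with provenance
#'   `"estimated"`.
#' @export
estimateEffects <- function(grid, anchorPeriod = periodGrid(grid)@mPeriods,
                            anchorCohort = NULL) {
    k <- cohortLayout(grid)@kCohorts
    if (is.null(anchorCohort))
        anchorCohort <- if (k >= 8L) 8L else as.integer(ceiling(k / 2))
    ratios <- estimatePeriodRatios(grid)
    v <- chainAndAnchor(ratios, anchor = anchorPeriod,
                        labels = periodGrid(grid)@labels)
    u <- estimateCohortEffects(grid, v, anchorCohort = anchorCohort)
    new("EffectEstimates", period = v, cohort = u,
        anchorPeriod = as.integer(anchorPeriod),
        anchorCohort = as.integer(anchorCohort), provenance = "estimated")
}

#' Construct effect estimates from supplied coefficients
#'
#' Validates externally obtained period/cohort coefficients (for
#' example, from other APC software) so they can drive [correctRates()]
#' in place of the package's own ratio-chaining estimator.
#'
#' @param v,u numeric coefficient vectors per period and cohort.
#' @param vSE,uSE standard errors (default 0).
#' @param anchorPeriod,anchorCohort anchor indices; the anchored entries
#'   must equal 1 exactly with SE 0.
#' @param periodLabels,cohortLabels optional labels.
#' @return An \linkS4class{EffectEstimates} with provenance
#'   `"supplied"`.
#' @examples
#' EffectEstimates(v = c(0.8, 1), u = rep(1, 3),
#'                 anchorPeriod = 2, anchorCohort = 2)
#' @export
EffectEstimates <- function(v, u, vSE = rep(0, length(v)),
                            uSE = rep(0, length(u)),
                            anchorPeriod, anchorCohort,
                            periodLabels = as.character(seq_along(v)),
                            cohortLabels = as.character(seq_along(u))) {
    mk <- function(val, se, anchor, labels)
        data.frame(index = seq_along(val), label = labels,
                   value = as.numeric(val), se = as.numeric(se),
                   is_anchor = seq_along(val) == as.integer(anchor))
    new("EffectEstimates",
        period = mk(v, vSE, anchorPeriod, periodLabels),
        cohort = mk(u, uSE, anchorCohort, cohortLabels),
        anchorPeriod = as.integer(anchorPeriod),
        anchorCohort = as.integer(anchorCohort), provenance = "supplied")
}

#' @rdname accessors
#' @export
setMethod("periodEffects", "EffectEstimates", function(x) x@period)

#' @rdname accessors
#' @export
setMethod("cohortEffects", "EffectEstimates", function(x) x@cohort)

#' @rdname accessors
#' @export
setMethod("anchors", "EffectEstimates", function(x)
    c(period = x@anchorPeriod, cohort = x@anchorCohort))

#' @rdname accessors
#' @export
setMethod("anchors", "HazardCurve", function(x)
    c(period = x@anchorPeriod, cohort = x@anchorCohort))

#' @rdname accessors
#' @export
setMethod("anchors", "RelativeHazardSeries", function(x)
    c(period = x@anchorPeriod, cohort = x@anchorCohort))

#' @rdname accessors
#' @export
setMethod("provenance", "EffectEstimates", function(x) x@provenance)

#' Read and write effect estimates
#'
#' CSV format: columns `kind` (`"period"` or `"cohort"`), `index`,
#' `label`, `value`, `se`, `is_anchor`. JSON format embeds the same two
#' tables plus the anchors and provenance. The format is chosen by the
#' file extension.
#'
#' @param eff an \linkS4class{EffectEstimates}.
#' @param path file path ending in `.csv` or `.json`.
#' @return `readEffects()` an \linkS4class{EffectEstimates};
#'   `writeEffects()` `path`, invisibly.
#' @export
writeEffects <- function(eff, path) {
    stopifnot(is(eff, "EffectEstimates"))
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
        jsonlite::write_json(list(
            provenance = eff@provenance,
            anchor_period = eff@anchorPeriod, anchor_cohort = eff@anchorCohort,
            period = eff@period, cohort = eff@cohort
        ), path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
    } else {
        df <- rbind(cbind(kind = "period", eff@period),
                    cbind(kind = "cohort", eff@cohort))
        df$value <- fmtNum(df$value); df$se <- fmtNum(df$se)
        utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    }
    invisible(path)
}

#' @rdname writeEffects
#' @param provenance provenance recorded when reading CSV (the JSON
#'   format stores its own).
#' @export
readEffects <- function(path, provenance = "supplied") {
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
        x <- jsonlite::read_json(path, simplifyVector = TRUE)
        per <- as.data.frame(x$period); coh <- as.data.frame(x$cohort)
        new("EffectEstimates", period = per, cohort = coh,
            anchorPeriod = as.integer(x$anchor_period),
            anchorCohort = as.integer(x$anchor_cohort),
            provenance = x$provenance)
    } else {
        df <- utils::read.csv(path, stringsAsFactors = FALSE)
        need <- c("kind", "index", "label", "value", "se", "is_anchor")
        if (!all(need %in% names(df)))
            stop("effects CSV must have columns ", paste(need, collapse = ", "),
                 call. = FALSE)
        df$label <- as.character(df$label)
        per <- df[df$kind == "period", need[-1L]]
        coh <- df[df$kind == "cohort", need[-1L]]
        rownames(per) <- rownames(coh) <- NULL
        new("EffectEstimates", period = per, cohort = coh,
            anchorPeriod = per$index[per$is_anchor][1L],
            anchorCohort = coh$index[coh$is_anchor][1L],
            provenance = provenance)
    }
}
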