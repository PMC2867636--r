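test_that("noise-free grids with null cohort effects give exact period ratios", {
    spec <- seerTruth(vTrue = c(1, 2, 2, 2, 2, 2), cv = 0)
    g <- generateGrid(spec)
    ratios <- estimatePeriodRatios(g)
    expect_equal(ratios$value, c(2, 1, 1, 1, 1), tolerance = 1e-12)
    specNull <- seerTruth(vTrue = rep(1, 6), cv = 0)
    expect_equal(estimatePeriodRatios(generateGrid(specNull))$value,
                 rep(1, 5), tolerance = 1e-12)
})

test_that("chaining and anchoring reproduces exact chains and closed-form SEs", {
    v <- chainAndAnchor(data.frame(value = c(2, 2), se = c(0, 0)), anchor = 3)
    expect_equal(v$value, c(0.25, 0.5, 1))
    expect_identical(v$is_anchor, c(FALSE, FALSE, TRUE))
    vNull <- chainAndAnchor(data.frame(value = c(1, 1, 1), se = 0), anchor = 2)
    expect_equal(vNull$value, rep(1, 4))
    # relative SE accumulates in quadrature on the log scale
    vSE <- chainAndAnchor(data.frame(value = c(1.5, 1.5), se = 0.015), anchor = 3)
    expect_equal(vSE$se[1L] / vSE$value[1L], sqrt(2) * 0.01, tolerance = 1e-12)
    expect_identical(vSE$se[3L], 0)
    expect_error(chainAndAnchor(data.frame(value = c(2, NA), se = 0), anchor = 1),
                 "missing ratio")
})

test_that("full anchored recovery of v, u and h is exact on noise-free grids", {
    vTrue <- exp(seq(-0.4, 0.1, length.out = 6))
    spec <- seerTruth(vTrue = vTrue, cv = 0)
    g <- applyFilters(generateGrid(spec))
    eff <- estimateEffects(g, anchorPeriod = 6L, anchorCohort = 8L)
    expect_equal(periodEffects(eff)$value, vTrue / vTrue[6L], tolerance = 1e-10)
    expect_equal(cohortEffects(eff)$value, rep(1, 16), tolerance = 1e-10)
    h <- estimateHazard(correctRates(g, eff))
    expect_equal(hazardTable(h)$hazard,
                 spec@hTrue[8:18] * vTrue[6L], tolerance = 1e-10)
})

test_that("cohort effects are recovered exactly when exact period effects are supplied", {
    uTrue <- 1.1^(seq_len(16) - 8)  # geometric drift, anchored at cohort 8
    vTrue <- exp(seq(-0.3, 0, length.out = 6))
    spec <- seerTruth(vTrue = vTrue, uTrue = uTrue, cv = 0)
    g <- applyFilters(generateGrid(spec))
    vExact <- data.frame(value = vTrue / vTrue[6L], se = 0)
    u <- estimateCohortEffects(g, vExact, anchorCohort = 8L)
    expect_equal(u$value, uTrue, tolerance = 1e-10)
    expect_identical(u$se[8L], 0)
})

test_that("pooled period ratio lands within 3 propagated SEs under 2% noise", {
    spec <- seerTruth(vTrue = c(1, 1.5, 1.5^2, 1.5^3, 1.5^4, 1.5^5), cv = 0.02)
    hits <- vapply(1:50, function(k) {
        ratios <- estimatePeriodRatios(generateGrid(spec, seed = 100L + k))
        all(abs(ratios$value - 1.5) <= 3 * ratios$se)
    }, logical(1L))
    expect_gte(mean(hits), 0.95)
})

test_that("chained log-cohort effects cover the truth within 3 SEs in >= 95% of cohorts", {
    uTrue <- 1.1^(seq_len(16) - 8)
    vTrue <- exp(seq(-0.3, 0, length.out = 6))
    spec <- seerTruth(vTrue = vTrue, uTrue = uTrue, cv = 0.02)
    vExact <- data.frame(value = vTrue / vTrue[6L], se = 0)
    hit <- tot <- 0
    for (k in 1:500) {
        g <- generateGrid(spec, seed = 3000L + k)
        u <- estimateCohortEffects(g, vExact, anchorCohort = 8L)
        ok <- !is.na(u$value) & u$index != 8L
        hit <- hit + sum(abs(log(u$value[ok]) - log(uTrue[ok])) <=
                         3 * u$se[ok] / u$value[ok])
        tot <- tot + sum(ok)
    }
    expect_gte(hit / tot, 0.95)
})

test_that("supplied coefficients are validated against the anchoring invariants", {
    eff <- EffectEstimates(v = rep(1, 6), u = rep(1, 16),
                           anchorPeriod = 6, anchorCohort = 8)
    expect_identical(provenance(eff), "supplied")
    expect_identical(anchors(eff), c(period = 6L, cohort = 8L))
    expect_error(EffectEstimates(v = c(rep(1, 5), 0), u = rep(1, 16),
                                 anchorPeriod = 1, anchorCohort = 8),
                 "strictly positive")
    expect_error(EffectEstimates(v = c(2, rep(1, 5)), u = rep(1, 16),
                                 anchorPeriod = 1, anchorCohort = 8),
                 "anchor must have value 1")
    expect_error(EffectEstimates(v = rep(1, 6), u = rep(1, 16),
                                 anchorPeriod = 7, anchorCohort = 8),
                 "anchor")
})

test_that("effect estimates round-trip through CSV and JSON", {
    spec <- seerTruth(cv = 0.03)
    g <- applyFilters(generateGrid(spec, seed = 42L))
    eff <- estimateEffects(g)
    for (ext in c(".csv", ".json")) {
        path <- tempfile(fileext = ext)
        writeEffects(eff, path)
        back <- readEffects(path, provenance = provenance(eff))
        expect_equal(periodEffects(back)$value, periodEffects(eff)$value)
        expect_equal(cohortEffects(back)$se, cohortEffects(eff)$se)
        expect_identical(anchors(back), anchors(eff))
    }
})
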