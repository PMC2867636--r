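test_that("relative hazards divide the curves and propagate both SEs", {
    men <- lungHazardCurves("men")
    ser <- seriesTable(ratioSeries(men[["Connecticut"]],
                                   men[["San Francisco-Oakland"]]))
    # age 67.5: 285.37 / 218.55 rounds to the published 1.31
    i14 <- ser[ser$age_midpoint == 67.5, ]
    expect_identical(sprintf("%.2f", i14$r), "1.31")
    # age 37.5: direct evaluation of the propagation formula
    i8 <- ser[ser$age_midpoint == 37.5, ]
    expect_equal(i8$r, 6.72 / 5.11, tolerance = 1e-12)
    expect_equal(i8$se, (6.72 / 5.11) * sqrt((0.62 / 6.72)^2 + (0.50 / 5.11)^2),
                 tolerance = 1e-6)
    expect_lt(abs(i8$se - 0.1769), 1e-4)
    expect_equal(ser$ci_high - ser$r, 1.96 * ser$se, tolerance = 1e-12)
})

test_that("a curve against itself gives ratios of exactly 1", {
    men <- lungHazardCurves("men")
    cur <- men[["Detroit"]]
    ser <- seriesTable(ratioSeries(cur, cur))
    expect_identical(ser$r, rep(1, 11))
    ht <- hazardTable(cur)
    expect_equal(ser$se, sqrt(2) * ht$se / ht$hazard, tolerance = 1e-12)
})

test_that("curves with different anchors are refused by name", {
    a <- HazardCurve(1:3, c(40, 45, 50), c(1, 2, 3), c(0.1, 0.1, 0.1),
                     anchorPeriod = 6L, anchorCohort = 8L)
    b <- HazardCurve(1:3, c(40, 45, 50), c(1, 2, 3), c(0.1, 0.1, 0.1),
                     anchorPeriod = 5L, anchorCohort = 8L)
    expect_error(ratioSeries(a, b), "anchor mismatch.*period 6.*period 5")
})

test_that("the |z| > 2 rule flags the published series' known outliers", {
    men <- lungHazardCurves("men")
    women <- lungHazardCurves("women")
    # women Connecticut vs San Francisco-Oakland: only the age-42.5 spike
    serW <- flagOutliers(ratioSeries(women[["Connecticut"]],
                                     women[["San Francisco-Oakland"]]))
    dfW <- seriesTable(serW)
    expect_identical(dfW$age_midpoint[dfW$outlier], 42.5)
    expect_gt(dfW$r[dfW$outlier], 1.7)
    # men Detroit vs San Francisco-Oakland: only the age-77.5 dip
    serM <- flagOutliers(ratioSeries(men[["Detroit"]],
                                     men[["San Francisco-Oakland"]]))
    expect_identical(seriesTable(serM)$age_midpoint[seriesTable(serM)$outlier],
                     77.5)
    # a flat series has no outliers
    flat <- ratioSeries(men[["Connecticut"]], men[["Connecticut"]])
    expect_false(any(seriesTable(flagOutliers(flat))$outlier))
})

test_that("averaged relative hazard excludes flagged points from mean and weights", {
    men <- lungHazardCurves("men")
    ser <- flagOutliers(ratioSeries(men[["Connecticut"]],
                                    men[["San Francisco-Oakland"]]))
    avg <- averagedRelativeHazard(ser)
    expect_identical(sprintf("%.2f", avg@R), "1.31")
    expect_length(avg@excluded, 0L)
    # two-point weighted mean without an outlier pass
    two <- new("RelativeHazardSeries",
               series = data.frame(age_index = 1:2, age_midpoint = c(40, 45),
                                   r = c(1, 3), se = 1,
                                   ci_low = c(1, 3) - 1.96,
                                   ci_high = c(1, 3) + 1.96, outlier = FALSE),
               category = 1L, refCategory = 0L,
               anchorPeriod = 1L, anchorCohort = 1L)
    avg2 <- averagedRelativeHazard(two)
    expect_equal(avg2@R, 2)
    expect_equal(avg2@se, 1 / sqrt(2))
})

test_that("averaged relative hazard is invariant under uniform SE rescaling", {
    men <- lungHazardCurves("men")
    ser <- ratioSeries(men[["Detroit"]], men[["San Francisco-Oakland"]])
    scaled <- ser
    scaled@series$se <- 2.5 * ser@series$se
    scaled@series$ci_low <- scaled@series$r - 1.96 * scaled@series$se
    scaled@series$ci_high <- scaled@series$r + 1.96 * scaled@series$se
    a1 <- averagedRelativeHazard(ser)
    a2 <- averagedRelativeHazard(scaled)
    expect_equal(a2@R, a1@R, tolerance = 1e-12)
    expect_equal(a2@se, 2.5 * a1@se, tolerance = 1e-12)
})

test_that("weighted slope matches the published fit and interpolates exact lines", {
    men <- lungHazardCurves("men")
    ser <- ratioSeries(men[["Connecticut"]], men[["San Francisco-Oakland"]])
    sl <- weightedSlope(ser, useFlagged = TRUE)
    expect_lt(abs(unname(sl[["slope"]]) - 0.0023), 3e-4)
    expect_lt(abs(unname(sl[["se"]]) - 0.0009), 5e-5)
    # exact line, equal weights
    t <- seq(40, 85, 5)
    line <- new("RelativeHazardSeries",
                series = data.frame(age_index = seq_along(t), age_midpoint = t,
                                    r = 1 + 0.01 * t, se = 0.05,
                                    ci_low = 1 + 0.01 * t - 1.96 * 0.05,
                                    ci_high = 1 + 0.01 * t + 1.96 * 0.05,
                                    outlier = FALSE),
                category = 1L, refCategory = 0L,
                anchorPeriod = 1L, anchorCohort = 1L)
    expect_equal(unname(weightedSlope(line)[["slope"]]), 0.01, tolerance = 1e-12)
    # constant series: slope 0
    cst <- line; cst@series$r <- 1.3
    cst@series$ci_low <- 1.3 - 1.96 * 0.05; cst@series$ci_high <- 1.3 + 1.96 * 0.05
    expect_equal(unname(weightedSlope(cst)[["slope"]]), 0, tolerance = 1e-12)
    # degenerate design: one distinct age
    degen <- line; degen@series$age_midpoint <- 50
    expect_error(weightedSlope(degen), "degenerate")
})

test_that("weighted mean and slope agree with brute-force oracles to 1e-12", {
    set.seed(314)
    for (k in 1:25) {
        n <- sample(5:12, 1L)
        t <- sort(runif(n, 37.5, 87.5))
        r <- exp(rnorm(n, 0.3, 0.2)); se <- runif(n, 0.02, 0.3)
        ser <- new("RelativeHazardSeries",
                   series = data.frame(age_index = seq_len(n), age_midpoint = t,
                                       r = r, se = se, ci_low = r - 1.96 * se,
                                       ci_high = r + 1.96 * se, outlier = FALSE),
                   category = 1L, refCategory = 0L,
                   anchorPeriod = 1L, anchorCohort = 1L)
        avg <- averagedRelativeHazard(ser)
        oracleMean <- bruteWeightedMean(r, se)
        expect_equal(avg@R, oracleMean$value, tolerance = 1e-12)
        expect_equal(avg@se, oracleMean$se, tolerance = 1e-12)
        sl <- weightedSlope(ser)
        oracleLine <- bruteWLS(t, r, 1 / se^2)
        expect_equal(unname(sl[["slope"]]), oracleLine$slope, tolerance = 1e-12)
        expect_equal(unname(sl[["se"]]), oracleLine$slopeSE, tolerance = 1e-12)
    }
})

test_that("adjusting by the averaged relative hazard superimposes the curves", {
    men <- lungHazardCurves("men")
    conn <- men[["Connecticut"]]; sfo <- men[["San Francisco-Oakland"]]
    avg <- averagedRelativeHazard(flagOutliers(ratioSeries(conn, sfo)))
    adj <- adjustCurve(conn, avg)
    expect_equal(hazardTable(adjustCurve(conn, 1)), hazardTable(conn))
    expect_equal(hazardTable(adjustCurve(conn, 1.3))$hazard[1L], 6.72 / 1.3)
    # mean absolute relative deviation from the reference over ages 47.5+
    a <- hazardTable(adj); b <- hazardTable(sfo)
    old <- a$age_midpoint >= 47.5
    dev <- abs(a$hazard[old] / b$hazard[old] - 1)
    expect_lt(mean(dev), 0.05)
})

test_that("relative hazards are invariant under a common change of anchors", {
    vTrue <- exp(seq(-0.3, 0, length.out = 6))
    uTrue <- 1.05^(seq_len(16) - 8)
    spec0 <- seerTruth(vTrue = vTrue, uTrue = uTrue, cv = 0.03,
                       RTrue = c("1" = 1.4))
    g0 <- applyFilters(generateGrid(spec0, category = 0L, seed = 61L))
    g1 <- applyFilters(generateGrid(spec0, category = 1L, seed = 62L))
    # re-anchoring at (period 1, cohort 4) rescales every v by a common
    # alpha and every u by a common beta
    effA <- EffectEstimates(v = vTrue / vTrue[6L], u = uTrue / uTrue[8L],
                            anchorPeriod = 6, anchorCohort = 8)
    effB <- EffectEstimates(v = vTrue / vTrue[1L], u = uTrue / uTrue[4L],
                            anchorPeriod = 1, anchorCohort = 4)
    alpha <- vTrue[6L] / vTrue[1L]; beta <- uTrue[8L] / uTrue[4L]
    h0a <- estimateHazard(correctRates(g0, effA))
    h1a <- estimateHazard(correctRates(g1, effA))
    h0b <- estimateHazard(correctRates(g0, effB))
    h1b <- estimateHazard(correctRates(g1, effB))
    # coefficients scale by (alpha, beta), so curves scale by 1/(alpha beta)
    expect_equal(hazardTable(h0b)$hazard * alpha * beta,
                 hazardTable(h0a)$hazard, tolerance = 1e-12)
    # ... but the relative hazards do not move
    ra <- seriesTable(ratioSeries(h1a, h0a))
    rb <- seriesTable(ratioSeries(h1b, h0b))
    expect_equal(rb$r, ra$r, tolerance = 1e-12)
    expect_equal(rb$se, ra$se, tolerance = 1e-12)
})
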