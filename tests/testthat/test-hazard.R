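test_that("rate correction divides by the effect product and propagates errors", {
    lay <- smallLayout()
    mkGrid <- function(rate, se) {
        r <- matrix(NA_real_, 4, 3); s <- matrix(NA_real_, 4, 3)
        r[1L, 1L] <- rate; s[1L, 1L] <- se
        IncidenceGrid(r, s, ages = lay$ages, periods = lay$periods)
    }
    # identity correction
    effId <- EffectEstimates(v = rep(1, 3), u = rep(1, 6),
                             anchorPeriod = 1, anchorCohort = 1)
    c1 <- correctRates(mkGrid(10, 1), effId)
    expect_equal(SummarizedExperiment::assay(c1, "value")[1L, 1L], 10)
    expect_equal(SummarizedExperiment::assay(c1, "se")[1L, 1L], 1)
    # cell (1,1) has cohort l = 1 - 1 + 4 = 4: 12 / (1.2 * 0.8) = 12.5
    eff3 <- EffectEstimates(v = c(1.2, 1, 1), u = c(1, 1, 1, 0.8, 1, 1),
                            anchorPeriod = 2, anchorCohort = 1)
    c3 <- correctRates(mkGrid(12, 1), eff3)
    expect_equal(SummarizedExperiment::assay(c3, "value")[1L, 1L], 12 / 0.96)
    # error propagation with coefficient uncertainty:
    # I=100, SE_I=10, v=u=1 with SE 0.05 each -> sqrt(100 + 25 + 25)
    eff4 <- EffectEstimates(v = c(1, 1, 1), u = rep(1, 6),
                            vSE = c(0.05, 0, 0), uSE = c(0, 0, 0, 0.05, 0, 0),
                            anchorPeriod = 2, anchorCohort = 1)
    c4 <- correctRates(mkGrid(100, 10), eff4)
    expect_equal(SummarizedExperiment::assay(c4, "se")[1L, 1L],
                 sqrt(100 + 25 + 25), tolerance = 1e-12)
})

test_that("hazard estimation is the inverse-variance weighted mean across periods", {
    lay <- smallLayout()
    r <- matrix(NA_real_, 4, 3); s <- matrix(NA_real_, 4, 3)
    r[1L, ] <- c(1, 3, NA);    s[1L, ] <- c(1, 1, NA)
    r[2L, ] <- c(5, NA, NA);   s[2L, ] <- c(0.5, NA, NA)
    r[3L, ] <- c(10, 20, NA);  s[3L, ] <- c(1, 2, NA)
    g <- IncidenceGrid(r, s, ages = lay$ages, periods = lay$periods)
    effId <- EffectEstimates(v = rep(1, 3), u = rep(1, 6),
                             anchorPeriod = 1, anchorCohort = 1)
    h <- hazardTable(estimateHazard(correctRates(g, effId)))
    expect_equal(h$hazard, c(2, 5, 12))
    expect_equal(h$se, c(1 / sqrt(2), 0.5, 1 / sqrt(1.25)), tolerance = 1e-12)
    expect_equal(h$n_cells, c(2L, 1L, 2L))
    expect_identical(nrow(h), 3L)  # the empty age row is absent
})

test_that("zero-SE cells are rejected unless floored or the whole row is exact", {
    lay <- smallLayout()
    r <- matrix(NA_real_, 4, 3); s <- matrix(NA_real_, 4, 3)
    r[1L, ] <- c(2, 3, NA); s[1L, ] <- c(0, 1, NA)
    g <- IncidenceGrid(r, s, ages = lay$ages, periods = lay$periods)
    effId <- EffectEstimates(v = rep(1, 3), u = rep(1, 6),
                             anchorPeriod = 1, anchorCohort = 1)
    corr <- correctRates(g, effId)
    expect_error(estimateHazard(corr), "SE floor")
    hf <- hazardTable(estimateHazard(corr, seFloor = 1))
    expect_equal(hf$hazard[1L], 2.5)
    # an all-exact row carries its common value with SE 0
    r2 <- matrix(NA_real_, 4, 3); s2 <- matrix(NA_real_, 4, 3)
    r2[2L, ] <- 7; s2[2L, ] <- 0
    g2 <- IncidenceGrid(r2, s2, ages = lay$ages, periods = lay$periods)
    h2 <- hazardTable(estimateHazard(correctRates(g2, effId)))
    expect_identical(h2$hazard, 7)
    expect_identical(h2$se, 0)
})

test_that("weighted-mean machinery agrees with a brute-force oracle to 1e-12", {
    set.seed(91)
    lay <- smallLayout()
    effId <- EffectEstimates(v = rep(1, 3), u = rep(1, 6),
                             anchorPeriod = 1, anchorCohort = 1)
    for (k in 1:25) {
        r <- matrix(exp(rnorm(12, 3, 0.5)), 4, 3)
        s <- matrix(runif(12, 0.1, 2), 4, 3)
        absent <- sample(12, 3)
        r[absent] <- NA; s[absent] <- NA
        g <- IncidenceGrid(r, s, ages = lay$ages, periods = lay$periods)
        h <- hazardTable(estimateHazard(correctRates(g, effId)))
        for (i in seq_len(nrow(h))) {
            row <- h$age_index[i]
            cells <- !is.na(r[row, ])
            oracle <- bruteWeightedMean(r[row, cells], s[row, cells])
            expect_equal(h$hazard[i], oracle$value, tolerance = 1e-12)
            expect_equal(h$se[i], oracle$se, tolerance = 1e-12)
        }
    }
})

test_that("rescaling the SEs of one age row leaves its hazard unchanged and scales its SE", {
    lay <- smallLayout()
    effId <- EffectEstimates(v = rep(1, 3), u = rep(1, 6),
                             anchorPeriod = 1, anchorCohort = 1)
    r <- matrix(exp(rnorm(12, 3, 0.3)), 4, 3)
    s <- matrix(runif(12, 0.2, 1), 4, 3)
    g1 <- IncidenceGrid(r, s, ages = lay$ages, periods = lay$periods)
    s2 <- s; s2[2L, ] <- 3.7 * s[2L, ]
    g2 <- IncidenceGrid(r, s2, ages = lay$ages, periods = lay$periods)
    h1 <- hazardTable(estimateHazard(correctRates(g1, effId)))
    h2 <- hazardTable(estimateHazard(correctRates(g2, effId)))
    expect_equal(h2$hazard[2L], h1$hazard[2L], tolerance = 1e-12)
    expect_equal(h2$se[2L], 3.7 * h1$se[2L], tolerance = 1e-12)
    expect_equal(h2$hazard[-2L], h1$hazard[-2L], tolerance = 1e-12)
})

test_that("the propagated SE of corrected rates matches Monte-Carlo spread within 10%", {
    set.seed(20)
    N <- 20000
    I0 <- 100; cv <- 0.03
    v0 <- 1.1; sev <- 0.02; u0 <- 0.9; seu <- 0.02
    I <- rnorm(N, I0, cv * I0)
    v <- rnorm(N, v0, sev); u <- rnorm(N, u0, seu)
    emp <- sd(I / (v * u))
    prop <- sqrt((1 / (v0 * u0))^2 * (cv * I0)^2 +
                 (I0 / (v0^2 * u0))^2 * sev^2 +
                 (I0 / (v0 * u0^2))^2 * seu^2)
    expect_lt(abs(emp / prop - 1), 0.10)
})

test_that("hazard curves round-trip through CSV with metadata intact", {
    spec <- seerTruth(cv = 0.03)
    g <- applyFilters(generateGrid(spec, seed = 5L))
    h <- estimateHazard(correctRates(g, estimateEffects(g)))
    path <- tempfile(fileext = ".csv")
    writeHazardCurve(h, path)
    back <- readHazardCurve(path)
    expect_equal(hazardTable(back)$hazard, hazardTable(h)$hazard)
    expect_equal(hazardTable(back)$se, hazardTable(h)$se)
    expect_identical(anchors(back), anchors(h))
    expect_identical(category(back), category(h))
})
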