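# Shared fixtures and independent oracles, built in code.

# Small 4-age x 3-period layout for cheap unit tests.
smallLayout <- function(usableFrom = 1L) {
    ages <- AgeGrid(c(42.5, 47.5, 52.5, 57.5), usableFrom = usableFrom)
    periods <- PeriodGrid(c("p1", "p2", "p3"))
    list(ages = ages, periods = periods,
         layout = CohortLayout(ages, periods))
}

# The SEER-style truth used in recovery experiments: standard 18x6
# layout, hazard shaped like the published male reference curve.
seerTruth <- function(vTrue = exp(seq(-0.3, 0, length.out = 6)),
                      uTrue = rep(1, 16), RTrue = numeric(), cv = 0.03) {
    hBase <- c(5.11, 14.34, 28.90, 56.89, 99.87, 158.96, 218.55, 253.56,
               283.49, 245.25, 171.04)
    TruthSpec(vTrue = vTrue, uTrue = uTrue,
              hTrue = c(rep(NA_real_, 7), hBase), RTrue = RTrue, cv = cv,
              ages = standardAgeGrid(), periods = standardPeriodGrid())
}

# Brute-force inverse-variance weighted mean, independent of ivPool.
bruteWeightedMean <- function(values, ses) {
    w <- 1 / ses^2
    list(value = sum(values * w) / sum(w), se = sqrt(1 / sum(w)))
}

# Brute-force weighted least squares through the normal equations,
# with residual-scaled slope SE (independent of lm).
bruteWLS <- function(x, y, w) {
    X <- cbind(1, x)
    XtWX <- t(X) %*% (w * X)
    beta <- solve(XtWX, t(X) %*% (w * y))
    resid <- y - X %*% beta
    sigma2 <- sum(w * resid^2) / (length(y) - 2)
    list(slope = beta[2L], slopeSE = sqrt(sigma2 * solve(XtWX)[2L, 2L]))
}

# Ratio series computed directly from two hazard tables (no package
# machinery beyond arithmetic).
bruteRatio <- function(num, ref) {
    r <- num$hazard / ref$hazard
    se <- r * sqrt((num$se / num$hazard)^2 + (ref$se / ref$hazard)^2)
    data.frame(t = num$age_midpoint, r = r, se = se)
}
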