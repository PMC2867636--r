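# Inverse-variance pooling with an explicit rule for exact (se = 0) data:
# if every SE is zero the inputs are treated as exact and must agree, and
# the common value is returned with se 0; a mix of zero and positive SEs
# is refused (an infinite weight would silently discard the rest).
ivPool <- function(values, ses, context = "pooling") {
    keep <- !is.na(values) & !is.na(ses)
    values <- values[keep]; ses <- ses[keep]
    if (!length(values))
        stop(sprintf("%s: no values with usable SEs", context), call. = FALSE)
    if (all(ses == 0)) {
        if (diff(range(values)) > 1e-8 * max(abs(values)))
            stop(sprintf(
                "%s: all SEs are zero but values disagree; supply an SE floor",
                context), call. = FALSE)
        return(list(value = values[[1L]], se = 0, n = length(values)))
    }
    if (any(ses == 0))
        stop(sprintf(
            "%s: mix of zero and positive SEs; supply an SE floor", context),
            call. = FALSE)
    w <- 1 / ses^2
    list(value = sum(w * values) / sum(w), se = 1 / sqrt(sum(w)), n = length(values))
}

# First-order (delta-method) SE of a ratio a/b with independent errors.
ratioSE <- function(a, seA, b, seB) {
    (a / b) * sqrt((seA / a)^2 + (seB / b)^2)
}

# Weighted least squares of y on x with weights w; returns the intercept
# and slope with residual-scaled standard errors (the standard linear
# regression convention).
wlsLine <- function(x, y, w) {
    if (length(unique(x)) < 2L)
        stop("degenerate design: need at least two distinct x values", call. = FALSE)
    fit <- stats::lm(y ~ x, weights = w)
    # exact data fit perfectly; the "essentially perfect fit" caution is
    # expected there and the zero residual SE is the right answer
    co <- suppressWarnings(summary(fit))$coefficients
    list(intercept = co[1L, 1L], slope = co[2L, 1L],
         interceptSE = co[1L, 2L], slopeSE = co[2L, 2L], fit = stats::fitted(fit))
}

fmtNum <- function(x) {
    ifelse(is.na(x), "NA", sprintf("%.17g", x))
}
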