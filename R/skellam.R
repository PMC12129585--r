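#' Skellam log probability mass function
#'
#' Log-probability of `y = N1 - N2` where `N1 ~ Poisson(lambdaPos)` and
#' `N2 ~ Poisson(lambdaNeg)` are independent:
#' \deqn{P(y) = e^{-(\lambda^+ + \lambda^-)}
#'   (\lambda^+/\lambda^-)^{y/2} I_{|y|}(2\sqrt{\lambda^+\lambda^-}),}
#' with \eqn{I_{|y|}} the modified Bessel function of the first kind.
#' Computation stays in the log domain with exponentially scaled Bessel
#' evaluation, so rates up to about 1e4 and outcomes up to |y| of about 1e3
#' are handled without overflow. Degenerate rates are supported: with one
#' rate zero the distribution reduces to a (possibly negated) Poisson, with
#' both zero to a point mass at zero; impossible outcomes return `-Inf`.
#'
#' @param y integer outcomes (vector).
#' @param lambdaPos,lambdaNeg nonnegative rates, recycled against `y`.
#' @return numeric vector of log-probabilities (each `<= 0`).
#' @examples
#' skellamLogPmf(0, 0, 0)                       # 0: point mass at zero
#' skellamLogPmf(3, 2, 0.5) - skellamLogPmf(-3, 0.5, 2)  # sign symmetry: 0
#' @export
skellamLogPmf <- function(y, lambdaPos, lambdaNeg) {
    if (any(!is.finite(lambdaPos)) || any(!is.finite(lambdaNeg)) ||
        any(lambdaPos < 0) || any(lambdaNeg < 0))
        stop("rates must be finite and nonnegative")
    if (any(y != round(y)))
        stop("outcomes y must be integers")
    n <- max(length(y), length(lambdaPos), length(lambdaNeg))
    y <- rep_len(y, n)
    lp <- rep_len(lambdaPos, n)
    ln <- rep_len(lambdaNeg, n)
    out <- numeric(n)

    zp <- lp == 0
    zn <- ln == 0
    both <- zp & zn
    out[both] <- ifelse(y[both] == 0, 0, -Inf)
    onlyN <- zn & !zp  # pure Poisson on the positive side
    out[onlyN] <- ifelse(y[onlyN] >= 0,
        stats::dpois(pmax(y[onlyN], 0), lp[onlyN], log = TRUE), -Inf)
    onlyP <- zp & !zn
    out[onlyP] <- ifelse(y[onlyP] <= 0,
        stats::dpois(pmax(-y[onlyP], 0), ln[onlyP], log = TRUE), -Inf)

    gen <- !(zp | zn)
    if (any(gen)) {
        yg <- y[gen]; lpg <- lp[gen]; lng <- ln[gen]
        u <- 2 * sqrt(lpg * lng)
        res <- -(lpg + lng) + (yg / 2) * (log(lpg) - log(lng))
        ay <- abs(yg)
        for (a in unique(ay)) {
            sel <- ay == a
            res[sel] <- res[sel] + .logBesselI(a, u[sel])
        }
        out[gen] <- res
    }
    out
}

#' Skellam sign-class probabilities
#'
#' Probability that a Skellam outcome is negative, exactly zero, or
#' positive: the three classes of the signed link-prediction task.
#'
#' @param lambdaPos,lambdaNeg nonnegative rates (vectors, recycled).
#' @return for scalar input a named numeric `c(neg, zr, pos)`; otherwise a
#'   matrix with columns `neg`, `zr`, `pos`. Rows sum to one.
#' @examples
#' skellamClassProbs(0, 0)      # (0, 1, 0)
#' skellamClassProbs(2, 2)      # symmetric: p_neg == p_pos
#' @export
skellamClassProbs <- function(lambdaPos, lambdaNeg) {
    if (any(!is.finite(lambdaPos)) || any(!is.finite(lambdaNeg)) ||
        any(lambdaPos < 0) || any(lambdaNeg < 0))
        stop("rates must be finite and nonnegative")
    n <- max(length(lambdaPos), length(lambdaNeg))
    lp <- rep_len(lambdaPos, n)
    ln <- rep_len(lambdaNeg, n)
    res <- matrix(0, n, 3, dimnames = list(NULL, c("neg", "zr", "pos")))
    for (r in seq_len(n)) {
        p0 <- exp(skellamLogPmf(0L, lp[r], ln[r]))
        tot <- lp[r] + ln[r]
        ymax <- ceiling(tot + 20 * sqrt(tot) + 30)
        ys <- seq_len(ymax)
        ppos <- if (lp[r] > 0) sum(exp(skellamLogPmf(ys, lp[r], ln[r]))) else 0
        pneg <- if (ln[r] > 0) sum(exp(skellamLogPmf(-ys, lp[r], ln[r]))) else 0
        s <- pneg + p0 + ppos
        res[r, ] <- c(pneg, p0, ppos) / s
    }
    if (n == 1L) res[1, ] else res
}
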