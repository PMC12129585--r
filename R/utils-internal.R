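## Internal numerical helpers shared across modules.

## Columnwise softmax, shift-invariant and overflow-safe.
.softmaxCols <- function(L) {
    L <- sweep(L, 2, apply(L, 2, max), "-")
    E <- exp(L)
    sweep(E, 2, colSums(E), "/")
}

## Euclidean distances between the columns of X (K x N) as an N x N matrix.
.pairDist <- function(X) {
    G <- crossprod(X)
    q <- diag(G)
    d2 <- outer(q, q, "+") - 2 * G
    sqrt(pmax(d2, 0))
}

## Power-series evaluation of log I_nu(x); converges quickly (and without
## cancellation, all terms being positive) when x^2/4 is small against nu.
.logBesselISeries <- function(nu, x) {
    lead <- nu * log(x / 2) - lgamma(nu + 1)  # -Inf at x = 0 for nu > 0
    q <- x^2 / 4
    term <- rep(1, length(x))
    ssum <- rep(1, length(x))
    for (k in 1:200) {
        term <- term * q / (k * (nu + k))
        ssum <- ssum + term
        if (all(term < 1e-18 * ssum)) break
    }
    lead + log(ssum)
}

## log I_nu(x) for scalar integer order nu >= 0 and a vector of arguments
## x >= 0. Uses the exponentially scaled Bessel function in the large-
## argument regime and the power series where base besselI loses precision
## or underflows (order large against the argument).
.logBesselI <- function(nu, x) {
    out <- numeric(length(x))
    seriesRegion <- nu >= 10 & x^2 / 4 < (nu + 1)
    direct <- which(!seriesRegion)
    if (length(direct)) {
        b <- suppressWarnings(besselI(x[direct], nu, expon.scaled = TRUE))
        ok <- is.finite(b) & b > 1e-290
        out[direct[ok]] <- log(b[ok]) + x[direct[ok]]
        seriesRegion[direct[!ok]] <- TRUE
    }
    if (any(seriesRegion))
        out[seriesRegion] <- .logBesselISeries(nu, x[seriesRegion])
    out
}

## Perron continued fraction for I_{nu+1}(x)/I_nu(x); reliable when x is
## not huge against the order (depth 120 covers x/nu up to ~30).
.besselIRatioCF <- function(nu, x) {
    t <- rep(0, length(x))
    for (m in 120:1) t <- 1 / (2 * (nu + m) / x + t)
    t[x == 0] <- 0
    t
}

## I_{nu+1}(x) / I_nu(x) for scalar integer order nu >= 0, vector x >= 0.
.besselIRatio <- function(nu, x) {
    r <- numeric(length(x))
    cfRegion <- (nu >= 10 & x^2 / 4 < (nu + 1)) | x == 0
    direct <- which(!cfRegion)
    if (length(direct)) {
        num <- suppressWarnings(besselI(x[direct], nu + 1,
                                        expon.scaled = TRUE))
        den <- suppressWarnings(besselI(x[direct], nu, expon.scaled = TRUE))
        ok <- is.finite(num) & is.finite(den) & den > 1e-290
        r[direct[ok]] <- num[ok] / den[ok]
        cfRegion[direct[!ok]] <- TRUE
    }
    if (any(cfRegion))
        r[cfRegion] <- .besselIRatioCF(nu, x[cfRegion])
    r
}

## Upper-triangle pair bookkeeping for an N-node network.
.pairIndex <- function(N) {
    ut <- which(upper.tri(matrix(FALSE, N, N)))
    list(
        idx = ut,
        i = ((ut - 1L) %% N) + 1L,
        j = ((ut - 1L) %/% N) + 1L
    )
}

.stopifnotScalarCount <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
        stop(sprintf("%s must be a single integer", what), call. = FALSE)
    as.integer(x)
}
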