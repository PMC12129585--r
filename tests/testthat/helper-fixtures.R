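## Shared fixtures and independent oracles, built in code at test time.

## Truncated Poisson-convolution oracle for the Skellam pmf.
skellamPmfOracle <- function(y, lp, ln, kmax = 1000) {
    k <- max(0, -y):kmax
    sum(dpois(y + k, lp) * dpois(k, ln))
}

## Random columnwise-simplex membership matrix.
randomMembership <- function(K, N, seed) {
    set.seed(seed)
    L <- matrix(rnorm(K * N), K, N)
    E <- exp(sweep(L, 2, apply(L, 2, max)))
    sweep(E, 2, colSums(E), "/")
}

## Hard-partition membership matrix from an assignment vector.
hardPartition <- function(assign, K = max(assign)) {
    Q <- matrix(0, K, length(assign))
    Q[cbind(assign, seq_along(assign))] <- 1
    Q
}

## A small connected signed network written by hand.
tinyNet <- function() {
    SignedNetwork(
        nodes = c("A", "B", "C", "D", "E"),
        edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5), c(2, 5)),
        weights = c(1L, -2L, 1L, 3L, -1L, 2L))
}

## Random valid ModelParams.
randomParams <- function(N, Kpos, Kneg = Kpos, seed = 1, sd = 1) {
    set.seed(seed)
    new("ModelParams",
        Zlogits = matrix(rnorm(Kpos * N, 0, sd), Kpos, N),
        Wlogits = matrix(rnorm(Kneg * N, 0, sd), Kneg, N),
        gamma = rnorm(N, 0, 0.3),
        delta = rnorm(N, 0, 0.3),
        Rpos = diag(Kpos) + matrix(rnorm(Kpos^2, 0, 0.1), Kpos, Kpos),
        Rneg = diag(Kneg) + matrix(rnorm(Kneg^2, 0, 0.1), Kneg, Kneg),
        Gpos = matrix(rnorm(Kpos * N, 0, sd), Kpos, N),
        Gneg = matrix(rnorm(Kneg * N, 0, sd), Kneg, N))
}

## Central finite-difference gradient of the NLL for one parameter block.
numericBlockGrad <- function(params, net, block, h = 1e-6) {
    x <- slot(params, block)
    g <- x * 0
    for (idx in seq_along(x)) {
        p1 <- params; p2 <- params
        v <- x; v[idx] <- v[idx] + h; slot(p1, block) <- v
        v <- x; v[idx] <- v[idx] - h; slot(p2, block) <- v
        g[idx] <- (skellamNll(p1, net) - skellamNll(p2, net)) / (2 * h)
    }
    g
}

## Write lines to a temp file and return its path.
tmpFile <- function(lines, ext = ".tsv") {
    path <- tempfile(fileext = ext)
    writeLines(lines, path)
    path
}

## Small fit configuration used across tests to keep runtimes short.
quickFit <- function(epochs = 150, polish = 60, ...) {
    fitControl(epochs = epochs, polishEpochs = polish, ...)
}
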