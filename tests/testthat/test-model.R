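test_that("memberships are columnwise softmax with shift invariance", {
    p <- randomParams(N = 6, Kpos = 4, seed = 11)
    p@Zlogits[, 1] <- 0
    m <- memberships(p)
    expect_equal(m$Z[, 1], rep(0.25, 4))
    expect_equal(colSums(m$Z), rep(1, 6))
    expect_equal(colSums(m$W), rep(1, 6))

    shifted <- p
    shifted@Zlogits[, 2] <- shifted@Zlogits[, 2] + 5
    expect_equal(memberships(shifted)$Z[, 2], m$Z[, 2])

    p@Zlogits[1:2, 3] <- log(c(1, 3))
    p@Zlogits[3:4, 3] <- -1e3
    expect_equal(memberships(p)$Z[1:2, 3], c(0.25, 0.75), tolerance = 1e-9)
})

test_that("gated coefficient matrix is normalized and honours the gates", {
    M <- cbind(c(0.8, 0.2), c(0.4, 0.6))
    G <- matrix(0, 2, 2)
    C <- gatedC(M, G)
    expect_equal(dim(C), c(2L, 2L))
    expect_equal(colSums(C), c(1, 1))
    ## sigma(0) = 1/2 cancels in the ratio: archetype 1 column = (2/3, 1/3)
    expect_equal(C[, 1], c(0.8, 0.4) / 1.2)

    ## saturated gates reduce to membership-share weights
    Cinf <- gatedC(M, matrix(50, 2, 2))
    expect_equal(Cinf[, 1], c(0.8, 0.4) / 1.2)
    expect_equal(Cinf[, 2], c(0.2, 0.6) / 0.8)

    set.seed(5)
    Mr <- randomMembership(3, 10, seed = 5)
    Cr <- gatedC(Mr, matrix(rnorm(30), 3, 10))
    expect_true(all(Cr >= 0))
    expect_lt(max(abs(colSums(Cr) - 1)), 1e-12)

    expect_error(gatedC(matrix(c(1, 0, 0, 1), 2), matrix(-800, 2, 2)),
                 "re-initialize")
})

test_that("archetypes compose as A = R Z C and stay in the hull", {
    ## hard memberships with identity R and saturated gates: A = identity
    N <- 3; K <- 3
    p <- randomParams(N, K, seed = 2)
    p@Zlogits <- 60 * diag(K)[, 1:N]
    p@Rpos <- diag(K)
    p@Gpos <- matrix(8, K, N)
    sol <- archetypes(p)
    expect_equal(sol@Apos, diag(K), tolerance = 1e-6)
    expect_true(validObject(sol))

    ## direct matrix arithmetic on a small numeric case
    p2 <- randomParams(N = 3, Kpos = 2, seed = 9)
    m <- memberships(p2)
    C <- gatedC(m$Z, p2@Gpos)
    expect_equal(archetypes(p2)@Apos, p2@Rpos %*% m$Z %*% C)

    ## each archetype is R times a convex combination of membership columns
    comb <- m$Z %*% C
    expect_true(all(comb >= -1e-12))
    expect_equal(colSums(comb), rep(1, 2))
})

test_that("pair rates follow the exponential latent-distance form", {
    N <- 4; K <- 2
    p <- randomParams(N, K, seed = 3)
    p@Zlogits[, 2] <- p@Zlogits[, 1]   # z_1 = z_2
    p@gamma[1:2] <- 0
    r <- pairRates(p, 1, 2)
    expect_equal(r$lambdaPos, 1)

    p@gamma[1] <- 1; p@gamma[2] <- -1  # offsets cancel
    expect_equal(pairRates(p, 1, 2)$lambdaPos, 1)

    ## hand evaluation: distance sqrt(2) between opposite corners under A = I
    ph <- randomParams(N = 2, Kpos = 2, seed = 4)
    ph@Zlogits <- cbind(c(60, -60), c(-60, 60))
    ph@Rpos <- diag(2)
    ph@Gpos <- matrix(8, 2, 2)
    ph@gamma[] <- 0
    expect_equal(pairRates(ph, 1, 2)$lambdaPos, exp(-sqrt(2)),
                 tolerance = 1e-6)

    expect_error(pairRates(p, 1, 1), "i == j")
    expect_error(pairRates(p, 1, 99), "out of range")

    ## batched variant agrees with the scalar one and is symmetric
    rm <- rateMatrices(p)
    expect_equal(rm$lambdaPos, t(rm$lambdaPos))
    expect_equal(rm$lambdaPos[3, 4], pairRates(p, 3, 4)$lambdaPos)
})

test_that("rate monotonicity: raising gamma_i scales lambda+ only", {
    p <- randomParams(N = 5, Kpos = 2, seed = 6)
    r0 <- rateMatrices(p)
    p2 <- p
    p2@gamma[2] <- p2@gamma[2] + 0.7
    r1 <- rateMatrices(p2)
    others <- setdiff(1:5, 2)
    expect_true(all(r1$lambdaPos[2, others] > r0$lambdaPos[2, others]))
    expect_equal(r1$lambdaNeg, r0$lambdaNeg)
})

test_that("nll equals the pairwise Skellam sum over all dyads", {
    truth <- makePlantedParams(N = 10, Kpos = 2, Kneg = 2, seed = 21,
                               separation = 3, effectScale = 0.3)
    net <- sampleNetwork(truth, seed = 22)$network
    p <- randomParams(nNodes(net), 2, seed = 23)
    Y <- adjacencyMatrix(net)
    direct <- 0
    for (i in 1:(nNodes(net) - 1)) for (j in (i + 1):nNodes(net)) {
        r <- pairRates(p, i, j)
        direct <- direct - skellamLogPmf(Y[i, j], r$lambdaPos, r$lambdaNeg)
    }
    expect_equal(skellamNll(p, net), direct, tolerance = 1e-9)

    ## rates driven to zero on an empty network: nll -> 0
    empty <- SignedNetwork(letters[1:6], rbind(c(1, 2)), 1L)
    empty@edges <- matrix(integer(0), 0, 2)
    empty@weights <- integer(0)
    pe <- randomParams(6, 2, seed = 24)
    pe@gamma[] <- -20
    pe@delta[] <- -20
    expect_lt(skellamNll(pe, empty), 1e-6)

    expect_error(skellamNll(randomParams(4, 2, seed = 1), net), "disagree")
})

test_that("analytic gradient matches central differences on all blocks", {
    truth <- makePlantedParams(N = 6, Kpos = 2, Kneg = 2, seed = 31,
                               separation = 3, effectScale = 0.6)
    net <- sampleNetwork(truth, seed = 32)$network
    p <- randomParams(nNodes(net), 2, seed = 45)
    an <- nllGradient(p, net)
    for (block in names(an)) {
        fd <- numericBlockGrad(p, net, block)
        rel <- sqrt(sum((fd - an[[block]])^2)) /
            max(sqrt(sum(an[[block]]^2)), 1e-12)
        expect_lt(rel, 1e-5)
    }
})

test_that("likelihood symmetry under space swap with negated weights", {
    truth <- makePlantedParams(N = 12, Kpos = 2, Kneg = 2, seed = 41,
                               separation = 3, effectScale = 0.4)
    net <- sampleNetwork(truth, seed = 42)$network
    p <- randomParams(nNodes(net), 2, seed = 43)
    swapped <- new("ModelParams",
        Zlogits = p@Wlogits, Wlogits = p@Zlogits,
        gamma = p@delta, delta = p@gamma,
        Rpos = p@Rneg, Rneg = p@Rpos,
        Gpos = p@Gneg, Gneg = p@Gpos)
    neg <- SignedNetwork(nodeLabels(net), net@edges, -net@weights)
    expect_equal(skellamNll(p, net), skellamNll(swapped, neg),
                 tolerance = 1e-9)
})

test_that("nll is invariant to archetype relabelling", {
    truth <- makePlantedParams(N = 10, Kpos = 3, Kneg = 3, seed = 51,
                               separation = 3, effectScale = 0.4)
    net <- sampleNetwork(truth, seed = 52)$network
    p <- randomParams(nNodes(net), 3, seed = 53)
    perm <- c(3, 1, 2)
    p2 <- p
    p2@Zlogits <- p@Zlogits[perm, ]
    p2@Gpos <- p@Gpos[perm, ]
    p2@Rpos <- p@Rpos[, perm]
    expect_equal(skellamNll(p, net), skellamNll(p2, net), tolerance = 1e-9)
})

test_that("fitting is deterministic given the seed and decreases the nll", {
    truth <- makePlantedParams(N = 40, Kpos = 2, Kneg = 2, seed = 61)
    net <- sampleNetwork(truth, seed = 62)$network
    f1 <- fitSignedArchetypes(net, 2, 2, control = quickFit(40, 20), seed = 9)
    f2 <- fitSignedArchetypes(net, 2, 2, control = quickFit(40, 20), seed = 9)
    expect_identical(f1@trace, f2@trace)
    expect_identical(f1@params@Zlogits, f2@params@Zlogits)
    n <- length(f1@trace)
    expect_lt(skellamNll(f1@params, net), f1@trace[1])
})

test_that("simplex structure survives fitting", {
    truth <- makePlantedParams(N = 40, Kpos = 2, Kneg = 2, seed = 71)
    net <- sampleNetwork(truth, seed = 72)$network
    fit <- fitSignedArchetypes(net, 2, 2, control = quickFit(80, 40),
                               seed = 5)
    sol <- fit@solution
    for (M in list(sol@Z, sol@W, sol@Cpos, sol@Cneg)) {
        expect_true(all(M >= -1e-9))
        expect_lt(max(abs(colSums(M) - 1)), 1e-9)
    }
})

test_that("single-archetype fit reduces to a random-effects model", {
    truth <- makePlantedParams(N = 15, Kpos = 1, Kneg = 1, seed = 81,
                               cornerFraction = 1, effectScale = 0.3)
    net <- sampleNetwork(truth, seed = 82)$network
    fit <- fitSignedArchetypes(net, 1, 1,
        control = fitControl(epochs = 2500, canonicalize = FALSE), seed = 4)
    n <- nNodes(net)
    Y <- adjacencyMatrix(net)
    pidx <- which(upper.tri(Y))
    ii <- ((pidx - 1) %% n) + 1
    jj <- ((pidx - 1) %/% n) + 1
    obj <- function(th) {
        g <- th[1:n]; d <- th[(n + 1):(2 * n)]
        -sum(skellamLogPmf(Y[pidx], exp(g[ii] + g[jj]), exp(d[ii] + d[jj])))
    }
    oracle <- optim(rep(0, 2 * n), obj, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-12))
    expect_equal(min(fit@trace), oracle$value, tolerance = 1e-3)
})

test_that("node-archetype distances live in the likelihood geometry", {
    p <- randomParams(N = 3, Kpos = 2, seed = 91)
    sol <- archetypes(p)
    D <- nodeArchetypeDistance(sol, "pos")
    expect_equal(dim(D), c(3L, 2L))
    expect_true(all(D >= 0))
    ## direct arithmetic
    X <- sol@Apos %*% sol@Z
    expect_equal(D[2, 1], sqrt(sum((X[, 2] - sol@Apos[, 1])^2)))

    ## a pure corner node sits exactly on its archetype
    ph <- randomParams(N = 3, Kpos = 2, seed = 92)
    ph@Zlogits[, 1] <- c(80, -80)
    solh <- archetypes(ph)
    expect_lt(nodeArchetypeDistance(solh, "pos", i = 1, k = 1)
              - 0, 1e-6)
    expect_error(nodeArchetypeDistance(sol, "pos", i = 10), "out of range")
})

test_that("node-subsampled fitting runs deterministically and improves the fit", {
    truth <- makePlantedParams(N = 50, Kpos = 2, Kneg = 2, seed = 95)
    net <- sampleNetwork(truth, seed = 96)$network
    ctl <- fitControl(epochs = 120, polishEpochs = 40,
                      subsampleThreshold = 20L, nodeSubsample = 25L)
    f1 <- fitSignedArchetypes(net, 2, 2, control = ctl, seed = 3)
    f2 <- fitSignedArchetypes(net, 2, 2, control = ctl, seed = 3)
    expect_identical(f1@trace, f2@trace)
    set.seed(3)
    init <- SignedArchetypes:::.initParams(net, 2L, 2L, ctl)
    expect_lt(skellamNll(f1@params, net), skellamNll(init, net))
})

test_that("divergent configurations raise errors", {
    net <- tinyNet()
    expect_error(fitSignedArchetypes(net, 0, 1), "Kpos")
    expect_error(fitSignedArchetypes(net, 9, 9), "as many nodes")
})
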