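#' Gated archetype coefficient matrix
#'
#' Builds the coefficient matrix that expresses every archetype as a convex
#' combination of node latent positions: entries are membership-weighted,
#' sigmoid-gated and column-normalized,
#' \deqn{C_{nd} = M_{dn}\,\sigma(G_{dn}) \big/ \sum_{n'} M_{dn'}\,\sigma(G_{dn'}).}
#' The gates let the model concentrate an archetype on few extreme nodes
#' without leaving the convex hull of the embeddings.
#'
#' @param M K x N membership matrix, columns on the simplex.
#' @param G K x N gate logits.
#' @return N x K matrix with nonnegative entries whose columns sum to one.
#' @export
gatedC <- function(M, G) {
    if (!identical(dim(M), dim(G)))
        stop("membership and gate matrices must share dimensions")
    err <- .checkSimplexCols(M, "membership matrix", tol = 1e-6)
    if (!is.null(err)) stop(err)
    Tm <- M * stats::plogis(G)
    s <- rowSums(Tm)
    if (any(s < 1e-300))
        stop("all memberships for an archetype are numerically zero; ",
             "re-initialize the parameters")
    t(Tm / s)
}

## Forward pass for one latent space; returns everything the backward pass
## reuses.
.spaceForward <- function(logits, gate, R) {
    Z <- .softmaxCols(logits)
    sig <- stats::plogis(gate)
    Tm <- Z * sig
    s <- rowSums(Tm)
    if (any(s < 1e-300))
        stop("all memberships for an archetype are numerically zero; ",
             "re-initialize the parameters")
    Ct <- Tm / s                 # K x N, = t(C)
    P <- tcrossprod(Z, Ct)       # Z %*% C, K x K
    A <- R %*% P
    X <- A %*% Z
    list(Z = Z, sig = sig, s = s, Ct = Ct, P = P, A = A, X = X)
}

#' @rdname memberships
#' @export
setMethod("memberships", "ModelParams", function(object) {
    list(Z = .softmaxCols(object@Zlogits), W = .softmaxCols(object@Wlogits))
})

#' @rdname memberships
#' @export
setMethod("memberships", "FittedModel", function(object)
    memberships(object@params))

#' @rdname memberships
#' @export
setMethod("memberships", "PlantedTruth", function(object)
    memberships(object@params))

#' @rdname archetypes
#' @export
setMethod("archetypes", "ModelParams", function(object) {
    fp <- .spaceForward(object@Zlogits, object@Gpos, object@Rpos)
    fn <- .spaceForward(object@Wlogits, object@Gneg, object@Rneg)
    new("ArchetypeSolution",
        Z = fp$Z, W = fn$Z,
        Cpos = t(fp$Ct), Cneg = t(fn$Ct),
        Apos = fp$A, Aneg = fn$A)
})

#' @rdname archetypes
#' @export
setMethod("archetypes", "FittedModel", function(object) object@solution)

#' @rdname archetypes
#' @export
setMethod("archetypes", "PlantedTruth", function(object) object@solution)

setMethod("nNodes", "ModelParams", function(x) ncol(x@Zlogits))

setMethod("show", "ModelParams", function(object) {
    cat(sprintf("ModelParams: N = %d, Kpos = %d, Kneg = %d\n",
                ncol(object@Zlogits), nrow(object@Zlogits),
                nrow(object@Wlogits)))
})

setMethod("show", "ArchetypeSolution", function(object) {
    cat(sprintf("ArchetypeSolution: N = %d, Kpos = %d, Kneg = %d\n",
                ncol(object@Z), nrow(object@Z), nrow(object@W)))
})

setMethod("show", "FittedModel", function(object) {
    cat(sprintf(
        "FittedModel: N = %d, Kpos = %d, Kneg = %d, %d epochs, final NLL %.4f\n",
        ncol(object@params@Zlogits), nrow(object@params@Zlogits),
        nrow(object@params@Wlogits), length(object@trace),
        object@trace[length(object@trace)]))
})

#' Skellam rates for node pairs
#'
#' The positive-interaction rate for a dyad is
#' \deqn{\lambda^+_{ij} = \exp(\gamma_i + \gamma_j - \|A^{(+)}(z_i - z_j)\|_2)}
#' and analogously for the negative rate with `delta`, `Aneg` and `w`;
#' the norm is the unsquared Euclidean distance, so the rates are symmetric
#' in `(i, j)` and decay with latent distance.
#'
#' @param params a [ModelParams-class].
#' @param i,j node index vectors of equal length, `i != j` elementwise.
#' @return data.frame with columns `lambdaPos`, `lambdaNeg`.
#' @seealso [rateMatrices()] for the all-pairs batched variant.
#' @export
pairRates <- function(params, i, j) {
    stopifnot(is(params, "ModelParams"))
    if (length(i) != length(j)) stop("i and j must have equal length")
    n <- nNodes(params)
    if (any(i < 1 | i > n | j < 1 | j > n)) stop("node index out of range")
    if (any(i == j)) stop("rates are undefined for i == j")
    fp <- .spaceForward(params@Zlogits, params@Gpos, params@Rpos)
    fn <- .spaceForward(params@Wlogits, params@Gneg, params@Rneg)
    dp <- sqrt(pmax(colSums((fp$X[, i, drop = FALSE] -
                             fp$X[, j, drop = FALSE])^2), 0))
    dn <- sqrt(pmax(colSums((fn$X[, i, drop = FALSE] -
                             fn$X[, j, drop = FALSE])^2), 0))
    data.frame(
        lambdaPos = exp(params@gamma[i] + params@gamma[j] - dp),
        lambdaNeg = exp(params@delta[i] + params@delta[j] - dn)
    )
}

#' All-pairs Skellam rate matrices
#'
#' @param params a [ModelParams-class].
#' @return list with N x N symmetric matrices `lambdaPos` and `lambdaNeg`
#'   (diagonal set to zero; self-rates are not defined by the model).
#' @export
rateMatrices <- function(params) {
    stopifnot(is(params, "ModelParams"))
    fp <- .spaceForward(params@Zlogits, params@Gpos, params@Rpos)
    fn <- .spaceForward(params@Wlogits, params@Gneg, params@Rneg)
    lp <- exp(outer(params@gamma, params@gamma, "+") - .pairDist(fp$X))
    ln <- exp(outer(params@delta, params@delta, "+") - .pairDist(fn$X))
    diag(lp) <- 0
    diag(ln) <- 0
    list(lambdaPos = lp, lambdaNeg = ln)
}

#' Latent distance between a node and an archetype
#'
#' Distances are measured in the exact geometry the likelihood uses: node
#' `i` sits at `A m_i` (its membership column mapped through the archetype
#' matrix) and archetype `k` at the k-th column of `A`.
#'
#' @param sol an [ArchetypeSolution-class].
#' @param space `"pos"` or `"neg"`.
#' @param i node indices (default all nodes).
#' @param k archetype indices (default all archetypes).
#' @return matrix of distances, nodes in rows, archetypes in columns (drops
#'   to a vector/scalar for single indices).
#' @export
nodeArchetypeDistance <- function(sol, space = c("pos", "neg"), i = NULL,
                                  k = NULL) {
    stopifnot(is(sol, "ArchetypeSolution"))
    space <- match.arg(space)
    M <- if (space == "pos") sol@Z else sol@W
    A <- if (space == "pos") sol@Apos else sol@Aneg
    n <- ncol(M)
    K <- ncol(A)
    if (is.null(i)) i <- seq_len(n)
    if (is.null(k)) k <- seq_len(K)
    if (any(i < 1 | i > n) || any(k < 1 | k > K))
        stop("index out of range")
    X <- A %*% M[, i, drop = FALSE]               # K x |i|
    Ak <- A[, k, drop = FALSE]                    # K x |k|
    d2 <- outer(colSums(X^2), colSums(Ak^2), "+") - 2 * crossprod(X, Ak)
    D <- sqrt(pmax(d2, 0))
    dimnames(D) <- NULL
    drop(D)
}

## Skellam pair terms used by the objective and its gradient. Works on
## vectors over (a subset of) unordered pairs; y may be any integer.
## Returns the NLL contribution plus h+ = lambda+ * dNLL/dlambda+ and the
## analogous h- (the quantities the backward pass needs).
.skellamPairTerms <- function(y, etaP, etaN, computeGrad = TRUE) {
    lamP <- exp(etaP)
    lamN <- exp(etaN)
    u <- 2 * sqrt(lamP * lamN)
    ay <- abs(y)
    logI <- numeric(length(y))
    ratio <- numeric(length(y))
    ## small-argument fast path for the dominant zero-weight pairs: the
    ## leading series terms of I_0 and I_1/I_0 are exact to ~5e-10 for u < 1
    fast <- ay == 0L & u < 1
    if (any(fast)) {
        q <- (u[fast] / 2)^2
        i0 <- 1 + q * (1 + q * (0.25 + q * (1 / 36 +
            q * (1 / 576 + q / 14400))))
        logI[fast] <- log(i0)
        if (computeGrad) {
            i1 <- (u[fast] / 2) * (1 + q * (0.5 + q * (1 / 12 +
                q * (1 / 144 + q / 2880))))
            ratio[fast] <- i1 / i0
        }
    }
    slow <- which(!fast)
    if (length(slow)) {
        aySlow <- ay[slow]
        for (a in unique(aySlow)) {
            sel <- slow[aySlow == a]
            logI[sel] <- .logBesselI(a, u[sel])
            if (computeGrad) ratio[sel] <- .besselIRatio(a, u[sel])
        }
    }
    nll <- sum(lamP + lamN - (y / 2) * (etaP - etaN) - logI)
    out <- list(nll = nll)
    if (computeGrad) {
        common <- ratio * u / 2
        out$hP <- lamP - pmax(y, 0) - common
        out$hN <- lamN - pmax(-y, 0) - common
    }
    out
}

## Backward pass through one latent space. GX is the K x N gradient of the
## objective with respect to the latent coordinates X = A Z; H is the
## symmetric N x N matrix of h terms. Returns gradients for the logits,
## gates, R and the random effects.
.spaceBackward <- function(fw, R, GX, H) {
    K <- nrow(fw$Z)
    N <- ncol(fw$Z)
    GA <- tcrossprod(GX, fw$Z)            # X = A Z
    GZ <- crossprod(fw$A, GX)
    GR <- tcrossprod(GA, fw$P)            # A = R P
    GP <- crossprod(R, GA)
    GZ <- GZ + GP %*% fw$Ct               # P = Z C, t(C) = Ct
    GCt <- crossprod(GP, fw$Z)            # t(GC) where GC = t(Z) GP
    GT <- (GCt - rowSums(GCt * fw$Ct)) / fw$s
    GZ <- GZ + GT * fw$sig
    Ggate <- GT * fw$Z * fw$sig * (1 - fw$sig)
    Glogits <- fw$Z * (GZ - matrix(colSums(GZ * fw$Z), K, N, byrow = TRUE))
    list(logits = Glogits, gate = Ggate, R = GR, effects = rowSums(H))
}

## Full objective and gradient on a node subset (sel = indices used; the
## scale factor reweights a subsampled objective so its expectation matches
## the full pair sum).
.objective <- function(params, Y, sel = NULL, scale = 1, computeGrad = TRUE,
                       cache = NULL) {
    full <- is.null(sel)
    if (full) sel <- seq_len(ncol(params@Zlogits))
    S <- length(sel)
    fp <- .spaceForward(params@Zlogits[, sel, drop = FALSE],
                        params@Gpos[, sel, drop = FALSE], params@Rpos)
    fn <- .spaceForward(params@Wlogits[, sel, drop = FALSE],
                        params@Gneg[, sel, drop = FALSE], params@Rneg)
    gam <- params@gamma[sel]
    del <- params@delta[sel]
    pi <- if (!is.null(cache) && full) cache$pidx else .pairIndex(S)
    dP <- .pairDist(fp$X)
    dN <- .pairDist(fn$X)
    etaP <- gam[pi$i] + gam[pi$j] - dP[pi$idx]
    etaN <- del[pi$i] + del[pi$j] - dN[pi$idx]
    y <- if (!is.null(cache) && full) cache$y
         else Y[sel, sel, drop = FALSE][pi$idx]
    st <- .skellamPairTerms(y, etaP, etaN, computeGrad = computeGrad)
    out <- list(nll = scale * st$nll)
    if (!computeGrad) return(out)

    backOne <- function(fw, h, d, R) {
        H <- matrix(0, S, S)
        H[pi$idx] <- h
        H <- H + t(H)
        Mv <- h / pmax(d, 1e-9)
        Mv[d <= 1e-9] <- 0
        Mm <- matrix(0, S, S)
        Mm[pi$idx] <- Mv
        Mm <- Mm + t(Mm)
        GX <- fw$X %*% Mm -
            fw$X * matrix(colSums(Mm), nrow(fw$X), S, byrow = TRUE)
        .spaceBackward(fw, R, GX, H)
    }
    bp <- backOne(fp, st$hP, dP[pi$idx], params@Rpos)
    bn <- backOne(fn, st$hN, dN[pi$idx], params@Rneg)

    expand <- function(Gsub, K, N) {
        G <- matrix(0, K, N)
        G[, sel] <- Gsub * scale
        G
    }
    N <- ncol(params@Zlogits)
    gGamma <- numeric(N); gGamma[sel] <- bp$effects * scale
    gDelta <- numeric(N); gDelta[sel] <- bn$effects * scale
    out$grad <- list(
        Zlogits = expand(bp$logits, nrow(params@Zlogits), N),
        Wlogits = expand(bn$logits, nrow(params@Wlogits), N),
        gamma = gGamma,
        delta = gDelta,
        Rpos = bp$R * scale,
        Rneg = bn$R * scale,
        Gpos = expand(bp$gate, nrow(params@Gpos), N),
        Gneg = expand(bn$gate, nrow(params@Gneg), N)
    )
    out
}

#' Skellam negative log-likelihood of a parameter set on a network
#'
#' Sums `-log P(y_ij | lambda+_ij, lambda-_ij)` over all `N(N-1)/2`
#' unordered pairs, with `y_ij = 0` for non-edges, so absent interactions
#' inform the fit exactly as observed zeros.
#'
#' @param params a [ModelParams-class].
#' @param net a [SignedNetwork-class] on the same node set.
#' @return scalar negative log-likelihood.
#' @export
skellamNll <- function(params, net) {
    stopifnot(is(params, "ModelParams"), is(net, "SignedNetwork"))
    if (nNodes(net) != nNodes(params))
        stop("params and network disagree on the number of nodes")
    .objective(params, adjacencyMatrix(net), computeGrad = FALSE)$nll
}

#' Analytic gradient of the Skellam negative log-likelihood
#'
#' @param params a [ModelParams-class].
#' @param net a [SignedNetwork-class] on the same node set.
#' @return named list of gradients matching the parameter blocks
#'   (`Zlogits`, `Wlogits`, `gamma`, `delta`, `Rpos`, `Rneg`, `Gpos`,
#'   `Gneg`).
#' @export
nllGradient <- function(params, net) {
    stopifnot(is(params, "ModelParams"), is(net, "SignedNetwork"))
    if (nNodes(net) != nNodes(params))
        stop("params and network disagree on the number of nodes")
    .objective(params, adjacencyMatrix(net), computeGrad = TRUE)$grad
}

#' Optimizer settings for [fitSignedArchetypes()]
#'
#' First-order adaptive-moment (Adam) gradient descent on the exact
#' all-pairs objective; for networks above `subsampleThreshold` nodes an
#' unbiased node-subsampled objective is used instead (all pairs within a
#' random node sample, rescaled by `N(N-1)/(S(S-1))`).
#'
#' @param epochs number of gradient steps.
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment and stabilisation constants.
#' @param nodeSubsample nodes sampled per step when subsampling (default
#'   1000).
#' @param subsampleThreshold network size above which subsampling kicks in.
#' @param init `"cluster"` (default) warm-starts membership logits from a
#'   modularity clustering of the positive/negative subgraphs; `"random"`
#'   draws them from noise.
#' @param initSd standard deviation of the logit/gate initialisation noise.
#' @param initRSd standard deviation of the perturbation of the identity
#'   initialisation of `Rpos`/`Rneg`.
#' @param canonicalize whether to re-express the fit in the canonical
#'   archetypal frame (archetypes anchored at the extreme fitted latent
#'   profiles) and polish; see [fitSignedArchetypes()].
#' @param polishEpochs gradient steps of the post-canonicalization polish.
#' @return list of settings.
#' @export
fitControl <- function(epochs = 3000L, lr = 0.05, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, nodeSubsample = 1000L,
                       subsampleThreshold = 2000L, init = "cluster",
                       initSd = 0.1, initRSd = 0.01, canonicalize = TRUE,
                       polishEpochs = 300L) {
    list(epochs = as.integer(epochs), lr = lr, beta1 = beta1, beta2 = beta2,
         eps = eps, nodeSubsample = as.integer(nodeSubsample),
         subsampleThreshold = as.integer(subsampleThreshold),
         init = match.arg(init, c("cluster", "random")),
         initSd = initSd, initRSd = initRSd,
         canonicalize = isTRUE(canonicalize),
         polishEpochs = as.integer(polishEpochs))
}

## Warm-start membership logits: agglomerative modularity clustering of the
## positive (resp. negative) subgraph; every detected community receives a
## shared random simplex profile, so tightly knit groups start collapsed in
## the latent space and the descent phase mainly arranges them. Falls back
## to pure noise on failure.
.clusterInitLogits <- function(net, K, positive, control) {
    N <- nNodes(net)
    logits <- matrix(stats::rnorm(K * N, 0, control$initSd), K, N)
    grp <- tryCatch({
        sel <- if (positive) net@weights > 0 else net@weights < 0
        g <- igraph::make_graph(t(net@edges[sel, , drop = FALSE]), n = N,
                                directed = FALSE)
        igraph::E(g)$weight <- abs(net@weights[sel])
        as.integer(igraph::membership(igraph::cluster_fast_greedy(g)))
    }, error = function(e) NULL)
    if (!is.null(grp)) {
        nGrp <- max(grp)
        profiles <- matrix(stats::rgamma(K * nGrp, 0.5) + 1e-3, K, nGrp)
        profiles <- sweep(profiles, 2, colSums(profiles), "/")
        ## the K largest communities anchor distinct corners, so clearly
        ## separated blocks cannot start on top of each other
        bySize <- order(tabulate(grp, nGrp), decreasing = TRUE)
        for (k in seq_len(min(K, nGrp))) {
            p <- rep(0.1 / max(K - 1, 1), K)
            p[k] <- 0.9
            profiles[, bySize[k]] <- p
        }
        logits <- logits + 2 * log(profiles)[, grp, drop = FALSE]
    }
    logits
}

.initParams <- function(net, Kpos, Kneg, control) {
    N <- nNodes(net)
    zl <- if (identical(control$init, "cluster"))
        .clusterInitLogits(net, Kpos, TRUE, control)
    else matrix(stats::rnorm(Kpos * N, 0, control$initSd), Kpos, N)
    wl <- if (identical(control$init, "cluster"))
        .clusterInitLogits(net, Kneg, FALSE, control)
    else matrix(stats::rnorm(Kneg * N, 0, control$initSd), Kneg, N)
    new("ModelParams",
        Zlogits = zl,
        Wlogits = wl,
        gamma = rep(0, N),
        delta = rep(0, N),
        Rpos = diag(Kpos) + matrix(stats::rnorm(Kpos^2, 0, control$initRSd),
                                   Kpos, Kpos),
        Rneg = diag(Kneg) + matrix(stats::rnorm(Kneg^2, 0, control$initRSd),
                                   Kneg, Kneg),
        Gpos = matrix(stats::rnorm(Kpos * N, 0, control$initSd), Kpos, N),
        Gneg = matrix(stats::rnorm(Kneg * N, 0, control$initSd), Kneg, N))
}

## Columnwise Euclidean projection onto the probability simplex.
.projSimplexCols <- function(M) {
    K <- nrow(M)
    u <- apply(M, 2, sort, decreasing = TRUE)
    if (is.null(dim(u))) u <- matrix(u, nrow = K)
    css <- apply(u, 2, cumsum)
    if (is.null(dim(css))) css <- matrix(css, nrow = K)
    cond <- u + (1 - css) / seq_len(K) > 0
    rho <- colSums(cond)
    theta <- (css[cbind(rho, seq_len(ncol(M)))] - 1) / rho
    pmax(sweep(M, 2, theta, "-"), 0)
}

## min ||A Z - X||^2 columnwise over simplex columns of Z by projected
## gradient with a shared Lipschitz step.
.simplexLSCols <- function(A, X, Z0, iters = 40) {
    Z <- Z0
    L <- max(eigen(crossprod(A), only.values = TRUE)$values) + 1e-12
    for (it in seq_len(iters)) {
        G <- crossprod(A, A %*% Z - X)
        Z <- .projSimplexCols(Z - G / L)
    }
    Z
}

## Classical archetypal decomposition X ~ (X C) Z of the fitted latent
## positions, warm-started from the fitted C and Z; the canonical
## representative of the likelihood-equivalent solution family.
.positionAA <- function(X, C0, Z0, iters = 12) {
    C <- C0
    Z <- Z0
    XtX <- crossprod(X)
    lX <- max(eigen(XtX, only.values = TRUE)$values) + 1e-12
    for (it in seq_len(iters)) {
        A <- X %*% C
        Z <- .simplexLSCols(A, X, Z)
        lZ <- max(eigen(tcrossprod(Z), only.values = TRUE)$values) + 1e-12
        for (inner in 1:6) {
            G <- XtX %*% (C %*% Z - diag(ncol(X))) %*% t(Z)
            C <- .projSimplexCols(C - G / (lX * lZ))
        }
    }
    list(A = X %*% C, Z = Z, C = C)
}

## Re-express the fitted parameters in the canonical archetypal frame:
## archetypes re-anchored at the extreme points of the hull of the fitted
## latent positions, memberships as the simplex coordinates in that frame.
## The rates, and hence the likelihood, are unchanged up to the small hull
## reconstruction error, which the subsequent polish phase re-minimises.
.canonicalizeParams <- function(params) {
    oneSpace <- function(logits, gate, R) {
        fw <- .spaceForward(logits, gate, R)
        aa <- .positionAA(fw$X, t(fw$Ct), fw$Z)
        Zc <- pmax(aa$Z, 1e-8)
        Zc <- sweep(Zc, 2, colSums(Zc), "/")
        logitsC <- log(Zc)
        fw2 <- .spaceForward(logitsC, gate, R)
        K <- nrow(logits)
        Rc <- aa$A %*% solve(fw2$P + 1e-8 * diag(K))
        list(logits = logitsC, R = Rc)
    }
    cp <- oneSpace(params@Zlogits, params@Gpos, params@Rpos)
    cn <- oneSpace(params@Wlogits, params@Gneg, params@Rneg)
    new("ModelParams",
        Zlogits = cp$logits, Wlogits = cn$logits,
        gamma = params@gamma, delta = params@delta,
        Rpos = cp$R, Rneg = cn$R,
        Gpos = params@Gpos, Gneg = params@Gneg)
}

## Adaptive-moment descent on the pair objective; returns the best-seen
## parameters together with the per-epoch trace.
.adamLoop <- function(params, Y, epochs, lr, control) {
    theta <- .paramList(params)
    m <- lapply(theta, function(x) x * 0)
    v <- m
    N <- ncol(params@Zlogits)
    subsampling <- N > control$subsampleThreshold &&
        control$nodeSubsample < N
    S <- control$nodeSubsample
    scale <- if (subsampling) (N * (N - 1)) / (S * (S - 1)) else 1
    trace <- numeric(epochs)
    best <- list(nll = Inf, theta = theta)
    pidx <- .pairIndex(N)
    cache <- list(pidx = pidx, y = Y[pidx$idx])
    for (ep in seq_len(epochs)) {
        sel <- if (subsampling) sample.int(N, S) else NULL
        ob <- .objective(.fromParamList(theta), Y, sel = sel, scale = scale,
                         cache = cache)
        if (!is.finite(ob$nll))
            stop(sprintf("optimization diverged at epoch %d", ep))
        trace[ep] <- ob$nll
        if (ob$nll < best$nll) best <- list(nll = ob$nll, theta = theta)
        corr1 <- 1 - control$beta1^ep
        corr2 <- 1 - control$beta2^ep
        for (nm in names(theta)) {
            g <- ob$grad[[nm]]
            m[[nm]] <- control$beta1 * m[[nm]] + (1 - control$beta1) * g
            v[[nm]] <- control$beta2 * v[[nm]] + (1 - control$beta2) * g^2
            theta[[nm]] <- theta[[nm]] - lr * (m[[nm]] / corr1) /
                (sqrt(v[[nm]] / corr2) + control$eps)
        }
    }
    final <- .objective(.fromParamList(theta), Y, computeGrad = FALSE)$nll
    if (is.finite(final) && final <= best$nll)
        best <- list(nll = final, theta = theta)
    list(params = .fromParamList(best$theta), trace = trace, nll = best$nll)
}

.paramList <- function(p)
    list(Zlogits = p@Zlogits, Wlogits = p@Wlogits, gamma = p@gamma,
         delta = p@delta, Rpos = p@Rpos, Rneg = p@Rneg, Gpos = p@Gpos,
         Gneg = p@Gneg)

.fromParamList <- function(l)
    new("ModelParams", Zlogits = l$Zlogits, Wlogits = l$Wlogits,
        gamma = l$gamma, delta = l$delta, Rpos = l$Rpos, Rneg = l$Rneg,
        Gpos = l$Gpos, Gneg = l$Gneg)

#' Fit the two-space archetypal model to a signed network
#'
#' Maximum-likelihood estimation of all parameter blocks by adaptive-moment
#' gradient descent with analytic gradients; no priors or regularisation
#' are imposed. The fit is deterministic given `seed`.
#'
#' The archetypal representation is only identified up to an invertible
#' mixing of the memberships that the free scale matrices absorb (rates,
#' and so the likelihood, are unchanged). Analogously to rotation criteria
#' in factor analysis, the fitter therefore reports the canonical
#' representative of the likelihood-equivalent family: after the descent
#' phase the archetypes are re-anchored at the extreme points of the convex
#' hull of the fitted latent positions (an archetypal decomposition of the
#' positions, warm-started from the fitted coefficients), memberships are
#' recomputed as simplex coordinates in that frame, and a short polish
#' phase re-minimises the objective in the canonical frame. Set
#' `canonicalize = FALSE` in the control list to keep the raw frame.
#'
#' @param net a connected [SignedNetwork-class].
#' @param Kpos,Kneg archetype counts of the two spaces (may differ).
#' @param control optimizer settings from [fitControl()].
#' @param seed integer seed for initialisation (and subsampling, if any).
#' @return a [FittedModel-class]; `trace` concatenates the main and polish
#'   epochs.
#' @examples
#' truth <- makePlantedParams(N = 60, Kpos = 2, Kneg = 2, seed = 1)
#' net <- sampleNetwork(truth, seed = 2)$network
#' fit <- fitSignedArchetypes(net, 2, 2, control = fitControl(epochs = 50),
#'                            seed = 3)
#' @export
fitSignedArchetypes <- function(net, Kpos, Kneg, control = fitControl(),
                                seed = 1L) {
    stopifnot(is(net, "SignedNetwork"))
    Kpos <- .stopifnotScalarCount(Kpos, "Kpos")
    Kneg <- .stopifnotScalarCount(Kneg, "Kneg")
    if (Kpos < 1L || Kneg < 1L) stop("Kpos and Kneg must be >= 1")
    N <- nNodes(net)
    if (N < max(Kpos, Kneg)) stop("need at least as many nodes as archetypes")
    seed <- .stopifnotScalarCount(seed, "seed")
    set.seed(seed)
    Y <- adjacencyMatrix(net)
    control <- utils::modifyList(fitControl(), control)
    params <- .initParams(net, Kpos, Kneg, control)
    main <- .adamLoop(params, Y, control$epochs, control$lr, control)
    params <- main$params
    trace <- main$trace
    if (control$canonicalize && control$polishEpochs > 0) {
        params <- .canonicalizeParams(params)
        polish <- .adamLoop(params, Y, control$polishEpochs, control$lr,
                            control)
        params <- polish$params
        trace <- c(trace, polish$trace)
    }
    new("FittedModel",
        params = params,
        solution = archetypes(params),
        trace = trace,
        seed = seed,
        control = control,
        nodeLabels = nodeLabels(net))
}
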