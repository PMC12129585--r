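## Three-class signed link prediction: connectivity-preserving splits,
## class prediction from Skellam rates, F1 scoring and a degree baseline.

.classLevels <- c("neg", "zr", "pos")

#' Connectivity-preserving link-prediction split
#'
#' Removes (sets to zero) a fraction of the network's links while ensuring
#' the residual network stays connected: candidate edges are drawn
#' uniformly without replacement and a removal is accepted only if the
#' remaining graph is still connected. Removed edges become positive or
#' negative test dyads by the sign of their weight; an equal-sized (scaled
#' by `zeroRatio`) sample of non-edges of the original network becomes the
#' zero-class test dyads. If fewer than the requested number of edges can
#' be removed (every remaining candidate is a bridge), the shortfall is
#' recorded and a warning is raised.
#'
#' @param net a connected [SignedNetwork-class].
#' @param fraction fraction of edges to remove, in (0, 1).
#' @param zeroRatio number of zero-class dyads per removed edge.
#' @param seed integer seed; the split is deterministic given it.
#' @return an [EvaluationSplit-class].
#' @export
makeSplit <- function(net, fraction = 0.1, zeroRatio = 1.0, seed = 1L) {
    stopifnot(is(net, "SignedNetwork"))
    if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
    g <- asIgraph(net)
    if (!igraph::is_connected(g)) stop("network must be connected")
    set.seed(.stopifnotScalarCount(seed, "seed"))
    E <- nEdges(net)
    target <- round(fraction * E)
    keep <- rep(TRUE, E)
    removed <- integer(0)
    for (cand in sample.int(E)) {
        if (length(removed) == target) break
        keep[cand] <- FALSE
        gg <- igraph::make_graph(t(net@edges[keep, , drop = FALSE]),
                                 n = nNodes(net), directed = FALSE)
        if (igraph::is_connected(gg)) {
            removed <- c(removed, cand)
        } else {
            keep[cand] <- TRUE
        }
    }
    shortfall <- target - length(removed)
    if (shortfall > 0)
        warning(sprintf("only %d of %d requested removals possible",
                        length(removed), target))
    trainNet <- SignedNetwork(net@nodes, net@edges[keep, , drop = FALSE],
                              net@weights[keep], net@metadata)
    dyads <- data.frame(
        i = net@edges[removed, 1], j = net@edges[removed, 2],
        class = ifelse(net@weights[removed] > 0, "pos", "neg"),
        stringsAsFactors = FALSE)
    nZr <- round(zeroRatio * length(removed))
    if (nZr > 0) {
        n <- nNodes(net)
        edgeKey <- net@edges[, 1] + n * (net@edges[, 2] - 1)
        zrKeys <- integer(0)
        while (length(zrKeys) < nZr) {
            ii <- sample.int(n, 2 * (nZr - length(zrKeys)), replace = TRUE)
            jj <- sample.int(n, 2 * (nZr - length(zrKeys)), replace = TRUE)
            lo <- pmin(ii, jj); hi <- pmax(ii, jj)
            ok <- lo != hi
            key <- lo + n * (hi - 1)
            key <- key[ok & !(key %in% edgeKey) & !(key %in% zrKeys)]
            key <- unique(key)
            zrKeys <- c(zrKeys, key)[seq_len(min(nZr,
                length(zrKeys) + length(key)))]
        }
        dyads <- rbind(dyads, data.frame(
            i = ((zrKeys - 1) %% n) + 1,
            j = ((zrKeys - 1) %/% n) + 1,
            class = "zr", stringsAsFactors = FALSE))
    }
    rownames(dyads) <- NULL
    new("EvaluationSplit", trainNet = trainNet, testDyads = dyads,
        fraction = fraction, shortfall = as.integer(shortfall),
        seed = as.integer(seed))
}

setMethod("show", "EvaluationSplit", function(object) {
    tab <- table(factor(object@testDyads$class, .classLevels))
    cat(sprintf(
        "EvaluationSplit: train %d edges; test %d neg / %d zr / %d pos; shortfall %d\n",
        nEdges(object@trainNet), tab["neg"], tab["zr"], tab["pos"],
        object@shortfall))
})

.argmaxClass <- function(probs) {
    ## ties favour zr, then pos, then neg
    ifelse(probs[, "zr"] >= probs[, "pos"] & probs[, "zr"] >= probs[, "neg"],
           "zr", ifelse(probs[, "pos"] >= probs[, "neg"], "pos", "neg"))
}

.predictFromRates <- function(lp, ln) {
    probs <- skellamClassProbs(lp, ln)
    if (is.null(dim(probs))) probs <- matrix(probs, 1,
        dimnames = list(NULL, names(probs)))
    .argmaxClass(probs)
}

.asDyadMatrix <- function(dyads) {
    if (is.data.frame(dyads)) dyads <- as.matrix(dyads[, c("i", "j")])
    storage.mode(dyads) <- "integer"
    dyads
}

#' @rdname predictClasses
#' @export
setMethod("predictClasses", "ModelParams", function(object, dyads) {
    dyads <- .asDyadMatrix(dyads)
    r <- pairRates(object, dyads[, 1], dyads[, 2])
    .predictFromRates(r$lambdaPos, r$lambdaNeg)
})

#' @rdname predictClasses
#' @export
setMethod("predictClasses", "FittedModel", function(object, dyads)
    predictClasses(object@params, dyads))

#' @rdname predictClasses
#' @export
setMethod("predictClasses", "PlantedTruth", function(object, dyads)
    predictClasses(object@params, dyads))

#' Per-class and support-weighted F1 scores
#'
#' Computes precision/recall F1 for the three interaction classes, with the
#' convention that a class with zero precision-plus-recall scores zero, and
#' the support-weighted mean over classes.
#'
#' @param truth,predicted character vectors over `c("neg", "zr", "pos")` of
#'   equal length.
#' @return named numeric: `neg`, `zr`, `pos`, `weighted`.
#' @export
f1Scores <- function(truth, predicted) {
    if (length(truth) == 0) stop("empty input")
    if (length(truth) != length(predicted)) stop("length mismatch")
    if (!all(c(truth, predicted) %in% .classLevels))
        stop("labels must be in {neg, zr, pos}")
    f1 <- vapply(.classLevels, function(cl) {
        tp <- sum(truth == cl & predicted == cl)
        fp <- sum(truth != cl & predicted == cl)
        fn <- sum(truth == cl & predicted != cl)
        p <- if (tp + fp > 0) tp / (tp + fp) else 0
        r <- if (tp + fn > 0) tp / (tp + fn) else 0
        if (p + r > 0) 2 * p * r / (p + r) else 0
    }, 0)
    support <- vapply(.classLevels, function(cl) sum(truth == cl), 0)
    c(f1, weighted = sum(support * f1) / sum(support))
}

#' Degree-product baseline classifier
#'
#' A structure-free sanity baseline: each node's positive and negative
#' degree (counts of incident positive/negative edges in the training
#' network) define Chung-Lu style rates
#' `lambda+_ij = d+_i d+_j / (2 E+)` (and analogously for the negative
#' side), which are pushed through the same Skellam class-probability
#' argmax rule as the model.
#'
#' @param trainNet the training [SignedNetwork-class].
#' @param dyads two-column matrix or data.frame of node index pairs.
#' @return character vector of predicted classes.
#' @export
degreeBaseline <- function(trainNet, dyads) {
    stopifnot(is(trainNet, "SignedNetwork"))
    dyads <- .asDyadMatrix(dyads)
    n <- nNodes(trainNet)
    dPos <- dNeg <- numeric(n)
    pos <- trainNet@weights > 0
    for (col in 1:2) {
        tp <- tabulate(trainNet@edges[pos, col], n)
        tn <- tabulate(trainNet@edges[!pos, col], n)
        dPos <- dPos + tp
        dNeg <- dNeg + tn
    }
    ePos <- sum(pos)
    eNeg <- sum(!pos)
    lp <- if (ePos > 0) dPos[dyads[, 1]] * dPos[dyads[, 2]] / (2 * ePos)
          else numeric(nrow(dyads))
    ln <- if (eNeg > 0) dNeg[dyads[, 1]] * dNeg[dyads[, 2]] / (2 * eNeg)
          else numeric(nrow(dyads))
    .predictFromRates(lp, ln)
}
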