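test_that("splits remove the requested share and keep the residual connected", {
    truth <- makePlantedParams(N = 80, Kpos = 2, Kneg = 2, seed = 1)
    net <- sampleNetwork(truth, seed = 2)$network
    split <- makeSplit(net, fraction = 0.1, zeroRatio = 1.0, seed = 3)
    E <- nEdges(net)
    target <- round(0.1 * E)
    dy <- split@testDyads
    nRemoved <- sum(dy$class != "zr")
    expect_equal(nRemoved + split@shortfall, target)
    expect_equal(sum(dy$class == "zr"), nRemoved)
    expect_true(igraph::is_connected(asIgraph(split@trainNet)))
    expect_equal(nEdges(split@trainNet), E - nRemoved)

    ## test dyads are disjoint from train edges and from each other
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    trainKeys <- key(split@trainNet@edges[, 1], split@trainNet@edges[, 2])
    dyKeys <- key(dy$i, dy$j)
    expect_false(any(dyKeys %in% trainKeys))
    expect_false(anyDuplicated(dyKeys) > 0)

    ## zr dyads are non-edges of the ORIGINAL network
    origKeys <- key(net@edges[, 1], net@edges[, 2])
    expect_false(any(dyKeys[dy$class == "zr"] %in% origKeys))

    ## removed-edge class is the sign of the original weight
    Y <- adjacencyMatrix(net)
    removed <- dy[dy$class != "zr", ]
    expect_equal(ifelse(Y[cbind(removed$i, removed$j)] > 0, "pos", "neg"),
                 removed$class)

    ## determinism
    split2 <- makeSplit(net, fraction = 0.1, zeroRatio = 1.0, seed = 3)
    expect_identical(split@testDyads, split2@testDyads)
})

test_that("a spanning tree admits no removals and warns", {
    n <- 10
    tree <- SignedNetwork(sprintf("n%d", 1:n),
                          cbind(1:(n - 1), 2:n),
                          rep(c(1L, -1L), length.out = n - 1))
    expect_warning(split <- makeSplit(tree, 0.5, 1.0, seed = 1),
                   "removals possible")
    expect_equal(nrow(split@testDyads), 0L)
    expect_gt(split@shortfall, 0L)
})

test_that("class prediction follows the Skellam class-probability argmax", {
    p <- randomParams(N = 20, Kpos = 2, seed = 4)
    dyads <- cbind(sample(1:10), sample(11:20))
    pred <- predictClasses(p, dyads)
    r <- pairRates(p, dyads[, 1], dyads[, 2])
    probs <- skellamClassProbs(r$lambdaPos, r$lambdaNeg)
    oracle <- apply(probs, 1, function(x) {
        cls <- c("neg", "zr", "pos")[x == max(x)]
        if ("zr" %in% cls) "zr" else if ("pos" %in% cls) "pos" else "neg"
    })
    expect_equal(pred, oracle)

    ## trivial extremes
    ph <- randomParams(N = 4, Kpos = 2, seed = 5)
    ph@gamma[] <- 3; ph@delta[] <- -6
    ph@Zlogits[] <- 0  # zero distances
    expect_equal(unique(predictClasses(ph, cbind(1, 2:4))), "pos")
    ph@gamma[] <- -6; ph@delta[] <- -6
    expect_equal(unique(predictClasses(ph, cbind(1, 2:4))), "zr")
})

test_that("f1 scores match the definitional arithmetic", {
    truth <- c(rep("pos", 5), rep("neg", 5), rep("zr", 10))
    allZr <- rep("zr", 20)
    f <- f1Scores(truth, allZr)
    expect_equal(unname(f["pos"]), 0)
    expect_equal(unname(f["neg"]), 0)
    expect_equal(unname(f["zr"]), 2 / 3)
    expect_equal(unname(f["weighted"]), 1 / 3)

    perfect <- f1Scores(truth, truth)
    expect_equal(unname(perfect), rep(1, 4))

    set.seed(6)
    perm <- sample(20)
    expect_equal(f1Scores(truth[perm], allZr[perm]), f)

    expect_error(f1Scores(character(0), character(0)), "empty")
    expect_error(f1Scores(truth, truth[-1]), "mismatch")
    expect_error(f1Scores(c("pos", "bad"), c("pos", "pos")), "labels")
})

test_that("f1 scores agree with an independent confusion-matrix oracle", {
    confOracle <- function(truth, pred) {
        lev <- c("neg", "zr", "pos")
        cm <- table(factor(truth, lev), factor(pred, lev))
        f1 <- vapply(lev, function(cl) {
            tp <- cm[cl, cl]
            prec <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else 0
            rec <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else 0
            if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
        }, 0)
        c(f1, weighted = sum(rowSums(cm) * f1) / sum(cm))
    }
    set.seed(8)
    for (rep in 1:100) {
        n <- sample(5:40, 1)
        truth <- sample(c("neg", "zr", "pos"), n, TRUE)
        pred <- sample(c("neg", "zr", "pos"), n, TRUE)
        expect_identical(f1Scores(truth, pred), confOracle(truth, pred))
    }
})

test_that("the degree baseline predicts from degree products only", {
    ## isolated nodes yield zero rates: zr
    net <- tinyNet()
    expect_equal(unique(degreeBaseline(net, cbind(1, 3:4))) %in%
                 c("neg", "zr", "pos"), TRUE)

    allPos <- SignedNetwork(letters[1:4],
                            rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)),
                            rep(2L, 4))
    pred <- degreeBaseline(allPos, cbind(c(1, 2), c(3, 4)))
    expect_false(any(pred == "neg"))

    lonely <- SignedNetwork(letters[1:5],
                            rbind(c(1, 2), c(2, 3)), c(1L, -1L))
    expect_equal(unique(degreeBaseline(lonely, cbind(4, c(1, 5)))), "zr")
})
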