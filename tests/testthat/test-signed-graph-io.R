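test_that("generic dialect parses, aggregates and canonicalizes", {
    p <- tmpFile(c("A\tB\t1", "B\tC\t-2"))
    net <- suppressMessages(readSignedEdgeList(p, "generic"))
    expect_equal(nNodes(net), 3L)
    expect_equal(nEdges(net), 2L)
    tab <- edgeTable(net)
    expect_equal(tab$weight[tab$a == "A" & tab$b == "B"], 1L)
    expect_equal(tab$weight[tab$b == "C" | tab$a == "C"], -2L)

    ## directed duplicates and repeated records aggregate by weight sum
    p2 <- tmpFile(c("A\tB\t1", "B\tA\t1", "A\tB\t-1"))
    net2 <- suppressMessages(readSignedEdgeList(p2, "generic"))
    expect_equal(nEdges(net2), 1L)
    expect_equal(edgeTable(net2)$weight, 1L)

    ## zero aggregate drops the pair
    p3 <- tmpFile(c("A\tB\t1", "B\tA\t-1", "B\tC\t2"))
    net3 <- suppressMessages(readSignedEdgeList(p3, "generic"))
    expect_equal(nEdges(net3), 1L)

    expect_error(suppressMessages(
        readSignedEdgeList(tmpFile("A\tB"), "generic")), "line 1")
    expect_error(suppressMessages(
        readSignedEdgeList(tmpFile("A\tB\tx"), "generic")), "non-integer")
})

test_that("signor dialect maps effects to signs and skips unknown effects", {
    hdr <- "ENTITYA\tENTITYB\tEFFECT"
    p <- tmpFile(c(hdr,
                   "P1\tP2\tup-regulates",
                   "P2\tP1\tup-regulates activity",
                   "P1\tP2\tdown-regulates"))
    net <- suppressMessages(readSignedEdgeList(p, "signor"))
    expect_equal(nEdges(net), 1L)
    expect_equal(edgeTable(net)$weight, 1L)  # 2 up - 1 down

    p2 <- tmpFile(c(hdr, "P1\tP1\tup-regulates", "P1\tP2\tup-regulates"))
    net2 <- suppressMessages(readSignedEdgeList(p2, "signor"))
    expect_equal(nEdges(net2), 1L)
    expect_equal(net2@metadata$records$selfLoops, 1L)

    p3 <- tmpFile(c(hdr, "P1\tP2\tbinds", "P1\tP2\tdown-regulates"))
    expect_warning(net3 <- suppressMessages(readSignedEdgeList(p3, "signor")),
                   "unknown effect")
    expect_equal(edgeTable(net3)$weight, -1L)
})

test_that("record accounting balances for arbitrary inputs", {
    set.seed(7)
    for (rep in 1:5) {
        n <- 40
        hdr <- "ENTITYA\tENTITYB\tEFFECT"
        eff <- sample(c("up-regulates", "down-regulates", "binds"), n,
                      replace = TRUE, prob = c(0.45, 0.45, 0.1))
        a <- sample(LETTERS[1:6], n, replace = TRUE)
        b <- sample(LETTERS[1:6], n, replace = TRUE)
        p <- tmpFile(c(hdr, paste(a, b, eff, sep = "\t")))
        net <- suppressWarnings(suppressMessages(
            readSignedEdgeList(p, "signor")))
        rec <- net@metadata$records
        expect_equal(rec$total,
                     rec$kept + rec$selfLoops + rec$zeroAggregates +
                     rec$unknownEffects)
    }
})

test_that("round trip through the generic dialect preserves the network", {
    net <- tinyNet()
    p <- tempfile(fileext = ".tsv")
    writeSignedEdgeList(net, p)
    back <- suppressMessages(readSignedEdgeList(p, "generic"))
    expect_setequal(nodeLabels(back), nodeLabels(net))
    t1 <- edgeTable(net)
    t2 <- edgeTable(back)
    key <- function(t) paste(pmin(t$a, t$b), pmax(t$a, t$b), t$weight)
    expect_setequal(key(t1), key(t2))
})

test_that("largest connected component is maximal with documented tie-break", {
    ## connected input: unchanged up to relabelling
    net <- tinyNet()
    lcc <- largestConnectedComponent(net)
    expect_equal(nNodes(lcc), nNodes(net))
    expect_equal(nEdges(lcc), nEdges(net))

    ## sizes 3 vs 2 keeps the triangle
    two <- SignedNetwork(nodes = c("a", "b", "c", "x", "y"),
                         edges = rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5)),
                         weights = c(1L, 1L, -1L, 2L))
    lcc2 <- largestConnectedComponent(two)
    expect_setequal(nodeLabels(lcc2), c("a", "b", "c"))

    ## tie on size: component with lexicographically smallest label wins
    tie <- SignedNetwork(nodes = c("z2", "z1", "a2", "a1"),
                         edges = rbind(c(1, 2), c(3, 4)),
                         weights = c(1L, -1L))
    expect_setequal(nodeLabels(largestConnectedComponent(tie)),
                    c("a1", "a2"))

    expect_error(largestConnectedComponent(
        SignedNetwork(character(0), matrix(integer(0), 0, 2), integer(0))),
        "empty")

    ## maximality on random graphs
    set.seed(3)
    for (rep in 1:5) {
        n <- 25
        e <- cbind(sample(n, 30, TRUE), sample(n, 30, TRUE))
        e <- e[e[, 1] != e[, 2], , drop = FALSE]
        e <- unique(t(apply(e, 1, sort)))
        g <- SignedNetwork(sprintf("n%02d", 1:n), e,
                           sample(c(-1L, 1L), nrow(e), TRUE))
        comp <- igraph::components(asIgraph(g))
        expect_equal(nNodes(largestConnectedComponent(g)), max(comp$csize))
    }
})

test_that("GO annotation readers deduplicate and skip bad aspects", {
    p <- tmpFile(c("P1\tGO:1\tBP", "P1\tGO:1\tBP", "P2\tGO:2\tMF"))
    ann <- readGoAnnotations(p, "tsv")
    expect_equal(nrow(ann@annotations), 2L)
    expect_equal(unname(termCounts(ann)[c("GO:1", "GO:2")]), c(1L, 1L))

    gaf <- tmpFile(c("!gaf-version: 2.1", "! comment",
                     paste("DB", "P9", "SYM", "", "GO:7", "REF", "IEA", "",
                           "P", "name", "", "protein", "taxon:9606",
                           sep = "\t")))
    annG <- readGoAnnotations(gaf, "gaf")
    expect_equal(nrow(annG@annotations), 1L)
    expect_equal(annG@annotations$aspect, "BP")

    expect_warning(empty <- readGoAnnotations(tmpFile(character(0)), "tsv"),
                   "no annotation")
    expect_equal(nrow(empty@annotations), 0L)

    bad <- tmpFile(c("P1\tGO:1\tBP", "P2\tGO:2\tQQ"))
    expect_warning(annB <- readGoAnnotations(bad, "tsv"), "aspect")
    expect_equal(nrow(annB@annotations), 1L)

    ## header line is tolerated
    withHdr <- tmpFile(c("protein_id\tgo_id\taspect", "P1\tGO:1\tCC"))
    expect_equal(nrow(readGoAnnotations(withHdr, "tsv")@annotations), 1L)
})

test_that("SignedNetwork validity catches malformed objects", {
    expect_error(SignedNetwork(c("A", "B"), rbind(c(1, 1)), 1L), "self-loops")
    expect_error(SignedNetwork(c("A", "B"), rbind(c(1, 2)), 0L), "nonzero")
    expect_error(SignedNetwork(c("A", "B"), rbind(c(1, 2), c(1, 2)),
                               c(1L, 2L)), "at most once")
})
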