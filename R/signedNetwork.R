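#' Construct a SignedNetwork
#'
#' Low-level constructor; most users will use [readSignedEdgeList()] or the
#' synthetic generator. Edge pairs are canonicalized to `i < j`.
#'
#' @param nodes character vector of unique protein labels.
#' @param edges two-column matrix of node indices (1-based).
#' @param weights nonzero integer edge weights.
#' @param metadata optional list of provenance.
#' @return a [SignedNetwork-class] object.
#' @export
SignedNetwork <- function(nodes, edges, weights, metadata = list()) {
    edges <- matrix(as.integer(edges), ncol = 2)
    weights <- as.integer(weights)
    if (nrow(edges) > 0) {
        flip <- edges[, 1] > edges[, 2]
        edges[flip, ] <- edges[flip, 2:1]
        o <- order(edges[, 1], edges[, 2])
        edges <- edges[o, , drop = FALSE]
        weights <- weights[o]
    }
    new("SignedNetwork", nodes = as.character(nodes), edges = edges,
        weights = weights, metadata = metadata)
}

#' @describeIn SignedNetwork number of nodes.
#' @param x a SignedNetwork.
#' @export
setMethod("nNodes", "SignedNetwork", function(x) length(x@nodes))

#' @describeIn SignedNetwork number of edges.
#' @export
setMethod("nEdges", "SignedNetwork", function(x) nrow(x@edges))

#' @describeIn SignedNetwork protein labels.
#' @export
setMethod("nodeLabels", "SignedNetwork", function(x) x@nodes)

setMethod("show", "SignedNetwork", function(object) {
    w <- object@weights
    cat(sprintf(
        "SignedNetwork: %d proteins, %d edges (%d positive, %d negative)\n",
        nNodes(object), nEdges(object), sum(w > 0), sum(w < 0)))
})

#' Edge table of a signed network
#'
#' @param net a [SignedNetwork-class].
#' @return data.frame with columns `a`, `b` (labels), `i`, `j` (indices) and
#'   `weight`.
#' @export
edgeTable <- function(net) {
    stopifnot(is(net, "SignedNetwork"))
    data.frame(
        a = net@nodes[net@edges[, 1]],
        b = net@nodes[net@edges[, 2]],
        i = net@edges[, 1],
        j = net@edges[, 2],
        weight = net@weights,
        stringsAsFactors = FALSE
    )
}

#' Dense signed adjacency matrix
#'
#' @param net a [SignedNetwork-class].
#' @return N x N integer matrix with `y_ij` at symmetric positions and zero
#'   elsewhere.
#' @export
adjacencyMatrix <- function(net) {
    stopifnot(is(net, "SignedNetwork"))
    n <- nNodes(net)
    Y <- matrix(0L, n, n, dimnames = list(net@nodes, net@nodes))
    if (nEdges(net) > 0) {
        Y[net@edges] <- net@weights
        Y[net@edges[, 2:1, drop = FALSE]] <- net@weights
    }
    Y
}

#' Convert to an igraph graph (signs kept as a weight attribute)
#'
#' @param net a [SignedNetwork-class].
#' @return an undirected igraph object with edge attribute `weight`.
#' @export
asIgraph <- function(net) {
    stopifnot(is(net, "SignedNetwork"))
    g <- igraph::make_graph(t(net@edges), n = nNodes(net), directed = FALSE)
    igraph::E(g)$weight <- net@weights
    igraph::V(g)$name <- net@nodes
    g
}

.aggregateRecords <- function(a, b, sign, lineNo) {
    ## a, b: labels; sign: +1/-1 per record (already resolved); returns the
    ## kept network plus record-level accounting.
    selfLoop <- a == b
    nSelf <- sum(selfLoop)
    a <- a[!selfLoop]; b <- b[!selfLoop]; sign <- sign[!selfLoop]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    key <- paste0(lo, "\r", hi)
    agg <- rowsum(as.numeric(sign), key)
    cnt <- rowsum(rep(1, length(key)), key)
    keys <- rownames(agg)
    keep <- agg[, 1] != 0
    nZeroAgg <- sum(cnt[!keep, 1])
    nKept <- sum(cnt[keep, 1])
    parts <- strsplit(keys[keep], "\r", fixed = TRUE)
    aK <- vapply(parts, `[`, "", 1L)
    bK <- vapply(parts, `[`, "", 2L)
    nodes <- sort(unique(c(aK, bK)))
    net <- SignedNetwork(
        nodes = nodes,
        edges = cbind(match(aK, nodes), match(bK, nodes)),
        weights = as.integer(agg[keep, 1]),
        metadata = list(
            records = list(
                total = length(selfLoop),
                kept = nKept,
                selfLoops = nSelf,
                zeroAggregates = nZeroAgg,
                unknownEffects = 0L
            )
        )
    )
    net
}

#' Read a signed edge list
#'
#' Reads a signed interaction network from a tab-separated file in one of
#' two dialects and canonicalizes it to an undirected simple graph.
#'
#' * `generic`: no header, columns `(node_a, node_b, integer_weight)`.
#'   Multiple records for an unordered pair are aggregated by summing their
#'   weights.
#' * `signor`: header-bearing TSV in the style of SIGNOR exports, with
#'   entity and effect columns (defaults `ENTITYA`, `ENTITYB`, `EFFECT`).
#'   Effects matching `up-regulat` (case-insensitive substring) count +1,
#'   `down-regulat` counts -1, anything else is skipped with a warning;
#'   records for a pair aggregate as (number of up) - (number of down).
#'
#' Direction is discarded in both dialects: the likelihood is defined over
#' unordered pairs, so a directed record and its reverse collapse onto one
#' edge. Pairs whose aggregate weight is zero and self-loop records are
#' dropped; the record-level accounting is stored in the returned object's
#' `metadata$records` and reported via [message()].
#'
#' @param path file path.
#' @param dialect `"generic"` or `"signor"`.
#' @param columns for the signor dialect, named character vector giving the
#'   `entityA`, `entityB` and `effect` column names.
#' @return a [SignedNetwork-class].
#' @export
readSignedEdgeList <- function(path, dialect = c("generic", "signor"),
                               columns = c(entityA = "ENTITYA",
                                           entityB = "ENTITYB",
                                           effect = "EFFECT")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    if (dialect == "generic") {
        lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
        lines <- lines[nzchar(lines)]
        if (length(lines) == 0) stop("no records in ", path)
        parts <- strsplit(lines, "\t", fixed = TRUE)
        bad <- which(lengths(parts) < 3L)
        if (length(bad))
            stop(sprintf("malformed line %d: expected 3 tab-separated fields",
                         bad[1]))
        a <- vapply(parts, `[`, "", 1L)
        b <- vapply(parts, `[`, "", 2L)
        wRaw <- vapply(parts, `[`, "", 3L)
        wNorm <- sub("^−", "-", trimws(wRaw))  # tolerate unicode minus
        badW <- which(!grepl("^[+-]?[0-9]+$", wNorm))
        if (length(badW))
            stop(sprintf("non-integer weight '%s' on line %d",
                         wRaw[badW[1]], badW[1]))
        net <- .aggregateRecords(a, b, as.integer(wNorm))
    } else {
        tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE, quote = "",
                                 check.names = FALSE)
        need <- unname(columns[c("entityA", "entityB", "effect")])
        miss <- setdiff(need, names(tab))
        if (length(miss))
            stop("missing SIGNOR columns: ", paste(miss, collapse = ", "))
        eff <- tolower(tab[[columns[["effect"]]]])
        sgn <- ifelse(grepl("up-regulat", eff, fixed = TRUE), 1L,
               ifelse(grepl("down-regulat", eff, fixed = TRUE), -1L, NA_integer_))
        nUnknown <- sum(is.na(sgn))
        if (nUnknown > 0)
            warning(sprintf("%d record(s) with unknown effect skipped", nUnknown))
        keep <- !is.na(sgn)
        net <- .aggregateRecords(tab[[columns[["entityA"]]]][keep],
                                 tab[[columns[["entityB"]]]][keep],
                                 sgn[keep])
        net@metadata$records$total <- net@metadata$records$total + nUnknown
        net@metadata$records$unknownEffects <- nUnknown
    }
    rec <- net@metadata$records
    message(sprintf(
        "read %d records: %d kept in %d edges; dropped %d self-loop, %d zero-aggregate, %d unknown-effect record(s)",
        rec$total, rec$kept, nEdges(net), rec$selfLoops, rec$zeroAggregates,
        rec$unknownEffects))
    net
}

#' Write a signed network in the generic edge-list dialect
#'
#' @param net a [SignedNetwork-class].
#' @param path output file path (TSV, no header).
#' @return invisibly, `path`.
#' @export
writeSignedEdgeList <- function(net, path) {
    stopifnot(is(net, "SignedNetwork"))
    tab <- edgeTable(net)
    utils::write.table(tab[c("a", "b", "weight")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Largest connected component of a signed network
#'
#' Connectivity ignores edge signs. Node indices are re-densified; original
#' labels are preserved. If several components tie on size, the one holding
#' the lexicographically smallest node label is returned, which keeps the
#' operation deterministic.
#'
#' @param net a [SignedNetwork-class].
#' @return a connected [SignedNetwork-class].
#' @export
largestConnectedComponent <- function(net) {
    stopifnot(is(net, "SignedNetwork"))
    if (nNodes(net) == 0) stop("empty network")
    comp <- igraph::components(asIgraph(net))
    sizes <- comp$csize
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
        rep_label <- vapply(best, function(cid)
            min(net@nodes[comp$membership == cid]), "")
        best <- best[order(rep_label)[1]]
    }
    keep <- which(comp$membership == best)
    sel <- net@edges[, 1] %in% keep & net@edges[, 2] %in% keep
    remap <- match(seq_len(nNodes(net)), keep)
    SignedNetwork(
        nodes = net@nodes[keep],
        edges = cbind(remap[net@edges[sel, 1]], remap[net@edges[sel, 2]]),
        weights = net@weights[sel],
        metadata = net@metadata
    )
}

#' Build an AnnotationTable from a data.frame
#'
#' @param annotations data.frame with columns `protein`, `goId`, `aspect`.
#'   Duplicated (protein, goId) pairs are collapsed.
#' @return an [AnnotationTable-class].
#' @export
AnnotationTable <- function(annotations) {
    annotations <- annotations[c("protein", "goId", "aspect")]
    annotations[] <- lapply(annotations, as.character)
    annotations <- annotations[!duplicated(annotations[c("protein", "goId")]), ,
                               drop = FALSE]
    rownames(annotations) <- NULL
    new("AnnotationTable", annotations = annotations)
}

#' @describeIn AnnotationTable number of distinct annotated proteins per term.
#' @param x an AnnotationTable.
#' @return named integer vector indexed by GO identifier.
#' @export
termCounts <- function(x) {
    stopifnot(is(x, "AnnotationTable"))
    tab <- table(x@annotations$goId)
    stats::setNames(as.integer(tab), names(tab))
}

setMethod("show", "AnnotationTable", function(object) {
    a <- object@annotations
    cat(sprintf("AnnotationTable: %d annotations, %d proteins, %d terms\n",
                nrow(a), length(unique(a$protein)), length(unique(a$goId))))
})

.aspectMap <- c(BP = "BP", MF = "MF", CC = "CC", P = "BP", F = "MF", C = "CC")

#' Read protein GO annotations
#'
#' Supports a plain three-column TSV (`protein_id`, `go_id`, `aspect`, with
#' an optional header) and a GAF 2.x subset (comment lines start with `!`;
#' columns 2, 5 and 9 are used; aspects `P`/`F`/`C` map to `BP`/`MF`/`CC`).
#' Records with an unreadable aspect code are skipped with a warning.
#' Proteins absent from any particular network are retained; restriction to
#' network proteins happens at enrichment time.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"gaf"`.
#' @return an [AnnotationTable-class].
#' @export
readGoAnnotations <- function(path, dialect = c("tsv", "gaf")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    if (dialect == "gaf") lines <- lines[!startsWith(lines, "!")]
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) {
        warning("no annotation records in ", path)
        return(AnnotationTable(data.frame(protein = character(0),
                                          goId = character(0),
                                          aspect = character(0))))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (dialect == "tsv") {
        if (any(lengths(parts) < 3L))
            stop("tsv annotation rows need 3 tab-separated fields")
        if (identical(tolower(parts[[1]][1]), "protein_id"))
            parts <- parts[-1]
        protein <- vapply(parts, `[`, "", 1L)
        goId <- vapply(parts, `[`, "", 2L)
        aspectRaw <- vapply(parts, `[`, "", 3L)
    } else {
        if (any(lengths(parts) < 9L))
            stop("GAF rows need at least 9 tab-separated fields")
        protein <- vapply(parts, `[`, "", 2L)
        goId <- vapply(parts, `[`, "", 5L)
        aspectRaw <- vapply(parts, `[`, "", 9L)
    }
    aspect <- .aspectMap[toupper(trimws(aspectRaw))]
    bad <- is.na(aspect)
    if (any(bad))
        warning(sprintf("%d record(s) with unreadable aspect skipped", sum(bad)))
    AnnotationTable(data.frame(protein = protein[!bad], goId = goId[!bad],
                               aspect = unname(aspect[!bad]),
                               stringsAsFactors = FALSE))
}
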