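## Circular archetype layouts and membership-ordered adjacency matrices.

#' Circular barycentric layout of memberships
#'
#' Places the K archetypes evenly around the unit circle (archetype k at
#' angle `2*pi*(k-1)/K`) and every node at the barycentre of the anchors
#' weighted by its memberships, so pure archetypal nodes sit on the circle
#' and mixed nodes fall inside it.
#'
#' @param M K x N columnwise-simplex membership matrix (K >= 2).
#' @return list with `nodes` (N x 2 coordinates) and `anchors` (K x 2).
#' @export
circularLayout <- function(M) {
    .checkMembershipRun(M, "M")
    K <- nrow(M)
    if (K < 2) stop("need at least two archetypes for a circular layout")
    ang <- 2 * pi * (seq_len(K) - 1) / K
    anchors <- cbind(cos(ang), sin(ang))
    list(nodes = crossprod(M, anchors), anchors = anchors)
}

#' Membership-ordered node permutation
#'
#' Orders nodes by maximum simplex-corner responsibility: grouped by argmax
#' membership (ties to the lowest archetype index), and within each group
#' by decreasing winning membership. Plotting the adjacency matrix in this
#' order exposes the archetypal block structure.
#'
#' @param net a [SignedNetwork-class] (only its size is used).
#' @param M K x N membership matrix over the same nodes.
#' @return integer permutation of `1..N`.
#' @export
orderedAdjacency <- function(net, M) {
    stopifnot(is(net, "SignedNetwork"))
    .checkMembershipRun(M, "M")
    if (ncol(M) != nNodes(net))
        stop("membership matrix and network disagree on node count")
    winner <- apply(M, 2, which.max)
    strength <- M[cbind(winner, seq_len(ncol(M)))]
    order(winner, -strength, seq_len(ncol(M)))
}

#' Plot a circular archetype layout
#'
#' Draws the [circularLayout()] of a membership matrix with edges overlaid:
#' positive edges in blue, negative in red.
#'
#' @param net a [SignedNetwork-class].
#' @param M K x N membership matrix.
#' @param edgeAlpha transparency of edge lines.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the layout.
#' @export
plotCircularArchetypes <- function(net, M, edgeAlpha = 0.15, ...) {
    lay <- circularLayout(M)
    graphics::plot(lay$nodes, pch = 16, cex = 0.5, col = "grey30",
                   xlab = "", ylab = "", asp = 1, ...)
    pos <- net@weights > 0
    cols <- ifelse(pos, grDevices::rgb(0, 0, 1, edgeAlpha),
                   grDevices::rgb(1, 0, 0, edgeAlpha))
    graphics::segments(lay$nodes[net@edges[, 1], 1],
                       lay$nodes[net@edges[, 1], 2],
                       lay$nodes[net@edges[, 2], 1],
                       lay$nodes[net@edges[, 2], 2], col = cols)
    graphics::points(lay$anchors, pch = 17, cex = 1.4, col = "black")
    graphics::text(lay$anchors * 1.08, labels = seq_len(nrow(lay$anchors)))
    invisible(lay)
}

#' Plot a membership-ordered adjacency matrix
#'
#' @param net a [SignedNetwork-class].
#' @param M K x N membership matrix used for the ordering.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the permutation used.
#' @export
plotOrderedAdjacency <- function(net, M, ...) {
    perm <- orderedAdjacency(net, M)
    Y <- adjacencyMatrix(net)[perm, perm]
    n <- nrow(Y)
    graphics::image(seq_len(n), seq_len(n), sign(t(Y[n:1, ])),
                    col = c("red", "white", "blue"), zlim = c(-1, 1),
                    xlab = "", ylab = "", axes = FALSE, ...)
    invisible(perm)
}
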