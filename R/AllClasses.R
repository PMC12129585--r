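#' @import methods
NULL

## Central data containers. All matrices of memberships are oriented K x N
## (archetypes in rows, proteins in columns); coefficient matrices C are
## N x K, matching A = R %*% Z %*% C.

#' SignedNetwork: an undirected signed interaction network
#'
#' Holds an undirected simple graph over proteins whose edges carry nonzero
#' integer weights: positive weights encode up-regulating interactions,
#' negative weights down-regulating ones. Node indices are dense `1..N` and
#' bijective with `nodeLabels`.
#'
#' @slot nodes character vector of protein identifiers (length N).
#' @slot edges two-column integer matrix of node index pairs, one row per
#'   unordered edge, with `edges[, 1] < edges[, 2]`.
#' @slot weights integer vector of nonzero edge weights, parallel to `edges`.
#' @slot metadata list of free-form provenance (e.g. parse counters).
#'
#' @seealso [readSignedEdgeList()], [largestConnectedComponent()]
#' @export
setClass("SignedNetwork",
    slots = c(
        nodes = "character",
        edges = "matrix",
        weights = "integer",
        metadata = "list"
    )
)

setValidity("SignedNetwork", function(object) {
    n <- length(object@nodes)
    e <- object@edges
    w <- object@weights
    msgs <- character(0)
    if (anyDuplicated(object@nodes))
        msgs <- c(msgs, "node labels must be unique")
    if (!is.numeric(e) || ncol(e) != 2L)
        msgs <- c(msgs, "edges must be a two-column index matrix")
    else {
        if (nrow(e) != length(w))
            msgs <- c(msgs, "weights must be parallel to edges")
        if (nrow(e) > 0) {
            if (any(e != round(e)) || any(e < 1L) || any(e > n))
                msgs <- c(msgs, "edge indices must be integers in 1..N")
            if (any(e[, 1] >= e[, 2]))
                msgs <- c(msgs, "edges must satisfy i < j (no self-loops)")
            if (anyDuplicated(e))
                msgs <- c(msgs, "each unordered pair may appear at most once")
        }
    }
    if (any(w == 0L)) msgs <- c(msgs, "edge weights must be nonzero")
    if (length(msgs)) msgs else TRUE
})

#' AnnotationTable: protein to GO-term assignments
#'
#' A deduplicated table of `(protein, goId, aspect)` records, with aspect one
#' of `BP` (biological process), `MF` (molecular function) or `CC` (cellular
#' component). Proteins need not belong to any particular network; filtering
#' to network membership happens at enrichment time.
#'
#' @slot annotations data.frame with character columns `protein`, `goId`,
#'   `aspect`.
#'
#' @seealso [readGoAnnotations()], [enrichArchetype()]
#' @export
setClass("AnnotationTable",
    slots = c(annotations = "data.frame")
)

setValidity("AnnotationTable", function(object) {
    a <- object@annotations
    msgs <- character(0)
    if (!all(c("protein", "goId", "aspect") %in% names(a)))
        msgs <- c(msgs, "annotations needs columns protein, goId, aspect")
    else {
        if (nrow(a) > 0 && !all(a$aspect %in% c("BP", "MF", "CC")))
            msgs <- c(msgs, "aspect must be one of BP, MF, CC")
        if (anyDuplicated(a[c("protein", "goId")]))
            msgs <- c(msgs, "duplicate (protein, goId) pairs must be collapsed")
    }
    if (length(msgs)) msgs else TRUE
})

#' ModelParams: free parameters of the two-space archetypal model
#'
#' All learnable quantities of both latent spaces. Memberships live on the
#' probability simplex via a columnwise softmax of the free logits; the gate
#' logits feed the gated archetype-coefficient construction; `Rpos`/`Rneg`
#' scale the archetype polytopes; `gamma`/`delta` are node random effects for
#' positive/negative degree heterogeneity.
#'
#' @slot Zlogits Kpos x N membership logits of the positive space.
#' @slot Wlogits Kneg x N membership logits of the negative space.
#' @slot gamma length-N positive-space random effects.
#' @slot delta length-N negative-space random effects.
#' @slot Rpos Kpos x Kpos scale matrix of the positive polytope.
#' @slot Rneg Kneg x Kneg scale matrix of the negative polytope.
#' @slot Gpos Kpos x N gate logits of the positive space.
#' @slot Gneg Kneg x N gate logits of the negative space.
#'
#' @seealso [memberships()], [archetypes()], [fitSignedArchetypes()]
#' @export
setClass("ModelParams",
    slots = c(
        Zlogits = "matrix", Wlogits = "matrix",
        gamma = "numeric", delta = "numeric",
        Rpos = "matrix", Rneg = "matrix",
        Gpos = "matrix", Gneg = "matrix"
    )
)

setValidity("ModelParams", function(object) {
    msgs <- character(0)
    n <- ncol(object@Zlogits)
    kp <- nrow(object@Zlogits)
    kn <- nrow(object@Wlogits)
    if (n < 2L) msgs <- c(msgs, "need at least N = 2 nodes")
    if (kp < 1L || kn < 1L) msgs <- c(msgs, "need Kpos >= 1 and Kneg >= 1")
    if (ncol(object@Wlogits) != n ||
        length(object@gamma) != n || length(object@delta) != n ||
        !identical(dim(object@Gpos), dim(object@Zlogits)) ||
        !identical(dim(object@Gneg), dim(object@Wlogits)) ||
        !identical(dim(object@Rpos), c(kp, kp)) ||
        !identical(dim(object@Rneg), c(kn, kn)))
        msgs <- c(msgs, "parameter block dimensions are inconsistent")
    allv <- c(object@Zlogits, object@Wlogits, object@gamma, object@delta,
              object@Rpos, object@Rneg, object@Gpos, object@Gneg)
    if (!all(is.finite(allv))) msgs <- c(msgs, "all entries must be finite")
    if (length(msgs)) msgs else TRUE
})

#' ArchetypeSolution: derived simplex quantities of a parameter set
#'
#' Memberships `Z`, `W` (columns on the simplex), gated coefficient matrices
#' `Cpos`, `Cneg` (columns on the simplex) and archetype matrices
#' `Apos = Rpos Z Cpos`, `Aneg = Rneg W Cneg`. Each archetype column is the
#' image under the scale matrix of a convex combination of node membership
#' columns, so archetypes lie inside the latent embedding hull.
#'
#' @slot Z Kpos x N membership matrix, columns on the simplex.
#' @slot W Kneg x N membership matrix.
#' @slot Cpos N x Kpos archetype coefficient matrix, columns on the simplex.
#' @slot Cneg N x Kneg archetype coefficient matrix.
#' @slot Apos Kpos x Kpos positive-space archetype matrix.
#' @slot Aneg Kneg x Kneg negative-space archetype matrix.
#'
#' @seealso [archetypes()], [nodeArchetypeDistance()]
#' @export
setClass("ArchetypeSolution",
    slots = c(
        Z = "matrix", W = "matrix",
        Cpos = "matrix", Cneg = "matrix",
        Apos = "matrix", Aneg = "matrix"
    )
)

.checkSimplexCols <- function(M, what, tol = 1e-9) {
    if (any(M < -tol))
        return(sprintf("%s has negative entries", what))
    if (any(abs(colSums(M) - 1) > tol))
        return(sprintf("%s columns must sum to 1 within %g", what, tol))
    NULL
}

setValidity("ArchetypeSolution", function(object) {
    msgs <- c(
        .checkSimplexCols(object@Z, "Z"),
        .checkSimplexCols(object@W, "W"),
        .checkSimplexCols(object@Cpos, "Cpos"),
        .checkSimplexCols(object@Cneg, "Cneg")
    )
    if (ncol(object@Apos) != nrow(object@Z))
        msgs <- c(msgs, "Apos must have Kpos columns")
    if (ncol(object@Aneg) != nrow(object@W))
        msgs <- c(msgs, "Aneg must have Kneg columns")
    if (length(msgs)) msgs else TRUE
})

#' FittedModel: a maximum-likelihood fit of the two-space model
#'
#' @slot params the fitted [ModelParams].
#' @slot solution the derived [ArchetypeSolution].
#' @slot trace numeric vector of negative log-likelihood per epoch.
#' @slot seed integer seed the fit was started from.
#' @slot control list of optimizer settings (see [fitControl()]).
#' @slot nodeLabels protein identifiers of the fitted network.
#'
#' @seealso [fitSignedArchetypes()], [predictClasses()], [writeModel()]
#' @export
setClass("FittedModel",
    slots = c(
        params = "ModelParams",
        solution = "ArchetypeSolution",
        trace = "numeric",
        seed = "integer",
        control = "list",
        nodeLabels = "character"
    )
)

#' PlantedTruth: ground truth for synthetic signed networks
#'
#' Planted model parameters together with the derived solution and the
#' intended corner assignment of each node (NA for nodes with diffuse,
#' non-corner memberships). Corner-assigned nodes carry membership of at
#' least 0.8 on their assigned archetype.
#'
#' @slot params planted [ModelParams].
#' @slot solution derived [ArchetypeSolution].
#' @slot cornerPos integer vector, positive-space corner archetype per node
#'   (NA = interior).
#' @slot cornerNeg integer vector for the negative space.
#' @slot nodeLabels synthetic protein identifiers.
#'
#' @seealso [makePlantedParams()], [sampleNetwork()], [plantGoLabels()]
#' @export
setClass("PlantedTruth",
    slots = c(
        params = "ModelParams",
        solution = "ArchetypeSolution",
        cornerPos = "integer",
        cornerNeg = "integer",
        nodeLabels = "character"
    )
)

setValidity("PlantedTruth", function(object) {
    msgs <- character(0)
    Z <- object@solution@Z
    W <- object@solution@W
    ok <- function(M, corner) {
        idx <- which(!is.na(corner))
        length(idx) == 0 ||
            all(M[cbind(corner[idx], idx)] >= 0.8)
    }
    if (!ok(Z, object@cornerPos))
        msgs <- c(msgs, "positive-space corner nodes need membership >= 0.8")
    if (!ok(W, object@cornerNeg))
        msgs <- c(msgs, "negative-space corner nodes need membership >= 0.8")
    if (length(msgs)) msgs else TRUE
})

#' EvaluationSplit: a connectivity-preserving link-prediction split
#'
#' @slot trainNet residual [SignedNetwork] (connected) after edge removal.
#' @slot testDyads data.frame with columns `i`, `j`, `class` (one of
#'   `"neg"`, `"zr"`, `"pos"`); indices refer to the original network.
#' @slot fraction requested removal fraction.
#' @slot shortfall number of requested removals that could not be made
#'   without disconnecting the network.
#' @slot seed integer seed.
#'
#' @seealso [makeSplit()], [predictClasses()], [f1Scores()]
#' @export
setClass("EvaluationSplit",
    slots = c(
        trainNet = "SignedNetwork",
        testDyads = "data.frame",
        fraction = "numeric",
        shortfall = "integer",
        seed = "integer"
    )
)

#' EnrichmentConfig: thresholds of the archetype enrichment procedure
#'
#' Defaults mirror the published protocol: terms need at least 20 annotated
#' network proteins; first-bin hypergeometric p below 0.002; Benjamini-
#' Hochberg FDR level 0.05; first-bin maximality probability above 0.5;
#' bin sizes from 1% to 20% of the network in 1% steps; a term is enriched
#' when significant at half or more of the bin sizes.
#'
#' @slot minTermSize integer, minimum annotated proteins per term.
#' @slot pThreshold hypergeometric p-value cutoff.
#' @slot fdrLevel Benjamini-Hochberg FDR level.
#' @slot pmaxThreshold cutoff on the first-bin maximality probability.
#' @slot binFractions bin sizes as fractions of the network size.
#' @slot sarThreshold significance appearance rate cutoff.
#' @slot bootstrapReps bootstrap replicates for the maximality probability.
#'
#' @seealso [enrichArchetype()]
#' @export
setClass("EnrichmentConfig",
    slots = c(
        minTermSize = "integer",
        pThreshold = "numeric",
        fdrLevel = "numeric",
        pmaxThreshold = "numeric",
        binFractions = "numeric",
        sarThreshold = "numeric",
        bootstrapReps = "integer"
    ),
    prototype = list(
        minTermSize = 20L,
        pThreshold = 0.002,
        fdrLevel = 0.05,
        pmaxThreshold = 0.5,
        binFractions = seq(0.01, 0.20, by = 0.01),
        sarThreshold = 0.5,
        bootstrapReps = 1000L
    )
)

setValidity("EnrichmentConfig", function(object) {
    msgs <- character(0)
    th <- c(object@pThreshold, object@fdrLevel, object@pmaxThreshold,
            object@sarThreshold)
    if (any(th <= 0) || any(th >= 1))
        msgs <- c(msgs, "thresholds must lie in (0, 1)")
    f <- object@binFractions
    if (length(f) == 0 || any(diff(f) <= 0) || any(f <= 0) || any(f > 0.5))
        msgs <- c(msgs, "binFractions must be strictly increasing in (0, 0.5]")
    if (object@minTermSize < 1L) msgs <- c(msgs, "minTermSize must be >= 1")
    if (length(msgs)) msgs else TRUE
})

#' EnrichmentReport: per-term enrichment results for one archetype
#'
#' @slot details data.frame with one row per (term, bin fraction): columns
#'   `space`, `archetype`, `goId`, `fraction`, `binSize`, `labelledInBin`,
#'   `enrichmentValue`, `pValue`, `bhPass`, `pmax`, `significant`.
#' @slot summary data.frame with one row per term: columns `space`,
#'   `archetype`, `goId`, `nTerm`, `sar`, `medianEb0`, `minP`, `enriched`.
#' @slot config the [EnrichmentConfig] used.
#'
#' @seealso [enrichArchetype()]
#' @export
setClass("EnrichmentReport",
    slots = c(
        details = "data.frame",
        summary = "data.frame",
        config = "EnrichmentConfig"
    )
)
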