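## Synthetic signed networks with planted archetypal structure.
##
## The generator emulates the modular organisation of signed regulatory
## proteomes: proteins come in small tight latent modules (complexes or
## pathway cores) placed inside each archetype polytope, a share of the
## modules sit exactly at the polytope corners (pure archetypal profiles),
## and node random effects add degree heterogeneity. Edges are sampled as
## explicit Poisson differences, matching the Skellam likelihood exactly.

## Draw module centres on the simplex, preferring sparse (boundary-heavy)
## profiles. Best-candidate placement: each centre is the candidate whose
## scaled distance to already-placed centres (and to the corners, which
## host the corner modules) is largest, so modules spread across the
## polytope and degrade gracefully when it gets crowded.
.moduleCentres <- function(nModules, K, separation, alpha) {
    placed <- separation * diag(K)  # corners are occupied
    centres <- matrix(NA_real_, K, 0)
    for (mod in seq_len(nModules)) {
        cand <- matrix(stats::rgamma(K * 40, alpha), K)
        cand <- sweep(cand, 2, colSums(cand), "/")
        cand <- pmax(cand, 1e-4)
        cand <- sweep(cand, 2, colSums(cand), "/")
        sc <- separation * cand
        d2 <- outer(colSums(placed^2), colSums(sc^2), "+") -
            2 * crossprod(placed, sc)
        best <- which.max(apply(d2, 2, min))
        centres <- cbind(centres, cand[, best])
        placed <- cbind(placed, sc[, best])
    }
    centres
}

## Membership logits for one latent space; returns logits, gate logits and
## the corner assignment vector.
.plantSpace <- function(N, K, cornerFraction, sharpness, separation,
                        moduleSize, jitter, alpha) {
    corner <- rep(NA_integer_, N)
    nCorner <- round(cornerFraction * N)
    cornerNodes <- if (nCorner > 0) sample.int(N, nCorner) else integer(0)
    corner[cornerNodes] <- rep_len(sample.int(K), nCorner)

    logits <- matrix(NA_real_, K, N)
    interior <- setdiff(seq_len(N), cornerNodes)
    nModules <- max(1L, ceiling(length(interior) / moduleSize))
    centres <- .moduleCentres(nModules, K, separation, alpha)
    moduleOf <- rep_len(sample.int(nModules), length(interior))
    for (n in seq_along(interior)) {
        logits[, interior[n]] <- log(centres[, moduleOf[n]]) +
            stats::rnorm(K, 0, jitter)
    }
    for (n in cornerNodes) {
        base <- rep(0, K)
        base[corner[n]] <- sharpness
        logits[, n] <- base + stats::rnorm(K, 0, jitter)
    }
    ## gates concentrate each archetype's coefficients on its corner nodes,
    ## so the planted archetypes coincide with the pure profiles
    gate <- matrix(-8, K, N)
    if (nCorner > 0) gate[cbind(corner[cornerNodes], cornerNodes)] <- 8
    list(logits = logits, gate = gate, corner = corner)
}

#' Plant ground-truth parameters for a synthetic signed network
#'
#' Builds a [PlantedTruth-class]: a `cornerFraction` share of nodes receive
#' sharp memberships at the simplex corners (balanced across archetypes, so
#' per-archetype corner counts differ by at most one), and the remaining
#' nodes are organised into small tight latent modules whose centres are
#' spread across the archetype polytope. Random effects are drawn as
#' `Normal(effectScale, 0.25^2)`. Deterministic given `seed`.
#'
#' Defaults are calibrated so that a sampled network with
#' `N = 300, Kpos = Kneg = 3` has mean total degree of about 10, with edge
#' rates near one inside modules (locally dense, globally sparse), which is
#' the regime of curated signed regulatory interactomes.
#'
#' @param N number of nodes; must be at least `max(Kpos, Kneg)`.
#' @param Kpos,Kneg archetype counts of the two spaces.
#' @param cornerFraction share of nodes planted at simplex corners, in
#'   (0, 1].
#' @param sharpness corner logit magnitude; 8 gives corner memberships
#'   above 0.999.
#' @param effectScale mean of the node random effects.
#' @param seed integer seed.
#' @param separation scale of the archetype polytope (`Rpos = Rneg =
#'   separation * I`); controls how far modules sit apart.
#' @param moduleSize target number of nodes per latent module.
#' @param jitter standard deviation of the within-module logit noise.
#' @param alpha Dirichlet concentration of the module-centre profiles;
#'   values below one favour boundary-heavy (sharp) profiles.
#' @return a [PlantedTruth-class].
#' @export
makePlantedParams <- function(N, Kpos = 3L, Kneg = 3L, cornerFraction = 0.1,
                              sharpness = 8, effectScale = 0.8, seed = 1L,
                              separation = 40, moduleSize = 5L,
                              jitter = 0.01, alpha = 0.3) {
    N <- .stopifnotScalarCount(N, "N")
    Kpos <- .stopifnotScalarCount(Kpos, "Kpos")
    Kneg <- .stopifnotScalarCount(Kneg, "Kneg")
    if (N < max(Kpos, Kneg)) stop("need N >= max(Kpos, Kneg)")
    if (cornerFraction <= 0 || cornerFraction > 1)
        stop("cornerFraction must lie in (0, 1]")
    if (sharpness <= 0) stop("sharpness must be positive")
    set.seed(.stopifnotScalarCount(seed, "seed"))
    sp <- .plantSpace(N, Kpos, cornerFraction, sharpness, separation,
                      moduleSize, jitter, alpha)
    sn <- .plantSpace(N, Kneg, cornerFraction, sharpness, separation,
                      moduleSize, jitter, alpha)
    params <- new("ModelParams",
        Zlogits = sp$logits, Wlogits = sn$logits,
        gamma = stats::rnorm(N, effectScale, 0.25),
        delta = stats::rnorm(N, effectScale, 0.25),
        Rpos = separation * diag(Kpos), Rneg = separation * diag(Kneg),
        Gpos = sp$gate, Gneg = sn$gate)
    new("PlantedTruth",
        params = params,
        solution = archetypes(params),
        cornerPos = sp$corner,
        cornerNeg = sn$corner,
        nodeLabels = sprintf("P%04d", seq_len(N)))
}

setMethod("nodeLabels", "PlantedTruth", function(x) x@nodeLabels)
setMethod("nodeLabels", "FittedModel", function(x) x@nodeLabels)

setMethod("show", "PlantedTruth", function(object) {
    cat(sprintf(
        "PlantedTruth: N = %d, Kpos = %d, Kneg = %d, %d/%d corner nodes (pos/neg)\n",
        length(object@nodeLabels), nrow(object@params@Zlogits),
        nrow(object@params@Wlogits), sum(!is.na(object@cornerPos)),
        sum(!is.na(object@cornerNeg))))
})

#' Sample a signed network from planted parameters
#'
#' For every unordered pair the edge weight is drawn as the difference of
#' two independent Poisson variables with the planted rates,
#' `y_ij = Poisson(lambda+_ij) - Poisson(lambda-_ij)`; nonzero outcomes
#' become edges. The largest connected component is then extracted,
#' mirroring the construction of real signed interactomes, and the mapping
#' back to the planted node indices is returned alongside.
#'
#' @param truth a [PlantedTruth-class].
#' @param seed integer seed.
#' @return list with elements `network` (a connected
#'   [SignedNetwork-class]) and `truthIndex` (integer vector mapping each
#'   network node to its row in the planted truth).
#' @export
sampleNetwork <- function(truth, seed = 1L) {
    stopifnot(is(truth, "PlantedTruth"))
    set.seed(.stopifnotScalarCount(seed, "seed"))
    rates <- rateMatrices(truth@params)
    N <- nNodes(truth@params)
    pidx <- .pairIndex(N)
    lp <- rates$lambdaPos[pidx$idx]
    ln <- rates$lambdaNeg[pidx$idx]
    y <- stats::rpois(length(lp), lp) - stats::rpois(length(ln), ln)
    keep <- y != 0L
    full <- SignedNetwork(
        nodes = truth@nodeLabels,
        edges = cbind(pidx$i[keep], pidx$j[keep]),
        weights = y[keep])
    if (nEdges(full) == 0)
        stop("no edges sampled; increase effectScale")
    lcc <- largestConnectedComponent(full)
    Kmax <- max(nrow(truth@params@Zlogits), nrow(truth@params@Wlogits))
    if (nNodes(lcc) < Kmax + 2)
        stop("largest connected component is too small; increase effectScale")
    list(network = lcc,
         truthIndex = match(nodeLabels(lcc), truth@nodeLabels))
}

#' Plant GO labels around an archetype
#'
#' Labels `nLabeled` proteins with a chosen term so that a `nearFraction`
#' share of the labels go to the nodes latent-closest to a given archetype
#' (by [nodeArchetypeDistance()] on the planted solution) and the rest are
#' scattered uniformly elsewhere. Uniformly labelled decoy terms of the
#' same size are emitted alongside, giving enrichment procedures a null to
#' calibrate against. Deterministic given `seed`.
#'
#' @param truth a [PlantedTruth-class].
#' @param space `"pos"` or `"neg"`.
#' @param archetype archetype index the term is planted around.
#' @param termId GO identifier of the planted term.
#' @param nLabeled total number of labelled proteins (at least 20, the
#'   minimum term size of the enrichment protocol).
#' @param nearFraction share of labels assigned to the closest nodes.
#' @param seed integer seed.
#' @param nDecoys number of uniformly labelled decoy terms.
#' @return an [AnnotationTable-class] (aspect `BP` throughout).
#' @export
plantGoLabels <- function(truth, space = c("pos", "neg"), archetype = 1L,
                          termId = "GO:9999999", nLabeled = 40L,
                          nearFraction = 0.9, seed = 1L, nDecoys = 50L) {
    stopifnot(is(truth, "PlantedTruth"))
    space <- match.arg(space)
    N <- length(truth@nodeLabels)
    nLabeled <- .stopifnotScalarCount(nLabeled, "nLabeled")
    if (nLabeled < 20L) stop("nLabeled must be at least 20")
    if (nLabeled > N) stop("cannot label more proteins than exist")
    if (nearFraction < 0 || nearFraction > 1)
        stop("nearFraction must lie in [0, 1]")
    set.seed(.stopifnotScalarCount(seed, "seed"))
    d <- nodeArchetypeDistance(truth@solution, space)[, archetype]
    nNear <- round(nearFraction * nLabeled)
    nearIdx <- order(d, seq_len(N))[seq_len(nNear)]
    restPool <- setdiff(seq_len(N), nearIdx)
    farIdx <- if (nLabeled - nNear > 0)
        sample(restPool, nLabeled - nNear) else integer(0)
    labelled <- c(nearIdx, farIdx)
    rows <- data.frame(
        protein = truth@nodeLabels[labelled],
        goId = termId,
        aspect = "BP",
        stringsAsFactors = FALSE)
    for (dcy in seq_len(nDecoys)) {
        idx <- sample.int(N, nLabeled)
        rows <- rbind(rows, data.frame(
            protein = truth@nodeLabels[idx],
            goId = sprintf("GO:DECOY%03d", dcy),
            aspect = "BP",
            stringsAsFactors = FALSE))
    }
    AnnotationTable(rows)
}
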