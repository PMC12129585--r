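## Archetype GO-term enrichment: distance-sorted equal-size bins,
## enrichment values, hypergeometric significance, Benjamini-Hochberg
## control, the bootstrap first-bin maximality probability, and the
## significance appearance rate over bin sizes.

#' Enrichment configuration constructor
#'
#' @param minTermSize,pThreshold,fdrLevel,pmaxThreshold,binFractions,sarThreshold,bootstrapReps
#'   see [EnrichmentConfig-class] for meanings and defaults.
#' @return an [EnrichmentConfig-class].
#' @export
enrichmentConfig <- function(minTermSize = 20L, pThreshold = 0.002,
                             fdrLevel = 0.05, pmaxThreshold = 0.5,
                             binFractions = seq(0.01, 0.20, by = 0.01),
                             sarThreshold = 0.5, bootstrapReps = 1000L) {
    new("EnrichmentConfig", minTermSize = as.integer(minTermSize),
        pThreshold = pThreshold, fdrLevel = fdrLevel,
        pmaxThreshold = pmaxThreshold, binFractions = binFractions,
        sarThreshold = sarThreshold, bootstrapReps = as.integer(bootstrapReps))
}

#' Assign nodes to equal-size distance bins
#'
#' Nodes are sorted by increasing distance to an archetype (ties broken by
#' node index) and cut into `floor(N / s)` bins of size
#' `s = max(1, round(binFraction * N))`; bin 1 holds the closest nodes.
#' When N is not divisible by the bin size, the leftover most-distant nodes
#' are appended to the last bin, so the tested first bin always has exactly
#' `s` members.
#'
#' @param distances length-N nonnegative distances.
#' @param binFraction bin size as a fraction of N, in (0, 0.5].
#' @return integer vector of bin labels (1 = closest bin).
#' @export
binNodes <- function(distances, binFraction) {
    if (binFraction <= 0 || binFraction > 0.5)
        stop("binFraction must lie in (0, 0.5]")
    if (any(distances < 0) || any(!is.finite(distances)))
        stop("distances must be finite and nonnegative")
    N <- length(distances)
    s <- max(1L, as.integer(round(binFraction * N)))
    if (N < 2L * s) stop("fewer than two bins; decrease binFraction")
    B <- N %/% s
    o <- order(distances, seq_len(N))
    lab <- pmin(((seq_len(N) - 1L) %/% s) + 1L, B)
    bins <- integer(N)
    bins[o] <- lab
    bins
}

#' Enrichment value of a term in a bin
#'
#' Ratio of the term's label density inside the bin to its density in the
#' whole network: `E = (|bin & labeled| / |bin|) / P`, where `P` is the
#' overall label density. A value above one means over-representation near
#' the archetype.
#'
#' @param binMembers integer vector of node indices in the bin.
#' @param labeled integer vector of labelled node indices.
#' @param overallDensity the term's density over all network nodes (> 0).
#' @return nonnegative enrichment value.
#' @export
enrichmentValue <- function(binMembers, labeled, overallDensity) {
    if (length(binMembers) == 0) stop("bin must be nonempty")
    if (overallDensity <= 0)
        stop("term has zero overall density; it should have been filtered")
    rho <- length(intersect(binMembers, labeled)) / length(binMembers)
    rho / overallDensity
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least `k` labelled proteins in a bin of size
#' `s` when `K` of the `N` network proteins carry the label:
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, s)`.
#'
#' @param k labelled-in-bin count.
#' @param s bin size.
#' @param K labelled-in-network count.
#' @param N network size.
#' @return p-value in (0, 1].
#' @export
hypergeomPvalue <- function(k, s, K, N) {
    if (any(k < 0) || any(k > pmin(s, K)) || any(K > N) || any(s > N))
        stop("inconsistent hypergeometric counts")
    stats::phyper(k - 1, K, N - K, s, lower.tail = FALSE)
}

#' Benjamini-Hochberg pass mask
#'
#' Step-up false-discovery-rate control: hypotheses whose BH-adjusted
#' p-value (via [stats::p.adjust()]) is at most `fdrLevel` pass, which is
#' equivalent to the classical largest-rank step-up rule.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @param fdrLevel FDR level.
#' @return logical pass mask (empty for empty input).
#' @export
benjaminiHochberg <- function(pvalues, fdrLevel = 0.05) {
    if (length(pvalues) == 0) return(logical(0))
    if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvalues, method = "BH") <= fdrLevel
}

#' Probability that the first bin's enrichment is maximal
#'
#' Bootstrap over proteins: in each replicate every bin's members are
#' resampled with replacement (bin sizes preserved), all enrichment values
#' are recomputed, and the replicate scores one if the first bin's value is
#' the strict maximum (ties score zero). The returned probability is the
#' scoring fraction. Deterministic given `seed`.
#'
#' @param bins integer bin labels from [binNodes()] (1 = closest).
#' @param labeled integer vector of labelled node indices.
#' @param reps bootstrap replicates (values below 100 warn).
#' @param seed integer seed.
#' @return estimated probability in [0, 1].
#' @export
pmaxProbability <- function(bins, labeled, reps = 1000L, seed = 1L) {
    reps <- .stopifnotScalarCount(reps, "reps")
    if (reps < 100) warning("fewer than 100 replicates: unstable estimate")
    B <- max(bins)
    if (B < 2) stop("need at least two bins")
    isLab <- seq_along(bins) %in% labeled
    s <- tabulate(bins, B)
    k <- vapply(seq_len(B), function(b) sum(isLab[bins == b]), 0L)
    set.seed(.stopifnotScalarCount(seed, "seed"))
    ## resampling a bin's members with replacement makes the resampled
    ## labelled count Binomial(s_b, k_b / s_b)
    draws <- matrix(stats::rbinom(B * reps, size = rep(s, each = reps),
                                  prob = rep(k / s, each = reps)),
                    nrow = reps)
    dens <- sweep(draws, 2, s, "/")
    mean(dens[, 1] > apply(dens[, -1, drop = FALSE], 1, max))
}

#' GO-term enrichment of one archetype
#'
#' Implements the full multi-bin-size protocol. Terms annotated on fewer
#' than `minTermSize` network proteins are excluded. For every bin-size
#' fraction, nodes are binned by latent distance to the archetype; a term
#' is significant at that fraction iff its first-bin hypergeometric
#' p-value is below `pThreshold`, it passes Benjamini-Hochberg control at
#' `fdrLevel` among the terms tested at that fraction, and its first-bin
#' maximality probability exceeds `pmaxThreshold`. The significance
#' appearance rate (SAR) is the share of bin fractions at which a term is
#' significant; terms with SAR at or above `sarThreshold` are declared
#' enriched. Label densities are computed over all network nodes, so
#' unannotated proteins count toward denominators.
#'
#' @param sol an [ArchetypeSolution-class].
#' @param space `"pos"` or `"neg"`.
#' @param archetype archetype index.
#' @param annotations an [AnnotationTable-class].
#' @param nodeLabels character vector of protein identifiers matching the
#'   solution's node columns (used to join annotations).
#' @param config an [EnrichmentConfig-class].
#' @param seed integer seed for the bootstrap maximality probability.
#' @return an [EnrichmentReport-class].
#' @export
enrichArchetype <- function(sol, space = c("pos", "neg"), archetype,
                            annotations, nodeLabels,
                            config = enrichmentConfig(), seed = 1L) {
    stopifnot(is(sol, "ArchetypeSolution"), is(annotations, "AnnotationTable"),
              is(config, "EnrichmentConfig"))
    space <- match.arg(space)
    seed <- .stopifnotScalarCount(seed, "seed")
    N <- ncol(if (space == "pos") sol@Z else sol@W)
    if (length(nodeLabels) != N)
        stop("nodeLabels must match the solution's node count")
    ann <- annotations@annotations
    ann <- ann[ann$protein %in% nodeLabels, , drop = FALSE]
    termNodes <- lapply(split(ann$protein, ann$goId),
                        function(p) match(unique(p), nodeLabels))
    sizes <- lengths(termNodes)
    termNodes <- termNodes[sizes >= config@minTermSize]
    emptyReport <- function() new("EnrichmentReport",
        details = data.frame(), summary = data.frame(), config = config)
    if (length(termNodes) == 0) {
        warning("no term meets the minimum size after network restriction")
        return(emptyReport())
    }
    terms <- names(termNodes)
    d <- nodeArchetypeDistance(sol, space)[, archetype]
    details <- list()
    for (fi in seq_along(config@binFractions)) {
        f <- config@binFractions[fi]
        bins <- tryCatch(binNodes(d, f), error = function(e) e)
        if (inherits(bins, "error")) {
            warning(sprintf("bin fraction %.2f skipped: %s", f,
                            conditionMessage(bins)))
            next
        }
        s <- sum(bins == 1L)
        firstBin <- which(bins == 1L)
        k <- vapply(termNodes, function(tn) length(intersect(firstBin, tn)),
                    0L)
        Kl <- lengths(termNodes)
        p <- hypergeomPvalue(k, s, Kl, N)
        bh <- benjaminiHochberg(p, config@fdrLevel)
        eb0 <- (k / s) / (Kl / N)
        pm <- rep(NA_real_, length(terms))
        cand <- which(p < config@pThreshold & bh)
        for (ti in cand) {
            pm[ti] <- pmaxProbability(bins, termNodes[[ti]],
                                      reps = config@bootstrapReps,
                                      seed = seed + 1000L * fi + ti)
        }
        details[[length(details) + 1L]] <- data.frame(
            space = space, archetype = archetype, goId = terms,
            fraction = f, binSize = s, labelledInBin = k,
            enrichmentValue = eb0, pValue = p, bhPass = bh, pmax = pm,
            significant = !is.na(pm) & pm > config@pmaxThreshold,
            stringsAsFactors = FALSE)
    }
    if (length(details) == 0) {
        warning("no usable bin fraction")
        return(emptyReport())
    }
    det <- do.call(rbind, details)
    rownames(det) <- NULL
    nFrac <- length(unique(det$fraction))
    summ <- do.call(rbind, lapply(terms, function(tm) {
        sub <- det[det$goId == tm, , drop = FALSE]
        sar <- sum(sub$significant) / nFrac
        data.frame(space = space, archetype = archetype, goId = tm,
                   nTerm = length(termNodes[[tm]]), sar = sar,
                   medianEb0 = stats::median(sub$enrichmentValue),
                   minP = min(sub$pValue),
                   enriched = sar >= config@sarThreshold,
                   stringsAsFactors = FALSE)
    }))
    rownames(summ) <- NULL
    new("EnrichmentReport", details = det, summary = summ, config = config)
}

setMethod("show", "EnrichmentReport", function(object) {
    s <- object@summary
    cat(sprintf("EnrichmentReport: %d terms tested, %d enriched\n",
                nrow(s), if (nrow(s)) sum(s$enriched) else 0L))
    if (nrow(s) && any(s$enriched)) {
        e <- s[s$enriched, c("goId", "nTerm", "sar", "medianEb0", "minP")]
        print(utils::head(e[order(-e$sar, e$minP), ], 10), row.names = FALSE)
    }
})
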