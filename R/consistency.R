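## Bayesian Normalized Mutual Information between soft membership
## solutions, the multi-rerun protocol, and its permutation null.

.checkMembershipRun <- function(Q, what) {
    if (!is.matrix(Q) || nrow(Q) < 1L)
        stop(what, " must be a K x N membership matrix")
    err <- .checkSimplexCols(Q, what)
    if (!is.null(err)) stop(err)
    Q
}

#' Soft mutual information between two membership solutions
#'
#' Treats a run's K x N membership matrix as the conditional distribution
#' `p(k | n)` over archetypes given a uniformly drawn node, forms the joint
#' \deqn{p(k, k') = \frac{1}{N}\sum_n q_{kn} q'_{k'n}} and returns its
#' mutual information in nats. Terms with `p(k, k') = 0` contribute zero.
#' The archetype counts of the two runs may differ.
#'
#' @param Qa,Qb K x N columnwise-simplex membership matrices over the same
#'   N nodes.
#' @return nonnegative mutual information (nats).
#' @export
softMutualInformation <- function(Qa, Qb) {
    .checkMembershipRun(Qa, "Qa")
    .checkMembershipRun(Qb, "Qb")
    if (ncol(Qa) != ncol(Qb))
        stop("membership runs must cover the same nodes")
    N <- ncol(Qa)
    P <- tcrossprod(Qa, Qb) / N
    E <- outer(rowSums(P), colSums(P))
    pos <- P > 0
    sum(P[pos] * log(P[pos] / E[pos]))
}

#' Bayesian Normalized Mutual Information
#'
#' Normalises the soft mutual information of two runs by the arithmetic
#' mean of their self-informations:
#' \deqn{\mathrm{BNMI}(Q, Q') = \frac{2 I(Q, Q')}{I(Q, Q) + I(Q', Q')}.}
#' Equals 1 when the runs agree exactly and 0 when their joint archetype
#' distribution factorizes (no shared structure). Symmetric in its
#' arguments and invariant to relabelling archetypes within either run.
#'
#' @param Qa,Qb K x N columnwise-simplex membership matrices.
#' @return a value in [0, 1] (up to floating-point rounding).
#' @export
bnmi <- function(Qa, Qb) {
    sa <- softMutualInformation(Qa, Qa)
    sb <- softMutualInformation(Qb, Qb)
    if (sa + sb == 0)
        stop("both solutions are uniform: no structure to compare")
    2 * softMutualInformation(Qa, Qb) / (sa + sb)
}

.permuteColumns <- function(Q) Q[, sample.int(ncol(Q)), drop = FALSE]

#' Consistency of archetype structure across model reruns
#'
#' Fits the model `runs` times with distinct seeds for each requested
#' archetype count, computes all pairwise BNMI values per latent space, and
#' contrasts them with a randomization null in which node correspondence is
#' destroyed: for every run pair the BNMI is averaged over random
#' permutations of the node axis of one member. High observed BNMI with a
#' null near zero indicates that the retrieved structure is consistent
#' rather than an artefact of the optimizer's randomness.
#'
#' @param net a connected [SignedNetwork-class].
#' @param kValues integer vector of archetype counts to profile (used for
#'   both spaces).
#' @param runs model reruns per K.
#' @param permutations random node permutations per run pair for the null.
#' @param seed integer seed; rerun seeds are derived from it.
#' @param control optimizer settings from [fitControl()].
#' @return data.frame with one row per (K, space): columns `K`, `space`,
#'   `nRuns`, `nPairs`, `meanBNMI`, `sdBNMI`, `nullMean`, `nullSd`.
#'   The fitted runs are attached as attribute `"fits"`.
#' @export
bnmiGrid <- function(net, kValues, runs = 5L, permutations = 100L,
                     seed = 1L, control = fitControl()) {
    stopifnot(is(net, "SignedNetwork"))
    runs <- .stopifnotScalarCount(runs, "runs")
    seed <- .stopifnotScalarCount(seed, "seed")
    rows <- list()
    fits <- list()
    for (ki in seq_along(kValues)) {
        K <- kValues[ki]
        runsQ <- list()
        for (r in seq_len(runs)) {
            fit <- tryCatch(
                fitSignedArchetypes(net, K, K, control = control,
                                    seed = seed + 1000L * ki + r),
                error = function(e) e)
            if (inherits(fit, "error")) {
                warning(sprintf("fit failed for K = %d, run %d: %s; excluded",
                                K, r, conditionMessage(fit)))
                next
            }
            runsQ[[length(runsQ) + 1L]] <- fit
        }
        fits[[as.character(K)]] <- runsQ
        for (space in c("pos", "neg")) {
            Qs <- lapply(runsQ, function(f)
                if (space == "pos") f@solution@Z else f@solution@W)
            nr <- length(Qs)
            obs <- c(); nul <- c()
            set.seed(seed + 17L * ki + (space == "neg"))
            if (nr >= 2) {
                for (a in seq_len(nr - 1)) for (b in (a + 1):nr) {
                    obs <- c(obs, bnmi(Qs[[a]], Qs[[b]]))
                    nul <- c(nul, mean(vapply(seq_len(permutations),
                        function(p) bnmi(Qs[[a]], .permuteColumns(Qs[[b]])),
                        0)))
                }
            }
            rows[[length(rows) + 1L]] <- data.frame(
                K = K, space = space, nRuns = nr,
                nPairs = length(obs),
                meanBNMI = mean(obs), sdBNMI = stats::sd(obs),
                nullMean = mean(nul), nullSd = stats::sd(nul))
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "fits") <- fits
    out
}
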