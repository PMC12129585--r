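#' @title Generics for SignedArchetypes containers
#' @name SignedArchetypes-generics
#' @keywords internal
NULL

#' Number of nodes
#' @param x a SignedNetwork or ModelParams.
#' @return integer scalar.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Number of edges
#' @param x a SignedNetwork.
#' @return integer scalar.
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' Node labels
#' @param x a SignedNetwork, FittedModel or PlantedTruth.
#' @return character vector of protein identifiers.
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' Simplex memberships of both latent spaces
#'
#' Columnwise softmax of the membership logits; each protein's memberships
#' over archetypes sum to one.
#'
#' @param object a ModelParams, FittedModel or PlantedTruth.
#' @return list with K x N matrices `Z` (positive space) and `W` (negative
#'   space).
#' @export
setGeneric("memberships", function(object) standardGeneric("memberships"))

#' Derived archetype solution
#'
#' Computes memberships, gated coefficient matrices and the archetype
#' matrices `Apos = Rpos Z Cpos`, `Aneg = Rneg W Cneg`.
#'
#' @param object a ModelParams, FittedModel or PlantedTruth.
#' @return an [ArchetypeSolution].
#' @export
setGeneric("archetypes", function(object) standardGeneric("archetypes"))

#' Predict three-way interaction classes for protein dyads
#'
#' For each dyad the Skellam class probabilities (negative, zero, positive
#' outcome) are computed from the model rates and the class with maximal
#' probability is returned; exact ties are broken in the order
#' zero > positive > negative, favouring the majority non-interaction class.
#'
#' @param object a [FittedModel], [ModelParams] or [PlantedTruth].
#' @param dyads two-column matrix or data.frame of node index pairs.
#' @return character vector of classes in `c("neg", "zr", "pos")`.
#' @export
setGeneric("predictClasses", function(object, dyads)
    standardGeneric("predictClasses"))
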