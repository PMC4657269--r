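#' @rdname ReactionUniverse-class
#' @param x,object a \code{ReactionUniverse}, \code{EnvironmentSet} or
#'   \code{RcfbaSolution}
#' @export
setGeneric("nMetabolites", function(x) standardGeneric("nMetabolites"))

#' @rdname ReactionUniverse-class
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' @rdname ReactionUniverse-class
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname ReactionUniverse-class
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname ReactionUniverse-class
#' @export
setGeneric("reactionKinds", function(x) standardGeneric("reactionKinds"))

#' @rdname ReactionUniverse-class
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' @rdname ReactionUniverse-class
#' @export
setGeneric("biomassId", function(x) standardGeneric("biomassId"))

#' @rdname ReactionUniverse-class
#' @export
setGeneric("exchangeIds", function(x) standardGeneric("exchangeIds"))

#' @rdname EnvironmentSet-class
#' @export
setGeneric("nConditions", function(x) standardGeneric("nConditions"))

#' @rdname EnvironmentSet-class
#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))

#' @rdname RcfbaSolution-class
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' @rdname RcfbaSolution-class
#' @export
setGeneric("investments", function(x) standardGeneric("investments"))

#' @rdname RcfbaSolution-class
#' @export
setGeneric("growthRates", function(x) standardGeneric("growthRates"))

#' @rdname RcfbaSolution-class
#' @export
setGeneric("switchingInvestments", function(x) standardGeneric("switchingInvestments"))

#' @rdname RcfbaSolution-class
#' @export
setGeneric("solutionStatus", function(x) standardGeneric("solutionStatus"))

#' Infer the optimal metabolic network from investment support
#'
#' Reactions whose optimised investment is above the support threshold in
#' at least one environmental condition are considered present in the
#' organism's metabolic network; pseudo-exchanges carry no investment and
#' are never part of the inferred network.
#'
#' @param solution an optimal [RcfbaSolution-class]
#' @param ... unused
#' @return character vector of selected reaction ids
#' @export
setGeneric("inferNetwork", function(solution, ...) standardGeneric("inferNetwork"))

#' Count regulons of an optimal solution
#'
#' Each selected reaction is assigned its binary activity pattern across
#' conditions (investment above threshold or not); reactions sharing a
#' pattern are regulated in concert and form one regulon.
#'
#' @param solution an optimal [RcfbaSolution-class]
#' @param ... unused
#' @return list with \code{count} (number of distinct patterns) and
#'   \code{patterns} (named list mapping pattern string to reaction ids)
#' @export
setGeneric("countRegulons", function(solution, ...) standardGeneric("countRegulons"))

#' Count selected input metabolites
#'
#' Number of exogenous metabolites actually taken up (pseudo-exchange flux
#' above tolerance) in at least one condition of an optimal solution.
#'
#' @param solution an optimal [RcfbaSolution-class]
#' @param ... unused
#' @return integer count
#' @export
setGeneric("selectedInputs", function(solution, ...) standardGeneric("selectedInputs"))
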