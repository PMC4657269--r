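#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

REACTION_KINDS <- c("enzymatic", "pseudo_exchange", "biomass")

#' ReactionUniverse: a universe of metabolic reactions
#'
#' Container for a constraint-based reaction universe: the stoichiometric
#' matrix \eqn{S} (metabolites x reactions) together with per-reaction
#' catalytic rates, reversibility and reaction kind. The universe is the
#' search space from which resource-constrained optimisation selects an
#' organism's metabolic network.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{isExternal} (extracellular copy of a transported metabolite) and
#'   \code{isCarrier} (currency/energy carrier, excluded from graph
#'   representations but never from the LP).
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{kind} (one of \code{enzymatic}, \code{pseudo_exchange},
#'   \code{biomass}), \code{reversible}, \code{alpha} (forward catalytic
#'   rate, flux units per resource unit) and \code{beta} (reverse rate;
#'   0 for irreversible reactions).
#' @slot S sparse \code{dgCMatrix}, one column per reaction holding its
#'   signed stoichiometry (negative = substrate, positive = product).
#'
#' @seealso [reactionUniverse()], [buildToyUniverse()], [readUniverse()]
#' @export
setClass("ReactionUniverse",
  representation(metabolites = "data.frame",
                 reactions   = "data.frame",
                 S           = "dgCMatrix"))

setValidity("ReactionUniverse", function(object) {
  met <- object@metabolites; rxn <- object@reactions; S <- object@S
  msgs <- character(0)
  needM <- c("id", "name", "isExternal", "isCarrier")
  needR <- c("id", "name", "kind", "reversible", "alpha", "beta")
  if (!all(needM %in% names(met))) return("metabolites table lacks required columns")
  if (!all(needR %in% names(rxn))) return("reactions table lacks required columns")
  if (anyDuplicated(met$id)) msgs <- c(msgs, "metabolite ids must be unique")
  if (anyDuplicated(rxn$id)) msgs <- c(msgs, "reaction ids must be unique")
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn))
    msgs <- c(msgs, "S dimensions do not match metabolite/reaction tables")
  if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id))
    msgs <- c(msgs, "S dimnames must equal metabolite and reaction ids")
  if (!all(rxn$kind %in% REACTION_KINDS))
    msgs <- c(msgs, sprintf("reaction kind must be one of: %s",
                            paste(REACTION_KINDS, collapse = ", ")))
  if (sum(rxn$kind == "biomass") > 1)
    msgs <- c(msgs, "at most one biomass reaction per universe")
  enz <- rxn$kind != "pseudo_exchange"
  if (any(enz & rxn$alpha <= 0))
    msgs <- c(msgs, "enzymatic alpha must be > 0")
  if (any(enz & !rxn$reversible & rxn$beta != 0))
    msgs <- c(msgs, "irreversible enzymatic reactions must have beta = 0")
  if (any(enz & rxn$reversible & rxn$beta <= 0))
    msgs <- c(msgs, "reversible enzymatic reactions must have beta > 0")
  if (nrow(S) > 0 && any(Matrix::rowSums(abs(S)) == 0))
    msgs <- c(msgs, "every metabolite must participate in at least one reaction")
  if (length(msgs)) msgs else TRUE
})

#' EnvironmentSet: per-condition exchange upper bounds
#'
#' A set of \eqn{P \ge 1} environmental conditions. Each condition maps
#' pseudo-exchange reaction ids to upper bounds on their (uptake-positive)
#' flux: \code{0} = nutrient absent, a finite value = limited supply,
#' \code{Inf} = unbounded availability. Pseudo-exchanges absent from a
#' condition's map default to upper bound 0. Secretion is never bounded:
#' pseudo-exchange fluxes have no lower bound.
#'
#' @slot conditions named list; each element a named numeric vector of
#'   upper bounds keyed by pseudo-exchange reaction id.
#'
#' @seealso [environmentSet()], [buildToyEnvironments()],
#'   [buildCoreEnvironments()]
#' @export
setClass("EnvironmentSet", representation(conditions = "list"))

setValidity("EnvironmentSet", function(object) {
  cond <- object@conditions
  if (length(cond) < 1) return("at least one condition is required")
  if (is.null(names(cond)) || anyDuplicated(names(cond)) || any(names(cond) == ""))
    return("conditions must have unique non-empty names")
  for (cc in cond) {
    if (length(cc) == 0) next
    if (!is.numeric(cc) || is.null(names(cc)) || any(names(cc) == ""))
      return("each condition must be a named numeric vector of upper bounds")
    if (any(is.na(cc)) || any(cc < 0))
      return("exchange upper bounds must be non-negative (Inf = unbounded)")
  }
  TRUE
})

#' ResourceParams: resource-allocation parameters
#'
#' @slot phi0 total cellular-resource capacity shared by all enzyme
#'   investments and the switching investment (resource units).
#' @slot r dimensionless switching parameter: weight of the investment
#'   needed to re-regulate enzymes between environments.
#' @slot tolSupport absolute threshold on an investment to count a
#'   reaction as present (default \code{1e-6 * phi0}).
#' @slot tolFeasibility feasibility tolerance used when checking solutions.
#' @slot weights optional per-condition objective weights (default uniform).
#'
#' @seealso [rcfbaParams()]
#' @export
setClass("ResourceParams",
  representation(phi0 = "numeric", r = "numeric", tolSupport = "numeric",
                 tolFeasibility = "numeric", weights = "numeric"))

setValidity("ResourceParams", function(object) {
  if (length(object@phi0) != 1 || object@phi0 <= 0) return("phi0 must be a single positive number")
  if (length(object@r) != 1 || object@r < 0) return("r must be a single non-negative number")
  if (object@tolSupport <= 0) return("tolSupport must be positive")
  if (object@tolFeasibility <= 0) return("tolFeasibility must be positive")
  if (length(object@weights) && any(object@weights < 0)) return("weights must be non-negative")
  TRUE
})

#' RcfbaSolution: solution of the resource-constrained multi-environment LP
#'
#' @slot universe the [ReactionUniverse-class] that was solved.
#' @slot envs the [EnvironmentSet-class] that was solved.
#' @slot params the [ResourceParams-class] used.
#' @slot nu N x P flux matrix (reactions x conditions).
#' @slot phi investment matrix (enzymatic + biomass reactions x conditions),
#'   non-negative.
#' @slot switching length-P switching investments, recomputed from \code{phi}.
#' @slot growth length-P biomass fluxes.
#' @slot objective weighted mean growth over conditions.
#' @slot selected ids of reactions with investment above threshold in at
#'   least one condition (the inferred metabolic network).
#' @slot activePerEnv per-condition list of reaction ids with investment
#'   above threshold.
#' @slot status \code{"optimal"}, \code{"infeasible"} or \code{"unbounded"}.
#'
#' @seealso [solveRcfba()], [inferNetwork()], [countRegulons()]
#' @export
setClass("RcfbaSolution",
  representation(universe = "ReactionUniverse", envs = "EnvironmentSet",
                 params = "ResourceParams", nu = "matrix", phi = "matrix",
                 switching = "numeric", growth = "numeric",
                 objective = "numeric", selected = "character",
                 activePerEnv = "list", status = "character"))

#' MetGraph: directed metabolite graph
#'
#' Directed graph over non-carrier metabolites: one edge from every
#' substrate to every product of each (non-pseudo, non-biomass) reaction,
#' both directions for reversible reactions, parallel edges collapsed.
#' Node roles: \code{input} (external copy of a transported metabolite),
#' \code{biomass_component} (non-carrier substrate of the biomass
#' reaction), otherwise \code{internal}.
#'
#' @slot graph an \pkg{igraph} directed graph; vertex attributes
#'   \code{role}, \code{isInput}, \code{isBiomassComponent}; edge attribute
#'   \code{reactions} (provenance: originating reaction ids).
#' @slot carriers carrier metabolite ids that were removed.
#'
#' @seealso [buildGraph()], [structuralMetrics()]
#' @export
setClass("MetGraph", representation(graph = "ANY", carriers = "character"))
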