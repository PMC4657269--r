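# Standard (resource-free) FBA and the single-reaction deletion screen.

assembleFba <- function(universe, environment, fluxBound = 1000,
                        knockout = NULL) {
  rxn <- universe@reactions
  S <- universe@S
  N <- ncol(S)
  bm <- which(rxn$kind == "biomass")
  if (!length(bm)) stop("universe has no biomass reaction")
  lower <- ifelse(rxn$kind == "pseudo_exchange" | rxn$reversible,
                  -fluxBound, 0)
  upper <- rep(fluxBound, N)
  exch <- rxn$kind == "pseudo_exchange"
  b <- exchangeBound(environment, 1)[rxn$id]
  b[exch & is.na(b)] <- 0
  upper[exch] <- pmin(b[exch], fluxBound)
  if (!is.null(knockout)) {
    j <- match(knockout, rxn$id)
    if (anyNA(j)) stop("unknown reaction id: ",
                       paste(knockout[is.na(j)], collapse = ", "))
    lower[j] <- 0; upper[j] <- 0
  }
  obj <- numeric(N); obj[bm] <- 1
  lp <- newLpProblem(N, obj, "max", lower, upper)
  ss <- Matrix::summary(S)
  lpAddRows(lp, "eq", i = ss$i, j = ss$j, x = ss$x, rhs = numeric(nrow(S)))
}

#' Maximal growth under standard flux balance analysis
#'
#' Maximises the biomass flux subject to mass balance and flux capacity
#' bounds only (no resource constraint). Enzymatic fluxes are capped at
#' \code{fluxBound} in the forward (and, if reversible, reverse)
#' direction; exchange uptakes are capped at the condition's bound, with
#' \code{fluxBound} standing in for unbounded availability. An infeasible
#' problem reports growth 0.
#'
#' @param universe a [ReactionUniverse-class]
#' @param environment an [EnvironmentSet-class] with a single condition
#'   (default: [richMedium()], every nutrient available)
#' @param fluxBound flux capacity in arbitrary units (default 1000, the
#'   common constraint-based convention)
#' @param knockout optional reaction id(s) whose flux is fixed to 0
#' @return maximal biomass flux (numeric)
#' @export
fbaMaxGrowth <- function(universe, environment = richMedium(universe),
                         fluxBound = 1000, knockout = NULL) {
  sol <- solveLp(assembleFba(universe, environment, fluxBound, knockout))
  if (!identical(sol$status, "optimal")) return(0)
  sol$objective
}

#' Single-reaction deletion screen
#'
#' Deletes every non-pseudo reaction in turn (reaction-level deletion;
#' gene-protein-reaction logic is out of scope) and re-solves standard
#' FBA in rich medium. A reaction is essential when the knockout growth
#' falls below \code{viabilityFraction} times the wild-type growth.
#'
#' @inheritParams fbaMaxGrowth
#' @param viabilityFraction relative viability threshold (default 1e-6)
#' @return data.frame with columns \code{id}, \code{wildType},
#'   \code{knockout}, \code{essential}
#' @export
deletionScreen <- function(universe, environment = richMedium(universe),
                           fluxBound = 1000, viabilityFraction = 1e-6) {
  targets <- knockoutIds(universe)
  lps <- c(list(assembleFba(universe, environment, fluxBound)),
           lapply(targets, function(id)
             assembleFba(universe, environment, fluxBound, knockout = id)))
  sols <- solveLpBatch(lps)
  gr <- vapply(sols, function(s)
    if (identical(s$status, "optimal")) s$objective else 0, numeric(1))
  wt <- gr[1]
  if (wt <= 0)
    stop("wild type does not grow in the given environment; ",
         "essentiality is undefined for a non-viable network")
  data.frame(id = targets, wildType = wt, knockout = gr[-1],
             essential = gr[-1] < viabilityFraction * wt)
}

#' Fraction of essential reactions
#'
#' Essential reactions divided by the number of non-pseudo reactions,
#' from an exhaustive single-deletion screen in rich medium.
#'
#' @inheritParams deletionScreen
#' @return numeric fraction in [0, 1]; the screen table is attached as
#'   attribute \code{"screen"}
#' @export
essentialFraction <- function(universe, environment = richMedium(universe),
                              fluxBound = 1000, viabilityFraction = 1e-6) {
  screen <- deletionScreen(universe, environment, fluxBound,
                           viabilityFraction)
  structure(mean(screen$essential), screen = screen)
}
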