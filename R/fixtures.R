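#' The canonical two-substrate toy universe
#'
#' A 12-metabolite universe with 14 enzymatic reactions (biomass included)
#' plus two costless pseudo-exchanges supplying the alternative substrates
#' S1 and S2. Two direct five-reaction routes (S1-A-C-D-E-P and
#' S2-B-F-G-E-P) compete with two six-reaction routes that share a hub
#' metabolite H (S1-A-H-I-D-E-P and S2-B-H-I-D-E-P). All catalytic rates
#' are 1, all reactions irreversible. Under a fluctuating two-condition
#' environment this universe exhibits a structural transition at r = 0.25
#' (direct routes replaced by the hub design) and a regulatory transition
#' at r = 0.5 (regulated expression replaced by constitutive expression).
#'
#' @return a [ReactionUniverse-class]
#' @examples
#' toy <- buildToyUniverse()
#' sum(reactionKinds(toy) != "pseudo_exchange")  # 14
#' @export
buildToyUniverse <- function() {
  mets <- data.frame(
    id = c("S1", "S2", "A", "B", "C", "D", "E", "F", "G", "H", "I", "P"),
    isExternal = c(TRUE, TRUE, rep(FALSE, 10)))
  conv <- list(
    uptake1 = c("S1", "A"), uptake2 = c("S2", "B"),
    A_C = c("A", "C"), C_D = c("C", "D"), D_E = c("D", "E"),
    B_F = c("B", "F"), F_G = c("F", "G"), G_E = c("G", "E"),
    E_P = c("E", "P"),
    A_H = c("A", "H"), B_H = c("B", "H"), H_I = c("H", "I"), I_D = c("I", "D"))
  sto <- lapply(conv, function(p) stats::setNames(c(-1, 1), p))
  sto$biomass <- c(P = -1)
  sto$EX_S1 <- c(S1 = 1)
  sto$EX_S2 <- c(S2 = 1)
  rxns <- data.frame(
    id = names(sto),
    kind = c(rep("enzymatic", length(conv)), "biomass",
             "pseudo_exchange", "pseudo_exchange"))
  reactionUniverse(mets, rxns, sto)
}

#' Two alternating single-substrate conditions for the toy universe
#'
#' Condition 1 supplies S1 only (unbounded), condition 2 supplies S2 only.
#'
#' @return an [EnvironmentSet-class] with P = 2
#' @export
buildToyEnvironments <- function() {
  environmentSet(list(env_S1 = c(EX_S1 = Inf, EX_S2 = 0),
                      env_S2 = c(EX_S1 = 0, EX_S2 = Inf)))
}

CORE_CARBON_EXCHANGES <- c(acetate = "EX_ac_e", pyruvate = "EX_pyr_e",
                           `L-malate` = "EX_mal__L_e",
                           `L-glutamate` = "EX_glu__L_e",
                           `D-glucose` = "EX_glc__D_e")
CORE_AUX_EXCHANGES <- c(O2 = "EX_o2_e", NH4 = "EX_nh4_e", Pi = "EX_pi_e",
                        CO2 = "EX_co2_e")
# water and protons are exchanged freely in the published core model
CORE_FREE_EXCHANGES <- c(H2O = "EX_h2o_e", H = "EX_h_e")

#' Five single-carbon-source conditions for the E. coli core universe
#'
#' One condition per carbon source (acetate, pyruvate, L-malate,
#' L-glutamate, D-glucose); in each, the focal carbon exchange is
#' unbounded and the other four are closed. Ammonium, phosphate and CO2
#' are unbounded in every condition; oxygen is unbounded in the four
#' aerobic conditions and closed in the D-glucose (anaerobic) condition.
#' Water and protons are exchanged freely in every condition (the
#' published model's default bounds); secretion of any exogenous
#' metabolite is always allowed.
#'
#' @param universe a core-network [ReactionUniverse-class] containing the
#'   standard exchange identifiers (\code{EX_ac_e}, \code{EX_pyr_e},
#'   \code{EX_mal__L_e}, \code{EX_glu__L_e}, \code{EX_glc__D_e},
#'   \code{EX_o2_e}, \code{EX_nh4_e}, \code{EX_pi_e}, \code{EX_co2_e})
#' @return an [EnvironmentSet-class] with P = 5
#' @export
buildCoreEnvironments <- function(universe) {
  need <- c(CORE_CARBON_EXCHANGES, CORE_AUX_EXCHANGES, CORE_FREE_EXCHANGES)
  missing <- setdiff(need, exchangeIds(universe))
  if (length(missing))
    stop("universe lacks expected exchange reaction(s): ",
         paste(missing, collapse = ", "),
         "; expected identifiers: ", paste(need, collapse = ", "))
  conds <- lapply(names(CORE_CARBON_EXCHANGES), function(cs) {
    b <- stats::setNames(rep(0, length(CORE_CARBON_EXCHANGES)),
                         CORE_CARBON_EXCHANGES)
    b[CORE_CARBON_EXCHANGES[[cs]]] <- Inf
    b[CORE_AUX_EXCHANGES[c("NH4", "Pi", "CO2")]] <- Inf
    b[CORE_AUX_EXCHANGES[["O2"]]] <- if (cs == "D-glucose") 0 else Inf
    b[CORE_FREE_EXCHANGES] <- Inf
    b
  })
  names(conds) <- names(CORE_CARBON_EXCHANGES)
  environmentSet(conds)
}

#' Rich-medium environment: every exogenous metabolite available
#'
#' @param universe a [ReactionUniverse-class]
#' @param bound upper bound placed on each uptake (default \code{Inf};
#'   the essentiality screen caps fluxes separately)
#' @return an [EnvironmentSet-class] with a single condition \code{rich}
#' @export
richMedium <- function(universe, bound = Inf) {
  ex <- exchangeIds(universe)
  environmentSet(list(rich = stats::setNames(rep(bound, length(ex)), ex)))
}

#' Randomize catalytic rates
#'
#' Returns a copy of the universe in which every invested (enzymatic or
#' biomass) reaction receives \code{alpha + U(-sigma, sigma)}; reversible
#' reactions also receive \code{beta + U(-sigma, sigma)}. Irreversible
#' betas stay 0. Draws are reproducible from \code{seed} and do not
#' disturb the caller's RNG state.
#'
#' @param universe a [ReactionUniverse-class] (rates are taken as the means)
#' @param sigma half-width of the uniform perturbation, in \code{[0, 1)}
#'   so that unit-mean rates stay positive
#' @param seed integer seed
#' @return a [ReactionUniverse-class]
#' @export
randomizeRates <- function(universe, sigma, seed) {
  if (sigma < 0 || sigma >= 1)
    stop("sigma must be in [0, 1): alpha could become non-positive")
  rxn <- universe@reactions
  enz <- rxn$kind != "pseudo_exchange"
  if (sigma > 0) {
    draws <- withSeed(seed, function() {
      list(a = stats::runif(sum(enz), -sigma, sigma),
           b = stats::runif(sum(enz), -sigma, sigma))
    })
    rxn$alpha[enz] <- rxn$alpha[enz] + draws$a
    rev <- enz & rxn$reversible
    rxn$beta[rev] <- rxn$beta[rev] + draws$b[rxn$reversible[enz]]
  }
  methods::initialize(universe, reactions = rxn)
}

# run fn under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a random layered viable universe
#'
#' Synthetic layered universe for property testing: \code{nSubstrates}
#' external substrates feed layer 1; every metabolite of layer j gains one
#' guaranteed and up to two extra random conversions into layer j+1; every
#' final-layer metabolite feeds the biomass reaction. Viability (a route
#' from every substrate to biomass) holds by construction. All rates are
#' 1, all reactions irreversible.
#'
#' @param nLayers number of internal layers (>= 2)
#' @param width metabolites per layer (>= 1)
#' @param nSubstrates number of external substrates (>= 1)
#' @param seed integer seed (reproducible)
#' @return a [ReactionUniverse-class]
#' @examples
#' u <- generateRandomUniverse(2, 1, 1, seed = 1)  # a single linear chain
#' @export
generateRandomUniverse <- function(nLayers, width, nSubstrates, seed) {
  stopifnot(nLayers >= 2, width >= 1, nSubstrates >= 1)
  withSeed(seed, function() {
    subs <- paste0("S", seq_len(nSubstrates))
    layers <- lapply(seq_len(nLayers), function(j)
      paste0("L", j, "_", seq_len(width)))
    mets <- data.frame(id = c(subs, unlist(layers), "BM"),
                       isExternal = c(rep(TRUE, nSubstrates),
                                      rep(FALSE, nLayers * width + 1)))
    sto <- list()
    addConv <- function(from, to) {
      id <- paste0("v_", from, "_", to)
      if (is.null(sto[[id]]))
        sto[[id]] <<- stats::setNames(c(-1, 1), c(from, to))
    }
    for (s in subs) addConv(s, sample(layers[[1]], 1))
    for (j in seq_len(nLayers - 1)) {
      for (m in layers[[j]]) {
        addConv(m, sample(layers[[j + 1]], 1))
        for (extra in seq_len(sample(0:2, 1)))
          addConv(m, sample(layers[[j + 1]], 1))
      }
    }
    for (m in layers[[nLayers]]) addConv(m, "BM")
    nEnz <- length(sto)
    sto$biomass <- c(BM = -1)
    for (s in subs) sto[[paste0("EX_", s)]] <- stats::setNames(1, s)
    rxns <- data.frame(id = names(sto),
                       kind = c(rep("enzymatic", nEnz), "biomass",
                                rep("pseudo_exchange", nSubstrates)))
    reactionUniverse(mets, rxns, sto)
  })
}

#' All-substrates environment for a generated universe
#'
#' @param universe a [ReactionUniverse-class]
#' @return an [EnvironmentSet-class] with one condition per substrate, the
#'   focal substrate unbounded and all others closed
#' @export
alternatingEnvironments <- function(universe) {
  ex <- exchangeIds(universe)
  conds <- lapply(ex, function(e) {
    b <- stats::setNames(rep(0, length(ex)), ex); b[e] <- Inf; b
  })
  names(conds) <- paste0("env_", sub("^EX_", "", ex))
  environmentSet(conds)
}
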