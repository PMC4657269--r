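# Resource-constrained multi-environment flux balance analysis.
#
# Decision variables, for P conditions over a universe with N reactions of
# which the invested ones (enzymatic + biomass) number nE:
#   nu_i^k   flux of reaction i in condition k (free for reversible and
#            for pseudo-exchanges, >= 0 otherwise)
#   phi_e^k  enzyme investment (>= 0), invested reactions only
#   d_e^{kl} auxiliary |phi_e^k - phi_e^l| linearisation, unordered pairs
# Constraints: mass balance S nu^k = 0; kinetic coupling
# -beta phi <= nu <= alpha phi; finite exchange upper bounds; capacity
# sum_e phi_e^k + (r/(P-1)) sum_{l != k} sum_e d_e^{kl} <= phi0.
# Objective: maximise the weighted mean biomass flux; a second
# lexicographic stage fixes the optimum and minimises total investment so
# that selected reaction sets are deterministic under equal rates.

assembleRcfba <- function(universe, envs, params) {
  rxn <- universe@reactions
  S <- universe@S
  N <- ncol(S); M <- nrow(S); P <- nConditions(envs)
  inv <- investedIdx(universe)
  nE <- length(inv)
  if (!any(rxn$kind == "biomass")) stop("universe has no biomass reaction")
  bm <- which(rxn$kind == "biomass")
  exch <- which(rxn$kind == "pseudo_exchange")
  badKeys <- setdiff(unlist(lapply(envs@conditions, names)), rxn$id[exch])
  if (length(badKeys))
    stop("environment bounds refer to non-pseudo-exchange reaction(s): ",
         paste(unique(badKeys), collapse = ", "))

  r <- params@r
  useD <- P > 1 && r > 0
  pairs <- if (useD) utils::combn(P, 2) else matrix(integer(0), 2, 0)
  nPair <- ncol(pairs)

  oPhi <- N * P
  oD <- oPhi + nE * P
  nVars <- oD + nE * nPair
  nuIdx <- function(i, k) (k - 1L) * N + i
  phiIdx <- function(e, k) oPhi + (k - 1L) * nE + e  # e indexes into inv
  dIdx <- function(e, q) oD + (q - 1L) * nE + e

  w <- params@weights
  if (!length(w)) w <- rep(1 / P, P) else {
    if (length(w) != P) stop("weights must have one entry per condition")
    w <- w / sum(w)
  }

  objective <- numeric(nVars)
  objective[vapply(seq_len(P), function(k) nuIdx(bm, k), numeric(1))] <- w

  lower <- rep(-Inf, nVars); upper <- rep(Inf, nVars)
  revr <- rxn$reversible
  for (k in seq_len(P)) {
    idx <- nuIdx(seq_len(N), k)
    lower[idx] <- ifelse(rxn$kind == "pseudo_exchange" | revr, -Inf, 0)
    bnd <- exchangeBound(envs, k)[rxn$id]       # NA for non-exchange / absent
    bnd[rxn$kind == "pseudo_exchange" & is.na(bnd)] <- 0
    upper[idx] <- ifelse(rxn$kind == "pseudo_exchange", bnd, Inf)
  }
  lower[(oPhi + 1L):nVars] <- 0

  lp <- newLpProblem(nVars, objective, "max", lower, upper)

  # mass balance per condition
  ss <- Matrix::summary(S)
  for (k in seq_len(P))
    lp <- lpAddRows(lp, "eq", i = ss$i, j = nuIdx(ss$j, k), x = ss$x,
                    rhs = numeric(M))

  # kinetic coupling nu <= alpha phi; and -nu <= beta phi where reversible
  e <- seq_len(nE)
  for (k in seq_len(P)) {
    lp <- lpAddRows(lp, "ub",
                    i = c(e, e), j = c(nuIdx(inv, k), phiIdx(e, k)),
                    x = c(rep(1, nE), -rxn$alpha[inv]), rhs = numeric(nE))
    er <- which(revr[inv])
    if (length(er))
      lp <- lpAddRows(lp, "ub",
                      i = c(seq_along(er), seq_along(er)),
                      j = c(nuIdx(inv[er], k), phiIdx(er, k)),
                      x = c(rep(-1, length(er)), -rxn$beta[inv[er]]),
                      rhs = numeric(length(er)))
  }

  # |.| linearisation rows
  if (useD) for (q in seq_len(nPair)) {
    k <- pairs[1, q]; l <- pairs[2, q]
    lp <- lpAddRows(lp, "ub",
                    i = rep(e, 3), j = c(phiIdx(e, k), phiIdx(e, l), dIdx(e, q)),
                    x = c(rep(1, nE), rep(-1, nE), rep(-1, nE)),
                    rhs = numeric(nE))
    lp <- lpAddRows(lp, "ub",
                    i = rep(e, 3), j = c(phiIdx(e, l), phiIdx(e, k), dIdx(e, q)),
                    x = c(rep(1, nE), rep(-1, nE), rep(-1, nE)),
                    rhs = numeric(nE))
  }

  # capacity per condition
  for (k in seq_len(P)) {
    j <- phiIdx(e, k); x <- rep(1, nE)
    if (useD) {
      qk <- which(pairs[1, ] == k | pairs[2, ] == k)
      j <- c(j, unlist(lapply(qk, function(q) dIdx(e, q))))
      x <- c(x, rep(r / (P - 1), nE * length(qk)))
    }
    lp <- lpAddRows(lp, "ub", i = rep(1L, length(j)), j = j, x = x,
                    rhs = params@phi0)
  }

  # lexicographic stage: fix growth, minimise total investment
  c2 <- numeric(nVars)
  c2[(oPhi + 1L):(oPhi + nE * P)] <- 1
  lp$c2 <- c2
  lp$sense2 <- "min"
  lp$lex_tol <- 1e-9 * max(1, params@phi0)
  lp
}

# build an RcfbaSolution from a backend result
rcfbaSolutionFromLp <- function(universe, envs, params, sol) {
  N <- nReactions(universe); P <- nConditions(envs)
  inv <- investedIdx(universe)
  nE <- length(inv)
  condNames <- conditionNames(envs)
  invIds <- reactionIds(universe)[inv]
  nu <- matrix(0, N, P, dimnames = list(reactionIds(universe), condNames))
  phi <- matrix(0, nE, P, dimnames = list(invIds, condNames))
  status <- sol$status
  if (identical(status, "optimal")) {
    x <- sol$x
    nu[] <- x[seq_len(N * P)]
    phi[] <- x[N * P + seq_len(nE * P)]
  }
  bmId <- biomassId(universe)
  growth <- stats::setNames(nu[bmId, ], condNames)
  w <- params@weights
  if (!length(w)) w <- rep(1 / P, P) else w <- w / sum(w)
  active <- lapply(seq_len(P), function(k) invIds[phi[, k] > params@tolSupport])
  names(active) <- condNames
  methods::new("RcfbaSolution", universe = universe, envs = envs,
               params = params, nu = nu, phi = phi,
               switching = switchingInvestment(phi, params@r),
               growth = growth, objective = sum(w * growth),
               selected = invIds[apply(phi, 1, max) > params@tolSupport],
               activePerEnv = active, status = status)
}

#' Solve the resource-constrained multi-environment flux balance problem
#'
#' Maximises the weighted mean biomass production rate over all
#' environmental conditions subject to per-condition mass balance,
#' kinetic coupling of fluxes to enzyme investments, exchange bounds, and
#' a shared resource capacity that must also fund the switching
#' investment (the \code{r}-weighted mean absolute investment difference
#' to the other conditions). Absolute values are linearised with per-pair
#' auxiliary variables, which is exact whenever the capacity constraint
#' binds; switching investments are always recomputed from the optimal
#' investments. After the growth stage, a second lexicographic stage
#' fixes the optimum and minimises total investment, making the selected
#' reaction set deterministic when catalytic rates are equal.
#'
#' @param universe a [ReactionUniverse-class] with a biomass reaction
#' @param envs an [EnvironmentSet-class]
#' @param params a [ResourceParams-class]
#' @return an [RcfbaSolution-class]
#' @examples
#' \donttest{
#' sol <- solveRcfba(buildToyUniverse(), buildToyEnvironments(),
#'                   rcfbaParams(phi0 = 1, r = 0))
#' objectiveValue(sol)  # 1/6
#' }
#' @export
solveRcfba <- function(universe, envs, params = rcfbaParams()) {
  lp <- assembleRcfba(universe, envs, params)
  rcfbaSolutionFromLp(universe, envs, params, solveLp(lp))
}

#' Switching investment from an investment matrix
#'
#' Evaluates, for each condition k, the switching investment
#' \eqn{\varphi'^k = \frac{r}{P-1}\sum_{l\neq k}\sum_i |\varphi_i^k -
#' \varphi_i^l|}; a single condition yields 0 by convention.
#'
#' @param phi investment matrix (invested reactions x conditions)
#' @param r switching parameter
#' @param k optional condition index (default: all conditions)
#' @return numeric vector of switching investments
#' @export
switchingInvestment <- function(phi, r, k = NULL) {
  phi <- as.matrix(phi)
  P <- ncol(phi)
  ks <- if (is.null(k)) seq_len(P) else k
  out <- vapply(ks, function(kk) {
    if (P == 1) return(0)
    r / (P - 1) * sum(vapply(setdiff(seq_len(P), kk),
                             function(l) sum(abs(phi[, kk] - phi[, l])),
                             numeric(1)))
  }, numeric(1))
  if (!is.null(colnames(phi))) names(out) <- colnames(phi)[ks]
  out
}

#' @rdname inferNetwork
#' @param tol support threshold override (default: the solution's
#'   \code{tolSupport})
#' @export
setMethod("inferNetwork", "RcfbaSolution", function(solution, tol = NULL, ...) {
  if (!identical(solution@status, "optimal"))
    stop("cannot infer a network from a non-optimal solution (status: ",
         solution@status, ")")
  if (is.null(tol)) tol <- solution@params@tolSupport
  ids <- rownames(solution@phi)
  ids[apply(solution@phi, 1, max) > tol]
})

#' @rdname countRegulons
#' @param tol support threshold override
#' @export
setMethod("countRegulons", "RcfbaSolution", function(solution, tol = NULL, ...) {
  if (!identical(solution@status, "optimal"))
    stop("cannot count regulons of a non-optimal solution")
  if (is.null(tol)) tol <- solution@params@tolSupport
  on <- solution@phi > tol
  sel <- rowSums(on) > 0
  if (!any(sel)) return(list(count = 0L, patterns = list()))
  pat <- apply(on[sel, , drop = FALSE], 1, function(b)
    paste(as.integer(b), collapse = ""))
  list(count = length(unique(pat)), patterns = split(names(pat), pat))
})

#' @rdname selectedInputs
#' @param tol flux threshold (default: the solution's \code{tolSupport})
#' @export
setMethod("selectedInputs", "RcfbaSolution", function(solution, tol = NULL, ...) {
  if (!identical(solution@status, "optimal"))
    stop("selectedInputs requires an optimal solution")
  if (is.null(tol)) tol <- solution@params@tolSupport
  u <- solution@universe
  exch <- which(u@reactions$kind == "pseudo_exchange")
  if (!length(exch)) return(0L)
  used <- apply(solution@nu[exch, , drop = FALSE], 1, max) > tol
  if (!any(used)) return(0L)
  # the supplied metabolite is the positive entry of the exchange column
  mets <- unlist(lapply(exch[used], function(j) {
    col <- u@S[, j]
    rownames(u@S)[col > 0]
  }))
  length(unique(mets))
})

#' Check an optimal solution against the model constraints
#'
#' Recomputes, from the returned fluxes and investments, the largest
#' violations of mass balance, kinetic coupling, exchange bounds and the
#' resource capacity (with the switching investment recomputed exactly).
#'
#' @param solution an [RcfbaSolution-class]
#' @return named numeric vector of maximal violations (0 = satisfied)
#' @export
verifySolution <- function(solution) {
  u <- solution@universe; envs <- solution@envs; p <- solution@params
  nu <- solution@nu; phi <- solution@phi
  rxn <- u@reactions
  inv <- investedIdx(u)
  P <- ncol(nu)
  massBal <- max(abs(u@S %*% nu))
  upViol <- max(nu[inv, , drop = FALSE] - rxn$alpha[inv] * phi, 0)
  loViol <- max(-nu[inv, , drop = FALSE] - rxn$beta[inv] * phi, 0)
  exch <- which(rxn$kind == "pseudo_exchange")
  exViol <- 0
  for (k in seq_len(P)) {
    b <- exchangeBound(envs, k)[rxn$id[exch]]
    b[is.na(b)] <- 0
    exViol <- max(exViol, nu[exch, k] - b, 0)
  }
  capViol <- max(colSums(phi) + switchingInvestment(phi, p@r) - p@phi0, 0)
  c(massBalance = massBal, kineticUpper = upViol, kineticLower = loViol,
    exchangeBound = exViol, capacity = capViol)
}

#' @rdname RcfbaSolution-class
#' @export
setMethod("fluxes", "RcfbaSolution", function(x) x@nu)

#' @rdname RcfbaSolution-class
#' @export
setMethod("investments", "RcfbaSolution", function(x) x@phi)

#' @rdname RcfbaSolution-class
#' @export
setMethod("growthRates", "RcfbaSolution", function(x) x@growth)

#' @rdname RcfbaSolution-class
#' @export
setMethod("switchingInvestments", "RcfbaSolution", function(x) x@switching)

#' @rdname RcfbaSolution-class
#' @export
setMethod("solutionStatus", "RcfbaSolution", function(x) x@status)

#' Objective value (weighted mean growth)
#'
#' @param x an [RcfbaSolution-class]
#' @return numeric scalar
#' @export
objectiveValue <- function(x) x@objective

#' Selected reactions of an optimal solution
#'
#' @param x an [RcfbaSolution-class]
#' @return character vector of reaction ids
#' @export
selectedReactions <- function(x) x@selected

#' Per-condition active reactions
#'
#' @param x an [RcfbaSolution-class]
#' @return named list of reaction id vectors
#' @export
activeReactions <- function(x) x@activePerEnv

setMethod("show", "RcfbaSolution", function(object) {
  cat("RcfbaSolution (status:", object@status, ")\n")
  if (identical(object@status, "optimal")) {
    cat("  mean growth:", format(object@objective, digits = 6), "\n")
    cat("  growth per condition:",
        paste(sprintf("%s=%.4g", names(object@growth), object@growth),
              collapse = ", "), "\n")
    cat("  selected reactions:", length(object@selected), "of",
        nrow(object@phi), "invested\n")
    cat("  regulons:", countRegulons(object)$count, "\n")
  }
  invisible(object)
})
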