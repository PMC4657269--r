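# Switching-parameter sweeps, transition detection and rate-randomised
# Monte-Carlo averaging.

profileFromSolution <- function(solution, r, carriers = defaultCarriers()) {
  out <- data.frame(r = r, growth = NA_real_, nReactions = NA_integer_,
                    nNodes = NA_integer_, nInputs = NA_integer_,
                    asp = NA_real_, nRegulons = NA_integer_)
  if (!identical(solution@status, "optimal")) return(out)
  out$growth <- solution@objective
  sel <- solution@selected
  out$nReactions <- length(sel)
  out$nRegulons <- countRegulons(solution)$count
  if (length(sel)) {
    g <- buildGraph(solution@universe, carriers = carriers, reactions = sel)
    out$nNodes <- nNodes(g)
    out$nInputs <- length(inputNodes(g))
    asp <- tryCatch(avgShortestPathToBiomass(g), error = function(e) NA_real_)
    out$asp <- as.numeric(asp)
  } else {
    out$nNodes <- 0L
    out$nInputs <- 0L
  }
  out
}

#' Sweep the switching parameter
#'
#' Solves the resource-constrained problem at every value of \code{rGrid}
#' (each a fresh two-stage lexicographic solve) and records one structural
#' profile per grid point: mean growth, number of selected reactions,
#' nodes and selected input metabolites, average shortest path to biomass
#' components of the selected subnetwork, and regulon count.
#'
#' @param universe a [ReactionUniverse-class]
#' @param envs an [EnvironmentSet-class]
#' @param params a [ResourceParams-class]; its \code{r} is overridden by
#'   the grid
#' @param rGrid increasing vector of non-negative switching parameters
#' @param carriers carrier metabolites excluded from graph metrics
#' @return data.frame with columns \code{r}, \code{growth},
#'   \code{nReactions}, \code{nNodes}, \code{nInputs}, \code{asp},
#'   \code{nRegulons}; the per-point [RcfbaSolution-class] objects are
#'   attached as attribute \code{"solutions"}
#' @export
sweepR <- function(universe, envs, params = rcfbaParams(),
                   rGrid, carriers = defaultCarriers()) {
  stopifnot(length(rGrid) >= 1, all(rGrid >= 0), !is.unsorted(rGrid))
  paramsAt <- lapply(rGrid, function(r)
    methods::initialize(params, r = r,
                        tolSupport = params@tolSupport))
  lps <- lapply(paramsAt, function(p) assembleRcfba(universe, envs, p))
  sols <- solveLpBatch(lps)
  solutions <- Map(function(p, s) rcfbaSolutionFromLp(universe, envs, p, s),
                   paramsAt, sols)
  bad <- which(!vapply(solutions, function(s) identical(s@status, "optimal"),
                       logical(1)))
  if (length(bad))
    warning("non-optimal solve at r = ", paste(rGrid[bad], collapse = ", "))
  profiles <- do.call(rbind, Map(profileFromSolution, solutions, rGrid,
                                 MoreArgs = list(carriers = carriers)))
  rownames(profiles) <- NULL
  attr(profiles, "solutions") <- solutions
  profiles
}

# canonical comparable state of a solve: selected set + activity patterns
solveState <- function(universe, envs, params, r) {
  p <- methods::initialize(params, r = r)
  sol <- solveRcfba(universe, envs, p)
  if (!identical(sol@status, "optimal"))
    stop("non-optimal solve at r = ", r, " (status ", sol@status, ")")
  on <- sol@phi > p@tolSupport
  sel <- rownames(sol@phi)[rowSums(on) > 0]
  pat <- apply(on[sel, , drop = FALSE], 1, function(b)
    paste(as.integer(b), collapse = ""))
  list(sel = sort(sel), pat = pat[order(names(pat))])
}

stateKind <- function(a, b) {
  if (!identical(a$sel, b$sel)) return("structural")
  if (!identical(a$pat, b$pat)) return("regulatory")
  NA_character_
}

#' Detect structural and regulatory transitions along r
#'
#' Solves on a uniform grid over \code{interval}; adjacent grid points
#' whose selected reaction sets differ bracket a structural transition,
#' and points whose activity patterns differ with an unchanged selected
#' set bracket a regulatory transition. Each bracket is refined by
#' bisection to width at most \code{resolution} and reported at the final
#' bracket midpoint. Pattern maps are compared in full, not just regulon
#' counts.
#'
#' @inheritParams sweepR
#' @param interval length-2 numeric range of r to scan
#' @param nGrid number of initial grid points (>= 2)
#' @param resolution final bracket width (default 1e-3)
#' @return data.frame with columns \code{r} (bracket midpoint) and
#'   \code{kind} (\code{"structural"} or \code{"regulatory"}); zero rows
#'   when no transition occurs
#' @export
detectTransitions <- function(universe, envs, params = rcfbaParams(),
                              interval = c(0, 1), nGrid = 21,
                              resolution = 1e-3) {
  stopifnot(length(interval) == 2, nGrid >= 1)
  grid <- seq(interval[1], interval[2], length.out = nGrid)
  if (nGrid < 2)
    return(data.frame(r = numeric(0), kind = character(0)))
  states <- lapply(grid, function(r) solveState(universe, envs, params, r))
  res <- data.frame(r = numeric(0), kind = character(0))
  for (j in seq_len(nGrid - 1)) {
    a <- grid[j]; b <- grid[j + 1]
    sa <- states[[j]]; sb <- states[[j + 1]]
    if (is.na(stateKind(sa, sb))) next
    while (b - a > resolution) {
      m <- (a + b) / 2
      sm <- solveState(universe, envs, params, m)
      if (is.na(stateKind(sa, sm))) { a <- m; sa <- sm } else { b <- m; sb <- sm }
    }
    res <- rbind(res, data.frame(r = (a + b) / 2, kind = stateKind(sa, sb)))
  }
  res[order(res$r), , drop = FALSE]
}

#' Locate slope discontinuities of the growth curve
#'
#' Second-difference kink detector on \code{growth} versus \code{r}: a
#' grid point is reported when the change in discrete slope across it
#' exceeds \code{threshold} and stands out as a strict local maximum
#' against the neighbouring slope changes (which filters the smooth
#' curvature of a growth curve sampled on a fine grid).
#'
#' @param profiles data.frame with columns \code{r} and \code{growth}
#'   (as returned by [sweepR()])
#' @param threshold minimal absolute slope change (default 1e-6)
#' @param dominance factor by which a kink must exceed neighbouring slope
#'   changes (default 3)
#' @return numeric vector of r values (possibly empty)
#' @export
growthBreakpoints <- function(profiles, threshold = 1e-6, dominance = 3) {
  r <- profiles$r; g <- profiles$growth
  stopifnot(length(r) >= 3)
  slope <- diff(g) / diff(r)
  ds <- abs(diff(slope))            # slope change across interior point j+1
  n <- length(ds)
  # a kink that falls between grid points splits its slope jump over two
  # adjacent interior points, so the background level is taken from the
  # next-nearest neighbours and adjacent spikes are merged afterwards
  isCand <- vapply(seq_len(n), function(j) {
    far <- c(j - 3, j - 2, j + 2, j + 3)
    far <- far[far >= 1 & far <= n]
    if (!length(far)) far <- c(j - 1, j + 1)[c(j - 1, j + 1) >= 1 &
                                               c(j - 1, j + 1) <= n]
    bg <- if (length(far)) max(ds[far]) else 0
    ds[j] > threshold && ds[j] > dominance * bg
  }, logical(1))
  out <- numeric(0)
  j <- 1
  while (j <= n) {
    if (isCand[j]) {
      run <- j
      while (j + 1 <= n && isCand[j + 1]) { j <- j + 1; run <- c(run, j) }
      out <- c(out, r[run[which.max(ds[run])] + 1])
    }
    j <- j + 1
  }
  out
}

#' Monte-Carlo sweep over randomized catalytic rates
#'
#' Repeats [sweepR()] for \code{nReps} universes with perturbed catalytic
#' rates (each replicate seeded as \code{seed + replicate - 1}) and
#' reports per-grid-point means and standard errors of every profile
#' field. Replicates whose solve fails at some grid point contribute to
#' the other grid points and are counted in attribute \code{"nFailed"};
#' failures are skipped, not resampled, so seeds stay aligned with
#' replicate indices.
#'
#' @inheritParams sweepR
#' @param sigma rate-perturbation half-width passed to [randomizeRates()]
#' @param nReps number of replicates (>= 1)
#' @param seed integer seed of the first replicate
#' @return data.frame keyed by \code{r} with \code{<field>} (mean) and
#'   \code{<field>.se} columns for growth, nReactions, nNodes, nInputs,
#'   asp and nRegulons
#' @export
monteCarloSweep <- function(universe, envs, params = rcfbaParams(), rGrid,
                            sigma, nReps, seed,
                            carriers = defaultCarriers()) {
  stopifnot(nReps >= 1)
  fields <- c("growth", "nReactions", "nNodes", "nInputs", "asp", "nRegulons")
  reps <- vector("list", nReps)
  nFailed <- 0L
  for (i in seq_len(nReps)) {
    ui <- randomizeRates(universe, sigma, seed + i - 1L)
    prof <- withCallingHandlers(
      sweepR(ui, envs, params, rGrid, carriers),
      warning = function(w) {
        if (grepl("non-optimal", conditionMessage(w))) {
          nFailed <<- nFailed + 1L
          invokeRestart("muffleWarning")
        }
      })
    attr(prof, "solutions") <- NULL
    reps[[i]] <- prof
  }
  out <- data.frame(r = rGrid)
  for (f in fields) {
    vals <- vapply(reps, function(p) as.numeric(p[[f]]), numeric(length(rGrid)))
    vals <- matrix(vals, nrow = length(rGrid))
    out[[f]] <- apply(vals, 1, mean, na.rm = TRUE)
    out[[paste0(f, ".se")]] <- apply(vals, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) return(NA_real_)
      stats::sd(v) / sqrt(length(v))
    })
  }
  attr(out, "nFailed") <- nFailed
  attr(out, "nReps") <- nReps
  out
}
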