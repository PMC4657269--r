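# Directed metabolite-graph representation and bow-tie structural metrics.

#' Default currency/energy carrier metabolites
#'
#' Carriers take part in many reactions and would create artificial
#' shortcuts, so they are excluded as graph nodes (never from the LP).
#' The list covers plain names and the compartment-suffixed identifiers
#' of published models; it is a configurable default because published
#' analyses state the principle (remove ATP, ADP, H2O, H+ and the like)
#' rather than an exhaustive list.
#'
#' @return character vector of metabolite ids treated as carriers
#' @export
defaultCarriers <- function() {
  base <- c("atp", "adp", "amp", "nad", "nadh", "nadp", "nadph",
            "fad", "fadh2", "h2o", "h", "pi", "ppi", "coa", "co2", "o2")
  plain <- setdiff(base, "h")   # a bare "h"/"H" is too ambiguous an id
  unique(c(plain, toupper(plain), "h+", "H+",
           paste0(base, "_c"), paste0(base, "_e"), paste0(base, "_p")))
}

#' Build the directed metabolite graph
#'
#' One node per non-carrier metabolite that takes part in at least one
#' edge; for every enzymatic reaction, a directed edge from each
#' non-carrier substrate to each non-carrier product (both directions for
#' reversible reactions). Pseudo-exchange reactions contribute no edges;
#' the biomass reaction contributes no edges but flags its non-carrier
#' substrates as biomass components. Parallel edges from different
#' reactions are collapsed, with the originating reaction ids kept as
#' edge provenance.
#'
#' @param universe a [ReactionUniverse-class]
#' @param carriers metabolite ids excluded as nodes
#'   (default [defaultCarriers()]); ids flagged \code{isCarrier} in the
#'   universe are always excluded
#' @param reactions optional reaction ids restricting the graph to a
#'   selected subnetwork (e.g. [selectedReactions()] of a solution)
#' @return a [MetGraph-class]
#' @export
buildGraph <- function(universe, carriers = defaultCarriers(),
                       reactions = NULL) {
  rxn <- universe@reactions
  met <- universe@metabolites
  carriers <- union(carriers, met$id[met$isCarrier])
  keep <- if (is.null(reactions)) rep(TRUE, nrow(rxn)) else rxn$id %in% reactions
  S <- universe@S

  from <- character(0); to <- character(0); via <- character(0)
  bmComponents <- character(0)
  for (j in which(keep)) {
    col <- S[, j]
    subs <- setdiff(rownames(S)[col < 0], carriers)
    prods <- setdiff(rownames(S)[col > 0], carriers)
    if (rxn$kind[j] == "biomass") {
      bmComponents <- union(bmComponents, subs)
      next
    }
    if (rxn$kind[j] == "pseudo_exchange") next
    if (!length(subs) || !length(prods)) next
    ee <- expand.grid(from = subs, to = prods, stringsAsFactors = FALSE)
    if (rxn$reversible[j])
      ee <- rbind(ee, data.frame(from = ee$to, to = ee$from))
    from <- c(from, ee$from); to <- c(to, ee$to)
    via <- c(via, rep(rxn$id[j], nrow(ee)))
  }

  key <- paste(from, to, sep = "\r")
  prov <- vapply(split(via, key), function(v) paste(sort(unique(v)),
                                                   collapse = ","), "")
  uq <- !duplicated(key)
  edges <- data.frame(from = from[uq], to = to[uq],
                      reactions = unname(prov[key[uq]]))
  nodes <- unique(c(edges$from, edges$to))
  # nodes with no remaining edges are dropped, including biomass components
  verts <- data.frame(name = nodes)
  ext <- met$id[met$isExternal]
  verts$isInput <- verts$name %in% ext
  verts$isBiomassComponent <- verts$name %in% bmComponents
  verts$role <- ifelse(verts$isInput, "input",
                       ifelse(verts$isBiomassComponent, "biomass_component",
                              "internal"))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
  methods::new("MetGraph", graph = g, carriers = carriers)
}

#' @rdname MetGraph-class
#' @param x a \code{MetGraph}
#' @export
nNodes <- function(x) igraph::vcount(x@graph)

#' @rdname MetGraph-class
#' @export
nEdges <- function(x) igraph::ecount(x@graph)

#' @rdname MetGraph-class
#' @export
nodeRoles <- function(x)
  stats::setNames(igraph::V(x@graph)$role, igraph::V(x@graph)$name)

#' @rdname MetGraph-class
#' @export
inputNodes <- function(x)
  igraph::V(x@graph)$name[igraph::V(x@graph)$isInput]

#' @rdname MetGraph-class
#' @export
biomassComponents <- function(x)
  igraph::V(x@graph)$name[igraph::V(x@graph)$isBiomassComponent]

#' @rdname MetGraph-class
#' @export
metGraph <- function(x) x@graph

setMethod("show", "MetGraph", function(object) {
  cat("MetGraph:", igraph::vcount(object@graph), "nodes,",
      igraph::ecount(object@graph), "edges\n")
  cat("  inputs:", sum(igraph::V(object@graph)$isInput),
      " biomass components:", sum(igraph::V(object@graph)$isBiomassComponent),
      "\n")
  invisible(object)
})

# shortest-path edge counts from inputs to biomass components (directed)
lminMatrix <- function(mg, mode = "out") {
  ins <- inputNodes(mg); bms <- biomassComponents(mg)
  if (!length(ins)) stop("graph has no input node")
  if (!length(bms)) stop("graph has no biomass component")
  igraph::distances(mg@graph, v = ins, to = bms, mode = mode,
                    weights = NA)
}

#' Average shortest path from inputs to biomass components
#'
#' For each biomass component, \code{l_min} is the smallest directed
#' shortest-path edge count from any input node; the average shortest
#' path (ASP) is the mean of \code{l_min} over biomass components
#' reachable from some input. Unreachable components are excluded and
#' counted in attribute \code{"nUnreachable"}.
#'
#' @param mg a [MetGraph-class]
#' @param mode \code{"out"} for directed paths (default) or \code{"all"}
#'   for the undirected variant
#' @return numeric ASP with attribute \code{nUnreachable}
#' @export
avgShortestPathToBiomass <- function(mg, mode = c("out", "all")) {
  mode <- match.arg(mode)
  d <- lminMatrix(mg, mode)
  lmin <- apply(d, 2, min)
  reach <- is.finite(lmin)
  if (!any(reach))
    stop("no biomass component is reachable from any input (non-viable network)")
  structure(mean(lmin[reach]), nUnreachable = sum(!reach))
}

# closeness with unreachable nodes excluded per node:
# C(v) = (r_v / (n-1)) * (r_v / sum of distances to reachable nodes)
closenessScores <- function(g, mode = "out") {
  n <- igraph::vcount(g)
  if (n < 2) return(stats::setNames(numeric(n), igraph::V(g)$name))
  d <- igraph::distances(g, mode = mode, weights = NA)
  diag(d) <- Inf
  vapply(seq_len(n), function(v) {
    dv <- d[v, ]
    reach <- is.finite(dv)
    rv <- sum(reach)
    if (rv == 0) return(0)
    (rv / (n - 1)) * (rv / sum(dv[reach]))
  }, numeric(1)) |> stats::setNames(igraph::V(g)$name)
}

#' Overall closeness centralization index (OCCI)
#'
#' Freeman closeness centralization
#' \eqn{\sum_v (C_{max} - C(v)) / ((n-1)(n-2)/(2n-3))} computed on
#' directed reachable distances, with unreachable distances excluded
#' per-node (nodes that reach nothing score 0). Used as a whole-graph
#' bow-tie proxy: hub-centred graphs centralize more than streamlined
#' chains.
#'
#' @param mg a [MetGraph-class]
#' @param mode \code{"out"} (default) or \code{"all"} for the undirected
#'   variant
#' @return numeric centralization index
#' @export
occi <- function(mg, mode = c("out", "all")) {
  mode <- match.arg(mode)
  g <- mg@graph
  n <- igraph::vcount(g)
  if (n < 3) return(NA_real_)
  cc <- closenessScores(g, mode)
  sum(max(cc) - cc) / ((n - 1) * (n - 2) / (2 * n - 3))
}

meanPairDistance <- function(g, nodes, mode) {
  if (length(nodes) < 2)
    return(structure(NA_real_, nExcluded = 0L))
  d <- igraph::distances(g, v = nodes, to = nodes, mode = mode, weights = NA)
  diag(d) <- NA
  vals <- d[!is.na(d)]
  structure(mean(vals[is.finite(vals)]),
            nExcluded = sum(is.infinite(vals)))
}

#' Structural metrics of a metabolite graph
#'
#' @param mg a [MetGraph-class]
#' @param pairMode distances between input pairs and between biomass-
#'   component pairs: \code{"all"} (undirected, default — input nodes are
#'   pure sources, so directed input-input distances are undefined) or
#'   \code{"out"}
#' @return list with \code{nInputs}, \code{nNodes}, \code{nEdges},
#'   \code{avgDegree} (edges per node; average in-degree = average
#'   out-degree), \code{asp} (directed \code{l_min} average),
#'   \code{meanInputDistance}, \code{meanBiomassDistance} (mean pairwise
#'   shortest paths, unreachable pairs excluded and counted),
#'   \code{nDirectImports} (biomass components with \code{l_min} = 1) and
#'   \code{occi}
#' @export
structuralMetrics <- function(mg, pairMode = c("all", "out")) {
  pairMode <- match.arg(pairMode)
  g <- mg@graph
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph")
  ins <- inputNodes(mg); bms <- biomassComponents(mg)
  asp <- NA_real_; nDirect <- NA_integer_
  if (length(ins) && length(bms)) {
    d <- lminMatrix(mg, "out")
    lmin <- apply(d, 2, min)
    asp <- if (any(is.finite(lmin))) mean(lmin[is.finite(lmin)]) else NA_real_
    nDirect <- sum(lmin == 1)
  }
  list(nInputs = length(ins),
       nNodes = n,
       nEdges = igraph::ecount(g),
       avgDegree = igraph::ecount(g) / n,
       asp = asp,
       meanInputDistance = meanPairDistance(g, ins, pairMode),
       meanBiomassDistance = meanPairDistance(g, bms, pairMode),
       nDirectImports = nDirect,
       occi = occi(mg))
}
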