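# Batch profiling of reconstructed models and the two-group
# nonparametric lifestyle comparison.

#' Structural and essentiality profile of one model
#'
#' Builds the metabolite graph of a model, computes the structural
#' metrics and the essential-reaction fraction, and passes through the
#' model's gene count when annotated.
#'
#' @param model a [ReactionUniverse-class] or a model file path (read
#'   with [readUniverse()])
#' @param carriers carrier metabolites excluded from the graph
#' @param fluxBound flux cap for the essentiality screen
#' @param ... further arguments to [readUniverse()]
#' @return one-row data.frame: \code{nInputs}, \code{nNodes},
#'   \code{nEdges}, \code{avgDegree}, \code{asp},
#'   \code{meanInputDistance}, \code{meanBiomassDistance},
#'   \code{nDirectImports}, \code{occi}, \code{essentialFraction},
#'   \code{nGenes}. Metrics that need a biomass reaction are \code{NA}
#'   when the model lacks one; the rest are still computed.
#' @export
profileModel <- function(model, carriers = defaultCarriers(),
                         fluxBound = 1000, ...) {
  u <- if (is.character(model)) readUniverse(model, carriers = carriers, ...)
       else model
  g <- buildGraph(u, carriers = carriers)
  m <- structuralMetrics(g)
  ef <- if (is.na(biomassId(u))) NA_real_ else
    tryCatch(as.numeric(essentialFraction(u, fluxBound = fluxBound)),
             error = function(e) NA_real_)
  data.frame(nInputs = m$nInputs, nNodes = m$nNodes, nEdges = m$nEdges,
             avgDegree = m$avgDegree, asp = as.numeric(m$asp),
             meanInputDistance = as.numeric(m$meanInputDistance),
             meanBiomassDistance = as.numeric(m$meanBiomassDistance),
             nDirectImports = m$nDirectImports, occi = m$occi,
             essentialFraction = ef,
             nGenes = as.integer(attr(u, "nGenes") %||% NA))
}

#' Kruskal-Wallis rank test for two groups
#'
#' Tie-corrected H statistic with the chi-square approximation (one
#' degree of freedom for two groups). A degenerate input with all pooled
#' values identical yields H = 0, p = 1.
#'
#' @param x,y numeric vectors of metric values for the two groups (each
#'   with at least two finite values)
#' @return list with \code{H} and \code{p}
#' @export
kruskalWallisTest <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least two finite values")
  if (length(unique(c(x, y))) == 1) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(list(x, y))
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Read a lifestyle label table
#'
#' TSV with columns \code{organism_id} and \code{lifestyle}
#' (\code{facultative} or \code{non_facultative}). When an organism
#' appears more than once, the first row wins with a warning (one model
#' per organism).
#'
#' @param path label TSV path
#' @return data.frame with columns \code{organism_id}, \code{lifestyle}
#' @export
readLifestyleLabels <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("organism_id", "lifestyle")
  if (!all(need %in% names(tab)))
    stop("label table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(tab$lifestyle), c("facultative", "non_facultative"))
  if (length(bad))
    stop("unknown lifestyle label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(tab$organism_id)) {
    warning("duplicated organism_id(s); keeping the first model per organism")
    tab <- tab[!duplicated(tab$organism_id), , drop = FALSE]
  }
  tab
}

#' Compare structural metrics between lifestyle groups
#'
#' Profiles each model, joins the lifestyle labels and runs the
#' two-group Kruskal-Wallis test per metric.
#'
#' @param models named list of [ReactionUniverse-class] objects or a
#'   character vector of model file paths (names / file base names are
#'   the organism ids)
#' @param labels label data.frame (see [readLifestyleLabels()]) or a
#'   path to one
#' @param metrics metric columns to test (default: all profiled metrics)
#' @param ... passed to [profileModel()]
#' @return data.frame with columns \code{metric}, \code{H}, \code{p},
#'   \code{nFacultative}, \code{nNonFacultative}; the per-organism
#'   profile table is attached as attribute \code{"profiles"}
#' @export
compareGroups <- function(models, labels,
                          metrics = c("nInputs", "nNodes", "avgDegree",
                                      "asp", "meanInputDistance",
                                      "meanBiomassDistance",
                                      "nDirectImports", "occi",
                                      "essentialFraction", "nGenes"),
                          ...) {
  if (is.character(labels)) labels <- readLifestyleLabels(labels)
  if (is.character(models)) {
    ids <- if (!is.null(names(models))) names(models)
           else tools::file_path_sans_ext(basename(models))
    models <- as.list(models); names(models) <- ids
  }
  if (is.null(names(models)) || any(names(models) == ""))
    stop("models must be named by organism id")
  prof <- do.call(rbind, lapply(names(models), function(id) {
    p <- profileModel(models[[id]], ...)
    cbind(data.frame(organism_id = id), p)
  }))
  prof <- merge(prof, labels, by = "organism_id")
  if (!nrow(prof)) stop("no model matched the label table")
  fac <- prof$lifestyle == "facultative"
  out <- do.call(rbind, lapply(metrics, function(mm) {
    v <- prof[[mm]]
    res <- tryCatch(kruskalWallisTest(v[fac], v[!fac]),
                    error = function(e) list(H = NA_real_, p = NA_real_))
    data.frame(metric = mm, H = res$H, p = res$p,
               nFacultative = sum(fac & is.finite(v)),
               nNonFacultative = sum(!fac & is.finite(v)))
  }))
  attr(out, "profiles") <- prof
  out
}
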