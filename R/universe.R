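#' Construct a ReactionUniverse
#'
#' @param metabolites data.frame with at least an \code{id} column;
#'   \code{name}, \code{isExternal}, \code{isCarrier} are filled with
#'   defaults when missing (name = id, both flags FALSE).
#' @param reactions data.frame with at least \code{id} and \code{kind};
#'   defaults: \code{name} = id, \code{reversible} = FALSE,
#'   \code{alpha} = 1, \code{beta} = 1 for reversible else 0.
#' @param stoichiometry either a metabolites x reactions matrix, or a named
#'   list (one element per reaction, in reaction order) of named numeric
#'   coefficient vectors (negative = substrate, positive = product).
#' @return a validated [ReactionUniverse-class]
#' @examples
#' u <- reactionUniverse(
#'   metabolites = data.frame(id = c("A", "B")),
#'   reactions = data.frame(id = c("EX_A", "v1", "bm"),
#'                          kind = c("pseudo_exchange", "enzymatic", "biomass")),
#'   stoichiometry = list(EX_A = c(A = 1), v1 = c(A = -1, B = 1), bm = c(B = -1)))
#' nReactions(u)
#' @export
reactionUniverse <- function(metabolites, reactions, stoichiometry) {
  metabolites <- as.data.frame(metabolites)
  reactions <- as.data.frame(reactions)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$isExternal)) metabolites$isExternal <- FALSE
  if (is.null(metabolites$isCarrier)) metabolites$isCarrier <- FALSE
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$reversible)) reactions$reversible <- FALSE
  if (is.null(reactions$alpha)) reactions$alpha <- 1
  if (is.null(reactions$beta)) reactions$beta <- ifelse(reactions$reversible, 1, 0)
  metabolites$id <- as.character(metabolites$id)
  reactions$id <- as.character(reactions$id)
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL

  if (is.list(stoichiometry) && !is.data.frame(stoichiometry)) {
    stopifnot(length(stoichiometry) == nrow(reactions))
    i <- integer(0); j <- integer(0); x <- numeric(0)
    for (jj in seq_along(stoichiometry)) {
      sto <- stoichiometry[[jj]]
      sto <- sto[sto != 0]
      if (!length(sto)) next
      idx <- match(names(sto), metabolites$id)
      if (anyNA(idx))
        stop("unknown metabolite id(s) in reaction '", reactions$id[jj], "': ",
             paste(names(sto)[is.na(idx)], collapse = ", "))
      i <- c(i, idx); j <- c(j, rep.int(jj, length(sto))); x <- c(x, unname(sto))
    }
    S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                              dims = c(nrow(metabolites), nrow(reactions)),
                              dimnames = list(metabolites$id, reactions$id))
  } else {
    S <- methods::as(methods::as(Matrix::Matrix(stoichiometry, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    dimnames(S) <- list(metabolites$id, reactions$id)
  }
  methods::new("ReactionUniverse", metabolites = metabolites,
               reactions = reactions, S = methods::as(S, "dgCMatrix"))
}

#' @rdname ReactionUniverse-class
#' @export
setMethod("nMetabolites", "ReactionUniverse", function(x) nrow(x@metabolites))

#' @rdname ReactionUniverse-class
#' @export
setMethod("nReactions", "ReactionUniverse", function(x) nrow(x@reactions))

#' @rdname ReactionUniverse-class
#' @export
setMethod("metaboliteIds", "ReactionUniverse", function(x) x@metabolites$id)

#' @rdname ReactionUniverse-class
#' @export
setMethod("reactionIds", "ReactionUniverse", function(x) x@reactions$id)

#' @rdname ReactionUniverse-class
#' @export
setMethod("reactionKinds", "ReactionUniverse",
          function(x) stats::setNames(x@reactions$kind, x@reactions$id))

#' @rdname ReactionUniverse-class
#' @export
setMethod("stoichiometry", "ReactionUniverse", function(x) x@S)

#' @rdname ReactionUniverse-class
#' @export
setMethod("biomassId", "ReactionUniverse", function(x) {
  id <- x@reactions$id[x@reactions$kind == "biomass"]
  if (length(id)) id else NA_character_
})

#' @rdname ReactionUniverse-class
#' @export
setMethod("exchangeIds", "ReactionUniverse",
          function(x) x@reactions$id[x@reactions$kind == "pseudo_exchange"])

#' Metabolite and reaction tables
#'
#' @param x a [ReactionUniverse-class]
#' @return a data.frame copy of the metabolite or reaction table
#' @export
metaboliteTable <- function(x) x@metabolites

#' @rdname metaboliteTable
#' @export
reactionTable <- function(x) x@reactions

# indices of reactions carrying enzyme investment (enzymatic + biomass)
investedIdx <- function(x) which(x@reactions$kind != "pseudo_exchange")

#' Restrict a universe to a subset of reactions
#'
#' Keeps the given reactions (pseudo-exchanges are retained by default so
#' the environment definition stays applicable) and drops metabolites no
#' longer participating in any reaction.
#'
#' @param x a [ReactionUniverse-class]
#' @param reactions reaction ids to keep
#' @param keepExchanges keep all pseudo-exchange reactions (default TRUE)
#' @return a [ReactionUniverse-class]
#' @export
subsetUniverse <- function(x, reactions, keepExchanges = TRUE) {
  keep <- x@reactions$id %in% reactions
  if (keepExchanges) keep <- keep | x@reactions$kind == "pseudo_exchange"
  if (!any(keep)) stop("no reactions left after subsetting")
  S <- x@S[, keep, drop = FALSE]
  mkeep <- Matrix::rowSums(abs(S)) > 0
  methods::new("ReactionUniverse",
               metabolites = x@metabolites[mkeep, , drop = FALSE] |>
                 (\(d) { rownames(d) <- NULL; d })(),
               reactions = x@reactions[keep, , drop = FALSE] |>
                 (\(d) { rownames(d) <- NULL; d })(),
               S = methods::as(S[mkeep, , drop = FALSE], "dgCMatrix"))
}

#' Remove one reaction's flux (knockout) helper
#'
#' @keywords internal
#' @noRd
knockoutIds <- function(x) x@reactions$id[x@reactions$kind != "pseudo_exchange"]

setMethod("show", "ReactionUniverse", function(object) {
  k <- table(factor(object@reactions$kind, levels = REACTION_KINDS))
  cat("ReactionUniverse with", nrow(object@metabolites), "metabolites and",
      nrow(object@reactions), "reactions\n")
  cat("  enzymatic:", k[["enzymatic"]],
      " pseudo_exchange:", k[["pseudo_exchange"]],
      " biomass:", k[["biomass"]], "\n")
  cat("  external metabolites:", sum(object@metabolites$isExternal),
      " carriers:", sum(object@metabolites$isCarrier), "\n")
  invisible(object)
})
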