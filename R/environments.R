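#' Construct an EnvironmentSet
#'
#' @param conditions named list; each element a named numeric vector of
#'   pseudo-exchange upper bounds (uptake-positive flux). \code{Inf} marks
#'   an unbounded nutrient; ids absent from a condition default to 0.
#' @return an [EnvironmentSet-class]
#' @examples
#' environmentSet(list(glucose = c(EX_glc = Inf), none = c(EX_glc = 0)))
#' @export
environmentSet <- function(conditions) {
  conditions <- lapply(conditions, function(cc) {
    v <- as.numeric(cc); names(v) <- names(cc); v
  })
  methods::new("EnvironmentSet", conditions = conditions)
}

#' @rdname EnvironmentSet-class
#' @export
setMethod("nConditions", "EnvironmentSet", function(x) length(x@conditions))

#' @rdname EnvironmentSet-class
#' @export
setMethod("conditionNames", "EnvironmentSet", function(x) names(x@conditions))

#' Upper bound of one exchange in one condition
#'
#' @param x an [EnvironmentSet-class]
#' @param condition condition name or index
#' @param reaction pseudo-exchange reaction id (omit for the full vector)
#' @return numeric bound(s); ids absent from the condition's map are 0
#' @export
exchangeBound <- function(x, condition, reaction = NULL) {
  cc <- x@conditions[[condition]]
  if (is.null(reaction)) return(cc)
  b <- unname(cc[reaction])
  b[is.na(b)] <- 0
  b
}

setMethod("show", "EnvironmentSet", function(object) {
  cat("EnvironmentSet with", length(object@conditions), "condition(s):\n")
  for (nm in names(object@conditions)) {
    cc <- object@conditions[[nm]]
    open <- names(cc)[is.infinite(cc)]
    fin <- names(cc)[is.finite(cc) & cc > 0]
    cat("  ", nm, ": unbounded {", paste(open, collapse = ", "), "}",
        if (length(fin)) paste0(" finite {", paste(fin, collapse = ", "), "}"),
        "\n", sep = "")
  }
  invisible(object)
})

#' Resource-allocation parameter set
#'
#' @param phi0 resource capacity shared by enzyme investments and the
#'   switching investment (default 100, matching the core-network setup;
#'   the toy analyses use \code{phi0 = 1}).
#' @param r dimensionless switching parameter (>= 0).
#' @param tolSupport investment threshold above which a reaction counts as
#'   present; default \code{1e-6 * phi0} (LP solvers return roughly 1e-9
#'   noise on unit-scale problems).
#' @param tolFeasibility tolerance used when verifying constraints.
#' @param weights optional per-condition objective weights (normalised to
#'   sum to one); default uniform.
#' @return a [ResourceParams-class]
#' @export
rcfbaParams <- function(phi0 = 100, r = 0, tolSupport = 1e-6 * phi0,
                        tolFeasibility = 1e-8, weights = numeric(0)) {
  methods::new("ResourceParams", phi0 = phi0, r = r, tolSupport = tolSupport,
               tolFeasibility = tolFeasibility, weights = as.numeric(weights))
}

setMethod("show", "ResourceParams", function(object) {
  cat(sprintf("ResourceParams: phi0 = %g, r = %g, tolSupport = %g\n",
              object@phi0, object@r, object@tolSupport))
  invisible(object)
})
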