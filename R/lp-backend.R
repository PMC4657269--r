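# Sparse LP container and batch interface to the HiGHS backend.
#
# Problems are plain lists in sparse-triplet form; batches are serialised
# to JSON and solved by inst/python/lp_solver.py (scipy.optimize.linprog,
# method "highs"). All model semantics stay on the R side.

newLpProblem <- function(nVars, objective, sense = c("max", "min"),
                         lower = rep(0, nVars), upper = rep(Inf, nVars)) {
  sense <- match.arg(sense)
  list(n = nVars, c = as.numeric(objective), sense = sense,
       eq = list(i = integer(0), j = integer(0), x = numeric(0), rhs = numeric(0)),
       ub = list(i = integer(0), j = integer(0), x = numeric(0), rhs = numeric(0)),
       lower = as.numeric(lower), upper = as.numeric(upper),
       c2 = NULL, sense2 = "min", lex_tol = 1e-9)
}

# append rows (triplets grouped by row) to the eq or ub block
lpAddRows <- function(lp, block, i, j, x, rhs) {
  b <- lp[[block]]
  off <- length(b$rhs)
  b$i <- c(b$i, i + off); b$j <- c(b$j, j); b$x <- c(b$x, x)
  b$rhs <- c(b$rhs, rhs)
  lp[[block]] <- b
  lp
}

lpPython <- function() {
  py <- getOption("rcfba.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("no python interpreter found; the LP backend needs python with ",
         "scipy on the PATH (or set options(rcfba.python = ...))")
  py
}

lpSolverScript <- function() {
  p <- system.file("python", "lp_solver.py", package = "rcfba")
  if (!nzchar(p)) stop("bundled LP solver script not found")
  p
}

# JSON encoding: Inf is not representable, use NULL for infinite bounds
encodeBounds <- function(v, inf) {
  lapply(v, function(b) if (is.infinite(b) && (b > 0) == (inf > 0)) NULL else b)
}

#' Solve a batch of linear programs
#'
#' Low-level interface to the HiGHS backend. Each problem is a list as
#' produced internally by the model-assembly code; exposed mainly for
#' diagnostics.
#'
#' @param problems list of LP problem lists
#' @return list of solutions: \code{status}, \code{objective},
#'   \code{objective2} (lexicographic stage, when requested), \code{x}
#' @keywords internal
solveLpBatch <- function(problems) {
  if (!length(problems)) return(list())
  enc <- lapply(problems, function(p) {
    list(n = p$n, c = p$c, sense = p$sense,
         eq = list(i = p$eq$i, j = p$eq$j, x = p$eq$x, rhs = p$eq$rhs),
         ub = list(i = p$ub$i, j = p$ub$j, x = p$ub$x, rhs = p$ub$rhs),
         lower = encodeBounds(p$lower, -Inf),
         upper = encodeBounds(p$upper, Inf),
         c2 = p$c2, sense2 = p$sense2, lex_tol = p$lex_tol)
  })
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)))
  jsonlite::write_json(list(problems = enc), fin, auto_unbox = TRUE,
                       digits = NA, null = "null")
  ret <- system2(lpPython(), c(shQuote(lpSolverScript()), shQuote(fin),
                               shQuote(fout)), stdout = TRUE, stderr = TRUE)
  status <- attr(ret, "status")
  if (!is.null(status) && status != 0)
    stop("LP backend failed (exit ", status, "):\n", paste(ret, collapse = "\n"))
  out <- jsonlite::fromJSON(fout, simplifyVector = FALSE)
  lapply(out, function(s) list(
    status = s$status,
    objective = if (is.null(s$objective)) NA_real_ else as.numeric(s$objective),
    objective2 = if (is.null(s$objective2)) NA_real_ else as.numeric(s$objective2),
    x = if (is.null(s$x)) NULL else vapply(s$x, as.numeric, numeric(1))))
}

solveLp <- function(problem) solveLpBatch(list(problem))[[1]]
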