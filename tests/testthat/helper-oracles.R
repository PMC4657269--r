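# Independent oracles used to cross-check the LP, graph and rank-test
# implementations on small fixtures. These deliberately avoid the code
# paths they verify.

# --- pure-strategy enumeration on the two-substrate toy universe ---
#
# Every pure strategy assigns each condition one of the two routes to
# biomass (direct 5-reaction route or 6-reaction hub route) and chooses
# regulated (express only the active route) or constitutive (express the
# union in both conditions) expression. At growth g every expressed
# enzyme needs investment g (unit rates); the switching investment is
# r * sum_i |phi_i^1 - phi_i^2|. Growth is the largest g whose worst
# condition fits the budget.

toyRoutes <- list(
  eff1 = c("uptake1", "A_C", "C_D", "D_E", "E_P"),
  eff2 = c("uptake2", "B_F", "F_G", "G_E", "E_P"),
  hub1 = c("uptake1", "A_H", "H_I", "I_D", "D_E", "E_P"),
  hub2 = c("uptake2", "B_H", "H_I", "I_D", "D_E", "E_P"))

toyStrategyGrowth <- function(r, phi0 = 1) {
  best <- 0
  for (r1 in c("eff1", "hub1")) for (r2 in c("eff2", "hub2")) {
    active <- list(c(toyRoutes[[r1]], "biomass"), c(toyRoutes[[r2]], "biomass"))
    for (constitutive in c(FALSE, TRUE)) {
      expressed <- if (constitutive) {
        u <- union(active[[1]], active[[2]]); list(u, u)
      } else active
      diffs <- length(setdiff(expressed[[1]], expressed[[2]])) +
        length(setdiff(expressed[[2]], expressed[[1]]))
      cost <- vapply(1:2, function(k)
        length(expressed[[k]]) + r * diffs, numeric(1))
      best <- max(best, phi0 / max(cost))
    }
  }
  best
}

# --- Floyd-Warshall all-pairs shortest paths (edge counts) ---
floydWarshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

metGraphAdjacency <- function(mg) {
  g <- metGraph(mg)
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
}

# --- reachability-based essentiality oracle ---
#
# A reaction set sustains growth iff, starting from the exchanged
# metabolites, reactions can fire (all substrates available => products
# available) until every biomass substrate is available. Valid for the
# irreversible fixtures it is used on.
reachabilityViable <- function(universe, knockout = NULL) {
  S <- as.matrix(stoichiometry(universe))
  kinds <- reactionKinds(universe)
  have <- rownames(S)[rowSums(S[, kinds == "pseudo_exchange", drop = FALSE] > 0) > 0]
  active <- setdiff(names(kinds)[kinds == "enzymatic"], knockout)
  if (!is.null(knockout) && any(kinds[knockout] == "biomass")) return(FALSE)
  repeat {
    fired <- FALSE
    for (j in active) {
      subs <- rownames(S)[S[, j] < 0]
      prods <- rownames(S)[S[, j] > 0]
      if (all(subs %in% have) && !all(prods %in% have)) {
        have <- union(have, prods)
        fired <- TRUE
      }
    }
    if (!fired) break
  }
  bm <- names(kinds)[kinds == "biomass"]
  bmSubs <- rownames(S)[S[, bm] < 0]
  all(bmSubs %in% have)
}

# --- permutation null for the two-group Kruskal-Wallis H ---
permutationKWPValue <- function(x, y, nPerm = 4000, seed = 42) {
  obs <- kruskalWallisTest(x, y)$H
  pool <- c(x, y)
  nx <- length(x)
  withr::with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(nPerm)) {
      idx <- sample.int(length(pool), nx)
      h <- kruskalWallisTest(pool[idx], pool[-idx])$H
      if (h >= obs - 1e-12) exceed <- exceed + 1L
    }
    (exceed + 1) / (nPerm + 1)
  })
}

# closed-form growth envelope of the toy fixture (cross-check of the
# enumeration oracle, not of the LP)
toyEnvelope <- function(r, phi0 = 1)
  phi0 * pmax(1 / (6 + 8 * r), 1 / (7 + 4 * r), 1 / 9)

toyParams <- function(r = 0) rcfbaParams(phi0 = 1, r = r)

coreModelPath <- function() {
  p <- system.file("extdata", "e_coli_core.json", package = "rcfba")
  stopifnot(nzchar(p))
  p
}
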