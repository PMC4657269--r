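test_that("toy graph has one edge per unary conversion", {
  mg <- buildGraph(buildToyUniverse())
  expect_equal(nNodes(mg), 12L)
  expect_equal(nEdges(mg), 13L)   # 14 enzymatic reactions minus biomass
  roles <- nodeRoles(mg)
  expect_setequal(inputNodes(mg), c("S1", "S2"))
  expect_setequal(biomassComponents(mg), "P")
  expect_equal(unname(roles[["A"]]), "internal")
})

test_that("carrier metabolites are removed from graphs, not from models", {
  u <- reactionUniverse(
    metabolites = data.frame(id = c("A", "B", "atp", "adp")),
    reactions = data.frame(id = c("EX_A", "v1", "bm"),
                           kind = c("pseudo_exchange", "enzymatic", "biomass")),
    stoichiometry = list(EX_A = c(A = 1),
                         v1 = c(A = -1, atp = -1, B = 1, adp = 1),
                         bm = c(B = -1)))
  mg <- buildGraph(u)
  expect_setequal(igraph::V(metGraph(mg))$name, c("A", "B"))
  expect_equal(nEdges(mg), 1L)    # single A -> B edge
  # the carriers still take part in the LP's mass balance
  expect_true(all(c("atp", "adp") %in% metaboliteIds(u)))
  # removing entries from the carrier list can only add nodes
  mgAll <- buildGraph(u, carriers = character(0))
  expect_gte(nNodes(mgAll), nNodes(mg))
})

test_that("reversible reactions contribute both edge directions", {
  u <- reactionUniverse(
    metabolites = data.frame(id = c("A", "B")),
    reactions = data.frame(id = c("v1", "bm"),
                           kind = c("enzymatic", "biomass"),
                           reversible = c(TRUE, FALSE),
                           beta = c(1, 0)),
    stoichiometry = list(v1 = c(A = -1, B = 1), bm = c(B = -1)))
  mg <- buildGraph(u)
  adj <- metGraphAdjacency(mg)
  expect_true(adj["A", "B"] && adj["B", "A"])
})

test_that("average shortest path separates the two toy designs", {
  toy <- buildToyUniverse()
  efficient <- c("uptake1", "A_C", "C_D", "D_E",
                 "uptake2", "B_F", "F_G", "G_E", "E_P", "biomass")
  hub <- c("uptake1", "A_H", "uptake2", "B_H", "H_I", "I_D", "D_E", "E_P",
           "biomass")
  expect_equal(as.numeric(avgShortestPathToBiomass(
    buildGraph(toy, reactions = efficient))), 5)
  expect_equal(as.numeric(avgShortestPathToBiomass(
    buildGraph(toy, reactions = hub))), 6)
  # hub designs pull the inputs closer together
  mEff <- structuralMetrics(buildGraph(toy, reactions = efficient))
  mHub <- structuralMetrics(buildGraph(toy, reactions = hub))
  expect_lt(as.numeric(mHub$meanInputDistance),
            as.numeric(mEff$meanInputDistance))
})

test_that("a biomass component imported directly scores l_min = 1", {
  u <- reactionUniverse(
    metabolites = data.frame(id = c("S", "B"),
                             isExternal = c(TRUE, FALSE)),
    reactions = data.frame(id = c("EX_S", "t1", "bm"),
                           kind = c("pseudo_exchange", "enzymatic", "biomass")),
    stoichiometry = list(EX_S = c(S = 1), t1 = c(S = -1, B = 1),
                         bm = c(B = -1)))
  m <- structuralMetrics(buildGraph(u))
  expect_equal(m$nDirectImports, 1L)
  expect_equal(as.numeric(m$asp), 1)
})

test_that("graph distances agree with a Floyd-Warshall oracle", {
  for (seed in 1:3) {
    u <- generateRandomUniverse(3, 3, 2, seed = seed)
    mg <- buildGraph(u)
    d <- floydWarshall(metGraphAdjacency(mg))
    ins <- inputNodes(mg); bms <- biomassComponents(mg)
    lmin <- apply(d[ins, bms, drop = FALSE], 2, min)
    expect_equal(as.numeric(avgShortestPathToBiomass(mg)),
                 mean(lmin[is.finite(lmin)]))
    ig <- igraph::distances(metGraph(mg), mode = "out", weights = NA)
    expect_equal(unname(ig[rownames(d), colnames(d)]), unname(d))
  }
})

test_that("structural metrics are invariant under node relabeling", {
  toy <- buildToyUniverse()
  met <- metaboliteTable(toy)
  met$id <- paste0("m_", rev(seq_len(nrow(met))))
  S <- as.matrix(stoichiometry(toy))
  rownames(S) <- met$id
  relab <- reactionUniverse(met, reactionTable(toy), S)
  m1 <- structuralMetrics(buildGraph(toy))
  m2 <- structuralMetrics(buildGraph(relab))
  for (f in c("nInputs", "nNodes", "nEdges", "avgDegree", "asp", "occi"))
    expect_equal(m2[[f]], m1[[f]], label = f)
})

test_that("closeness centralization peaks for the star", {
  starUniverse <- function(k) {
    ids <- c("hub", paste0("leaf", seq_len(k)), "Z")
    rx <- data.frame(id = c(paste0("v", seq_len(k)), "vz", "bm"),
                     kind = c(rep("enzymatic", k + 1), "biomass"))
    sto <- c(lapply(seq_len(k), function(i)
      stats::setNames(c(-1, 1), c("hub", paste0("leaf", i)))),
      list(vz = c(Z = -1, hub = 1), bm = c(Z = -1)))
    names(sto) <- rx$id
    reactionUniverse(data.frame(id = ids), rx, sto)
  }
  chainUniverse <- function(k) {
    ids <- c(paste0("n", seq_len(k + 1)), "Z")
    rx <- data.frame(id = c(paste0("v", seq_len(k)), "vz", "bm"),
                     kind = c(rep("enzymatic", k + 1), "biomass"))
    sto <- c(lapply(seq_len(k), function(i)
      stats::setNames(c(-1, 1), c(paste0("n", i), paste0("n", i + 1)))),
      list(vz = c(Z = -1, n1 = 1), bm = c(Z = -1)))
    names(sto) <- rx$id
    reactionUniverse(data.frame(id = ids), rx, sto)
  }
  k <- 6
  expect_gt(occi(buildGraph(starUniverse(k))),
            occi(buildGraph(chainUniverse(k))))
})

test_that("unreachable pairs are excluded and counted", {
  # two disconnected chains with two inputs
  u <- reactionUniverse(
    metabolites = data.frame(id = c("S1", "S2", "B", "P"),
                             isExternal = c(TRUE, TRUE, FALSE, FALSE)),
    reactions = data.frame(
      id = c("EX_S1", "EX_S2", "v1", "v2", "bm"),
      kind = c("pseudo_exchange", "pseudo_exchange", "enzymatic",
               "enzymatic", "biomass")),
    stoichiometry = list(EX_S1 = c(S1 = 1), EX_S2 = c(S2 = 1),
                         v1 = c(S1 = -1, P = 1),
                         v2 = c(S2 = -1, B = 1), bm = c(P = -1)))
  m <- structuralMetrics(buildGraph(u))
  expect_equal(attr(m$meanInputDistance, "nExcluded"), 2L)
  asp <- avgShortestPathToBiomass(buildGraph(u))
  expect_equal(attr(asp, "nUnreachable"), 0L)
})
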