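test_that("toy universe matches its canonical description", {
  toy <- buildToyUniverse()
  expect_equal(nMetabolites(toy), 12L)
  kinds <- reactionKinds(toy)
  expect_equal(sum(kinds != "pseudo_exchange"), 14L)
  expect_equal(sum(kinds == "pseudo_exchange"), 2L)
  expect_equal(sum(kinds == "biomass"), 1L)
  rxn <- reactionTable(toy)
  enz <- rxn$kind != "pseudo_exchange"
  expect_true(all(rxn$alpha[enz] == 1))
  expect_true(all(rxn$beta[enz] == 0))
  expect_false(any(rxn$reversible))
  # every unary conversion column has exactly one -1 and one +1
  S <- stoichiometry(toy)
  conv <- setdiff(reactionIds(toy), c("biomass", "EX_S1", "EX_S2"))
  for (j in conv) {
    col <- S[, j]
    expect_equal(sort(as.numeric(col[col != 0])), c(-1, 1))
  }
  expect_equal(sum(metaboliteTable(toy)$isExternal), 2L)
})

test_that("toy routes have the published lengths (direct 5, hub 6)", {
  # breadth-first search over the fixture graph, independent of the LP
  mg <- buildGraph(buildToyUniverse())
  adj <- metGraphAdjacency(mg)
  d <- floydWarshall(adj)
  expect_equal(d["S1", "P"], 5)
  expect_equal(d["S2", "P"], 5)
  # hub route: forced through H
  dH <- floydWarshall(adj)
  expect_equal(d["S1", "H"] + d["H", "P"], 6)
  expect_equal(d["S2", "H"] + d["H", "P"], 6)
})

test_that("toy environments alternate the two substrates", {
  envs <- buildToyEnvironments()
  expect_equal(nConditions(envs), 2L)
  expect_equal(exchangeBound(envs, 1, "EX_S2"), 0)
  expect_equal(exchangeBound(envs, 2, "EX_S1"), 0)
  expect_true(is.infinite(exchangeBound(envs, 1, "EX_S1")))
  expect_true(is.infinite(exchangeBound(envs, 2, "EX_S2")))
})

test_that("universes round-trip exactly through every supported format", {
  toy <- buildToyUniverse()
  for (fmt in c("tsv", "cobra_json", "sbml")) {
    path <- withr::local_tempfile(fileext = paste0(
      ".", switch(fmt, tsv = "tsv", cobra_json = "json", sbml = "xml")))
    writeUniverse(toy, path, fmt)
    back <- readUniverse(path, fmt)
    expect_identical(as.matrix(stoichiometry(back)),
                     as.matrix(stoichiometry(toy)), label = fmt)
    expect_identical(reactionKinds(back), reactionKinds(toy), label = fmt)
    expect_identical(reactionTable(back)$reversible,
                     reactionTable(toy)$reversible, label = fmt)
    expect_identical(reactionTable(back)$alpha, reactionTable(toy)$alpha,
                     label = fmt)
    expect_identical(reactionTable(back)$beta, reactionTable(toy)$beta,
                     label = fmt)
    expect_identical(metaboliteTable(back)$isExternal,
                     metaboliteTable(toy)$isExternal, label = fmt)
  }
})

test_that("perturbed rates survive a round trip exactly", {
  u <- randomizeRates(buildToyUniverse(), sigma = 0.9, seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  writeUniverse(u, path, "cobra_json")
  expect_identical(reactionTable(readUniverse(path))$alpha,
                   reactionTable(u)$alpha)
})

test_that("minimal tabular model parses", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# one-reaction universe",
               "v1\tenzymatic\tFALSE\t1\t0\tA -> B"), path)
  u <- readUniverse(path)
  expect_equal(nMetabolites(u), 2L)
  expect_equal(nReactions(u), 1L)
  expect_true(is.na(biomassId(u)))
})

test_that("tabular equations support coefficients and exchanges", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("@external S",
               "EX_S\tpseudo_exchange\tFALSE\t1\t0\t-> S",
               "v1\tenzymatic\tFALSE\t1\t0\t2 S + B -> C",
               "bm\tbiomass\tFALSE\t1\t0\tC ->"), path)
  u <- readUniverse(path)
  S <- stoichiometry(u)
  expect_equal(S["S", "v1"], -2)
  expect_equal(S["B", "v1"], -1)
  expect_equal(S["C", "v1"], 1)
  expect_equal(S["S", "EX_S"], 1)   # uptake-positive supply
  expect_equal(biomassId(u), "bm")
  expect_true(metaboliteTable(u)$isExternal[metaboliteTable(u)$id == "S"])
})

test_that("malformed files produce informative errors", {
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("v1\tenzymatic\tFALSE\t1", p1)
  expect_error(readUniverse(p1), "line 1")
  p2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"metabolites": []}', p2)
  expect_error(readUniverse(p2), "reactions")
  # model without an identifiable biomass asks for the biomass argument
  p3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list(list(id = "A", compartment = "c"),
                       list(id = "B", compartment = "c")),
    reactions = list(list(id = "v1", metabolites = list(A = -1, B = 1),
                          lower_bound = 0, upper_bound = 1000),
                     list(id = "v2", metabolites = list(B = -1),
                          lower_bound = 0, upper_bound = 1000))),
    p3, auto_unbox = TRUE)
  expect_error(readUniverse(p3), "biomass")
  u <- readUniverse(p3, biomass = "v2")
  expect_equal(biomassId(u), "v2")
})

test_that("published core model loads with its printed dimensions", {
  core <- readUniverse(coreModelPath())
  expect_equal(nReactions(core), 95L)   # pseudo reactions included
  expect_equal(nMetabolites(core), 72L)
  expect_equal(sum(reactionKinds(core) == "pseudo_exchange"), 20L)
  expect_equal(biomassId(core), "Biomass_Ecoli_core")
  # default rates: alpha 1 everywhere, beta 1 only where reversible
  rxn <- reactionTable(core)
  enz <- rxn$kind != "pseudo_exchange"
  expect_true(all(rxn$alpha[enz] == 1))
  expect_true(all(rxn$beta[enz & rxn$reversible] == 1))
  expect_true(all(rxn$beta[enz & !rxn$reversible] == 0))
})

test_that("core environment set encodes the five carbon-source conditions", {
  core <- readUniverse(coreModelPath())
  envs <- buildCoreEnvironments(core)
  expect_equal(nConditions(envs), 5L)
  # single carbon source per condition
  expect_equal(exchangeBound(envs, "acetate", "EX_glc__D_e"), 0)
  expect_equal(exchangeBound(envs, "acetate", "EX_pyr_e"), 0)
  expect_true(is.infinite(exchangeBound(envs, "acetate", "EX_ac_e")))
  # D-glucose is the anaerobic condition
  expect_equal(exchangeBound(envs, "D-glucose", "EX_o2_e"), 0)
  expect_true(is.infinite(exchangeBound(envs, "acetate", "EX_o2_e")))
  for (k in conditionNames(envs)) {
    expect_true(is.infinite(exchangeBound(envs, k, "EX_nh4_e")))
    expect_true(is.infinite(exchangeBound(envs, k, "EX_pi_e")))
    expect_true(is.infinite(exchangeBound(envs, k, "EX_co2_e")))
  }
  expect_error(buildCoreEnvironments(buildToyUniverse()), "EX_glc__D_e")
})

test_that("rate randomization honours its stated bounds and seeds", {
  toy <- buildToyUniverse()
  expect_identical(randomizeRates(toy, 0, seed = 1), toy)
  u1 <- randomizeRates(toy, 0.9, seed = 1)
  u2 <- randomizeRates(toy, 0.9, seed = 2)
  a1 <- reactionTable(u1)$alpha[reactionTable(u1)$kind != "pseudo_exchange"]
  a2 <- reactionTable(u2)$alpha[reactionTable(u2)$kind != "pseudo_exchange"]
  expect_false(identical(a1, a2))
  expect_true(all(a1 >= 0.1 & a1 <= 1.9))
  expect_true(all(a2 >= 0.1 & a2 <= 1.9))
  a3 <- reactionTable(randomizeRates(toy, 0.1, seed = 3))$alpha
  expect_true(all(a3 >= 0.9 & a3 <= 1.1))
  expect_identical(randomizeRates(toy, 0.9, seed = 1), u1)  # reproducible
  # irreversible betas untouched
  expect_true(all(reactionTable(u1)$beta == 0))
  expect_error(randomizeRates(toy, 1), "sigma")
})

test_that("rate draws are centred on the mean rate", {
  toy <- buildToyUniverse()
  draws <- vapply(seq_len(600), function(s)
    reactionTable(randomizeRates(toy, 0.9, seed = s))$alpha[1], numeric(1))
  se <- 0.9 / sqrt(3) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 1), 3 * se)
})

test_that("environment configs round-trip through YAML and JSON", {
  envs <- buildToyEnvironments()
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    writeEnvironments(envs, path)
    back <- readEnvironments(path)
    expect_equal(nConditions(back), 2L)
    expect_true(is.infinite(exchangeBound(back, "env_S1", "EX_S1")))
    expect_equal(exchangeBound(back, "env_S1", "EX_S2"), 0)
  }
})
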