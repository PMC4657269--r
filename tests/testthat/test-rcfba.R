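# The toy-universe expectations below were computed with the
# pure-strategy enumeration oracle in helper-oracles.R (and, where
# noted, by hand from the switching-investment definition), not with
# the LP under test.

test_that("optimal growth matches the enumeration oracle across r", {
  toy <- buildToyUniverse(); envs <- buildToyEnvironments()
  rGrid <- seq(0, 1, by = 0.05)
  prof <- sweepR(toy, envs, toyParams(), rGrid)
  oracle <- vapply(rGrid, toyStrategyGrowth, numeric(1))
  expect_equal(prof$growth, oracle, tolerance = 1e-8)
  # the enumeration oracle itself agrees with the closed-form envelope
  expect_equal(oracle, toyEnvelope(rGrid), tolerance = 1e-12)
  # frozen anchor values: 1/6 with dedicated routes, 1/9 constitutive hub
  expect_equal(prof$growth[prof$r == 0], 1 / 6, tolerance = 1e-8)
  expect_equal(prof$growth[prof$r == 1], 1 / 9, tolerance = 1e-8)
})

test_that("network inference recovers the expected designs", {
  toy <- buildToyUniverse(); envs <- buildToyEnvironments()
  solLow <- solveRcfba(toy, envs, toyParams(0.1))
  expect_setequal(inferNetwork(solLow),
                  c("uptake1", "A_C", "C_D", "D_E",
                    "uptake2", "B_F", "F_G", "G_E", "E_P", "biomass"))
  solMid <- solveRcfba(toy, envs, toyParams(0.4))
  expect_setequal(inferNetwork(solMid),
                  c("uptake1", "A_H", "uptake2", "B_H",
                    "H_I", "I_D", "D_E", "E_P", "biomass"))
  expect_identical(sort(selectedReactions(solMid)),
                   sort(inferNetwork(solMid)))
})

test_that("regulon counting tracks the regulation strategy", {
  toy <- buildToyUniverse(); envs <- buildToyEnvironments()
  regLow <- countRegulons(solveRcfba(toy, envs, toyParams(0.1)))
  expect_equal(regLow$count, 3L)
  sizes <- sort(vapply(regLow$patterns, length, integer(1)))
  expect_equal(unname(sizes), c(2L, 4L, 4L))   # always-on pair + two route sets
  regHigh <- countRegulons(solveRcfba(toy, envs, toyParams(0.6)))
  expect_equal(regHigh$count, 1L)
  expect_equal(names(regHigh$patterns), "11")
  # a single environment with growth has exactly one regulon
  envs1 <- environmentSet(list(only_S1 = c(EX_S1 = Inf, EX_S2 = 0)))
  expect_equal(countRegulons(solveRcfba(toy, envs1, toyParams(0.7)))$count, 1L)
})

test_that("switching investment evaluates its defining sum exactly", {
  # identical investments: no switching cost
  phi <- matrix(c(1, 2, 1, 2), 2, 2)
  expect_equal(switchingInvestment(phi, r = 0.7), c(0, 0))
  # single enzyme expressed in one of two conditions: phi' = r * g
  g <- 0.35
  phi1 <- matrix(c(g, 0), 1, 2)
  expect_equal(switchingInvestment(phi1, r = 0.4), c(0.4 * g, 0.4 * g))
  # hand evaluation on the efficient toy design: 8 r g per condition
  sol <- solveRcfba(buildToyUniverse(), buildToyEnvironments(), toyParams(0.1))
  gopt <- objectiveValue(sol)
  expect_equal(unname(switchingInvestments(sol)), rep(8 * 0.1 * gopt, 2),
               tolerance = 1e-6)
  # recomputation from the returned investments matches the stored value
  expect_equal(switchingInvestments(sol),
               switchingInvestment(investments(sol), 0.1))
  # P = 1 yields 0 by convention
  expect_equal(switchingInvestment(matrix(1:3, 3, 1), r = 5), 0)
})

test_that("solutions satisfy every model constraint", {
  toy <- buildToyUniverse(); envs <- buildToyEnvironments()
  for (r in c(0, 0.2, 0.45, 0.8)) {
    v <- verifySolution(solveRcfba(toy, envs, toyParams(r)))
    expect_true(all(v <= 1e-8), label = paste("violations at r =", r))
  }
  core <- readUniverse(coreModelPath())
  vc <- verifySolution(solveRcfba(core, buildCoreEnvironments(core),
                                  rcfbaParams(phi0 = 100, r = 0.5)))
  expect_true(all(vc <= 1e-5 * 100))  # relative to the phi0 = 100 scale
})

test_that("capacity binds whenever the organism grows", {
  toy <- buildToyUniverse(); envs <- buildToyEnvironments()
  sol <- solveRcfba(toy, envs, toyParams(0.3))
  used <- colSums(investments(sol)) + switchingInvestments(sol)
  expect_equal(unname(used), c(1, 1), tolerance = 1e-6)
})

test_that("objective scales linearly with the resource capacity", {
  toy <- buildToyUniverse(); envs <- buildToyEnvironments()
  base <- objectiveValue(solveRcfba(toy, envs, rcfbaParams(phi0 = 1, r = 0.3)))
  scaled <- objectiveValue(solveRcfba(toy, envs, rcfbaParams(phi0 = 2.5, r = 0.3)))
  expect_equal(scaled, 2.5 * base, tolerance = 1e-8)
})

test_that("r = 0 decomposes into independent per-condition problems", {
  toy <- buildToyUniverse(); envs <- buildToyEnvironments()
  joint <- objectiveValue(solveRcfba(toy, envs, toyParams(0)))
  singles <- vapply(conditionNames(envs), function(nm) {
    e1 <- environmentSet(envs@conditions[nm])
    objectiveValue(solveRcfba(toy, e1, toyParams(0)))
  }, numeric(1))
  expect_equal(joint, mean(singles), tolerance = 1e-8)
})

test_that("a single environment is insensitive to r", {
  toy <- buildToyUniverse()
  e1 <- environmentSet(list(only_S1 = c(EX_S1 = Inf, EX_S2 = 0)))
  s0 <- solveRcfba(toy, e1, toyParams(0))
  s5 <- solveRcfba(toy, e1, toyParams(5))
  expect_equal(objectiveValue(s5), objectiveValue(s0), tolerance = 1e-9)
  expect_identical(selectedReactions(s5), selectedReactions(s0))
})

test_that("growth is non-increasing in r and in nutrient scarcity", {
  toy <- buildToyUniverse(); envs <- buildToyEnvironments()
  prof <- sweepR(toy, envs, toyParams(), seq(0, 1.2, by = 0.1))
  expect_true(all(diff(prof$growth) <= 1e-9))
  # tightening an exchange bound cannot increase growth
  envTight <- environmentSet(list(env_S1 = c(EX_S1 = 0.5, EX_S2 = 0),
                                  env_S2 = c(EX_S1 = 0, EX_S2 = Inf)))
  expect_lte(objectiveValue(solveRcfba(toy, envTight, toyParams(0))),
             objectiveValue(solveRcfba(toy, envs, toyParams(0))) + 1e-9)
})

test_that("closed environments yield zero growth and an empty network", {
  toy <- buildToyUniverse()
  closed <- environmentSet(list(none = c(EX_S1 = 0, EX_S2 = 0),
                                still_none = c(EX_S1 = 0, EX_S2 = 0)))
  sol <- solveRcfba(toy, closed, toyParams(0.2))
  expect_equal(solutionStatus(sol), "optimal")
  expect_equal(unname(growthRates(sol)), c(0, 0))
  expect_length(inferNetwork(sol), 0)
  expect_equal(countRegulons(sol)$count, 0L)
  expect_equal(selectedInputs(sol), 0L)
})

test_that("degenerate inputs are rejected with clear errors", {
  toy <- buildToyUniverse()
  noBm <- subsetUniverse(toy, setdiff(reactionIds(toy), "biomass"))
  expect_error(solveRcfba(noBm, buildToyEnvironments(), toyParams(0)),
               "biomass")
  expect_error(solveRcfba(toy, environmentSet(list(bad = c(A_C = Inf))),
                          toyParams(0)),
               "pseudo-exchange")
  expect_error(rcfbaParams(phi0 = -1))
  expect_error(rcfbaParams(r = -0.1))
})
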