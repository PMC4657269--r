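test_that("sweep profiles reproduce the toy restructuring", {
  toy <- buildToyUniverse(); envs <- buildToyEnvironments()
  rGrid <- seq(0, 1, by = 0.1)
  prof <- sweepR(toy, envs, toyParams(), rGrid)
  expect_equal(nrow(prof), length(rGrid))
  # growth strictly decreasing until the regulatory transition, then flat
  pre <- prof$growth[prof$r <= 0.5]
  expect_true(all(diff(pre) < 0))
  expect_equal(prof$growth[prof$r > 0.5], rep(1 / 9, sum(prof$r > 0.5)),
               tolerance = 1e-8)
  # network size shrinks across the structural transition
  expect_equal(prof$nReactions[prof$r < 0.25], rep(10L, sum(rGrid < 0.25)))
  expect_equal(prof$nReactions[prof$r > 0.3], rep(9L, sum(rGrid > 0.3)))
  expect_equal(prof$nInputs, rep(2L, length(rGrid)))
  # pathway length grows from the direct to the hub design
  expect_equal(prof$asp[prof$r < 0.25], rep(5, sum(rGrid < 0.25)))
  expect_equal(prof$asp[prof$r > 0.3], rep(6, sum(rGrid > 0.3)))
  expect_equal(prof$nRegulons[prof$r < 0.5], rep(3L, sum(rGrid < 0.5)))
  expect_equal(prof$nRegulons[prof$r > 0.5], rep(1L, sum(rGrid > 0.5)))
  # a profile at a given r equals a direct solve at that r
  one <- sweepR(toy, envs, toyParams(), 0.3)
  expect_equal(one$nReactions, 9L)
  expect_equal(one$growth, objectiveValue(solveRcfba(toy, envs, toyParams(0.3))),
               tolerance = 1e-10)
})

test_that("transition detection localizes both toy transitions", {
  toy <- buildToyUniverse(); envs <- buildToyEnvironments()
  tr <- detectTransitions(toy, envs, toyParams(), interval = c(0, 1),
                          nGrid = 11, resolution = 1e-3)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$kind, c("structural", "regulatory"))
  expect_equal(tr$r[1], 0.25, tolerance = 0.01)
  expect_equal(tr$r[2], 0.5, tolerance = 0.01)
})

test_that("bisection refinement is consistent across resolutions", {
  toy <- buildToyUniverse(); envs <- buildToyEnvironments()
  coarse <- detectTransitions(toy, envs, toyParams(), interval = c(0.1, 0.4),
                              nGrid = 4, resolution = 1e-2)
  fine <- detectTransitions(toy, envs, toyParams(), interval = c(0.1, 0.4),
                            nGrid = 4, resolution = 1e-3)
  expect_equal(nrow(coarse), 1L)
  expect_equal(nrow(fine), 1L)
  expect_lt(abs(coarse$r - fine$r), 1e-2)
})

test_that("degenerate sweeps report no transitions", {
  toy <- buildToyUniverse()
  # a constant environment makes r irrelevant
  e1 <- environmentSet(list(only_S1 = c(EX_S1 = Inf, EX_S2 = 0)))
  tr <- detectTransitions(toy, e1, toyParams(), interval = c(0, 1), nGrid = 5)
  expect_equal(nrow(tr), 0L)
  # a single grid point yields an empty report
  tr1 <- detectTransitions(toy, buildToyEnvironments(), toyParams(),
                           interval = c(0.1, 0.1), nGrid = 1)
  expect_equal(nrow(tr1), 0L)
})

test_that("growth breakpoints sit at the envelope kinks", {
  # closed-form envelope samples (no LP involved)
  r <- seq(0, 1, by = 0.01)
  prof <- data.frame(r = r, growth = toyEnvelope(r))
  expect_equal(growthBreakpoints(prof), c(0.25, 0.5))
  # a linear curve has no breakpoints
  lin <- data.frame(r = r, growth = 3 - 2 * r)
  expect_length(growthBreakpoints(lin), 0)
  # a smooth convex curve sampled finely has none either
  smooth <- data.frame(r = r, growth = 1 / (6 + 8 * r))
  expect_length(growthBreakpoints(smooth), 0)
})

test_that("zero-noise Monte-Carlo averaging equals a single sweep", {
  toy <- buildToyUniverse(); envs <- buildToyEnvironments()
  rGrid <- c(0, 0.3, 0.7)
  mc <- monteCarloSweep(toy, envs, toyParams(), rGrid, sigma = 0,
                        nReps = 3, seed = 11)
  single <- sweepR(toy, envs, toyParams(), rGrid)
  expect_equal(mc$growth, single$growth, tolerance = 1e-9)
  expect_equal(mc$nReactions, as.numeric(single$nReactions))
  expect_equal(mc$growth.se, rep(0, 3), tolerance = 1e-12)
  expect_equal(attr(mc, "nFailed"), 0L)
})

test_that("Monte-Carlo replicates are seeded reproducibly", {
  toy <- buildToyUniverse(); envs <- buildToyEnvironments()
  a <- monteCarloSweep(toy, envs, toyParams(), c(0.2, 0.6), sigma = 0.5,
                       nReps = 2, seed = 5)
  b <- monteCarloSweep(toy, envs, toyParams(), c(0.2, 0.6), sigma = 0.5,
                       nReps = 2, seed = 5)
  expect_equal(a, b)
})
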