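# The synthetic-model stage: the PYRCORE fixture, the seeded random
# generator, and the brute-force design oracle.

test_that("the fixture is built exactly as specified", {
  m <- makePyrcore()
  expect_identical(length(reactionIds(m)), 23L)
  expect_identical(length(metaboliteIds(m)), 21L)
  expect_identical(length(geneIds(m)), 7L)
  expect_setequal(unique(m@metabolites$compartment), c("e", "c"))
  expect_identical(objectiveId(m), "BIOMASS")
  # cofactor pairs conserved by every internal reaction
  S <- as.matrix(stoichiometricMatrix(m))
  internal <- reactionIds(m)[reactionKinds(m) %in%
                               c("internal", "biomass", "maintenance")]
  for (r in internal) {
    expect_identical(sum(S[c("nad_c", "nadh_c"), r]), 0)
    expect_identical(sum(S[c("atp_c", "adp_c"), r]), 0)
  }
  # deterministic: two builds are identical
  expect_identical(makePyrcore(), m)
})

test_that("the random generator is seeded-deterministic", {
  spec <- randomModelSpec(seed = 42)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  writeModelJSON(makeRandomModel(spec), p1)
  writeModelJSON(makeRandomModel(spec), p2)
  expect_identical(readLines(p1), readLines(p2))
  # and the global RNG stream is left untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(makeRandomModel(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("every generated model is growth-feasible and mass-balanced", {
  for (seed in 1:15) {
    spec <- randomModelSpec(seed = seed,
                            n_segments = 1 + seed %% 3,
                            n_cofactor_pairs = 1 + seed %% 2,
                            n_branches = 1 + seed %% 4)
    m <- makeRandomModel(spec)
    sol <- solveFBA(m)
    expect_identical(solverStatus(sol), "optimal")
    expect_gt(objectiveValue(sol), 0)
    expect_lt(max(abs(as.matrix(stoichiometricMatrix(m)) %*%
                        fluxes(sol))), 1e-6)
  }
  expect_error(randomModelSpec(n_segments = 0), "n_segments")
})

test_that("brute-force design reproduces the fixture's hand optima", {
  m <- makePyrcore()
  b0 <- bruteForceDesign(m, pyrEnv(), "EX_bdo_e", K = 0, f_min = 1.1)
  expect_identical(b0$reactions, character())
  expect_lt(abs(b0$growth - 11), 1e-6)
  expect_lt(abs(b0$target), 1e-6)
  b1 <- bruteForceDesign(m, pyrEnv(), "EX_bdo_e", K = 1, f_min = 1.1)
  expect_identical(b1$reactions, "ADH")
  expect_lt(abs(b1$growth - 117 / 11), 1e-6)
  expect_lt(abs(b1$target - 10 / 11), 1e-6)
  b2 <- bruteForceDesign(m, pyrEnv(), "EX_bdo_e", K = 2, f_min = 1.1)
  expect_setequal(b2$reactions, c("ADH", "RESP"))
  expect_lt(abs(b2$growth - 7), 1e-6)
  expect_lt(abs(b2$target - 2), 1e-6)
})

test_that("the enumeration guard refuses oversized searches", {
  m <- makePyrcore()
  expect_error(
    bruteForceDesign(m, pyrEnv(), "EX_bdo_e", K = 3, f_min = 1.1,
                     guard = 10L),
    "guard")
})
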