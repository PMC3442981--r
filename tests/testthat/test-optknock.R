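# Bilevel knockout design: candidate construction, the MILP against
# the enumeration oracle, alternative enumeration, iterative
# refinement, and independent verification.

tol <- 1e-6

test_that("candidate set applies the exclusion rules with reasons", {
  m <- makePyrcore()
  cs <- buildCandidateSet(m, pyrEnv(), f_min = 1.1)
  expect_identical(cs$candidates,
                   sort(c("GPD", "PDC", "ACB", "ADH", "BDH", "RESP")))
  # the two glycolytic steps are essential, everything else is excluded
  # by kind
  ess <- cs$exclusions$reaction[grepl("essential", cs$exclusions$reason)]
  expect_setequal(ess, c("GLY1", "GLY2"))
  bykind <- cs$exclusions$reaction[grepl("^kind:", cs$exclusions$reason)]
  expect_setequal(bykind,
                  reactionIds(m)[reactionKinds(m) != "internal"])
})

test_that("an exchange-only model yields an empty candidate set", {
  mets <- c("a_e", "b_e")
  rx <- data.frame(id = c("EX_a_e", "EX_b_e", "AB"),
                   lb = c(-5, 0, 0), ub = c(0, 10, 10),
                   kind = c(NA, NA, "biomass"))
  sto <- list(EX_a_e = c(a_e = -1), EX_b_e = c(b_e = -1),
              AB = c(a_e = -1, b_e = 1))
  m <- metabolicModel(mets, rx, sto, objective = "AB")
  expect_warning(cs <- buildCandidateSet(m, NULL, 0), "empty")
  expect_length(cs$candidates, 0L)
})

test_that("the MILP matches the fixture's enumeration oracle at K = 0..3", {
  m <- makePyrcore()
  prev <- -Inf
  for (K in 0:3) {
    st <- solveOptKnock(m, pyrEnv(), "EX_bdo_e",
                        optKnockConfig(K = K, f_min = 1.1))
    bf <- bruteForceDesign(m, pyrEnv(), "EX_bdo_e", K, f_min = 1.1)
    expect_lt(abs(st@targetFlux - bf$target), tol)
    expect_identical(deletedReactions(st), bf$reactions)
    expect_gte(st@targetFlux, prev - tol)   # monotone in K
    prev <- st@targetFlux
  }
  # K = 0 reduces to wild-type FBA
  st0 <- solveOptKnock(m, pyrEnv(), "EX_bdo_e",
                       optKnockConfig(K = 0, f_min = 1.1))
  expect_identical(deletedReactions(st0), character())
  expect_lt(abs(st0@growth - 11), tol)
  expect_lt(abs(st0@targetFlux), tol)
})

test_that("designs are growth-coupled as the fixture's biology demands", {
  m <- makePyrcore()
  st1 <- solveOptKnock(m, pyrEnv(), "EX_bdo_e",
                       optKnockConfig(K = 1, f_min = 1.1))
  expect_identical(deletedReactions(st1), "ADH")
  expect_lt(abs(st1@growth - 117 / 11), tol)
  expect_lt(abs(st1@targetFlux - 10 / 11), tol)
  expect_lt(abs(st1@targetFluxMin - 10 / 11), tol)   # coupled: min = max
  st2 <- solveOptKnock(m, pyrEnv(), "EX_bdo_e",
                       optKnockConfig(K = 2, f_min = 1.1))
  expect_setequal(deletedReactions(st2), c("ADH", "RESP"))
  expect_lt(abs(st2@growth - 7), tol)
  expect_lt(abs(st2@targetFlux - 2), tol)
})

test_that("the MILP matches brute force on seeded random models", {
  for (seed in c(1, 5, 12, 19, 28)) {
    m <- makeRandomModel(randomModelSpec(seed = seed,
                                         n_branches = 2 + seed %% 3))
    tgt <- grep("^EX_p", reactionIds(m), value = TRUE)
    tgt <- tgt[length(tgt)]
    f_min <- 0.05 * objectiveValue(solveFBA(m))
    K <- 1 + seed %% 3
    st <- solveOptKnock(m, NULL, tgt, optKnockConfig(K = K, f_min = f_min))
    bf <- bruteForceDesign(m, NULL, tgt, K, f_min = f_min)
    expect_lt(abs(st@targetFlux - bf$target), tol * max(1, abs(bf$target)))
    expect_identical(deletedReactions(st), bf$reactions)
  }
})

test_that("alternative enumeration cuts are sound and ordered", {
  m <- makePyrcore()
  alts <- enumerateAlternatives(m, pyrEnv(), "EX_bdo_e",
                                optKnockConfig(K = 1, f_min = 1.1),
                                n_solutions = 3)
  expect_gte(length(alts), 2L)
  expect_identical(deletedReactions(alts[[1]]), "ADH")
  expect_lt(abs(alts[[1]]@targetFlux - 10 / 11), tol)
  keys <- vapply(alts, function(s)
    paste(deletedReactions(s), collapse = ","), character(1))
  expect_identical(anyDuplicated(keys), 0L)   # no strategy twice
  objs <- vapply(alts, function(s) s@targetFlux, numeric(1))
  expect_true(all(diff(objs) <= tol))         # descending
  # n = 1 coincides with a single solve
  one <- enumerateAlternatives(m, pyrEnv(), "EX_bdo_e",
                               optKnockConfig(K = 1, f_min = 1.1),
                               n_solutions = 1)
  expect_identical(deletedReactions(one[[1]]), "ADH")
  # K = 0: the empty strategy, then exhaustion
  k0 <- suppressMessages(
    enumerateAlternatives(m, pyrEnv(), "EX_bdo_e",
                          optKnockConfig(K = 0, f_min = 1.1),
                          n_solutions = 2))
  expect_length(k0, 1L)
  expect_identical(deletedReactions(k0[[1]]), character())
})

test_that("iterative refinement respects the ban list", {
  m <- makePyrcore()
  st <- iterativeRefine(m, pyrEnv(), "EX_bdo_e",
                        optKnockConfig(K = 2, f_min = 1.1),
                        ban = "RESP")
  expect_length(intersect(deletedReactions(st), "RESP"), 0L)
  expect_gte(st@targetFlux, 10 / 11 - tol)
  # empty ban is a plain solve
  st0 <- iterativeRefine(m, pyrEnv(), "EX_bdo_e",
                         optKnockConfig(K = 2, f_min = 1.1))
  expect_setequal(deletedReactions(st0), c("ADH", "RESP"))
  # unknown entries are warned about and ignored
  expect_warning(
    iterativeRefine(m, pyrEnv(), "EX_bdo_e",
                    optKnockConfig(K = 1, f_min = 1.1),
                    ban = c("RESP", "NOT_A_CANDIDATE")),
    "NOT_A_CANDIDATE")
  # banning everything is an explicit error
  cand <- buildCandidateSet(m, pyrEnv(), 1.1)$candidates
  expect_error(
    iterativeRefine(m, pyrEnv(), "EX_bdo_e",
                    optKnockConfig(K = 1, f_min = 1.1), ban = cand),
    "empty")
})

test_that("verification records growth, coupling range and envelope", {
  m <- makePyrcore()
  ver <- verifyStrategy(m, pyrEnv(), "EX_bdo_e", "ADH",
                        substrate_id = "EX_glc_e")
  expect_length(ver$flags, 0L)
  expect_lt(abs(ver$growth - 117 / 11), tol)
  expect_lt(abs(ver$target_max - 10 / 11), tol)
  expect_lt(abs(ver$target_min - 10 / 11), tol)
  df <- as.data.frame(ver$envelope)
  expect_lt(abs(df$max[1] - 8), tol)
  expect_lt(abs(df$max[nrow(df)] - 10 / 11), tol)
  want_yield <- (10 / 11) * molarMasses[["butanediol"]] /
    (10 * molarMasses[["glucose"]])
  expect_lt(abs(ver$yield - want_yield), 1e-9)

  # empty strategy: the wild-type record
  wt <- verifyStrategy(m, pyrEnv(), "EX_bdo_e", character())
  expect_lt(abs(wt$growth - 11), tol)
  expect_lt(abs(wt$target_max), tol)

  # a lethal deletion comes back flagged with zero growth
  dead <- verifyStrategy(m, pyrEnv(), "EX_bdo_e", "GLY1")
  expect_identical(dead$growth, 0)
  expect_gt(length(dead$flags), 0L)

  # stored predictions that disagree get flagged
  bogus <- new("KnockoutStrategy", reactions = "ADH", geneSets = list(),
               growth = 5, targetFlux = 10 / 11, targetFluxMin = 10 / 11,
               yield = NA_real_, target = "EX_bdo_e", gap = 0, bound = 0)
  verb <- verifyStrategy(m, pyrEnv(), "EX_bdo_e", bogus)
  expect_true(any(grepl("growth", verb$flags)))
})

test_that("every returned strategy passes verification without flags", {
  m <- makePyrcore()
  for (K in 0:2) {
    st <- solveOptKnock(m, pyrEnv(), "EX_bdo_e",
                        optKnockConfig(K = K, f_min = 1.1))
    ver <- verifyStrategy(m, pyrEnv(), "EX_bdo_e", st)
    expect_length(ver$flags, 0L)
  }
})

test_that("an unreachable viability threshold is an explicit error", {
  m <- makePyrcore()
  expect_error(
    solveOptKnock(m, pyrEnv(), "EX_bdo_e",
                  optKnockConfig(K = 1, f_min = 50,
                                 candidates = c("ADH", "GPD"))),
    "no knockout strategy")
})
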