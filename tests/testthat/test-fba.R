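# Flux balance analysis on the hand-solvable fixture. All expected
# numbers are exact rationals derived by hand from the fixture's
# stoichiometry (cofactor balances around the pyruvate node), so the
# assertions are at solver tolerance.

tol <- 1e-6

test_that("wild-type optimum reproduces the hand solution exactly", {
  m <- makePyrcore()
  sol <- solveFBA(m, pyrEnv())
  expect_identical(solverStatus(sol), "optimal")
  expect_lt(abs(objectiveValue(sol) - 11), tol)
  f <- fluxes(sol)
  expect_lt(abs(f[["EX_etoh_e"]] - 2), tol)
  expect_lt(abs(f[["EX_glyc_e"]] - 7), tol)
  expect_lt(abs(f[["RESP"]] - 4), tol)
  expect_lt(abs(f[["EX_bdo_e"]]), tol)
})

test_that("no substrate means no maintenance: infeasible", {
  m <- makePyrcore()
  env0 <- environmentSpec(uptakes = c(EX_glc_e = 0, EX_o2_e = -2))
  expect_identical(solverStatus(solveFBA(m, env0)), "infeasible")
})

test_that("ADH knockout reroutes flux to butanediol and glycerol", {
  ko <- applyKnockouts(makePyrcore(), reactions = "ADH")
  sol <- solveFBA(ko, pyrEnv())
  expect_lt(abs(objectiveValue(sol) - 117 / 11), tol)
  at_mu <- fixAndOptimize(ko, pyrEnv(), "BIOMASS", "EX_bdo_e")
  expect_lt(abs(objectiveValue(at_mu) - 10 / 11), tol)
  expect_lt(abs(fluxes(at_mu)[["EX_glyc_e"]] - 83 / 11), tol)
})

test_that("lexicographic re-optimization resolves degenerate optima", {
  m <- makePyrcore()
  ko <- applyKnockouts(m, reactions = "ADH")
  # max and min coincide at the growth optimum: growth-coupled
  mx <- fixAndOptimize(ko, pyrEnv(), "BIOMASS", "EX_bdo_e",
                       secondary_sense = "max")
  mn <- fixAndOptimize(ko, pyrEnv(), "BIOMASS", "EX_bdo_e",
                       secondary_sense = "min")
  expect_lt(abs(objectiveValue(mx) - 10 / 11), tol)
  expect_lt(abs(objectiveValue(mn) - 10 / 11), tol)
  # wild type produces nothing at its optimum
  wt <- fixAndOptimize(m, pyrEnv(), "BIOMASS", "EX_bdo_e")
  expect_lt(abs(objectiveValue(wt)), tol)
  # infeasible first stage propagates
  env0 <- environmentSpec(uptakes = c(EX_glc_e = 0, EX_o2_e = -2))
  expect_identical(solverStatus(
    fixAndOptimize(m, env0, "BIOMASS", "EX_bdo_e")), "infeasible")
})

test_that("FVA brackets the attainable flux range", {
  ko <- applyKnockouts(makePyrcore(), reactions = "ADH")
  at1 <- solveFVA(ko, pyrEnv(), "EX_bdo_e", growth_fraction = 1)
  expect_lt(abs(at1$min - 10 / 11), tol)
  expect_lt(abs(at1$max - 10 / 11), tol)
  at0 <- solveFVA(ko, pyrEnv(), "EX_bdo_e", growth_fraction = 0)
  expect_lt(abs(at0$min), tol)
  expect_lt(abs(at0$max - 8), tol)
  empty <- solveFVA(ko, pyrEnv(), character())
  expect_identical(nrow(empty), 0L)
})

test_that("production envelopes have consistent endpoints", {
  ko <- applyKnockouts(makePyrcore(), reactions = "ADH")
  pe <- productionEnvelope(ko, pyrEnv(), "EX_bdo_e", n_points = 2)
  df <- as.data.frame(pe)
  expect_identical(nrow(df), 2L)
  expect_lt(abs(df$growth[1]), tol)
  expect_lt(abs(df$max[1] - 8), tol)
  expect_lt(abs(df$growth[2] - 117 / 11), tol)
  expect_lt(abs(df$min[2] - 10 / 11), tol)
  expect_lt(abs(df$max[2] - 10 / 11), tol)

  wt <- productionEnvelope(makePyrcore(), pyrEnv(), "EX_bdo_e",
                           n_points = 2)
  expect_lt(abs(as.data.frame(wt)$max[2]), tol)

  # self-envelope: biomass against itself collapses onto the grid
  se <- productionEnvelope(makePyrcore(), pyrEnv(), "BIOMASS",
                           n_points = 5)
  df <- as.data.frame(se)
  expect_true(all(abs(df$min - df$growth) < 1e-5))
  expect_true(all(abs(df$max - df$growth) < 1e-5))
})

test_that("knockouts follow GPR semantics and never mutate the input", {
  m <- makePyrcore()
  # one isozyme down: reaction survives, growth unchanged
  k1 <- applyKnockouts(m, genes = "ADH1")
  expect_length(attr(k1, "knockedOut"), 0L)
  expect_lt(abs(objectiveValue(solveFBA(k1, pyrEnv())) - 11), tol)
  # all isozymes down: reaction off
  k3 <- applyKnockouts(m, genes = c("ADH1", "ADH3", "ADH5"))
  expect_identical(attr(k3, "knockedOut"), "ADH")
  expect_lt(abs(objectiveValue(solveFBA(k3, pyrEnv())) - 117 / 11), tol)
  # reaction-level double knockout
  k2 <- applyKnockouts(m, reactions = c("ADH", "RESP"))
  expect_setequal(attr(k2, "knockedOut"), c("ADH", "RESP"))
  expect_lt(abs(objectiveValue(solveFBA(k2, pyrEnv())) - 7), tol)
  expect_lt(abs(objectiveValue(
    fixAndOptimize(k2, pyrEnv(), "BIOMASS", "EX_bdo_e")) - 2), tol)
  # original untouched; unknown ids error before any mutation
  expect_lt(abs(objectiveValue(solveFBA(m, pyrEnv())) - 11), tol)
  expect_error(applyKnockouts(m, reactions = "NOPE"), "unknown reaction")
  expect_error(applyKnockouts(m, genes = "NOPE"), "unknown gene")
})

test_that("mass yield conversion matches the published strain-A figure", {
  # invert the 0.313 g/g yield at 10 mmol/gDCW/h glucose uptake
  v_t <- 0.313 * 10 * molarMasses[["glucose"]] / molarMasses[["butanediol"]]
  expect_lt(abs(v_t - 6.256), 5e-3)
  y <- fluxToMassYield(v_t, -10, molarMasses[["butanediol"]],
                       molarMasses[["glucose"]])
  expect_lt(abs(y$yield - 0.313), 5e-4)

  expect_identical(fluxToMassYield(0, -10, 90, 180)$yield, 0)
  expect_identical(fluxToMassYield(10, -10, 90, 90)$yield, 1)
  expect_error(fluxToMassYield(1, 0, 90, 180), "zero")

  # round trip Y -> v_t -> Y at full precision
  set.seed(3)
  for (i in 1:10) {
    Y <- runif(1); vs <- -runif(1, 1, 20)
    vt <- Y * abs(vs) * molarMasses[["glucose"]] /
      molarMasses[["butanediol"]]
    back <- fluxToMassYield(vt, vs, molarMasses[["butanediol"]],
                            molarMasses[["glucose"]])$yield
    expect_lt(abs(back - Y), 1e-12 * max(1, Y))
  }
})

test_that("environment constraints only land on legal reactions", {
  m <- makePyrcore()
  expect_error(applyEnvironment(m,
    environmentSpec(uptakes = c(GLY1 = -5))), "non-exchange")
  expect_error(applyEnvironment(m,
    environmentSpec(maintenance = c(GLY1 = 1))), "non-maintenance")
  expect_error(environmentSpec(uptakes = c(EX_glc_e = 5)), "uptake")
  expect_error(environmentSpec(maintenance = c(ATPM = -1)),
               "maintenance")
})
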