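# Serialization round trips (native JSON and both SBML dialects) and
# reaction classification.

test_that("JSON round trip preserves every field", {
  m <- makePyrcore()
  p <- withr::local_tempfile(fileext = ".json")
  writeModelJSON(m, p)
  m2 <- readModelJSON(p)
  expect_identical(m@metabolites, m2@metabolites)
  expect_identical(m@reactions, m2@reactions)
  expect_true(all(m@stoichiometry == m2@stoichiometry))
  expect_identical(m@genes, m2@genes)
  expect_identical(m@objective, m2@objective)
})

test_that("JSON round trip holds for seeded random models", {
  for (seed in 1:10) {
    m <- makeRandomModel(randomModelSpec(seed = seed,
                                         n_branches = 1 + seed %% 3))
    p <- withr::local_tempfile(fileext = ".json")
    writeModelJSON(m, p)
    m2 <- readModelJSON(p)
    expect_identical(m@reactions, m2@reactions)
    expect_true(all(m@stoichiometry == m2@stoichiometry))
  }
})

test_that("JSON schema violations are rejected with a pointer", {
  m <- makePyrcore()
  p <- withr::local_tempfile(fileext = ".json")
  writeModelJSON(m, p)
  doc <- jsonlite::read_json(p)
  doc$reactions <- NULL
  p2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, p2, auto_unbox = TRUE)
  expect_error(readModelJSON(p2), "/reactions")
  doc2 <- jsonlite::read_json(p)
  doc2$schema <- "something-else"
  jsonlite::write_json(doc2, p2, auto_unbox = TRUE)
  expect_error(readModelJSON(p2), "/schema")
})

test_that("SBML L3+fbc round trip preserves the model semantically", {
  for (m in list(makePyrcore(),
                 makeRandomModel(randomModelSpec(seed = 4)))) {
    p <- withr::local_tempfile(fileext = ".xml")
    writeSBML(m, p, dialect = "fbc")
    m2 <- suppressMessages(readSBML(p))
    expect_identical(reactionIds(m), reactionIds(m2))
    expect_identical(metaboliteIds(m), metaboliteIds(m2))
    expect_identical(geneIds(m), geneIds(m2))
    expect_identical(reactionKinds(m), reactionKinds(m2))
    expect_identical(objectiveId(m), objectiveId(m2))
    expect_equal(lowerBounds(m), lowerBounds(m2))
    expect_equal(upperBounds(m), upperBounds(m2))
    expect_true(all(m@stoichiometry ==
      m2@stoichiometry[metaboliteIds(m), reactionIds(m)]))
    for (r in reactionIds(m))   # GPRs equal as boolean functions
      expect_identical(gprToDNF(gprOf(m, r)), gprToDNF(gprOf(m2, r)))
  }
})

test_that("legacy COBRA-notes dialect round trips", {
  m <- makePyrcore()
  p <- withr::local_tempfile(fileext = ".xml")
  writeSBML(m, p, dialect = "cobra")
  m2 <- suppressMessages(readSBML(p))
  expect_identical(reactionIds(m), reactionIds(m2))
  expect_identical(reactionKinds(m), reactionKinds(m2))
  expect_identical(objectiveId(m2), "BIOMASS")
  expect_equal(lowerBounds(m), lowerBounds(m2))
  expect_identical(gprRules(m2)[["ADH"]], "ADH1 or ADH3 or ADH5")
  # and the re-read model solves to the same optimum
  expect_lt(abs(objectiveValue(solveFBA(m2, pyrEnv())) - 11), 1e-6)
})

test_that("defective SBML is rejected with a useful message", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model><unclosed></model></sbml>", p)
  expect_error(suppressMessages(readSBML(p)))

  # strip the bound attributes from one reaction: rejected by id
  m <- makePyrcore()
  p2 <- withr::local_tempfile(fileext = ".xml")
  writeSBML(m, p2, dialect = "fbc")
  full <- readLines(p2)
  hit <- grepl('reaction id="GLY2"', full)
  full[hit] <- gsub('fbc:(lower|upper)FluxBound="[^"]*" ?', "", full[hit])
  writeLines(full, p2)
  expect_error(suppressMessages(readSBML(p2)), "GLY2")
})

test_that("reaction classification partitions the fixture", {
  m <- makePyrcore()
  kinds <- vapply(reactionIds(m), function(r) classifyReaction(m, r),
                  character(1))
  expect_identical(unname(kinds[c("EX_glc_e", "GLCt", "ADH")]),
                   c("exchange", "transport", "internal"))
  expect_identical(unname(kinds[c("ATPM", "BIOMASS")]),
                   c("maintenance", "biomass"))
  # every reaction gets exactly one kind, and the table is as built
  expect_true(all(kinds %in% c("exchange", "transport", "internal",
                               "biomass", "maintenance")))
  tab <- table(kinds)
  expect_identical(as.integer(tab[c("exchange", "transport", "internal",
                                    "maintenance", "biomass")]),
                   c(7L, 6L, 8L, 1L, 1L))
  expect_error(classifyReaction(m, "NOPE"), "unknown reaction")
})

test_that("stored kinds equal structural classification on random models", {
  for (seed in c(2, 9, 21)) {
    m <- makeRandomModel(randomModelSpec(seed = seed))
    kinds <- vapply(reactionIds(m), function(r) classifyReaction(m, r),
                    character(1))
    expect_identical(kinds, reactionKinds(m))
  }
})
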