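test_that("rules parse into the expected boolean trees", {
  e <- parseGPR("(ADH1 or ADH3 or ADH5)")
  expect_s3_class(e, "gpr")
  expect_identical(e$op, "or")
  expect_length(e$args, 3L)
  expect_setequal(gprGenes(e), c("ADH1", "ADH3", "ADH5"))

  # empty rule = always on, under any deletion set
  on <- parseGPR("")
  expect_identical(on$op, "true")
  expect_true(evaluateGPR(on, character()))
  expect_true(evaluateGPR(on, c("ADH1", "ADH3", "ADH5", "X")))

  # case-insensitive connectives, nesting, precedence (and binds tighter)
  e2 <- parseGPR("A AND b Or c")
  expect_identical(e2$op, "or")
  expect_identical(e2$args[[1]]$op, "and")
})

test_that("malformed rules fail with a position", {
  expect_error(parseGPR("(A and (B or"), "position 8")
  expect_error(parseGPR("A or or B"), "unexpected")
  expect_error(parseGPR("A B"), "unexpected")
  expect_error(parseGPR("A & B"), "illegal character")
})

test_that("evaluation matches boolean semantics", {
  or3 <- parseGPR("ADH1 or ADH3 or ADH5")
  expect_true(evaluateGPR(or3, "ADH1"))
  expect_true(evaluateGPR(or3, c("ADH1", "ADH3")))
  expect_false(evaluateGPR(or3, c("ADH1", "ADH3", "ADH5")))

  # exhaustive truth table for a two-subunit complex
  and2 <- parseGPR("PDA1 and PDB1")
  for (del in list(character(), "PDA1", "PDB1", c("PDA1", "PDB1"))) {
    want <- !("PDA1" %in% del) && !("PDB1" %in% del)
    expect_identical(evaluateGPR(and2, del), want)
  }
})

test_that("parse -> deparse -> parse is idempotent on the tree", {
  set.seed(42)
  for (i in 1:25) {
    tr <- randomGprTree()
    s1 <- format(tr)
    t2 <- parseGPR(s1)
    expect_identical(format(t2), s1)
    # and semantics survive: same value under random deletions
    genes <- gprGenes(tr)
    del <- sample(genes, sample(0:length(genes), 1))
    expect_identical(evaluateGPR(tr, del), evaluateGPR(t2, del))
  }
})

test_that("DNF conjuncts are the irredundant enzyme alternatives", {
  expect_identical(gprToDNF(parseGPR("A or B")), list("A", "B"))
  expect_identical(gprToDNF(parseGPR("A and B")), list(c("A", "B")))
  expect_identical(gprToDNF(parseGPR("A or (A and B)")), list("A"))
  expect_identical(gprToDNF(parseGPR("")), list())
  dnf <- gprToDNF(parseGPR("(A or B) and (C or D)"))
  expect_setequal(lapply(dnf, paste, collapse = "+"),
                  list("A+C", "A+D", "B+C", "B+D"))
})

test_that("minimal gene knockouts match the fixture's biology", {
  m <- makePyrcore()
  adh <- minimalGeneKnockouts(m, "ADH")
  expect_length(adh, 1L)
  expect_identical(adh[[1]]$genes, c("ADH1", "ADH3", "ADH5"))
  expect_length(adh[[1]]$side_effects, 0L)

  # PDC1 also catalyses the acetoin condensation: deleting it takes
  # ACB down as a side effect
  pdc <- minimalGeneKnockouts(m, "PDC")
  expect_identical(pdc[[1]]$genes, "PDC1")
  expect_identical(pdc[[1]]$side_effects, "ACB")

  empty <- minimalGeneKnockouts(m, character())
  expect_length(empty, 1L)
  expect_length(empty[[1]]$genes, 0L)
  expect_length(empty[[1]]$side_effects, 0L)

  expect_error(minimalGeneKnockouts(m, "RESP"), "not gene-disableable")
  expect_error(minimalGeneKnockouts(m, "NOPE"), "unknown reaction")
})

test_that("minimal sets agree with exhaustive subset enumeration", {
  m <- makePyrcore()
  targets <- list("ADH", "GPD", c("ADH", "BDH"), c("GPD", "PDC"),
                  c("ADH", "GPD", "BDH"))
  for (tg in targets) {
    got <- minimalGeneKnockouts(m, tg)
    exprs <- lapply(tg, function(r) gprOf(m, r))
    want <- oracleMinimalKnockouts(exprs, geneIds(m))
    expect_setequal(lapply(got, function(x) paste(x$genes, collapse = "+")),
                    lapply(want, paste, collapse = "+"))
    # returned in deterministic order: size then lexicographic
    key <- vapply(got, function(x) paste(x$genes, collapse = ","),
                  character(1))
    expect_identical(key, key[order(lengths(lapply(got, `[[`, "genes")),
                                    key)])
  }
})

test_that("branch-and-bound hitting sets match exhaustive search", {
  # force the implicit-enumeration path with a low exhaustive limit
  m <- makePyrcore()
  got <- minimalGeneKnockouts(m, c("ADH", "GPD"), exhaustive_limit = 1L)
  exprs <- list(gprOf(m, "ADH"), gprOf(m, "GPD"))
  want <- oracleMinimalKnockouts(exprs, geneIds(m))
  # the branch path returns the minimum-cardinality sets
  wmin <- want[lengths(want) == min(lengths(want))]
  expect_setequal(lapply(got, function(x) paste(x$genes, collapse = "+")),
                  lapply(wmin, paste, collapse = "+"))
})
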