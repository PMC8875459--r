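test_that("SBML write/read round-trips toy and random models structurally", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "m.xml")

  m <- chainModel()
  writeSBML(m, p)
  expect_true(modelsEqual(m, readSBML(p)))

  # nested GPR survives the association tree
  m2 <- parallelModel()
  writeSBML(m2, p)
  back <- readSBML(p)
  expect_true(modelsEqual(m2, back))
  expect_identical(gprToString(gprRules(back)[["R_hi"]]), "gHiA or gHiB")

  # model with no genes at all
  m3 <- makeMetabolicModel("nogene",
    metabolites = data.frame(id = "A"),
    reactions = data.frame(id = c("IN", "OUT"),
                           lower_bound = c(-5, 0), upper_bound = c(5, 5)),
    stoichiometry = list(IN = c(A = 1), OUT = c(A = -1)),
    objectiveReaction = "OUT")
  writeSBML(m3, p)
  expect_true(modelsEqual(m3, readSBML(p)))

  # seeded generator output, varied shapes
  for (seed in 1:25) {
    spec <- scenarioSpec(n_pathways = 2 + seed %% 3,
                         reactions_per_pathway = 1 + seed %% 4, seed = seed)
    mt <- makeToyNetwork(spec)
    writeSBML(mt, p)
    expect_true(modelsEqual(mt, readSBML(p)), label = paste("seed", seed))
  }
})

test_that("SBML reader fails loudly on malformed input and missing objectives", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "bad.xml")
  writeLines("<sbml><model><unterminated>", p)
  expect_error(readSBML(p), "parse failure")

  # syntactically valid but objective-free
  m <- chainModel()
  writeSBML(m, p)
  doc <- xml2::read_xml(p)
  xml2::xml_remove(xml2::xml_find_all(doc, ".//*[local-name()='listOfObjectives']"))
  xml2::write_xml(doc, p)
  expect_error(readSBML(p), "no objective")

  expect_error(readSBML(file.path(tmp, "absent.xml")), "not found")
})

test_that("internal JSON dialect round-trips and validates its schema", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "m.json")
  m <- makeToyNetwork(scenarioSpec(seed = 3))
  writeModelJSON(m, p)
  expect_true(modelsEqual(m, readModelJSON(p)))

  jsonlite::write_json(list(model_id = "x"), p, auto_unbox = TRUE)
  expect_error(readModelJSON(p), "missing fields")
})

test_that("table readers enforce schemas and deduplicate targets", {
  tmp <- withr::local_tempdir()
  tp <- file.path(tmp, "targets.tsv")
  writeLines(c("drug_id\tgene_id", "d1\tg1", "d1\tg1", "d2\tg2"), tp)
  targets <- readDrugTargets(tp)
  expect_identical(nrow(targets), 2L)          # duplicate row dropped
  expect_setequal(unique(targets$drug_id), c("d1", "d2"))

  writeLines("drug_id\tgene_id", tp)           # header only
  expect_identical(nrow(readDrugTargets(tp)), 0L)

  writeLines(c("drug\tgene", "d1\tg1"), tp)    # wrong header
  expect_error(readDrugTargets(tp), "schema error")

  mp <- file.path(tmp, "medium.tsv")
  writeLines(c("metabolite_id", "glc_e", "glc_e", "o2_e"), mp)
  expect_identical(readMedium(mp), c("glc_e", "o2_e"))

  ep <- file.path(tmp, "expr.tsv")
  writeLines(c("gene_id\tDMSO\tdrugA", "g1\t2.0\t-1.0"), ep)
  ex <- readExpression(ep)
  expect_named(ex, c("gene_id", "DMSO", "drugA"))
  writeLines("gene_id", ep)
  expect_error(readExpression(ep), "no condition columns")
})
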