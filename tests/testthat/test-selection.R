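test_that("reference drugs are those above the dissimilarity floor, ranked", {
  scores <- c(drugA = 0, drugB = 0.3, drugC = 0.7)
  expect_identical(pickReferenceDrugs(scores, 1e-4), c("drugC", "drugB"))
  expect_identical(pickReferenceDrugs(c(x = 0, y = 0), 1e-4), character(0))
  expect_identical(pickReferenceDrugs(scores, 0),
                   c("drugC", "drugB"))            # zero floor: all above 0
  # ties resolve alphabetically
  expect_identical(pickReferenceDrugs(c(b = 0.5, a = 0.5), 1e-4), c("a", "b"))
})

test_that("the published worked example yields 23 flagged and 9 validated products", {
  flags <- candidateStepFlags()
  expect_identical(nrow(flags), 23L)
  config <- selectionConfig(
    min_steps = 2,
    exclude_list = c(toxicity = "Strychnine",
                     `well characterised` = "Narciclasine"),
    include_list = c(`database evidence` = "Emodin",
                     `database evidence` = "Salvianic acid A sodium",
                     `database evidence` = "Scutellarein",
                     `literature evidence` = "Bruceine D"))
  table <- aggregateCandidates(
    flags$product[flags$step1_deletion],
    flags$product[flags$step2_dissimilarity],
    flags$product[flags$step3_flux_similarity],
    flags$product[flags$step4_pathway],
    config)
  expect_identical(sum(table$n_steps >= 1), 23L)
  validated <- table$product[table$verdict %in%
                             c("selected", "included_by_evidence")]
  expect_identical(length(validated), 9L)
  expect_setequal(validated,
    c("Ferulic acid", "Glycyrrhizic acid", "Resveratrol",
      "Hydroxysafflor yellow A", "Salvianolic acid B",
      "Emodin", "Salvianic acid A sodium", "Scutellarein", "Bruceine D"))
  expect_identical(table$verdict[table$product == "Strychnine"], "excluded")
  expect_identical(table$verdict[table$product == "Narciclasine"], "excluded")
})

test_that("aggregation is order-independent, exhaustive and exclusive", {
  config <- selectionConfig(min_steps = 2)
  s1 <- c("p3", "p1"); s2 <- c("p1"); s3 <- c("p2", "p1"); s4 <- character(0)
  a <- aggregateCandidates(s1, s2, s3, s4, config)
  b <- aggregateCandidates(rev(s1), s2, rev(s3), s4, config)
  expect_identical(a, b)
  expect_true(all(a$verdict %in% c("selected", "included_by_evidence",
                                   "excluded", "rejected")))
  expect_identical(a$n_steps,
                   as.integer(a$step1_deletion + a$step2_dissimilarity +
                              a$step3_flux_similarity + a$step4_pathway))
  # all-empty steps: empty table
  empty <- aggregateCandidates(character(0), character(0), character(0),
                               character(0), config)
  expect_identical(nrow(empty), 0L)
})

test_that("a product on both include and exclude lists is a configuration error", {
  config <- selectionConfig(exclude_list = "p1", include_list = "p1")
  expect_error(aggregateCandidates("p1", character(0), character(0),
                                   character(0), config),
               "configuration error")
})
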