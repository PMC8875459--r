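test_that("gene knockout disables exactly the rule-dead reactions", {
  m <- chainModel()
  # no knockout: untouched
  none <- deleteGenes(m, character(0))
  expect_identical(none$disabled_reactions, character(0))
  expect_true(modelsEqual(m, none$model))

  # sole transporter gene: T_A closed, chain dies
  ko <- deleteGenes(m, "gT")
  expect_identical(ko$disabled_reactions, "T_A")
  b <- reactionBounds(ko$model)
  expect_identical(b$lower_bound[b$id == "T_A"], 0)
  expect_identical(b$upper_bound[b$id == "T_A"], 0)

  # one isozyme of an OR pair: nothing disabled
  mp <- parallelModel()
  expect_identical(deleteGenes(mp, "gHiA")$disabled_reactions, character(0))
  # genes unknown to the model are ignored
  expect_identical(deleteGenes(mp, "no_such_gene")$disabled_reactions,
                   character(0))
})

test_that("growth ratios classify essential, redundant and null knockouts", {
  m <- parallelModel()
  expect_equal(growthRatio(m, character(0))$grRatio, 1, tolerance = 1e-9)
  # transporter is essential: all flux passes T_A
  expect_identical(growthRatio(m, "gT")$grRatio, 0)
  # losing the low-capacity path costs 4 of 10
  expect_equal(growthRatio(m, "gLo")$grRatio, 0.6, tolerance = 1e-6)
  # one isozyme of the high path is redundant
  expect_equal(growthRatio(m, "gHiA")$grRatio, 1, tolerance = 1e-9)
  # a non-growing reference is an error, not a ratio
  dead <- applyMedium(m, character(0))
  expect_error(growthRatio(dead, "gT"), "non-growing reference")
})

test_that("single-gene screen equals per-gene growthRatio and finds planted essentials", {
  for (seed in 1:20) {
    m <- makeToyNetwork(scenarioSpec(seed = seed))
    screen <- singleGeneDeletion(m)
    expect_identical(screen$label, geneIds(m))
    for (g in sample(geneIds(m), 4)) {
      expect_equal(screen$grRatio[screen$label == g],
                   growthRatio(m, g)$grRatio, tolerance = 1e-9,
                   label = sprintf("seed %d gene %s", seed, g))
    }
  }
  # the backbone single-gene steps are the only essential genes: AND
  # complexes also die, OR pairs survive
  m <- makeToyNetwork(scenarioSpec(seed = 1))
  screen <- singleGeneDeletion(m)
  essential <- screen$label[screen$grRatio == 0]
  # backbone pathway_1: single genes at positions 1 and 4, AND pair at 2
  expect_setequal(essential,
                  c("g_p1_r1", "g_p1_r4", "g_p1_r2_a", "g_p1_r2_b"))
  # a model with no GPR rules knocks out nothing
  nogpr <- makeMetabolicModel("plain",
    metabolites = data.frame(id = "A"),
    reactions = data.frame(id = c("IN", "OUT"),
                           lower_bound = c(-5, 0), upper_bound = c(5, 5)),
    stoichiometry = list(IN = c(A = 1), OUT = c(A = -1)),
    objectiveReaction = "OUT")
  expect_identical(nrow(singleGeneDeletion(nogpr)), 0L)
})

test_that("knockout growth is monotone: larger knocked sets never grow faster", {
  draws <- 0L
  for (seed in 1:20) {
    m <- makeToyNetwork(scenarioSpec(seed = seed))
    wt <- optimizeModel(m)$objective_value
    genes <- geneIds(m)
    for (k in 1:10) {
      set.seed(seed * 100 + k)
      g1 <- sample(genes, sample(1:3, 1))
      g2 <- sample(genes, sample(1:3, 1))
      r1 <- growthRatio(m, g1, wt = wt)$grRatio
      r2 <- growthRatio(m, g2, wt = wt)$grRatio
      r12 <- growthRatio(m, union(g1, g2), wt = wt)$grRatio
      expect_lte(r12, min(r1, r2) + 1e-6)
      draws <- draws + 1L
    }
  }
  expect_identical(draws, 200L)
})

test_that("combination screen detects isozyme synergy and respects idempotence", {
  m <- parallelModel()
  targets <- data.frame(
    drug_id = c("dHiA", "dHiB", "dLo", "dSame", "dNone"),
    gene_id = c("gHiA", "gHiB", "gLo", "gLo", "ghost"),
    drug_class = "natural_product", stringsAsFactors = FALSE)

  # A = B: union adds nothing, no synergy
  same <- combinationDeletion(m, data.frame(label_a = "dLo", label_b = "dSame"),
                              targets)
  expect_equal(same$grRatio_AB, same$grRatio_A, tolerance = 1e-9)
  expect_false(same$synergy)

  # two redundant isozymes: individually harmless, jointly the high path dies
  iso <- combinationDeletion(m, data.frame(label_a = "dHiA", label_b = "dHiB"),
                             targets)
  expect_equal(iso$grRatio_A, 1, tolerance = 1e-9)
  expect_equal(iso$grRatio_B, 1, tolerance = 1e-9)
  expect_equal(iso$grRatio_AB, 0.4, tolerance = 1e-6)  # only R_lo's 4 remain
  expect_true(iso$synergy)

  # disjoint irrelevant genes: all ratios 1
  no <- combinationDeletion(m, data.frame(label_a = "dHiA", label_b = "dNone"),
                            targets)
  expect_equal(unlist(no[, c("grRatio_A", "grRatio_B", "grRatio_AB")]),
               c(grRatio_A = 1, grRatio_B = 1, grRatio_AB = 1),
               tolerance = 1e-9)
  expect_false(no$synergy)
})

test_that("drug deletion screen flags planted essential products only", {
  spec <- scenarioSpec(seed = 7)
  m <- makeToyNetwork(spec)
  dat <- makeConditionData(m, spec)
  np <- dat$targets[dat$targets$drug_class == "natural_product", ]
  screen <- drugDeletion(m, np)
  expect_setequal(screen$label[screen$grRatio == 0],
                  spec$planted_essential_products)
  expect_true(all(screen$grRatio >= 0 & screen$grRatio <= 1 + 1e-6))
})
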