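miniRefModel <- function() {
  # two labeled subsystems (4 + 3 reactions) plus an unlabeled one
  rid <- c(sprintf("a%d", 1:4), sprintf("b%d", 1:3), "x1")
  makeMetabolicModel("ref",
    metabolites = data.frame(id = c("M", "N")),
    reactions = data.frame(id = rid,
                           subsystem = c(rep("alpha", 4), rep("beta", 3), ""),
                           lower_bound = -5, upper_bound = 5),
    stoichiometry = stats::setNames(
      rep(list(c(M = -1, N = 1)), 8), rid),
    gpr = c(a1 = "g1", a2 = "g1 or g2", b1 = "g3", x1 = "g4"),
    objectiveReaction = "a1")
}

test_that("pathway index maps subsystems and gene control correctly", {
  idx <- buildPathwayIndex(miniRefModel())
  expect_setequal(names(idx$pathways), c("alpha", "beta", "UNASSIGNED"))
  expect_setequal(idx$pathways$alpha, sprintf("a%d", 1:4))
  expect_setequal(idx$pathways$beta, sprintf("b%d", 1:3))
  expect_identical(idx$pathways$UNASSIGNED, "x1")
  # gene->reaction equals a GPR-leaf scan
  expect_setequal(idx$gene_reactions$g1, c("a1", "a2"))
  expect_identical(idx$gene_reactions$g3, "b1")

  # label-free model collapses into one UNASSIGNED group
  m <- makeMetabolicModel("nolabel",
    metabolites = data.frame(id = "A"),
    reactions = data.frame(id = c("r1", "r2"),
                           lower_bound = c(-5, 0), upper_bound = 5),
    stoichiometry = list(r1 = c(A = 1), r2 = c(A = -1)),
    objectiveReaction = "r2")
  expect_identical(names(buildPathwayIndex(m)$pathways), "UNASSIGNED")
})

test_that("drug counting requires a gene-controlled reaction in the pathway", {
  idx <- buildPathwayIndex(miniRefModel())
  targets <- data.frame(
    drug_id = c("d1", "d1", "d2", "d3"),
    gene_id = c("g1", "g3", "g2", "ghost"),   # d3 targets nothing in-model
    drug_class = c("natural_product", "natural_product",
                   "cancer_drug", "natural_product"),
    stringsAsFactors = FALSE)
  counts <- countPathwayTargets(idx, targets)
  get <- function(pw, cl) counts[[cl]][counts$pathway == pw]
  expect_identical(get("alpha", "natural_product"), 1L)  # d1 via g1
  expect_identical(get("beta", "natural_product"), 1L)   # d1 via g3
  expect_identical(get("alpha", "cancer_drug"), 1L)      # d2 via g2
  expect_identical(get("beta", "cancer_drug"), 0L)
  expect_identical(sum(counts$natural_product[counts$pathway == "UNASSIGNED"]), 0L)
  # gene-controlled reaction counts per pathway
  expect_identical(counts$n_gene_controlled_reactions[counts$pathway == "alpha"], 2L)
})

test_that("presence rates are simple shares of the reference pathway", {
  idx <- buildPathwayIndex(miniRefModel())
  expect_equal(presenceRates(sprintf("a%d", 1:4), idx)[["alpha"]], 1.0)
  expect_equal(presenceRates(character(0), idx)[["alpha"]], 0.0)
  expect_equal(presenceRates(c("a1", "a3"), idx)[["alpha"]], 0.5)
  expect_equal(presenceRates(c("a1", "b2"), idx)[["beta"]], 1 / 3)
})

test_that("alteration report excludes small pathways and ranks planted shutdowns first", {
  idx <- buildPathwayIndex(miniRefModel())
  all_r <- sprintf("a%d", 1:4)

  # treatment == control: all differences zero, nothing displayed
  rep0 <- alterationReport(list(t1 = c(all_r, "b1", "b2", "b3")),
                           c(all_r, "b1", "b2", "b3"), idx)
  expect_true(all(rep0$difference == 0))
  expect_false(any(rep0$display))
  # beta (3 reactions) and UNASSIGNED (1) fall under the size cutoff
  expect_identical(unique(rep0$pathway), "alpha")

  # planted shutdown of a 10-reaction pathway tops the ranking
  rid <- c(sprintf("p%d", 1:10), sprintf("q%d", 1:10))
  big <- makeMetabolicModel("big",
    metabolites = data.frame(id = "A"),
    reactions = data.frame(id = rid,
                           subsystem = rep(c("pw_hit", "pw_other"), each = 10),
                           lower_bound = -5, upper_bound = 5),
    stoichiometry = stats::setNames(rep(list(c(A = 1)), 20), rid),
    objectiveReaction = "p1")
  bidx <- buildPathwayIndex(big)
  control <- rid
  hit <- c(sprintf("p%d", 1:1), sprintf("q%d", 1:10))  # 9 of 10 pw_hit lost
  other <- rid                                          # unaffected treatment
  rep1 <- alterationReport(list(trA = hit, trB = other), control, bidx)
  hit_rows <- rep1[rep1$pathway == "pw_hit", ]
  expect_equal(hit_rows$difference[hit_rows$treatment == "trA"], -0.9)
  expect_true(all(rep1$iqr_rank[rep1$pathway == "pw_hit"] == 1))
  expect_true(hit_rows$display[hit_rows$treatment == "trA"])
  expect_false(any(rep1$display[rep1$pathway == "pw_other"]))
})
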