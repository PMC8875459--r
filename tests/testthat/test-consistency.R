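test_that("consistency finder equals the per-reaction LP oracle", {
  # fully connected chain: everything consistent
  m <- chainModel()
  expect_setequal(fastcc(m), reactionIds(m))

  # dead-end metabolite: its producing reaction is blocked
  m2 <- makeMetabolicModel("deadend",
    metabolites = data.frame(id = c("A", "Z")),
    reactions = data.frame(id = c("IN", "OUT", "DEAD"),
                           lower_bound = c(-5, 0, 0),
                           upper_bound = c(5, 5, 5)),
    stoichiometry = list(IN = c(A = 1), OUT = c(A = -1), DEAD = c(Z = 1)),
    objectiveReaction = "OUT")
  expect_setequal(fastcc(m2), c("IN", "OUT"))
  expect_setequal(consistentReactionsOracle(m2), c("IN", "OUT"))

  # 50 random networks, including reversible reactions; zero flux is kept
  # feasible so the consistency question is well posed
  for (seed in 1:50) {
    m3 <- randomNetwork(seed, contain_zero = TRUE)
    expect_setequal(fastcc(m3), consistentReactionsOracle(m3))
  }
})

test_that("consistency is idempotent on the induced sub-model", {
  checked <- 0L
  for (seed in 1:40) {
    m <- randomNetwork(seed, contain_zero = TRUE)
    cons <- fastcc(m)
    if (!objectiveReaction(m) %in% cons) next
    sub <- subsetReactions(m, cons)
    expect_setequal(fastcc(sub), cons)
    checked <- checked + 1L
    if (checked >= 5L) break
  }
  expect_gte(checked, 1L)
})

test_that("activity calls split genes by the two thresholds", {
  ex <- data.frame(gene_id = c("g1", "g2", "g3"),
                   condA = c(2.0, -1.0, 0.3),
                   allna = c(NA_real_, NA, NA))
  calls <- callActivity(ex, "condA", 1, 0)
  expect_identical(calls$core_genes, "g1")
  expect_identical(calls$inactive_genes, "g2")
  expect_identical(calls$unknown_genes, "g3")

  # equal thresholds leave no unknowns
  calls2 <- callActivity(ex, "condA", 0.5, 0.5)
  expect_length(calls2$unknown_genes, 0)
  expect_setequal(c(calls2$core_genes, calls2$inactive_genes),
                  c("g1", "g2", "g3"))

  expect_error(callActivity(ex, "nope", 1, 0), "absent")
  expect_error(callActivity(ex, "allna", 1, 0), "no usable scores")
  expect_error(callActivity(ex, "condA", 0, 1))   # inverted thresholds
})

test_that("core mapping uses three-valued GPR semantics", {
  m <- makeMetabolicModel("tri",
    metabolites = data.frame(id = c("A", "B", "C", "D")),
    reactions = data.frame(id = c("IN", "R_or", "R_and", "R_unk", "OUT"),
                           lower_bound = c(-5, 0, 0, 0, 0),
                           upper_bound = c(5, 5, 5, 5, 5)),
    stoichiometry = list(IN = c(A = 1), R_or = c(A = -1, B = 1),
                         R_and = c(B = -1, C = 1), R_unk = c(C = -1, D = 1),
                         OUT = c(D = -1)),
    gpr = c(R_or = "g1 or g2", R_and = "g1 and g2", R_unk = "g1 and g3"),
    objectiveReaction = "OUT")
  calls <- list(condition_id = "x", core_genes = "g1",
                inactive_genes = "g2", unknown_genes = "g3")
  mapped <- genesToCoreReactions(m, calls)
  expect_identical(mapped$core, "R_or")              # isozyme: g1 suffices
  expect_true("R_and" %in% mapped$inactive)          # complex needs dead g2
  expect_true("R_unk" %in% mapped$unpenalized)       # undecided via g3
  expect_true(all(c("IN", "OUT") %in% mapped$unpenalized))  # no rule
})
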