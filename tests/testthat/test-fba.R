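test_that("FVA reproduces hand-computed ranges on the fixtures", {
  # chain at full optimum: every carrying reaction is pinned at 10
  fva <- fluxVariability(chainModel(), 1.0)
  expect_equal(fva$vmin[fva$id == "R1"], 10, tolerance = 1e-6)
  expect_equal(fva$vmax[fva$id == "R1"], 10, tolerance = 1e-6)
  expect_equal(fva$vmin[fva$id == "EX_A"], -10, tolerance = 1e-6)
  expect_equal(fva$vmax[fva$id == "EX_A"], -10, tolerance = 1e-6)

  # parallel fixture, unconstrained objective: low-capacity path spans [0, 4]
  fva0 <- fluxVariability(parallelModel(), 0.0)
  expect_equal(fva0$vmin[fva0$id == "R_lo"], 0, tolerance = 1e-6)
  expect_equal(fva0$vmax[fva0$id == "R_lo"], 4, tolerance = 1e-6)

  # structurally blocked reaction: [0, 0] at any fraction
  m <- makeMetabolicModel("blocked",
    metabolites = data.frame(id = c("A", "Z")),
    reactions = data.frame(id = c("IN", "OUT", "DEAD"),
                           lower_bound = c(-5, 0, 0),
                           upper_bound = c(5, 5, 5)),
    stoichiometry = list(IN = c(A = 1), OUT = c(A = -1), DEAD = c(Z = 1)),
    objectiveReaction = "OUT")
  for (f in c(0, 0.5, 1)) {
    fv <- fluxVariability(m, f)
    expect_equal(fv$vmin[fv$id == "DEAD"], 0, tolerance = 1e-9)
    expect_equal(fv$vmax[fv$id == "DEAD"], 0, tolerance = 1e-9)
  }
})

test_that("FBA optimum and FVA ranges match the enumeration oracle on random networks", {
  checked <- 0L
  for (seed in 1:50) {
    m <- randomNetwork(seed)
    S <- as.matrix(stoichiometricMatrix(m))
    b <- rep(0, nrow(S))
    lb <- reactionBounds(m)$lower_bound
    ub <- reactionBounds(m)$upper_bound
    obj <- as.numeric(reactionIds(m) == objectiveReaction(m))
    want <- enumerateLP(obj, S, b, lb, ub)
    got <- optimizeModel(m)
    if (is.na(want$objective)) {
      expect_identical(got$status, "infeasible", label = paste("seed", seed))
      next
    }
    expect_equal(got$objective_value, want$objective, tolerance = 1e-6,
                 label = paste("seed", seed))

    # FVA at fraction 0.9 of optimum vs per-reaction enumeration
    fva <- fluxVariability(m, 0.9)
    lb2 <- lb
    iobj <- which(obj == 1)
    floor_obj <- if (want$objective >= 0) 0.9 * want$objective
                 else want$objective
    lb2[iobj] <- max(lb2[iobj], floor_obj)
    if (lb2[iobj] > ub[iobj]) lb2[iobj] <- ub[iobj]
    for (i in seq_along(lb)) {
      ei <- numeric(length(lb)); ei[i] <- 1
      lo <- enumerateLP(ei, S, b, lb2, ub, maximize = FALSE)
      hi <- enumerateLP(ei, S, b, lb2, ub, maximize = TRUE)
      expect_equal(fva$vmin[i], lo$objective, tolerance = 1e-6,
                   label = sprintf("seed %d vmin %s", seed, reactionIds(m)[i]))
      expect_equal(fva$vmax[i], hi$objective, tolerance = 1e-6,
                   label = sprintf("seed %d vmax %s", seed, reactionIds(m)[i]))
    }
    checked <- checked + 1L
  }
  expect_gte(checked, 15L)  # enough feasible draws for real coverage
})

test_that("FVA containment: optimal FBA fluxes lie within the FVA ranges", {
  for (seed in 1:5) {
    m <- makeToyNetwork(scenarioSpec(seed = seed))
    sol <- optimizeModel(m)
    fva <- fluxVariability(m, 1.0)
    v <- sol$flux_vector[fva$id]
    expect_true(all(v >= fva$vmin - 1e-6 & v <= fva$vmax + 1e-6),
                label = paste("seed", seed))
    expect_true(all(fva$vmin <= fva$vmax + 1e-9))
  }
})
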