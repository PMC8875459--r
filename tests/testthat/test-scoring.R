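test_that("content dissimilarity matches hand counts and closed forms", {
  expect_equal(jaccardDissimilarity(c("r1", "r2"), c("r1", "r2"))$dissimilarity, 0)
  expect_equal(jaccardDissimilarity(c("r1"), c("r2"))$dissimilarity, 1)
  d <- jaccardDissimilarity(c("r1", "r2", "r3"), c("r2", "r3", "r4"))
  expect_equal(d$jaccard, 0.5)             # 2 shared of 4 total
  expect_equal(d$dissimilarity, 0.5)
  expect_error(jaccardDissimilarity(character(0), character(0)), "empty")
  # symmetry
  expect_equal(jaccardDissimilarity(c("a", "b"), c("b", "c"))$jaccard,
               jaccardDissimilarity(c("b", "c"), c("a", "b"))$jaccard)
})

test_that("range overlap matches hand arithmetic", {
  eps <- 1e-4
  expect_equal(rangeOverlap(c(0, 10), c(0, 10), eps), 1.0)
  expect_equal(rangeOverlap(c(0, 1), c(2, 3), eps), 0.0)
  expect_equal(rangeOverlap(c(0, 4), c(2, 6), eps), (2 + eps) / (6 + eps))
  # two zero-width (absent) ranges are identical: eps/eps
  expect_equal(rangeOverlap(c(0, 0), c(0, 0), eps), 1.0)
  # symmetry
  expect_equal(rangeOverlap(c(0, 4), c(2, 6), eps),
               rangeOverlap(c(2, 6), c(0, 4), eps))
  # monotone: sliding the second range away never increases the score
  prev <- Inf
  for (shift in seq(0, 6, by = 0.5)) {
    s <- rangeOverlap(c(0, 4), c(0 + shift, 4 + shift), eps)
    expect_lte(s, prev + 1e-12)
    prev <- s
  }
  # eps-limit: identical nonzero-width ranges score 1 for any eps
  for (e in c(1e-2, 1e-4, 1e-8)) {
    expect_equal(rangeOverlap(c(-3, 5), c(-3, 5), e), 1.0)
  }
})

test_that("flux dissimilarity handles union semantics with zero-bound absences", {
  eps <- 1e-4
  fa <- data.frame(id = c("r1", "r2"), vmin = c(0, -1), vmax = c(1, 1))
  expect_equal(fluxDissimilarity(fa, fa, eps)$dissimilarity, 0)

  # disjoint tables: both reactions compare against [0, 0]
  a <- data.frame(id = "r1", vmin = 0, vmax = 1)
  b <- data.frame(id = "r2", vmin = 0, vmax = 1)
  got <- fluxDissimilarity(a, b, eps)
  expect_identical(got$n_reactions, 2L)
  term <- eps / (1 + eps)     # [0,1] vs [0,0]
  expect_equal(got$si, term, tolerance = 1e-12)
  expect_equal(got$dissimilarity, 1 - term, tolerance = 1e-12)

  expect_error(fluxDissimilarity(a[0, ], b[0, ], eps), "empty")
})

test_that("flux dissimilarity equals a straight-line reimplementation on random tables", {
  # independent oracle: naive loop over the union, no vectorisation shared
  # with the implementation
  naive <- function(fa, fb, eps) {
    ids <- union(fa$id, fb$id)
    total <- 0
    for (id in ids) {
      r1 <- if (id %in% fa$id) c(fa$vmin[fa$id == id], fa$vmax[fa$id == id])
            else c(0, 0)
      r2 <- if (id %in% fb$id) c(fb$vmin[fb$id == id], fb$vmax[fb$id == id])
            else c(0, 0)
      num <- max(0, min(r1[2], r2[2]) - max(r1[1], r2[1]) + eps)
      den <- max(r1[2], r2[2]) - min(r1[1], r2[1]) + eps
      total <- total + num / den
    }
    1 - total / length(ids)
  }
  set.seed(99)
  for (k in 1:500) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    ida <- sample(sprintf("r%d", 1:8), na)
    idb <- sample(sprintf("r%d", 1:8), nb)
    lo_a <- round(runif(na, -5, 5), 2); lo_b <- round(runif(nb, -5, 5), 2)
    fa <- data.frame(id = ida, vmin = lo_a, vmax = lo_a + round(runif(na, 0, 5), 2))
    fb <- data.frame(id = idb, vmin = lo_b, vmax = lo_b + round(runif(nb, 0, 5), 2))
    eps <- sample(c(1e-4, 1e-2), 1)
    expect_equal(fluxDissimilarity(fa, fb, eps)$dissimilarity,
                 naive(fa, fb, eps), tolerance = 1e-12,
                 label = paste("pair", k))
    # symmetry
    expect_equal(fluxDissimilarity(fa, fb, eps)$si,
                 fluxDissimilarity(fb, fa, eps)$si, tolerance = 1e-12)
  }
})

test_that("product ranking is stable with alphabetical tie-break", {
  s <- c(b = 0.5, a = 0.5, c = 0.9)
  expect_identical(rankProducts(s, 2), c("c", "a"))
  expect_identical(rankProducts(s, 5), c("c", "a", "b"))   # k > n: all
  shuffled <- s[c(3, 1, 2)]
  expect_identical(rankProducts(shuffled, 3), rankProducts(s, 3))
})
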