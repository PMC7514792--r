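test_that("symmetrical uncertainty matches hand-computed values", {
  x <- c(1, 1, 2, 2, 1, 2)
  expect_equal(symmetricalUncertainty(x, x), 1)
  expect_equal(symmetricalUncertainty(rep(1, 6), x), 0)
  expect_error(symmetricalUncertainty(1:4, 1:5), "length")

  # joint counts [[2,1],[1,2]] over n = 6, plugged in directly
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 1, 2, 2)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hx <- ent(c(3, 3) / 6); hy <- ent(c(3, 3) / 6)
  hxy <- ent(c(2, 1, 1, 2) / 6)
  expect_equal(symmetricalUncertainty(a, b),
               2 * (hx - (hxy - hy)) / (hx + hy), tolerance = 1e-12)
})

test_that("symmetrical uncertainty is symmetric", {
  withr::with_seed(51, {
    for (rep in 1:5) {
      x <- sample(1:4, 60, TRUE)
      y <- sample(1:3, 60, TRUE)
      expect_equal(symmetricalUncertainty(x, y),
                   symmetricalUncertainty(y, x), tolerance = 1e-12)
    }
  })
})

test_that("equal-frequency discretization balances occupancy", {
  x <- matrix(rep(1:10, 10), 100, 1)
  expect_identical(sort(unique(discretizeFeatures(x)[, 1])), 1:10)
  cst <- matrix(5, 20, 1)
  expect_identical(unique(discretizeFeatures(cst)[, 1]), 1L)
  r <- withr::with_seed(52, matrix(rnorm(100), 100, 1))
  occ <- table(discretizeFeatures(r)[, 1])
  expect_lte(diff(range(occ)), 1)
})

test_that("FCBF removes duplicates and keeps label-identical features", {
  withr::with_seed(53, {
    n <- 200
    y <- rbinom(n, 1, 0.5)
    X <- cbind(a = rnorm(n) + y, b = 0, c = rnorm(n))
    X[, "b"] <- X[, "a"]  # exact duplicate
    sel <- fcbf(X, y)
    expect_identical(sum(sel %in% c("a", "b")), 1L)

    X2 <- cbind(lab = y * 1.0, x1 = rnorm(n) + 0.5 * y, x2 = rnorm(n))
    sel2 <- fcbf(X2, y)
    expect_identical(sel2[1], "lab")
  })
  expect_error(fcbf(matrix(rnorm(40), 20, 2), rep(1, 20)), "single class")
})

test_that("FCBF equals an exhaustive independent implementation", {
  withr::with_seed(54, {
    for (rep in 1:4) {
      n <- 200
      y <- rbinom(n, 1, 0.5)
      X <- matrix(rnorm(n * 5), n, 5)
      X[, 1] <- X[, 1] + y
      X[, 2] <- X[, 1] + 0.2 * rnorm(n)
      colnames(X) <- paste0("f", 1:5)
      D <- discretizeFeatures(X)
      expect_identical(as.character(fcbf(X, y)), oracleFcbf(D, y))
    }
  })
})

test_that("FCBF is invariant to sample order", {
  withr::with_seed(55, {
    n <- 150
    y <- rbinom(n, 1, 0.5)
    X <- matrix(rnorm(n * 4), n, 4)
    X[, 2] <- X[, 2] + y
    colnames(X) <- paste0("f", 1:4)
    p <- sample(n)
    expect_identical(as.character(fcbf(X, y)),
                     as.character(fcbf(X[p, ], y[p])))
  })
})

test_that("bootstrap selection is seeded, prefix-monotone and reduces to one run", {
  withr::with_seed(56, {
    n <- 120
    y <- rbinom(n, 1, 0.5)
    X <- matrix(rnorm(n * 6), n, 6)
    X[, 3] <- X[, 3] + 1.5 * y
    colnames(X) <- paste0("f", 1:6)
  })
  one <- bootstrapFcbf(X, y, B = 1, threshold = 1, seed = 9)
  idx <- retiqa:::withSeed(retiqa:::spawnSeeds(9, 1)[1],
                           sample.int(n, n, replace = TRUE))
  expect_setequal(selectedFeatures(one), as.character(fcbf(X[idx, ], y[idx])))

  s1 <- bootstrapFcbf(X, y, B = 40, threshold = 20, seed = 9)
  s2 <- bootstrapFcbf(X, y, B = 40, threshold = 20, seed = 9)
  expect_identical(selectionCounts(s1), selectionCounts(s2))
  s3 <- bootstrapFcbf(X, y, B = 80, threshold = 40, seed = 9)
  expect_true(all(selectionCounts(s3) >= selectionCounts(s1)))
})

test_that("informative features dominate noise in a planted design", {
  withr::with_seed(57, {
    n <- 400
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- as.integer(x1 + x2 + 0.5 * rnorm(n) > 0)
    X <- cbind(inf1 = x1, inf2 = x2,
               matrix(rnorm(n * 8), n, 8,
                      dimnames = list(NULL, paste0("noise", 1:8))))
  })
  sel <- bootstrapFcbf(X, y, B = 100, threshold = 50, seed = 11)
  cnt <- selectionCounts(sel)
  expect_gte(cnt["inf1"], 50)
  expect_gte(cnt["inf2"], 50)
})
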