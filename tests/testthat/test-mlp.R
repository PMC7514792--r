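test_that("SMOTE produces k synthetic points per sample on recorded segments", {
  m <- withr::with_seed(61, matrix(rnorm(148 * 4), 148, 4))
  syn <- smoteOversample(m, k = 5, seed = 2)
  expect_identical(nrow(syn), 740L)
  dr <- attr(syn, "draws")
  expect_true(all(dr$c >= 0 & dr$c <= 1))
  # replay every recorded (u, v, c) draw
  w <- m[dr$u, ] + dr$c * (m[dr$v, ] - m[dr$u, ])
  expect_lt(max(abs(w - syn)), 1e-10)
  # convexity: synthetic points stay inside the per-pair bounding segment
  lo <- pmin(m[dr$u, ], m[dr$v, ]); hi <- pmax(m[dr$u, ], m[dr$v, ])
  expect_true(all(syn >= lo - 1e-12 & syn <= hi + 1e-12))
  expect_error(smoteOversample(m[1:4, ], k = 5), "m > k")
})

test_that("SMOTE endpoints follow the interpolation formula", {
  m <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 2, 2, 3, 3), 6, 2, byrow = TRUE)
  syn <- smoteOversample(m, k = 2, seed = 5)
  dr <- attr(syn, "draws")
  # c = 0 would give u, c = 1 would give v; verify via the formula limits
  for (r in seq_len(nrow(syn))) {
    u <- m[dr$u[r], ]; v <- m[dr$v[r], ]
    expect_equal(unname(syn[r, ]), unname(u + dr$c[r] * (v - u)),
                 tolerance = 1e-12)
  }
})

test_that("the MLP separates separable blobs and responds to weight decay", {
  XY <- withr::with_seed(62, {
    X <- rbind(matrix(rnorm(100, -2, 0.5), 50, 2),
               matrix(rnorm(100, 2, 0.5), 50, 2))
    list(X = scale(X), y = rep(c(0, 1), each = 50))
  })
  fit0 <- trainMlp(XY$X, XY$y, nHidden = 4, eta = 0, seed = 3)
  acc <- mean((predictMlp(fit0, XY$X) > 0.5) == XY$y)
  expect_equal(acc, 1)

  fit9 <- trainMlp(XY$X, XY$y, nHidden = 4, eta = 0.9, seed = 3)
  sq <- function(f) sum(f$W1^2) + sum(f$w2^2)
  expect_lt(sq(fit9), sq(fit0))

  sc <- predictMlp(fit0, XY$X)
  expect_true(all(sc > 0 & sc < 1))
  expect_true(all(diff(fit0$trace) <= 1e-12))
  expect_error(trainMlp(XY$X, rep(1, 100), 4, 0), "single class")
  expect_error(trainMlp(XY$X, XY$y, 4, eta = 1), "eta")
})

test_that("training is deterministic given the seed", {
  XY <- withr::with_seed(63, {
    X <- matrix(rnorm(60 * 3), 60, 3)
    list(X = X, y = rbinom(60, 1, 0.5))
  })
  f1 <- trainMlp(XY$X, XY$y, 3, 0.1, seed = 7)
  f2 <- trainMlp(XY$X, XY$y, 3, 0.1, seed = 7)
  expect_identical(f1$W1, f2$W1)
  expect_identical(f1$trace, f2$trace)
})

test_that("grid search returns the accuracy argmax with seeded folds", {
  XY <- withr::with_seed(64, {
    X <- rbind(matrix(rnorm(160, -1.2), 80, 2),
               matrix(rnorm(160, 1.2), 80, 2))
    list(X = X, y = rep(c(0L, 1L), each = 80))
  })
  single <- gridSearchCv(XY$X, XY$y, hiddenGrid = 3, etaGrid = 0.2,
                         folds = 4, seed = 1, maxit = 120)
  expect_identical(single$nHidden, 3)
  expect_identical(single$eta, 0.2)

  g1 <- gridSearchCv(XY$X, XY$y, hiddenGrid = c(1, 4), etaGrid = c(0, 0.9),
                     folds = 4, seed = 2, maxit = 120)
  g2 <- gridSearchCv(XY$X, XY$y, hiddenGrid = c(1, 4), etaGrid = c(0, 0.9),
                     folds = 4, seed = 2, maxit = 120)
  expect_identical(g1$cvTable, g2$cvTable)
  bestAcc <- g1$cvTable$accuracy[g1$cvTable$nHidden == g1$nHidden &
                                   g1$cvTable$eta == g1$eta]
  worst <- g1$cvTable$accuracy[g1$cvTable$nHidden == 1 &
                                 g1$cvTable$eta == 0.9]
  expect_gte(bestAcc, worst)
  expect_error(gridSearchCv(XY$X[1:6, ], XY$y[1:6], 2, 0, folds = 10),
               "fewer samples than folds")
})

test_that("the ROC threshold lands at the (0,1)-closest point", {
  th <- selectThresholdRoc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(th, 0.5)  # midpoint between class extremes, distance 0
  sc <- withr::with_seed(65, runif(4000))
  la <- withr::with_seed(66, rbinom(4000, 1, 0.5))
  th2 <- selectThresholdRoc(sc, la)
  cc <- confusionCounts(sc, la, th2)
  fpr <- cc["fp"] / (cc["fp"] + cc["tn"])
  tpr <- cc["tp"] / (cc["tp"] + cc["fn"])
  expect_lt(abs(sqrt(fpr^2 + (1 - tpr)^2) - sqrt(2) / 2), 0.05)
  expect_error(selectThresholdRoc(sc, rep(1, 4000)), "single class")
})

test_that("the trained quality model round-trips and ignores column order", {
  XY <- withr::with_seed(67, {
    n <- 120
    X <- data.frame(good = rnorm(n), junk = rnorm(n), also = rnorm(n))
    y <- as.integer(X$good + 0.3 * rnorm(n) > 0)
    list(X = X, y = y)
  })
  mod <- trainQualityModel(XY$X, XY$y, c("good", "also"), nHidden = 3,
                           eta = 0.1, seed = 4, maxit = 200)
  expect_s4_class(mod, "TrainedQualityModel")
  s1 <- predict(mod, XY$X)
  s2 <- predict(mod, XY$X[, c(3, 1, 2)])
  expect_identical(s1, s2)
  expect_true(all(s1 > 0 & s1 < 1))

  path <- tempfile(fileext = ".json")
  writeQualityModel(mod, path)
  back <- readQualityModel(path)
  expect_equal(predict(back, XY$X), s1, tolerance = 1e-9)
  expect_identical(selectedFeatures(back), selectedFeatures(mod))
  expect_equal(back@threshold, mod@threshold, tolerance = 1e-12)
})
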