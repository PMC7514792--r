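test_that("FOV geometry is recovered on a clean synthetic disk", {
  img <- makeDiskImage(1000, 1000, 500, 500, 400)
  g <- estimateFovGeometry(img)
  expect_lt(abs(g["centerRow"] - 500), 5)
  expect_lt(abs(g["centerCol"] - 500), 5)
  expect_lt(abs(g["diameter"] - 800) / 800, 0.02)
})

test_that("degenerate images raise a fov-not-found error", {
  dark <- array(0, c(100, 100, 3))
  expect_error(estimateFovGeometry(dark), "fov-not-found")
  bright <- array(200, c(100, 100, 3))
  expect_error(estimateFovGeometry(bright), "fov-not-found")
})

test_that("FOV masks have disk geometry", {
  m <- buildFovMask(100, 100, 120, c(200, 200))
  expect_s4_class(m, "FovMask")
  expect_lt(abs(sum(fovInside(m)) - pi * 60^2) / (pi * 60^2), 0.01)
  expect_false(fovInside(m)[1, 1])
  expect_true(fovInside(m)[100, 100])
  expect_error(buildFovMask(100, 100, 0, c(200, 200)), "positive")
  expect_error(buildFovMask(300, 100, 50, c(200, 200)), "inside")
})

test_that("FOV extension keeps interior pixels and fills the canvas", {
  img <- makeDiskImage(120, 140, 60, 70, 40)
  mask <- buildFovMask(60, 70, 80, c(120, 140))
  prep <- extendFov(img, mask)
  px <- imagePixels(prep)
  ins <- fovInside(mask)
  for (k in 1:3)
    expect_identical(px[, , k][ins], img[, , k][ins])
  expect_true(all(is.finite(px)))
  # constant disk extends to a constant canvas
  for (k in 1:3)
    expect_equal(max(abs(px[, , k] - img[, , k][60, 70])), 0, tolerance = 1e-9)
})

test_that("a full mask leaves the image untouched in zero iterations", {
  img <- makeDiskImage(80, 80, 40, 40, 25)
  full <- buildFovMask(40, 40, 400, c(80, 80))
  prep <- extendFov(img, full)
  expect_identical(imagePixels(prep), img * 1.0)
  expect_identical(prep@extension$iterations, 0L)
})

test_that("the extended mask strictly grows each iteration until full", {
  img <- makeDiskImage(100, 100, 50, 50, 30)
  mask <- buildFovMask(50, 50, 60, c(100, 100))
  prep <- extendFov(img, mask)
  added <- prep@extension$added
  expect_true(all(added >= 1))
  expect_identical(sum(fovInside(mask)) + sum(added), 100L * 100L)
})

test_that("extension reduces contrast across the original FOV border", {
  sc <- fixtureScene()
  borderJump <- function(px, mask) {
    ins <- fovInside(mask)
    # horizontal neighbor pairs straddling the border
    a <- ins[, -ncol(ins)] != ins[, -1]
    d <- 0
    for (k in 1:3) {
      ch <- px[, , k]
      d <- max(d, max(abs(ch[, -ncol(ch)] - ch[, -1])[a]))
    }
    d
  }
  mask <- sc$prep@fov
  expect_lte(borderJump(imagePixels(sc$prep), mask),
             borderJump(sc$raw * 1.0, mask))
})

test_that("re-extending a border-free image is the identity", {
  sc <- fixtureScene()
  px <- imagePixels(sc$prep)
  d <- dim(px)
  full <- buildFovMask(d[1] / 2, d[2] / 2, 4 * max(d), d[1:2])
  again <- extendFov(pmin(pmax(px, 0), 255), full)
  expect_equal(imagePixels(again), pmin(pmax(px, 0), 255), tolerance = 0)
})
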