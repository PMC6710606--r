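test_that("apparent total LE averages component efficiencies", {
  expect_equal(leApparentArithmetic(0.4), 0.4)
  expect_equal(leApparentArithmetic(c(0.3, 0.5)), 0.4)
  expect_equal(leApparentArithmetic(c(0.2, 0.4, 0.6)), 0.4)
  expect_error(leApparentArithmetic(numeric(0)), "non-empty")

  expect_equal(leApparentWrms(c(0.4, 0.4), c(10, 17)), 0.4)
  expect_equal(leApparentWrms(c(0.3, 0.5), c(10, 10)), sqrt(0.17))
  expect_equal(leApparentWrms(0.5, 12), 0.5)
  expect_error(leApparentWrms(c(0.3, -0.2), c(1, 1)), "mixed-sign")
  expect_error(leApparentWrms(c(0.3, 0.5), c(10, -1)), "positive")
  expect_error(leApparentWrms(c(0.3, 0.5), 10), "length")
})

test_that("RMS dominates the mean for unequal values, equal weights", {
  set.seed(21)
  for (i in 1:100) {
    x <- sample(2:6, 1)
    les <- runif(x, 0.05, 0.8)
    w <- rep(1, x)
    if (max(les) - min(les) > 1e-9)
      expect_gt(leApparentWrms(les, w), leApparentArithmetic(les))
    expect_equal(leApparentWrms(rep(les[1], x), runif(x, 1, 20)), les[1])
  }
})

test_that("arithmetic LE-delta is the subtractive average with its validity limits", {
  expect_equal(leDeltaArithmetic(0.4, 3, known = 0.2), 0.5)
  expect_equal(leDeltaArithmetic(0.37, 4), 0.37)          # nothing known yet
  expect_equal(leDeltaArithmetic(0.4, 2, known = 0.3), 0.5)
  # round trip through the forward average
  expect_equal(leApparentArithmetic(c(0.3, 0.5)), 0.4)
  expect_error(leDeltaArithmetic(0.4, 2, known = c(0.3, 0.5)), "invalid slate")
  expect_error(leDeltaArithmetic(0.4, 0), "x")
})

test_that("LE-delta is strictly decreasing in each known fragment's LE", {
  set.seed(31)
  for (i in 1:60) {
    x <- sample(3:6, 1)
    a <- sample.int(x - 1, 1)
    known <- runif(a, 0.05, 0.7)
    target <- runif(1, 0.2, 0.6)
    base <- leDeltaArithmetic(target, x, known)
    j <- sample.int(a, 1)
    bumped <- known
    bumped[j] <- bumped[j] + 0.05
    expect_lt(leDeltaArithmetic(target, x, bumped), base)
  }
})

test_that("WRMS LE-delta inverts the weighted average and signals infeasibility", {
  expect_equal(leDeltaWrms(sqrt(0.17), 2, known = 0.3, knownWeights = 10,
                           wDelta = 10), 0.5)
  # fixed-point: the returned value reproduces the target when inserted
  v <- leDeltaWrms(0.45, 3, known = 0.4, knownWeights = 12, wDelta = 8)
  expect_equal(leApparentWrms(c(0.4, v, v), c(12, 8, 8)), 0.45,
               tolerance = 1e-10)
  # known fragments already exceed what the target allows: no real answer
  expect_true(is.na(leDeltaWrms(0.2, 2, known = 0.9, knownWeights = 10,
                                wDelta = 10)))
  expect_error(leDeltaWrms(0.4, 2, known = 0.3, knownWeights = c(1, 2),
                           wDelta = 5), "length")
  expect_error(leDeltaWrms(0.4, 2, known = 0.3, knownWeights = 10,
                           wDelta = 0), "wDelta")
})

test_that("revealing one unknown keeps the round trip consistent, ending at LE_u", {
  set.seed(41)
  for (i in 1:60) {
    x <- sample(2:6, 1)
    les <- runif(x, 0.05, 0.8)
    w <- runif(x, 5, 20)
    target <- leApparentWrms(les, w)
    for (a in 0:(x - 1)) {
      wd <- mean(w[seq_len(x - a) + a])
      v <- leDeltaWrms(target, x, les[seq_len(a)], w[seq_len(a)], wDelta = wd)
      expect_equal(
        leApparentWrms(c(les[seq_len(a)], rep(v, x - a)),
                       c(w[seq_len(a)], rep(wd, x - a))),
        target, tolerance = 1e-10)
    }
    # one unknown left, with its true weight: LE-delta IS that fragment's LE
    v <- leDeltaWrms(target, x, les[-x], w[-x], wDelta = w[x])
    expect_equal(v, les[x], tolerance = 1e-9)
    vA <- leDeltaArithmetic(leApparentArithmetic(les), x, les[-x])
    expect_equal(vA, les[x], tolerance = 1e-9)
  }
})

test_that("closed-form WRMS LE-delta agrees with a numeric root finder", {
  set.seed(51)
  for (i in 1:80) {
    x <- sample(2:6, 1)
    a <- sample(0:(x - 1), 1)
    known <- runif(a, 0.05, 0.8)
    kw <- runif(a, 5, 20)
    wd <- runif(1, 5, 20)
    target <- runif(1, 0.1, 0.7)
    closed <- leDeltaWrms(target, x, known, kw, wDelta = wd)
    numeric <- wrmsDeltaByRootFinder(target, x, known, kw, wd)
    if (is.na(closed)) expect_true(is.na(numeric))
    else expect_equal(closed, numeric, tolerance = 1e-8)
  }
})

test_that("default weights follow heavy-atom count with selectable policies", {
  expect_equal(defaultWeights(c(10L, 17L)), c(10, 17))
  expect_equal(defaultWeights(12L), 12)
  expect_equal(defaultWeights(c(9L, 16L), "sqrt_n"), sqrt(c(9, 16)))
  expect_equal(defaultWeights(c(9L, 16L), "equal"), c(1, 1))
  # equal N: the weighted RMS collapses to the unweighted RMS
  les <- c(0.25, 0.45, 0.6)
  expect_equal(leApparentWrms(les, defaultWeights(rep(12L, 3))),
               sqrt(mean(les^2)))
  expect_error(defaultWeights(integer(0)), "non-empty")
})
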