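test_that("totalLoss has the uniform-logit closed form", {
  # uniform logits everywhere: each cross-entropy term is ln 2; with
  # (2, 1, 1) selected nodes over 3 stages, total = (1 + 4) * ln 2
  lb <- totalLoss(c(0, 0), list(matrix(0, 2, 2), matrix(0, 1, 2),
                                matrix(0, 1, 2)), y = 1L)
  expect_equal(lb$total, 5 * log(2), tolerance = 1e-12)
  expect_equal(lb$diagnosis, log(2))
  expect_equal(lb$select, rep(log(2), 3) * c(2, 1, 1))
  expect_equal(lb$total, lb$diagnosis + sum(lb$select))
})

test_that("confident correct diagnosis drives the loss to zero", {
  lb <- totalLoss(c(1000, -1000), list(), y = 0L)
  expect_lt(lb$total, 1e-10)
  expect_error(totalLoss(c(0, 0), list(), y = 2L), "0 or 1")
})

test_that("single-node select term matches the softplus identity", {
  for (ab in list(c(0.3, -1.2), c(2, 2), c(-5, 1))) {
    lb <- totalLoss(c(0, 0), list(matrix(ab, 1, 2)), y = 1L)
    expect_equal(lb$select, log(1 + exp(ab[1] - ab[2])), tolerance = 1e-10)
  }
})

test_that("raising the correct-class logit never increases the loss", {
  set.seed(2)
  for (trial in 1:20) {
    y <- sample(0:1, 1)
    z <- rnorm(2)
    sel <- list(matrix(rnorm(4), 2, 2))
    z2 <- z
    z2[y + 1] <- z2[y + 1] + runif(1, 0, 2)
    expect_lte(totalLoss(z2, sel, y)$total, totalLoss(z, sel, y)$total)
  }
})

test_that("mean reduction averages the per-node select terms", {
  m <- matrix(rnorm(6), 3, 2)
  s <- totalLoss(c(0, 0), list(m), 1L, reduce = "sum")$select
  mn <- totalLoss(c(0, 0), list(m), 1L, reduce = "mean")$select
  expect_equal(s / 3, mn)
})

test_that("accuracy follows the confusion-count formula", {
  expect_equal(accuracy(c(tp = 1, tn = 1, fp = 0, fn = 0)), 1.0)
  expect_equal(accuracy(c(tp = 3, tn = 5, fp = 1, fn = 1)), 0.8)
  expect_equal(accuracy(c(tp = 0, tn = 0, fp = 2, fn = 2)), 0.0)
  expect_error(accuracy(c(tp = 0, tn = 0, fp = 0, fn = 0)), "no observations")
  expect_equal(accuracy(confusionCounts(c(1, 0, 1, 1), c(1, 0, 0, 1))), 0.75)
})

test_that("rocAuc reproduces known values and handles ties", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(rocAuc(c(0.4, 0.4), c(1, 0)), 0.5)
  expect_equal(rocAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_error(rocAuc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("rocAuc equals the exhaustive concordant-pair oracle", {
  set.seed(77)
  for (n in 2:8) {
    for (labs in list(rep(c(1, 0), length.out = n),
                      c(1, rep(0, n - 1)),
                      sample(0:1, n, replace = TRUE))) {
      if (length(unique(labs)) < 2) next
      sc <- round(runif(n), 1)  # coarse grid forces frequent ties
      expect_equal(rocAuc(sc, labs), oracleAuc(sc, labs), tolerance = 1e-9)
    }
  }
})

test_that("rocAuc agrees with pROC on random score sets", {
  set.seed(5)
  for (trial in 1:10) {
    labs <- c(rep(1, 6), rep(0, 7))
    sc <- rnorm(13)
    ref <- as.numeric(pROC::auc(pROC::roc(labs, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocAuc(sc, labs), ref, tolerance = 1e-10)
  }
})

test_that("metrics are invariant to simultaneous permutation of scans", {
  set.seed(9)
  labs <- sample(0:1, 10, replace = TRUE)
  labs[1:2] <- c(0, 1)
  sc <- rnorm(10)
  pred <- as.integer(sc > 0)
  perm <- sample(10)
  expect_equal(rocAuc(sc, labs), rocAuc(sc[perm], labs[perm]))
  expect_equal(accuracy(confusionCounts(pred, labs)),
               accuracy(confusionCounts(pred[perm], labs[perm])))
})

test_that("throughput follows the printed formula", {
  expect_equal(throughput(128, 1.0, 1), 128)
  expect_equal(throughput(128, 2.0, 1), 64)
  expect_equal(throughput(256, 0.5, 4), 128)
  expect_error(throughput(128, 0, 1), "positive")
})

test_that("learning-rate schedule hits the warmup peak and the floor", {
  expect_equal(lrSchedule(5, 200), 1e-4)
  expect_equal(lrSchedule(200, 200), 1e-6)
  expect_equal(lrSchedule(1, 200), 1e-4 / 5)    # linear warmup
  tr <- lrSchedule(1:200, 200)
  expect_true(all(diff(tr[5:200]) < 0))          # monotone cosine decay
  # halfway through the decay the rate is the midpoint of the cosine
  expect_equal(lrSchedule(5 + 195 / 2, 200), (1e-4 + 1e-6) / 2,
               tolerance = 1e-10)
})
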