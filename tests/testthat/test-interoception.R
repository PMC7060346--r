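test_that("standard accuracy follows the per-trial ratio formula", {
  expect_equal(std_accuracy(make_trials(50, 50)), 1)
  expect_equal(std_accuracy(make_trials(50, 40)), 0.8)
  tr <- make_trials(50, 110)
  expect_equal(std_accuracy(tr), -0.2)
  expect_true(flag_overestimator(tr))
  expect_error(std_accuracy(make_trials(0, 10)), "nbeats_real")
})

test_that("alternative accuracy uses the mean-count denominator", {
  expect_equal(alt_accuracy(make_trials(50, 50)), 1)
  expect_equal(alt_accuracy(make_trials(50, 40)), 1 - 10 / 45)
  expect_equal(alt_accuracy(make_trials(60, 10)), 1 - 50 / 35)
})

test_that("alternative accuracy is bounded in [-1, 1] for any report", {
  set.seed(7)
  for (i in 1:200) {
    real <- sample(20:80, 6, replace = TRUE)
    reported <- sample(0:300, 6, replace = TRUE)
    a <- alt_accuracy(make_trials(real, reported))
    expect_gte(a, -1)
    expect_lte(a, 1)
  }
})

test_that("standard accuracy is <= 1, negative exactly beyond 2x reports", {
  set.seed(8)
  for (i in 1:200) {
    real <- sample(20:80, 1)
    reported <- sample(0:300, 1)
    a <- std_accuracy(make_trials(real, reported))
    expect_lte(a, 1)
    expect_equal(a < 0, reported > 2 * real)
  }
})

test_that("insight is the signed mean accuracy-confidence discrepancy", {
  ## accuracy 0.8 with confidence 8 on every trial: perfect alignment
  expect_equal(insight(make_trials(rep(50, 6), rep(40, 6), rep(8, 6))), 0)
  ## accuracy 0.9, confidence 4: high performance, low confidence
  expect_equal(insight(make_trials(rep(50, 6), rep(45, 6), rep(4, 6))), 0.5)
  ## accuracy 0.3, confidence 8: low performance, high confidence
  expect_equal(insight(make_trials(rep(50, 6), rep(15, 6), rep(8, 6))), -0.5)
  ## withheld for over-estimators
  expect_warning(v <- insight(make_trials(rep(50, 6), rep(120, 6))),
                 "over-estimator")
  expect_true(is.na(v))
})

test_that("insight is antisymmetric when accuracy and confidence swap roles", {
  set.seed(9)
  for (i in 1:20) {
    real <- rep(100, 6)
    reported <- sample(60:100, 6, replace = TRUE)
    acc <- 1 - abs(real - reported) / real
    conf <- round(runif(6, 3, 9), 1)
    a <- insight(make_trials(real, reported, conf))
    ## swap: accuracy playing the confidence role and vice versa
    ## (reported = 10 * conf makes std accuracy equal conf / 10 at real 100)
    b <- insight(make_trials(real, 10 * conf, 10 * acc))
    expect_equal(a, -b, tolerance = 1e-12)
  }
})

test_that("awareness is the trialwise accuracy-confidence correlation", {
  ## confidence exactly affine in per-trial alternative accuracy
  real <- rep(100, 6)
  reported0 <- c(70, 76, 82, 88, 94, 100)
  acc0 <- 1 - abs(real - reported0) / ((real + reported0) / 2)
  tr <- make_trials(real, reported0, confidence = 5 * acc0 + 2)
  expect_equal(awareness(tr), 1)
  tr2 <- make_trials(real, reported0, confidence = 10 - 6 * acc0)
  expect_equal(awareness(tr2), -1)
  ## frozen oracle: cor() on the alternative-accuracy pairs
  reported <- c(60, 70, 75, 85, 95, 100)
  conf <- c(2, 4, 3, 7, 6, 9)
  acc <- 1 - abs(real - reported) / ((real + reported) / 2)
  expect_equal(awareness(make_trials(real, reported, conf)),
               stats::cor(acc, conf))
  ## degenerate confidence
  expect_warning(v <- awareness(make_trials(real, reported, rep(5, 6))),
                 "zero variance")
  expect_true(is.na(v))
})

test_that("awareness is invariant under positive affine confidence rescaling", {
  real <- rep(80, 6)
  reported <- c(50, 60, 66, 70, 74, 80)
  conf <- c(1, 3, 2, 6, 5, 8)
  base <- awareness(make_trials(real, reported, conf))
  expect_equal(awareness(make_trials(real, reported, 0.5 * conf + 2)), base)
  expect_equal(awareness(make_trials(real, reported, 1.1 * conf + 0.1)),
               base)
})

test_that("confidence mean and sensibility are plain means with range checks", {
  expect_equal(confidence_mean(make_trials(rep(50, 3), rep(50, 3),
                                           rep(5, 3))), 5)
  expect_equal(confidence_mean(make_trials(rep(50, 6), rep(50, 6),
                                           c(2, 4, 6, 8, 10, 0))), 5)
  expect_equal(sensibility(rep(3, 45)), 3)
  expect_equal(sensibility(rep(5, 45)), 5)
  expect_equal(sensibility(c(rep(1, 22), rep(5, 22), 3)), 3)
  expect_error(sensibility(c(rep(3, 44), 6)), "1, 5")
})

test_that("TIPE is the difference of n-1 z-scores with cohort mean zero", {
  acc <- c(0.2, 0.5, 0.8)
  sens <- c(2, 3, 4)
  expect_equal(tipe(acc, sens), c(0, 0, 0))
  set.seed(10)
  acc <- runif(41, 0, 1)
  sens <- runif(41, 1, 5)
  ti <- tipe(acc, sens)
  expect_equal(mean(ti), 0, tolerance = 1e-9)
  zs <- (sens - mean(sens)) / sd(sens)
  za <- (acc - mean(acc)) / sd(acc)
  expect_equal(sd(zs), 1, tolerance = 1e-9)
  expect_equal(sd(za), 1, tolerance = 1e-9)
  expect_equal(ti, zs - za)
  expect_error(tipe(rep(0.5, 5), 1:5), "zero variance")
})

test_that("over-estimator rule uses six-trial totals", {
  expect_false(flag_overestimator(make_trials(rep(50, 6), rep(50, 6))))
  tr <- make_trials(rep(200 / 6, 6), rep(450 / 6, 6))
  expect_true(flag_overestimator(tr))
  ## one wild trial does not flag a subject whose totals stay under 2x
  tr2 <- make_trials(rep(50, 6), c(rep(45, 5), 120))
  expect_false(flag_overestimator(tr2))
})

test_that("cohort profiles withhold standard indices for over-estimators", {
  set.seed(11)
  n <- 41
  rows <- lapply(1:n, function(i) {
    real <- sample(30:60, 6, replace = TRUE)
    reported <- if (i == 5) real * 3 else pmax(0, round(real * 0.7 +
                                                          rnorm(6)))
    cbind(subject_id = sprintf("s%02d", i),
          make_trials(real, reported, round(runif(6, 0, 10), 1)))
  })
  tracking <- do.call(rbind, rows)
  quest <- data.frame(subject_id = sprintf("s%02d", 1:n),
                      bpq_mean = round(runif(n, 1.5, 4), 2))
  prof <- interoception_profiles(tracking, quest)
  expect_equal(nrow(prof), 41)
  expect_equal(sum(prof$overestimator), 1)
  expect_equal(sum(!is.na(prof$std_accuracy)), 40)
  expect_equal(sum(!is.na(prof$insight)), 40)
  expect_equal(sum(!is.na(prof$alt_accuracy)), 41)
  expect_equal(mean(prof$tipe), 0, tolerance = 1e-9)
})
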