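test_that("paired t matches hand arithmetic and always covers its estimate", {
  x <- c(2, 4, 6)
  y <- c(1, 2, 3)                         # d = 1, 2, 3: mean 2, sd 1
  res <- paired_t(x, y)
  expect_equal(res$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(res$statistic, 3.464, tolerance = 1e-3)
  expect_equal(as.numeric(res$df), 2)
  expect_equal(res$estimate, 2)
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
  set.seed(15)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(20)
    r <- paired_t(a, b)
    expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
    expect_gte(r$p, 0); expect_lte(r$p, 1); expect_gt(r$bf10, 0)
  }
  expect_error(paired_t(1:5, 1:5), "zero variance")
})

test_that("wilcoxon signed-rank reproduces exact enumeration", {
  ## all five differences positive: W = 15; one-sided exact p = 1/32,
  ## two-sided = 1/16
  res <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(res$statistic, 15)
  expect_equal(res$p, 2 / 32)
  ## antisymmetric differences: W = n(n+1)/4, p in the null region
  x <- c(1, 2, 3, 4, 5, 6)
  y <- x + c(1, -1, 2, -2, 3, -3)
  res2 <- wilcoxon_signed_rank(y, x)
  expect_equal(res2$statistic, 6 * 7 / 4)
  expect_gt(res2$p, 0.9)
  ## exact and normal-approximate p agree within 0.02 at n = 20
  set.seed(16)
  for (i in 1:5) {
    a <- rnorm(20); b <- rnorm(20)
    pe <- wilcoxon_signed_rank(a, b)$p          # exact at n = 20, no ties
    pa <- stats::wilcox.test(a - b, exact = FALSE)$p.value
    expect_lt(abs(pa - pe), 0.02)
  }
})

test_that("pearson test matches hand values and the t-transform", {
  res1 <- suppressWarnings(pearson_test(1:10, 2 * (1:10) + 1))
  expect_equal(res1$estimate, 1)
  expect_equal(res1$bf10, Inf)
  res <- pearson_test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$estimate, 0.6)
  expect_equal(res$estimate, pearson_test(c(2, 1, 4, 3),
                                          c(1, 2, 3, 4))$estimate)
  set.seed(17)
  x <- rnorm(30); y <- rnorm(30)
  r <- pearson_test(x, y)
  tstat <- r$estimate * sqrt(28 / (1 - r$estimate^2))
  expect_equal(r$p, 2 * pt(-abs(tstat), 28), tolerance = 1e-12)
  ## pairwise deletion reports the effective n
  x[3] <- NA
  expect_equal(pearson_test(x, y)$n, 29)
  expect_error(pearson_test(rep(1, 5), 1:5), "zero variance")
})

test_that("enter-method regression has the right df, R2 and rank check", {
  set.seed(18)
  X <- data.frame(a = rnorm(41), b = rnorm(41))
  y_exact <- 2 * X$a - X$b + 3
  expect_equal(suppressWarnings(ols_enter(y_exact, X))$estimate, 1)
  y <- rnorm(41)
  res <- ols_enter(y, X)
  expect_equal(res$df, "2,38")
  expect_equal(res$p, pf(res$statistic, 2, 38, lower.tail = FALSE))
  expect_error(ols_enter(y, cbind(X, z = 0)), "rank")
})

test_that("correlation matrix is symmetric, NA-aware, with per-cell n", {
  set.seed(19)
  d <- data.frame(a = rnorm(41), b = rnorm(41), c = rnorm(41))
  d$a[1] <- NA                            # one missing value
  m <- correlation_matrix(d, c("a", "b"), c("b", "c"))
  expect_equal(nrow(m), 4)
  ab <- m[m$row == "a" & m$col == "b", ]
  expect_equal(ab$n, 40)
  expect_equal(m[m$row == "b" & m$col == "c", "r"],
               correlation_matrix(d, "c", "b")$r)
  expect_equal(suppressWarnings(correlation_matrix(d, "b", "b"))$r, 1)
  ## degenerate cells come back missing, not as errors
  d$k <- 1
  mk <- correlation_matrix(d, "k", "b")
  expect_true(is.na(mk$r))
})

test_that("behaviour scoring matches the worked toy session", {
  trials <- make_session(go_rt = c(400, 500, 600), go_n = 4,
                         nogo_rt = 450, nogo_n = 2,
                         choose_rt = c(500, 700), choose_n = 4)
  s <- score_session(trials)
  expect_equal(s$go_rt_mean, 500)
  expect_equal(s$go_omissions_mean, 25)
  expect_equal(s$nogo_err_mean, 50)
  expect_equal(s$nogo_rt_mean, 450)
  expect_equal(s$choose_go_mean, 50)
  expect_equal(s$choose_go_rt_mean, 600)
  ## no NoGo presses: 0% errors, RT absent
  s2 <- score_session(make_session(go_rt = 500, go_n = 1, nogo_n = 2,
                                   choose_rt = 400, choose_n = 1))
  expect_equal(s2$nogo_err_mean, 0)
  expect_true(is.na(s2$nogo_rt_mean))
})

test_that("scoring is order-invariant and pools phases as weighted means", {
  set.seed(20)
  cfg <- gen_config(seed = 20)
  lat <- subject_latents(cfg)[1, ]
  sched <- gen_session_schedule(cfg, seed = 20)
  trials <- gen_behavior(lat, sched, cfg, seed = 20)
  s <- score_session(trials)
  perm <- trials[sample.int(nrow(trials)), ]
  expect_equal(score_session(perm), s)
  for (v in c("go_omissions", "nogo_err", "choose_go")) {
    lo <- min(s[[paste0(v, "_systole")]], s[[paste0(v, "_diastole")]])
    hi <- max(s[[paste0(v, "_systole")]], s[[paste0(v, "_diastole")]])
    expect_gte(s[[paste0(v, "_mean")]], lo)
    expect_lte(s[[paste0(v, "_mean")]], hi)
  }
  ## %Choose-Go and %Choose-NoGo partition the Choose trials
  ch <- trials[trials$trial_type == "choose", ]
  expect_equal(s$choose_go_mean + 100 * mean(ch$pressed == 0), 100)
})

test_that("exclusion rule flags only high NoGo-error outliers, single pass", {
  expect_false(any(exclusion_flags(rep(4, 10))))
  v <- c(rep(4, 40), 60)
  f <- exclusion_flags(v)
  expect_equal(which(f), 41L)
  ## one-sided: a zero-error subject is never flagged
  v2 <- c(rep(4, 40), 0)
  expect_false(any(exclusion_flags(v2)))
})

test_that("cohort table reports n-1 descriptives with pairwise deletion", {
  d <- data.frame(a = c(40, 80), b = c(1, NA))
  tab <- cohort_table(d)
  expect_equal(tab$mean[tab$variable == "a"], 60)
  expect_equal(tab$min[tab$variable == "a"], 40)
  expect_equal(tab$max[tab$variable == "a"], 80)
  expect_equal(tab$sd[tab$variable == "a"], sd(c(40, 80)))
  expect_equal(tab$n[tab$variable == "b"], 1)
  expect_true(is.na(tab$sd[tab$variable == "b"]))
})
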