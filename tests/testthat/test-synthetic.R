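test_that("config validates its invariants", {
  expect_error(gen_config(trial_mix = c(go = 0.5, nogo = 0.3, choose = 0.3)),
               "sum to 1")
  expect_error(gen_config(rmssd_target = -1), "positive")
  expect_error(gen_config(mean_bpm = 20), "30, 180")
})

test_that("generated RR series control RMSSD and mean rate", {
  r <- gen_rr_series(75, 54, 10000, seed = 1)
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(r) >= 300 & diff(r) <= 2000))
  expect_equal(rmssd(diff(r)), 54, tolerance = 0.02)
  expect_equal(mean(diff(r)), 800, tolerance = 0.01)
  ## degenerate jitter: near-periodic series
  r2 <- gen_rr_series(60, 0.001, 100, seed = 2)
  expect_true(all(abs(diff(diff(r2))) < 1))
  ## determinism
  expect_identical(gen_rr_series(75, 54, 100, seed = 9),
                   gen_rr_series(75, 54, 100, seed = 9))
  expect_error(gen_rr_series(75, 0, 100), "positive")
  expect_error(gen_rr_series(75, 54, 3), "at least 4")
})

test_that("session schedules have exact type counts and balanced phases", {
  cfg <- gen_config()
  s <- gen_session_schedule(cfg, seed = 4)
  expect_equal(sum(s$trial_type == "go"), 200)
  expect_equal(sum(s$trial_type == "nogo"), 66)
  expect_equal(sum(s$trial_type == "choose"), 134)
  expect_equal(sum(s$trial_type == "choose" & s$intended_phase == "systole"),
               67)
  for (tt in c("go", "nogo", "choose")) {
    k <- table(s$intended_phase[s$trial_type == tt])
    expect_lte(abs(k[["systole"]] - k[["diastole"]]), 1)
  }
  expect_identical(gen_session_schedule(cfg, seed = 4), s)
  ## odd counts split within one trial
  cfg2 <- gen_config(n_trials = 101,
                     trial_mix = c(go = 0.5, nogo = 0.25, choose = 0.25))
  s2 <- gen_session_schedule(cfg2, seed = 4)
  expect_equal(nrow(s2), 101)
  k <- table(s2$intended_phase[s2$trial_type == "go"])
  expect_lte(abs(k[["systole"]] - k[["diastole"]]), 1)
})

test_that("behaviour generator matches its configured rates", {
  cfg <- gen_config(seed = 6)
  lat <- subject_latents(cfg)
  sched <- gen_session_schedule(cfg, seed = 6)
  ## pool many sessions of one average subject for a tight rate estimate
  lat1 <- lat[1, ]
  lat1$impulsivity <- 0
  omitted <- pressed_nogo <- n_go <- n_nogo <- 0
  for (s in 1:25) {
    b <- gen_behavior(lat1, sched, cfg, seed = 600 + s)
    omitted <- omitted + sum(b$trial_type == "go" & b$pressed == 0)
    n_go <- n_go + sum(b$trial_type == "go")
    pressed_nogo <- pressed_nogo + sum(b$trial_type == "nogo" & b$pressed == 1)
    n_nogo <- n_nogo + sum(b$trial_type == "nogo")
  }
  expect_equal(omitted / n_go, 0.01, tolerance = 0.5)      # ~1% of Go
  expect_equal(pressed_nogo / n_nogo, 0.04, tolerance = 0.5)
  b <- gen_behavior(lat1, sched, cfg, seed = 601)
  expect_true(all(is.na(b$rt_ms[b$pressed == 0])))
  expect_true(all(b$rt_ms[b$pressed == 1] > 0 &
                    b$rt_ms[b$pressed == 1] <= 1000))
  expect_error(gen_behavior(lat1, sched[0, ], cfg), "nonempty")
})

test_that("tracking trials use the six canonical durations and honour ability", {
  cfg <- gen_config(seed = 8)
  lat <- subject_latents(cfg)[1, ]
  tr <- gen_tracking_trials(lat, 75, seed = 8)
  expect_setequal(tr$duration_s, c(25, 30, 35, 40, 45, 50))
  expect_true(all(tr$confidence >= 0 & tr$confidence <= 10))
  expect_true(all(tr$nbeats_reported >= 0))
  ## perfect counter with zero noise scores standard accuracy 1 per trial
  lat$tracking_ability <- 1
  tr2 <- gen_tracking_trials(lat, 75, seed = 9, count_noise_sd = 0)
  expect_equal(std_accuracy(tr2), 1)
  expect_equal(tr2$nbeats_reported, tr2$nbeats_real)
})

test_that("full confidence coupling yields high measured awareness", {
  cfg <- gen_config(seed = 12)
  lat <- subject_latents(cfg)[1, ]
  lat$confidence_coupling <- 1
  aw <- vapply(1:30, function(s)
    suppressWarnings(awareness(gen_tracking_trials(lat, 75, seed = 1200 + s))),
    numeric(1))
  expect_gt(mean(aw, na.rm = TRUE), 0.8)
})

test_that("questionnaire scores are integers inside instrument ranges", {
  cfg <- gen_config(seed = 13)
  lat <- subject_latents(cfg)
  q <- gen_questionnaires(lat[1, ], seed = 13)
  int_cols <- setdiff(names(q), "bpq_mean")
  expect_true(all(vapply(q[int_cols], function(x) x == round(x),
                         logical(1))))
  expect_equal(q$bis_total, q$bis_attention + q$bis_motor + q$bis_planning)
  expect_gte(q$bpq_mean, 1)
  expect_lte(q$bpq_mean, 5)
  ## monotone: an extreme impulsivity latent pushes scores high
  hi <- lat[1, ]; hi$impulsivity <- 6
  qh <- gen_questionnaires(hi, seed = 13)
  expect_true(all(qh[int_cols] >= q[int_cols]))
  expect_identical(gen_questionnaires(lat[1, ], seed = 13), q)
})

test_that("zero-effect cohorts show null awareness-behaviour correlations", {
  cfg <- gen_config(n_subjects = 200, seed = 1)
  coh <- gen_cohort(cfg)
  prof <- interoception_profiles(coh$tracking_trials, coh$questionnaires)
  beh <- behavior_summaries(coh$task_trials)
  r <- cor(prof$awareness,
           beh$choose_go_mean[match(prof$subject_id, beh$subject_id)],
           use = "complete.obs")
  expect_lt(abs(r), 0.15)
})

test_that("datasets round-trip through disk exactly", {
  dir <- withr::local_tempdir()
  cfg <- gen_config(n_subjects = 5, seed = 14)
  coh <- gen_dataset(cfg, dir)
  expect_equal(nrow(coh$subjects), 5)
  expect_equal(nrow(coh$task_trials), 5 * 400)
  task <- read_task_trials(file.path(dir, "task_trials.csv"))
  expect_equal(task$pressed, coh$task_trials$pressed)
  expect_equal(task$rt_ms, coh$task_trials$rt_ms)
  track <- read_tracking_trials(file.path(dir, "tracking_trials.csv"))
  expect_equal(track$nbeats_reported, coh$tracking_trials$nbeats_reported)
  expect_equal(track$confidence, coh$tracking_trials$confidence)
  rr <- read_rr_file(file.path(dir, "rr_s01.txt"))
  expect_equal(rr, coh$rr[["s01"]])
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 14)
  ## byte-identical regeneration under the same seed
  dir2 <- withr::local_tempdir()
  gen_dataset(cfg, dir2)
  for (f in list.files(dir, pattern = "csv$|txt$"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})
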