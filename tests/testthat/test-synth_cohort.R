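test_that("age map is a noise-free linear function when noise is silenced", {
  m <- age_morphology_model()
  m$noise_sd[] <- 0
  out <- age_to_morphology(60, m, n_beats = 3, seed = 1)
  expect_equal(out$heart_rate, 78 - 0.08 * 60)
  expect_equal(unique(out$beats$pr), 0.14 + 4e-4 * 60)
  expect_equal(unique(out$beats$qrs), 0.085 + 3e-4 * 60)
  expect_equal(unique(out$beats$qt), 0.36 + 6e-4 * 60)
  expect_equal(unique(out$beats$r_amp), 1.2 - 4e-3 * 60)
  expect_equal(unique(out$beats$t_amp), 0.3 - 1e-3 * 60)
  # brute-force scan: PR non-decreasing in age for a positive PR slope
  prs <- vapply(0:95, function(a)
    age_to_morphology(a, m, seed = 1)$beats$pr[1], numeric(1))
  expect_true(all(diff(prs) >= 0))
  # wave centers ordered P < Q < R < S < T, widths positive
  b <- out$beats[1, ]
  centers <- c(b$p_center, b$q_center, b$r_center, b$s_center, b$t_center)
  expect_true(all(diff(centers) > 0))
  expect_true(all(c(b$p_width, b$q_width, b$r_width, b$s_width,
                    b$t_width) > 0))
})

test_that("morphology draws are deterministic given a seed and reject bad ages", {
  a <- age_to_morphology(40, n_beats = 5, seed = 11)
  b <- age_to_morphology(40, n_beats = 5, seed = 11)
  expect_identical(a, b)
  expect_error(age_to_morphology(96), "age")
  expect_error(age_to_morphology(-1), "age")
})

test_that("zero-amplitude model renders an all-zero record", {
  m <- age_morphology_model(r_amp = c(0, 0), t_amp = c(0, 0),
                            p_amp = 0, wander_amp = 0, noise_mv = 0)
  m$noise_sd[] <- 0
  rec <- synthesize_record(50, rate = 100, duration = 2, model = m, seed = 1)
  expect_true(all(rec$signal == 0))
  expect_equal(dim(rec$signal), c(12L, 200L))
})

test_that("rendered beats sit at the drawn heart rate", {
  rec <- synthesize_record(50, rate = 500, duration = 10, seed = 21)
  # peak-picking oracle on the strongest positive lead
  lead <- which.max(age_morphology_model()$lead_weights)
  x <- rec$signal[lead, ]
  thr <- 0.5 * max(x)
  above <- which(x > thr)
  peaks <- above[c(TRUE, diff(above) > 50)]   # group consecutive runs
  periods <- diff(peaks) / rec$rate
  hr_drawn <- 60 / median(periods)
  hr_ann <- 60 / (median(diff(rec$annotations$qrs_on)) / rec$rate)
  expect_lt(abs(hr_drawn - hr_ann) / hr_ann, 0.05)
  # R-peak count within +/-1 of heart_rate * duration / 60
  expect_lte(abs(length(peaks) - hr_ann * 10 / 60), 1.5)
  # per-lead mean bounded by baseline wander
  m <- age_morphology_model()
  expect_true(all(abs(rowMeans(rec$signal)) <= 3 * m$wander_amp + 0.05))
})

test_that("annotations are sound: ordered fiducials matching the generating intervals", {
  for (seed in 1:5) {
    rec <- synthesize_record(30 + 10 * seed, rate = 500, duration = 10,
                             seed = seed)
    ann <- rec$annotations
    expect_gt(nrow(ann), 5)
    for (b in seq_len(nrow(ann))) {
      expect_true(ann$p_on[b] < ann$qrs_on[b])
      expect_true(ann$qrs_on[b] < ann$qrs_off[b])
      expect_true(ann$qrs_off[b] < ann$t_off[b])
    }
    expect_true(all(ann$t_off < ncol(rec$signal)))
    # beats are non-overlapping and ordered in time
    expect_true(all(diff(ann$p_on) > 0))
    expect_true(all(utils::head(ann$t_off, -1) < utils::tail(ann$p_on, -1)))
  }
})

test_that("mask intervals match the generating durations within one sample", {
  m <- age_morphology_model()
  m$noise_sd[] <- 0
  rec <- synthesize_record(60, rate = 500, duration = 10, model = m, seed = 3)
  ann <- rec$annotations
  pr <- (0.14 + 4e-4 * 60) * 500
  qrs <- (0.085 + 3e-4 * 60) * 500
  qt <- (0.36 + 6e-4 * 60) * 500
  expect_true(all(abs((ann$qrs_on - ann$p_on) - pr) <= 1))
  expect_true(all(abs((ann$qrs_off - ann$qrs_on) - qrs) <= 1))
  expect_true(all(abs((ann$t_off - ann$qrs_on) - qt) <= 1))
})

test_that("cohort ages reproduce the left-skewed reference distribution", {
  co <- generate_cohort(2000, rate = 100, duration = 1, seed = 5)
  ages <- co$table$age
  expect_true(all(ages >= 0 & ages <= 95))
  expect_lt(abs(median(ages) - 62), 2)
  expect_lt(abs(unname(diff(quantile(ages, c(0.25, 0.75)))) - 22), 3)
  # left skew: mean below median
  expect_lt(mean(ages), median(ages))
})

test_that("fold assignment is a patient-level partition", {
  co <- generate_cohort(500, records_per_patient = 2L, rate = 100,
                        duration = 1, seed = 8)
  tab <- co$table
  expect_true(all(tab$fold_id %in% 0:9))
  expect_setequal(unique(tab$fold_id), 0:9)
  # no patient id appears in two folds (exhaustive check)
  per_patient <- tapply(tab$fold_id, tab$patient_id,
                        function(f) length(unique(f)))
  expect_true(all(per_patient == 1L))
  expect_equal(nrow(tab), 1000L)
})

test_that("degenerate single-patient cohort works and cohorts are seed-reproducible", {
  co <- generate_cohort(1, records_per_patient = 3L, rate = 100,
                        duration = 1, seed = 2)
  expect_equal(nrow(co$table), 3L)
  expect_equal(length(unique(co$table$fold_id)), 1L)
  a <- generate_cohort(20, rate = 100, duration = 1, seed = 31)
  b <- generate_cohort(20, rate = 100, duration = 1, seed = 31)
  expect_identical(a$table, b$table)
  expect_identical(a$records[[7]]$signal, b$records[[7]]$signal)
})

test_that("age signal exists: age correlates strongly with mean PR duration", {
  co <- generate_cohort(1000, rate = 100, duration = 2, seed = 13)
  pr <- vapply(co$records, function(r) {
    ann <- r$annotations
    mean(ann$qrs_on - ann$p_on)
  }, numeric(1))
  expect_gt(cor(co$table$age, pr), 0.5)
})
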