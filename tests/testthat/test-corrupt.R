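test_that("masking requires annotations and honors p_lead = 0 and 1", {
  rec <- fixture_record(rate = 500, duration = 10, seed = 41)
  bare <- rec; bare$annotations <- NULL
  expect_error(feature_mask(bare, mask_scheme("QRS")), "annotation")
  set.seed(1)
  expect_identical(feature_mask(rec, mask_scheme("QRS", p_lead = 0))$signal,
                   rec$signal)
  # p_lead = 1, QRS: masked sample count equals the annotated interval sum
  out <- feature_mask(rec, mask_scheme("QRS", p_lead = 1))
  ann <- rec$annotations
  per_lead <- sum(ann$qrs_off - ann$qrs_on)
  changed <- sum(out$signal == 0 & rec$signal != 0)
  expect_equal(sum(out$signal != rec$signal),
               sum(rec$signal[rep(TRUE, 12),
                              unlist(mapply(function(a, b) (a + 1):b,
                                            ann$qrs_on, ann$qrs_off))] != 0))
  # exact count: all 12 leads masked over every beat interval
  masked_cols <- unlist(mapply(function(a, b) (a + 1):b, ann$qrs_on,
                               ann$qrs_off))
  expect_length(masked_cols, per_lead)
  expect_true(all(out$signal[, masked_cols] == 0))
})

test_that("PR and QT masks cover their half-open fiducial intervals", {
  rec <- fixture_record(rate = 500, duration = 10, seed = 42)
  ann <- rec$annotations
  set.seed(2)
  pr <- feature_mask(rec, mask_scheme("PR", p_lead = 1))
  cols_pr <- unlist(mapply(function(a, b) (a + 1):b, ann$p_on, ann$qrs_on))
  expect_true(all(pr$signal[, cols_pr] == 0))
  # sample just before P onset untouched
  expect_identical(pr$signal[, ann$p_on[2]], rec$signal[, ann$p_on[2]])
  qt <- feature_mask(rec, mask_scheme("QT", p_lead = 1))
  cols_qt <- unlist(mapply(function(a, b) (a + 1):b, ann$qrs_on, ann$t_off))
  expect_true(all(qt$signal[, cols_qt] == 0))
})

test_that("unselected leads are bit-identical and selection is calibrated", {
  rec <- fixture_record(rate = 100, duration = 1, seed = 43)
  set.seed(3)
  n_sel <- integer(0)
  for (i in 1:10000) {
    sel <- which(stats::runif(12) < 0.25)
    n_sel <- c(n_sel, length(sel))
  }
  expect_lt(abs(mean(n_sel) / 12 - 0.25), 0.02)
  # behavioral check on the masking path itself (fewer draws)
  set.seed(4)
  freq <- matrix(FALSE, 500, 12)
  for (i in 1:500) {
    out <- feature_mask(rec, mask_scheme("QRS", p_lead = 0.25))
    sel <- attr(out, "masked_leads")
    freq[i, sel] <- TRUE
    unsel <- setdiff(1:12, sel)
    expect_identical(out$signal[unsel, ], rec$signal[unsel, ])
  }
  expect_lt(abs(mean(freq) - 0.25), 0.05)
})

test_that("random masks remove as much signal as their matched feature mask", {
  rec <- fixture_record(rate = 500, duration = 10, seed = 44)
  ann <- rec$annotations
  set.seed(5)
  out <- random_mask(rec, mask_scheme("random", p_lead = 1, match = "QRS"))
  w <- attr(out, "window_len")
  expect_equal(w, as.integer(round(mean(ann$qrs_off - ann$qrs_on))))
  # per lead and beat, one window of w samples is zeroed within the beat span
  for (l in c(1, 8)) {
    diffs <- which(out$signal[l, ] != rec$signal[l, ])
    # changed samples fall inside annotated beat spans
    in_span <- any(vapply(seq_len(nrow(ann)), function(b)
      all(diffs >= ann$p_on[b] + 1 | diffs <= ann$t_off[b]), logical(1)))
    expect_true(in_span)
    # count matches the matched feature within one sample per beat
    expect_lte(abs(length(diffs) - nrow(ann) * w), nrow(ann))
  }
  expect_identical(random_mask(rec, mask_scheme("random", p_lead = 0))$signal,
                   rec$signal)
})

test_that("random mask onsets are uniform within the beat span", {
  rec <- fixture_record(rate = 500, duration = 10, seed = 45)
  ann <- rec$annotations
  b <- 2L
  span_lo <- ann$p_on[b]
  scheme <- mask_scheme("random", p_lead = 1, match = "QRS")
  iv <- ann$qrs_off - ann$qrs_on
  w <- as.integer(round(mean(iv)))
  lo_max <- ann$t_off[b] - w
  set.seed(6)
  onsets <- integer(0)
  for (i in 1:2000) {
    out <- random_mask(rec, scheme)
    d <- which(out$signal[1, (span_lo + 1):(ann$t_off[b])] !=
                 rec$signal[1, (span_lo + 1):(ann$t_off[b])])
    if (length(d)) onsets <- c(onsets, min(d))
  }
  n_bins <- 8
  obs <- table(cut(onsets, breaks = n_bins))
  expect_gt(stats::chisq.test(obs)$p.value, 0.001)
})

test_that("batch corruption mirrors the record-level operators", {
  cache <- fixture_cache(n = 6, rate = 100, duration = 2, seed = 46)
  b <- cache$signals[1:3, , , drop = FALSE]
  set.seed(7)
  out <- corrupt_batch(b, cache$annotations[1:3],
                       mask_scheme("QRS", p_lead = 1))
  for (i in 1:3) {
    ann <- cache$annotations[[i]]
    cols <- unlist(mapply(function(a, b) (a + 1):b, ann$qrs_on,
                          ann$qrs_off))
    expect_true(all(out[i, , cols] == 0))
  }
  expect_error(corrupt_batch(b, list(NULL, NULL, NULL),
                             mask_scheme("QRS")), "annotations")
})
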