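#' Age-to-morphology model for the synthetic ECG generator
#'
#' Defines how beat morphology evolves with age. Each age-dependent quantity
#' (heart rate, PR interval, QRS duration, QT interval, R amplitude,
#' T amplitude) is a linear map \code{intercept + slope * age} plus Gaussian
#' noise; the rendered beat is projected onto twelve leads through a fixed
#' weight vector, with additive sinusoidal baseline wander and white
#' measurement noise.
#'
#' Defaults encode healthy-aging trends: heart rate 78 - 0.08*age bpm,
#' PR 0.14 + 0.0004*age s, QRS 0.085 + 0.0003*age s, QT 0.36 + 0.0006*age s,
#' R amplitude 1.2 - 0.004*age mV, T amplitude 0.3 - 0.001*age mV, with
#' noise standard deviations of 5 percent of each intercept.
#'
#' @param hr,pr,qrs,qt,r_amp,t_amp length-2 numeric vectors
#'   \code{c(intercept, slope)} (bpm, s, s, s, mV, mV against years).
#' @param noise_sd named numeric vector of per-quantity noise SDs
#'   (same units as the quantity).
#' @param p_amp P-wave amplitude (mV); \code{q_frac}, \code{s_frac} are Q/S
#'   amplitudes as fractions of the R amplitude.
#' @param lead_weights 12 projection weights in \[-1, 1\]; at least one
#'   negative so leads have distinct polarity.
#' @param wander_amp,wander_freq baseline-wander amplitude (mV) and
#'   frequency (Hz).
#' @param noise_mv measurement noise SD (mV).
#' @param age_loc,age_scale,age_shape skew-normal parameters of the cohort
#'   age distribution, truncated to \[0, 95\] (defaults reproduce a median
#'   near 62 years with an interquartile range near 22 years, left-skewed).
#' @return An object of class \code{age_morphology_model}.
#' @export
age_morphology_model <- function(hr = c(78, -0.08),
                                 pr = c(0.14, 4e-4),
                                 qrs = c(0.085, 3e-4),
                                 qt = c(0.36, 6e-4),
                                 r_amp = c(1.2, -4e-3),
                                 t_amp = c(0.3, -1e-3),
                                 noise_sd = NULL,
                                 p_amp = 0.12, q_frac = -0.12, s_frac = -0.2,
                                 lead_weights = c(0.5, 0.75, 0.25, -0.45,
                                                  0.2, 0.62, -0.3, 0.9,
                                                  1.0, 0.95, 0.85, 0.7),
                                 wander_amp = 0.05, wander_freq = 0.25,
                                 noise_mv = 0.01,
                                 age_loc = 79.601, age_scale = 26.162,
                                 age_shape = -4) {
  if (is.null(noise_sd))
    noise_sd <- c(hr = 0.05 * hr[1], pr = 0.05 * pr[1], qrs = 0.05 * qrs[1],
                  qt = 0.05 * qt[1], r_amp = 0.05 * abs(r_amp[1]),
                  t_amp = 0.05 * abs(t_amp[1]))
  m <- structure(list(hr = hr, pr = pr, qrs = qrs, qt = qt, r_amp = r_amp,
                      t_amp = t_amp, noise_sd = noise_sd, p_amp = p_amp,
                      q_frac = q_frac, s_frac = s_frac,
                      lead_weights = lead_weights, wander_amp = wander_amp,
                      wander_freq = wander_freq, noise_mv = noise_mv,
                      age_loc = age_loc, age_scale = age_scale,
                      age_shape = age_shape),
                 class = "age_morphology_model")
  validate_age_morphology_model(m)
}

validate_age_morphology_model <- function(m) {
  if (length(m$lead_weights) != 12L)
    stop_ecg("lead_weights must have length 12 (got %d)", length(m$lead_weights))
  if (any(abs(m$lead_weights) > 1))
    stop_ecg("lead_weights must lie in [-1, 1]")
  if (!any(m$lead_weights < 0))
    stop_ecg("at least one lead weight must be negative")
  ages <- c(0, 95)
  for (q in c("pr", "qrs", "qt", "hr")) {
    v <- m[[q]][1] + m[[q]][2] * ages
    if (any(v <= 0))
      stop_ecg("age map for `%s` is non-positive within [0, 95]", q)
  }
  pr <- m$pr[1] + m$pr[2] * ages
  qt <- m$qt[1] + m$qt[2] * ages
  if (any(pr >= qt)) stop_ecg("age map violates PR < QT on [0, 95]")
  m
}

#' Map an age to per-beat wave parameters
#'
#' Draws, for each beat, the PR/QRS/QT intervals and R/T amplitudes as
#' \code{intercept + slope * age + noise}, plus one record-level heart rate,
#' and converts them to the five Gaussian wave components (P, Q, R, S, T)
#' used to render a beat. Noise is drawn per beat, so beat-to-beat
#' variability is present but the age signal is shared.
#'
#' @param age age in years, within \[0, 95\].
#' @param model an \code{\link{age_morphology_model}}.
#' @param n_beats number of beats to draw parameters for.
#' @param seed optional integer; when given, the draw is made under a
#'   temporary RNG state so the result is reproducible.
#' @return List with \code{heart_rate} (bpm) and \code{beats}, a data frame
#'   of one row per beat: intervals \code{pr, qrs, qt} (s), amplitudes and,
#'   for each wave, amplitude (mV), center offset from beat start (s) and
#'   width (s).
#' @export
age_to_morphology <- function(age, model = age_morphology_model(),
                              n_beats = 1L, seed = NULL) {
  check_number(age, "age", 0)
  if (age > 95) stop_ecg("age must lie in [0, 95] (got %g)", age)
  with_seed(seed, {
    hr <- model$hr[1] + model$hr[2] * age +
      rnorm(1L, 0, model$noise_sd[["hr"]])
    hr <- max(hr, 20)
    draw <- function(q) {
      model[[q]][1] + model[[q]][2] * age +
        rnorm(n_beats, 0, model$noise_sd[[q]])
    }
    pr <- pmax(draw("pr"), 0.05)
    qrs <- pmax(draw("qrs"), 0.03)
    qt <- pmax(draw("qt"), qrs + 0.1)
    r_a <- draw("r_amp")
    t_a <- draw("t_amp")
    beats <- data.frame(
      pr = pr, qrs = qrs, qt = qt,
      p_amp = rep(model$p_amp, n_beats), p_center = 0.4 * pr,
      p_width = 0.13 * pr,
      q_amp = model$q_frac * r_a, q_center = pr + 0.15 * qrs,
      q_width = 0.06 * qrs,
      r_amp = r_a, r_center = pr + 0.45 * qrs, r_width = 0.11 * qrs,
      s_amp = model$s_frac * r_a, s_center = pr + 0.8 * qrs,
      s_width = 0.06 * qrs,
      t_amp = t_a, t_center = pr + qrs + 0.55 * (qt - qrs),
      t_width = 0.15 * (qt - qrs))
    list(heart_rate = hr, beats = beats)
  })
}

#' Synthesize one annotated 12-lead ECG record
#'
#' Beats are placed at the drawn heart rate; each beat is a sum of five
#' Gaussian waves, projected to 12 leads through the model's lead weights,
#' with sinusoidal baseline wander and white measurement noise added per
#' lead. Fiducial annotations (P onset, QRS onset/offset, T offset) are
#' emitted as 0-based sample indices consistent with the generating
#' intervals.
#'
#' @param age age in years.
#' @param rate sampling rate in Hz (commonly 100 or 500).
#' @param duration record duration in seconds.
#' @param model an \code{\link{age_morphology_model}}.
#' @param seed optional integer seed.
#' @param patient_id,record_id identifiers stored on the record.
#' @return An object of class \code{ecg_record}: list with \code{signal}
#'   (12 x T matrix, mV), \code{rate}, \code{duration}, \code{age},
#'   \code{patient_id}, \code{record_id} and \code{annotations} (data frame
#'   \code{beat, p_on, qrs_on, qrs_off, t_off}, 0-based sample indices,
#'   half-open intervals).
#' @export
synthesize_record <- function(age, rate = 500, duration = 10,
                              model = age_morphology_model(), seed = NULL,
                              patient_id = "P0", record_id = "R0") {
  check_number(rate, "rate", 0, strict = TRUE)
  check_number(duration, "duration", 0, strict = TRUE)
  with_seed(seed, {
    n_samp <- round(duration * rate)
    tgrid <- (seq_len(n_samp) - 1) / rate
    # upper bound on beats, trimmed below to those fully inside the record
    n_max <- ceiling(duration * 130 / 60) + 2L
    morph <- age_to_morphology(age, model, n_beats = n_max)
    period <- 60 / morph$heart_rate
    starts <- 0.04 + (seq_len(n_max) - 1L) * period
    keep <- starts + morph$beats$qt * 1.05 < duration
    starts <- starts[keep]
    beats <- morph$beats[keep, , drop = FALSE]
    base <- numeric(n_samp)
    for (b in seq_along(starts)) {
      for (w in c("p", "q", "r", "s", "t")) {
        a <- beats[[paste0(w, "_amp")]][b]
        if (a == 0) next
        ctr <- starts[b] + beats[[paste0(w, "_center")]][b]
        sig <- beats[[paste0(w, "_width")]][b]
        lo <- max(1L, floor((ctr - 4 * sig) * rate) + 1L)
        hi <- min(n_samp, ceiling((ctr + 4 * sig) * rate) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        base[idx] <- base[idx] +
          a * exp(-((tgrid[idx] - ctr)^2) / (2 * sig^2))
      }
    }
    signal <- matrix(0, nrow = 12L, ncol = n_samp)
    phase <- runif(12L, 0, 2 * pi)
    for (l in 1:12) {
      lead <- model$lead_weights[l] * base
      if (model$wander_amp > 0)
        lead <- lead + model$wander_amp *
          sin(2 * pi * model$wander_freq * tgrid + phase[l])
      if (model$noise_mv > 0)
        lead <- lead + rnorm(n_samp, 0, model$noise_mv)
      signal[l, ] <- lead
    }
    ann <- data.frame(
      beat = seq_along(starts) - 1L,
      p_on = as.integer(round(starts * rate)),
      qrs_on = as.integer(round((starts + beats$pr) * rate)),
      qrs_off = as.integer(round((starts + beats$pr + beats$qrs) * rate)),
      t_off = as.integer(round((starts + beats$pr + beats$qt) * rate)))
    ann <- ann[ann$t_off < n_samp, , drop = FALSE]
    new_ecg_record(signal, rate, duration, age, patient_id, record_id, ann)
  })
}

new_ecg_record <- function(signal, rate, duration, age, patient_id,
                           record_id, annotations) {
  if (nrow(signal) != 12L)
    stop_ecg("ECG record must have exactly 12 leads (got %d)", nrow(signal))
  structure(list(signal = signal, rate = rate, duration = duration,
                 age = age, patient_id = patient_id, record_id = record_id,
                 annotations = annotations),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> patient %s, age %.1f y, 12 x %d @ %g Hz, %d annotated beats\n",
              x$record_id, x$patient_id, x$age, ncol(x$signal), x$rate,
              nrow(x$annotations)))
  invisible(x)
}

# Left-skewed cohort ages: skew-normal draw truncated to [0, 95].
draw_ages <- function(n, model = age_morphology_model()) {
  a <- model$age_shape
  delta <- a / sqrt(1 + a^2)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 16L)
    z0 <- abs(rnorm(m)); z1 <- rnorm(m)
    x <- model$age_loc +
      model$age_scale * (delta * z0 + sqrt(1 - delta^2) * z1)
    out <- c(out, x[x >= 0 & x <= 95])
  }
  out[seq_len(n)]
}

#' Generate a synthetic annotated ECG cohort
#'
#' Ages are drawn from a left-skewed (truncated skew-normal) distribution on
#' \[0, 95\]; patients are shuffled and assigned round-robin to 10 folds, so
#' all records of one patient share a fold (patient-level split).
#'
#' @param n_patients number of patients (>= 1).
#' @param records_per_patient records synthesized per patient.
#' @param rate sampling rate (Hz) for the synthesized records.
#' @param duration record duration (s).
#' @param model an \code{\link{age_morphology_model}}.
#' @param seed optional integer seed; the same seed reproduces the cohort
#'   bit for bit.
#' @return List with \code{table} (data frame \code{patient_id, record_id,
#'   age, fold_id}) and \code{records} (list of \code{ecg_record}, one per
#'   table row).
#' @export
generate_cohort <- function(n_patients, records_per_patient = 1L,
                            rate = 500, duration = 10,
                            model = age_morphology_model(), seed = NULL) {
  check_number(n_patients, "n_patients", 1)
  with_seed(seed, {
    ages <- draw_ages(n_patients, model)
    folds <- (sample.int(n_patients) - 1L) %% 10L
    rows <- vector("list", n_patients * records_per_patient)
    recs <- vector("list", n_patients * records_per_patient)
    k <- 0L
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%05d", p)
      for (r in seq_len(records_per_patient)) {
        k <- k + 1L
        rid <- sprintf("%s_%02d", pid, r)
        recs[[k]] <- synthesize_record(ages[p], rate, duration, model,
                                       patient_id = pid, record_id = rid)
        rows[[k]] <- data.frame(patient_id = pid, record_id = rid,
                                age = ages[p], fold_id = folds[p])
      }
    }
    list(table = do.call(rbind, rows), records = recs)
  })
}
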