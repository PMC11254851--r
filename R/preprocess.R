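#' Resample a record to a new sampling rate
#'
#' Interpolates every lead independently on the shared time grid; duration
#' is preserved, so the sample count becomes \code{duration * target_rate}.
#' Intermediate acquisition rates (200/300/400 Hz) are meant to be derived
#' from the 100 Hz signal, never downsampled from 500 Hz.
#'
#' @param record an \code{ecg_record}.
#' @param target_rate target rate in Hz.
#' @param method \code{"cubic"} (spline, default), \code{"linear"}, or
#'   \code{"fourier"} (FFT zero-pad/truncate).
#' @return The resampled \code{ecg_record}; annotation indices are rescaled.
#' @export
interpolate_rate <- function(record, target_rate,
                             method = c("cubic", "linear", "fourier")) {
  check_number(target_rate, "target_rate", 0, strict = TRUE)
  method <- match.arg(method)
  if (target_rate == record$rate) return(record)
  n_old <- ncol(record$signal)
  n_new <- round(record$duration * target_rate)
  t_old <- (seq_len(n_old) - 1) / record$rate
  t_new <- (seq_len(n_new) - 1) / target_rate
  out <- matrix(0, 12L, n_new)
  for (l in 1:12) {
    out[l, ] <- switch(method,
      cubic = spline(t_old, record$signal[l, ], xout = t_new,
                     method = "fmm")$y,
      linear = approx(t_old, record$signal[l, ], xout = t_new,
                      rule = 2)$y,
      fourier = fourier_resample(record$signal[l, ], n_new))
  }
  ann <- record$annotations
  if (!is.null(ann) && nrow(ann)) {
    for (cl in c("p_on", "qrs_on", "qrs_off", "t_off"))
      ann[[cl]] <- as.integer(round(ann[[cl]] * target_rate / record$rate))
    ann <- ann[ann$t_off < n_new, , drop = FALSE]
  }
  rec <- record
  rec$signal <- out
  rec$rate <- target_rate
  rec$annotations <- ann
  rec
}

fourier_resample <- function(y, n_new) {
  n <- length(y)
  sp <- fft(y)
  half <- floor(min(n, n_new) / 2)
  out <- complex(n_new)
  out[1] <- sp[1]
  if (half > 1) {
    out[2:half] <- sp[2:half]
    out[(n_new - half + 2):n_new] <- sp[(n - half + 2):n]
  }
  Re(fft(out, inverse = TRUE)) / n
}

#' Keep only the first k seconds of a record
#'
#' @param record an \code{ecg_record}.
#' @param k window length in seconds, \code{0 < k <= duration}.
#' @return The truncated record; beats not fully inside the window are
#'   dropped from the annotations.
#' @export
take_first_seconds <- function(record, k) {
  check_number(k, "k", 0, strict = TRUE)
  if (k > record$duration)
    stop_ecg("k (%g s) exceeds record duration (%g s)", k, record$duration)
  n_keep <- round(k * record$rate)
  rec <- record
  rec$signal <- record$signal[, seq_len(n_keep), drop = FALSE]
  rec$duration <- k
  ann <- record$annotations
  if (!is.null(ann) && nrow(ann))
    rec$annotations <- ann[ann$qrs_on < n_keep & ann$t_off < n_keep, ,
                           drop = FALSE]
  rec
}

#' Zero-pad a signal to the 1,024-sample grid
#'
#' Network input lengths live on a fixed grid: the padded length is the
#' smallest multiple of \code{grid} at or above the raw length, with zeros
#' appended at the end. A 10-s record at 500 Hz (5,000 raw samples) becomes
#' 5,120; at 100 Hz (1,000 raw) it becomes 1,024. The operation is
#' idempotent.
#'
#' @param x a leads x samples matrix (or an \code{ecg_record}, in which
#'   case the padded matrix is returned).
#' @param grid grid unit in samples.
#' @return The zero-padded matrix.
#' @export
pad_to_grid <- function(x, grid = 1024L) {
  if (inherits(x, "ecg_record")) x <- x$signal
  if (!is.matrix(x) || ncol(x) < 1L)
    stop_ecg("pad_to_grid needs a non-empty leads x samples matrix")
  n <- ncol(x)
  target <- as.integer(ceiling(n / grid) * grid)
  if (target == n) return(x)
  cbind(x, matrix(0, nrow(x), target - n))
}

#' Stretch (upsample) a record to an exact number of points
#'
#' Interpolates — rather than zero-pads — every lead to exactly
#' \code{n_points}, e.g. to feed a 2-s signal into a network built for
#' 5,120-point inputs. The duration metadata is preserved; the effective
#' rate becomes \code{n_points / duration}.
#'
#' @param record an \code{ecg_record}.
#' @param n_points target sample count, at least the raw length.
#' @param method interpolation kind, as in \code{\link{interpolate_rate}}.
#' @return The stretched \code{ecg_record}.
#' @export
stretch_to_length <- function(record, n_points,
                              method = c("cubic", "linear", "fourier")) {
  method <- match.arg(method)
  n_old <- ncol(record$signal)
  if (n_points < n_old)
    stop_ecg("n_points (%d) is below the raw length (%d)", n_points, n_old)
  if (n_points == n_old) return(record)
  rec <- interpolate_rate(record, target_rate = n_points / record$duration,
                          method = method)
  # guard against round-off in the sample count
  if (ncol(rec$signal) != n_points)
    rec$signal <- rec$signal[, seq_len(n_points), drop = FALSE]
  rec
}
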