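#' Augmentation policy
#'
#' Bundles an augmentation scheme with its application probability. Flip,
#' reverse and their combination default to probability 0.5 per training
#' batch; random crop is applied to every batch (probability 1) and draws a
#' fresh window each epoch.
#'
#' @param scheme one of \code{"none"}, \code{"flip"}, \code{"reverse"},
#'   \code{"flip_reverse"}, \code{"random_crop"}.
#' @param p_apply probability that a batch is transformed; defaults to 0.5
#'   for flip/reverse/flip_reverse, 1.0 for random_crop.
#' @param crop_seconds window length k (s) for random crop, \code{0 < k <= 10}.
#' @param crop_per draw one crop offset per \code{"record"} (default) or one
#'   per \code{"batch"}.
#' @param seed optional seed recorded on the policy for logging.
#' @return An object of class \code{augment_policy}.
#' @export
augment_policy <- function(scheme = c("none", "flip", "reverse",
                                      "flip_reverse", "random_crop"),
                           p_apply = NULL, crop_seconds = NULL,
                           crop_per = c("record", "batch"), seed = NULL) {
  scheme <- match.arg(scheme)
  crop_per <- match.arg(crop_per)
  if (is.null(p_apply))
    p_apply <- switch(scheme, none = 0, random_crop = 1, 0.5)
  if (p_apply < 0 || p_apply > 1) stop_ecg("p_apply must lie in [0, 1]")
  if (scheme == "random_crop") {
    if (is.null(crop_seconds))
      stop_ecg("random_crop needs `crop_seconds`")
    check_number(crop_seconds, "crop_seconds", 0, strict = TRUE)
  }
  structure(list(scheme = scheme, p_apply = p_apply,
                 crop_seconds = crop_seconds, crop_per = crop_per,
                 seed = seed),
            class = "augment_policy")
}

# batches are arrays of dim (records, 12, samples)
check_batch <- function(batch) {
  if (!is.array(batch) || length(dim(batch)) != 3L || dim(batch)[2] != 12L)
    stop_ecg("a batch must be an array of dim (records, 12, samples)")
  invisible(batch)
}

#' Flip a batch across the zero-volt baseline
#'
#' Negates every amplitude; all leads and all records in the batch are
#' treated identically. An involution: \code{ecg_flip(ecg_flip(x)) == x}.
#' @param batch array of dim (records, 12, samples).
#' @return The flipped batch.
#' @export
ecg_flip <- function(batch) {
  check_batch(batch)
  -batch
}

#' Reverse a batch in time
#'
#' Reverses the sample order identically across the twelve leads, so the
#' cross-lead temporal alignment is preserved. An involution.
#' @inheritParams ecg_flip
#' @return The time-reversed batch.
#' @export
ecg_reverse <- function(batch) {
  check_batch(batch)
  batch[, , rev(seq_len(dim(batch)[3])), drop = FALSE]
}

#' Randomly crop a k-second window from every record
#'
#' Draws a start offset uniformly over \code{{0, ..., (duration - k) * rate}}
#' (sample granularity) and applies the same offset to all 12 leads of a
#' record, so label alignment and cross-lead timing are preserved.
#'
#' @inheritParams ecg_flip
#' @param k window length in seconds.
#' @param rate sampling rate of the batch (Hz).
#' @param per draw one offset per \code{"record"} or a single offset for the
#'   whole \code{"batch"}.
#' @return The cropped batch (records x 12 x k*rate), with the drawn 0-based
#'   start offsets attached as attribute \code{"starts"}.
#' @export
ecg_random_crop <- function(batch, k, rate, per = c("record", "batch")) {
  check_batch(batch)
  per <- match.arg(per)
  n_samp <- dim(batch)[3]
  w <- round(k * rate)
  if (w > n_samp)
    stop_ecg("crop of %g s (%d samples) exceeds record length (%d samples)",
             k, w, n_samp)
  n <- dim(batch)[1]
  max_start <- n_samp - w
  starts <- if (max_start == 0L) rep(0L, n)
            else if (per == "batch")
              rep(sample.int(max_start + 1L, 1L) - 1L, n)
            else sample.int(max_start + 1L, n, replace = TRUE) - 1L
  out <- array(0, dim = c(n, 12L, w))
  for (i in seq_len(n))
    out[i, , ] <- batch[i, , (starts[i] + 1L):(starts[i] + w)]
  attr(out, "starts") <- starts
  out
}

#' Apply an augmentation policy to a training batch
#'
#' One Bernoulli(\code{p_apply}) draw per batch decides whether the scheme
#' is applied; \code{flip_reverse} applies both transforms (they commute).
#' Randomness comes from the session RNG, so seeded runs reproduce exactly.
#'
#' @inheritParams ecg_flip
#' @param policy an \code{\link{augment_policy}}.
#' @param rate sampling rate of the batch (needed for random crop).
#' @return The (possibly) transformed batch; attribute \code{"applied"}
#'   records the Bernoulli outcome.
#' @export
apply_policy <- function(batch, policy, rate = NULL) {
  check_batch(batch)
  if (policy$scheme == "none" || policy$p_apply == 0) {
    attr(batch, "applied") <- FALSE
    return(batch)
  }
  applied <- runif(1) < policy$p_apply
  if (applied) {
    batch <- switch(policy$scheme,
      flip = ecg_flip(batch),
      reverse = ecg_reverse(batch),
      flip_reverse = ecg_reverse(ecg_flip(batch)),
      random_crop = {
        if (is.null(rate)) stop_ecg("random_crop needs the batch `rate`")
        ecg_random_crop(batch, policy$crop_seconds, rate,
                        per = policy$crop_per)
      })
  }
  attr(batch, "applied") <- applied
  batch
}
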