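#' Masking scheme for signal-corruption experiments
#'
#' Describes systematic (PR/QRS/QT) or random masking of ECG segments,
#' applied independently to each lead with probability \code{p_lead}
#' (emulating machine faults and electrode dropout). The random scheme
#' zeroes, per beat, a window whose length equals the record's mean duration
#' of a matched fiducial feature, so systematic and random corruption remove
#' the same amount of signal.
#'
#' @param kind \code{"PR"}, \code{"QRS"}, \code{"QT"} or \code{"random"}.
#' @param p_lead per-lead selection probability (default 0.25).
#' @param fill replacement value in mV (default 0, the signal baseline).
#' @param match for \code{kind = "random"}, the feature whose mean duration
#'   sizes the window (default \code{"QRS"}).
#' @param when apply during \code{"both"} training and evaluation (default)
#'   or \code{"train"} only.
#' @param seed optional seed recorded for logging.
#' @return An object of class \code{mask_scheme}.
#' @export
mask_scheme <- function(kind = c("QRS", "PR", "QT", "random"),
                        p_lead = 0.25, fill = 0,
                        match = c("QRS", "PR", "QT"),
                        when = c("both", "train"), seed = NULL) {
  kind <- match.arg(kind)
  match <- match.arg(match)
  when <- match.arg(when)
  if (p_lead < 0 || p_lead > 1) stop_ecg("p_lead must lie in [0, 1]")
  structure(list(kind = kind, p_lead = p_lead, fill = fill,
                 match = if (kind == "random") match else kind,
                 when = when, seed = seed),
            class = "mask_scheme")
}

# half-open [start, end) columns of the masked interval, 0-based annotations
feature_interval <- function(ann, kind) {
  switch(kind,
         PR = cbind(ann$p_on, ann$qrs_on),
         QRS = cbind(ann$qrs_on, ann$qrs_off),
         QT = cbind(ann$qrs_on, ann$t_off),
         stop_ecg("unknown feature kind `%s`", kind))
}

check_annotated <- function(record) {
  ann <- record$annotations
  if (is.null(ann) || nrow(ann) == 0L)
    stop_ecg(paste("record `%s` carries no beat annotations;",
                   "masking requires fiducial annotations"),
             record$record_id)
  ann
}

#' Mask a fiducial feature interval in randomly selected leads
#'
#' Each lead is selected independently with probability \code{p_lead}; in
#' selected leads, for every annotated beat, the target interval (PR:
#' \code{[P_on, QRS_on)}; QRS: \code{[QRS_on, QRS_off)}; QT:
#' \code{[QRS_on, T_off)}) is set to the fill value. Unselected leads are
#' returned bit-identical.
#'
#' @param record an annotated \code{ecg_record}.
#' @param scheme a \code{\link{mask_scheme}} with a feature \code{kind}.
#' @return The corrupted record; attribute \code{"masked_leads"} gives the
#'   selected lead indices.
#' @export
feature_mask <- function(record, scheme) {
  ann <- check_annotated(record)
  if (scheme$kind == "random")
    stop_ecg("feature_mask needs a feature kind; use random_mask()")
  sel <- which(runif(12L) < scheme$p_lead)
  iv <- feature_interval(ann, scheme$kind)
  rec <- record
  for (l in sel)
    for (b in seq_len(nrow(iv)))
      if (iv[b, 2] > iv[b, 1])
        rec$signal[l, (iv[b, 1] + 1L):iv[b, 2]] <- scheme$fill
  attr(rec, "masked_leads") <- sel
  rec
}

#' Mask random windows matched in length to a fiducial feature
#'
#' In each selected lead, one window per beat is filled at a uniformly
#' random onset within that beat's annotated span; the window length equals
#' the record's mean duration of the matched feature (rounded to samples),
#' so the corruption removes as much signal as the matched systematic mask.
#'
#' @inheritParams feature_mask
#' @return The corrupted record, with attributes \code{"masked_leads"} and
#'   \code{"window_len"}.
#' @export
random_mask <- function(record, scheme) {
  ann <- check_annotated(record)
  iv <- feature_interval(ann, scheme$match)
  w <- as.integer(round(mean(iv[, 2] - iv[, 1])))
  sel <- which(runif(12L) < scheme$p_lead)
  rec <- record
  n_samp <- ncol(record$signal)
  for (l in sel) {
    for (b in seq_len(nrow(ann))) {
      span_lo <- ann$p_on[b]
      span_hi <- min(ann$t_off[b], n_samp)        # never past record end
      lo_max <- span_hi - w
      if (lo_max < span_lo) next                  # beat span shorter than window
      start <- span_lo + sample.int(lo_max - span_lo + 1L, 1L) - 1L
      rec$signal[l, (start + 1L):(start + w)] <- scheme$fill
    }
  }
  attr(rec, "masked_leads") <- sel
  attr(rec, "window_len") <- w
  rec
}

#' Apply a masking scheme to a cached training batch
#'
#' Batch-level counterpart of \code{\link{feature_mask}} /
#' \code{\link{random_mask}} used by the training harness: corruption is
#' drawn independently per record and per lead.
#'
#' @param batch array of dim (records, 12, samples).
#' @param annotations list of per-record annotation data frames.
#' @param scheme a \code{\link{mask_scheme}}.
#' @return The corrupted batch.
#' @export
corrupt_batch <- function(batch, annotations, scheme) {
  check_batch(batch)
  n <- dim(batch)[1]
  n_samp <- dim(batch)[3]
  for (i in seq_len(n)) {
    ann <- annotations[[i]]
    if (is.null(ann) || nrow(ann) == 0L)
      stop_ecg("batch record %d carries no annotations", i)
    ann <- ann[ann$t_off < n_samp, , drop = FALSE]
    if (nrow(ann) == 0L) next
    sel <- which(runif(12L) < scheme$p_lead)
    if (!length(sel)) next
    if (scheme$kind == "random") {
      iv <- feature_interval(ann, scheme$match)
      w <- as.integer(round(mean(iv[, 2] - iv[, 1])))
      for (l in sel)
        for (b in seq_len(nrow(ann))) {
          lo_max <- min(ann$t_off[b], n_samp) - w
          if (lo_max < ann$p_on[b]) next
          start <- ann$p_on[b] + sample.int(lo_max - ann$p_on[b] + 1L, 1L) - 1L
          batch[i, l, (start + 1L):(start + w)] <- scheme$fill
        }
    } else {
      iv <- feature_interval(ann, scheme$kind)
      for (l in sel)
        for (b in seq_len(nrow(iv)))
          if (iv[b, 2] > iv[b, 1])
            batch[i, l, (iv[b, 1] + 1L):iv[b, 2]] <- scheme$fill
    }
  }
  batch
}
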