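#' Write an ECG record in WFDB format
#'
#' Emits a WFDB header (\code{.hea}) and a format-16 signal file
#' (\code{.dat}): 16-bit little-endian integers, interleaved across the 12
#' leads, gain 1000 ADU/mV so one least-significant bit is 1 microvolt.
#'
#' @param record an \code{ecg_record}.
#' @param dir output directory (created if needed).
#' @param name base record name; defaults to the record id.
#' @return Invisibly, the path of the header file.
#' @export
write_wfdb <- function(record, dir, name = record$record_id) {
  if (!inherits(record, "ecg_record")) stop_ecg("`record` must be an ecg_record")
  if (any(abs(record$signal) > 32.767))
    stop_ecg("amplitudes exceed the 16-bit range at 1 uV/LSB (|x| > 32.767 mV)")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  adu <- round(record$signal * 1000)
  storage.mode(adu) <- "integer"
  n_sig <- nrow(adu); n_samp <- ncol(adu)
  dat <- file.path(dir, paste0(name, ".dat"))
  hea <- file.path(dir, paste0(name, ".hea"))
  con <- file(dat, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.integer(as.vector(adu)), con, size = 2L, endian = "little")
  chks <- vapply(seq_len(n_sig), function(l) {
    s <- sum(as.numeric(adu[l, ])) %% 65536
    if (s > 32767) s <- s - 65536
    s
  }, numeric(1))
  lines <- c(sprintf("%s %d %g %d", name, n_sig, record$rate, n_samp),
             sprintf("%s.dat 16 1000(0)/mV 16 0 %d %d 0 lead%d",
                     name, adu[, 1], as.integer(chks), seq_len(n_sig)))
  writeLines(lines, hea)
  invisible(hea)
}

#' Read a WFDB record
#'
#' Parses a format-16 WFDB header/signal pair written by
#' \code{\link{write_wfdb}} (or any single-segment 12-lead format-16 record
#' with a common gain). Amplitudes are returned in mV.
#'
#' @param path record path without extension (or the \code{.hea} path).
#' @param annotations optional data frame of beat annotations to attach.
#' @return An \code{ecg_record} (age and ids are \code{NA} unless supplied
#'   by the caller through the cohort metadata).
#' @export
read_wfdb <- function(path, annotations = NULL) {
  path <- sub("\\.hea$", "", path)
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop_ecg("WFDB header not found: %s", hea)
  lines <- readLines(hea)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_sig <- as.integer(hdr[2]); rate <- as.numeric(hdr[3])
  n_samp <- as.integer(hdr[4])
  if (is.na(n_sig) || is.na(rate) || is.na(n_samp))
    stop_ecg("malformed WFDB header: %s", hea)
  if (n_sig != 12L)
    stop_ecg("expected 12 leads, header declares %d signals", n_sig)
  sig_specs <- strsplit(trimws(lines[2:(1 + n_sig)]), "\\s+")
  dat <- file.path(dirname(hea), sig_specs[[1]][1])
  if (!file.exists(dat)) stop_ecg("WFDB signal file not found: %s", dat)
  gains <- vapply(sig_specs, function(s)
    as.numeric(sub("\\(.*$", "", sub("/.*$", "", s[3]))), numeric(1))
  con <- file(dat, "rb")
  on.exit(close(con), add = TRUE)
  raw <- readBin(con, "integer", n = n_sig * n_samp, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) != n_sig * n_samp)
    stop_ecg("WFDB signal file truncated: %s", dat)
  adu <- matrix(raw, nrow = n_sig)
  signal <- adu / gains
  new_ecg_record(signal, rate, n_samp / rate, NA_real_, NA_character_,
                 basename(path), annotations)
}

#' Write a cohort (records, metadata and annotation sidecar) to disk
#'
#' @param cohort list with \code{table} and \code{records} as produced by
#'   \code{\link{generate_cohort}}.
#' @param dir output directory.
#' @return Invisibly, the metadata CSV path.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (rec in cohort$records) write_wfdb(rec, dir)
  meta <- file.path(dir, "metadata.csv")
  tab <- cohort$table
  tab$age <- sprintf("%.17g", tab$age)   # ages must survive the round trip
  write.csv(tab, meta, row.names = FALSE, quote = FALSE)
  ann <- do.call(rbind, lapply(cohort$records, function(r) {
    if (is.null(r$annotations) || nrow(r$annotations) == 0L) return(NULL)
    data.frame(record_id = r$record_id, beat_idx = r$annotations$beat,
               p_on = r$annotations$p_on, qrs_on = r$annotations$qrs_on,
               qrs_off = r$annotations$qrs_off, t_off = r$annotations$t_off)
  }))
  write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(meta)
}

#' Load a cohort into a dense in-memory cache
#'
#' Reads every record referenced by the metadata table into one contiguous
#' array block of shape (records x 12 x T_max) with aligned age, fold and
#' valid-length vectors, keyed by record id (row order of the CSV does not
#' matter). The cache is the unit the training harness iterates over, so
#' epoch iteration does no file I/O.
#'
#' @param metadata_csv path of the cohort metadata CSV
#'   (\code{patient_id, record_id, age, fold_id}).
#' @param records_dir directory holding the WFDB files (and, optionally,
#'   \code{annotations.csv}).
#' @return An object of class \code{ecg_cohort_cache}.
#' @export
load_cohort <- function(metadata_csv, records_dir) {
  meta <- read.csv(metadata_csv, stringsAsFactors = FALSE)
  need <- c("patient_id", "record_id", "age", "fold_id")
  if (!all(need %in% names(meta)))
    stop_ecg("metadata must have columns %s", paste(need, collapse = ", "))
  meta <- meta[order(meta$record_id), , drop = FALSE]
  ann_path <- file.path(records_dir, "annotations.csv")
  ann_all <- if (file.exists(ann_path))
    read.csv(ann_path, stringsAsFactors = FALSE) else NULL
  recs <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    rid <- meta$record_id[i]
    base <- file.path(records_dir, rid)
    if (!file.exists(paste0(base, ".hea")))
      stop_ecg("record `%s` listed in metadata but missing on disk", rid)
    ann <- NULL
    if (!is.null(ann_all)) {
      sub <- ann_all[ann_all$record_id == rid, , drop = FALSE]
      if (nrow(sub))
        ann <- data.frame(beat = sub$beat_idx, p_on = sub$p_on,
                          qrs_on = sub$qrs_on, qrs_off = sub$qrs_off,
                          t_off = sub$t_off)
    }
    recs[[i]] <- read_wfdb(base, annotations = ann)
    recs[[i]]$age <- meta$age[i]
    recs[[i]]$patient_id <- meta$patient_id[i]
  }
  cohort_cache(recs, meta)
}

#' Build a cohort cache directly from in-memory records
#'
#' @param records list of \code{ecg_record}.
#' @param table cohort table aligned with \code{records} (matched by
#'   record id).
#' @return An object of class \code{ecg_cohort_cache}: list with
#'   \code{signals} (records x 12 x T_max array, zero-padded), per-record
#'   \code{valid_len}, \code{age}, \code{fold}, \code{record_id},
#'   \code{patient_id}, \code{rate} and \code{annotations}.
#' @export
cohort_cache <- function(records, table) {
  ids <- vapply(records, function(r) r$record_id, character(1))
  table <- table[match(ids, table$record_id), , drop = FALSE]
  if (any(is.na(table$record_id)))
    stop_ecg("cohort table is missing rows for some records")
  lens <- vapply(records, function(r) ncol(r$signal), integer(1))
  tmax <- max(lens)
  block <- array(0, dim = c(length(records), 12L, tmax))
  for (i in seq_along(records))
    block[i, , seq_len(lens[i])] <- records[[i]]$signal
  structure(list(signals = block, valid_len = lens,
                 age = as.numeric(table$age),
                 fold = as.integer(table$fold_id),
                 record_id = ids, patient_id = table$patient_id,
                 rate = records[[1]]$rate,
                 annotations = lapply(records, function(r) r$annotations)),
            class = "ecg_cohort_cache")
}

#' @export
print.ecg_cohort_cache <- function(x, ...) {
  cat(sprintf("<ecg_cohort_cache> %d records @ %g Hz, T_max %d, folds {%s}\n",
              length(x$record_id), x$rate, dim(x$signals)[3],
              paste(sort(unique(x$fold)), collapse = ",")))
  invisible(x)
}

#' Persist / restore a cohort cache
#'
#' The cache is one self-contained container of aligned arrays; these two
#' helpers serialize it to a single file so repeated experiments skip the
#' WFDB parse.
#' @param cache an \code{ecg_cohort_cache}.
#' @param path file path.
#' @return \code{load_cache} returns the cache; \code{save_cache} its path,
#'   invisibly.
#' @export
save_cache <- function(cache, path) {
  saveRDS(cache, path)
  invisible(path)
}

#' @rdname save_cache
#' @export
load_cache <- function(path) readRDS(path)
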