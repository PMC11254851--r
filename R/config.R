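#' Reduced (desk-scale) architecture configurations
#'
#' Down-scaled variants of the two canonical networks keeping their block
#' structure (four temporal blocks / four residual blocks) but with small
#' filter counts, suitable for CPU-scale experiments on synthetic cohorts.
#'
#' @return An \code{attianet_config} / \code{resnet1d_config}.
#' @export
reduced_attianet_config <- function() {
  attianet_config(filters = c(4, 8, 16, 16), kernels = c(7, 5, 5, 3),
                  pools = c(8L, 4L, 4L, 2L), spatial_filters = 4L,
                  head = c(16L, 8L))
}

#' @rdname reduced_attianet_config
#' @export
reduced_resnet1d_config <- function() {
  resnet1d_config(stem_filters = 8L, stem_kernels = 7L,
                  channels = c(8L, 16L, 24L, 32L, 40L), kernel = 9L,
                  reduction = 4L, dropout = 0.1, head_width = 8L)
}

config_defaults <- function() {
  list(experiment = NULL,
       model = list(arch = "attianet", reduced = TRUE),
       rates = c(100, 200, 300, 400, 500),
       durations = c(2, 4, 6, 8, 10),
       schedule = c(8000, 4000, 2000, 1000, 500, 250, 125),
       augment = list(scheme = "none", p_apply = NULL, crop_seconds = NULL,
                      crop_per = "record"),
       corrupt = list(kind = "none", p_lead = 0.25, fill = 0,
                      match = "QRS", when = "both"),
       train = list(epochs = 200L, batch_size = 96L, lr = 1e-3,
                    decay_factor = 0.1, decay_every = 80L),
       cohort = list(n_patients = 200L, records_per_patient = 1L,
                     rate = 500, duration = 10,
                     metadata = NULL, records_dir = NULL),
       folds = NULL, outdir = NULL, seed = 1L)
}

#' Validate and normalize an experiment configuration
#'
#' Accepts a YAML file path or a nested list; unknown keys are rejected
#' (strict schema), defaults are filled in (epochs 200, batch size 96,
#' learning rate 0.001, ...), and units are normalized (rates in Hz,
#' durations in seconds, both numeric and positive).
#'
#' @param x path of a YAML config or a named list.
#' @return A normalized config list of class \code{run_config}.
#' @export
validate_config <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  if (!is.list(x)) stop_ecg("config must be a YAML file or a named list")
  def <- config_defaults()
  bad <- setdiff(names(x), names(def))
  if (length(bad))
    stop_ecg("unknown config keys: %s (valid: %s)",
             paste(bad, collapse = ", "), paste(names(def), collapse = ", "))
  cfg <- utils::modifyList(def, x)
  for (sub in c("model", "augment", "corrupt", "train", "cohort")) {
    extra <- setdiff(names(x[[sub]]), names(def[[sub]]))
    if (length(extra))
      stop_ecg("unknown keys in `%s`: %s (valid: %s)", sub,
               paste(extra, collapse = ", "),
               paste(names(def[[sub]]), collapse = ", "))
  }
  valid_exp <- c("sampling_rate", "duration", "augmentation", "corruption",
                 "transfer")
  if (is.null(cfg$experiment) || !(cfg$experiment %in% valid_exp))
    stop_ecg("experiment must be one of: %s", paste(valid_exp, collapse = ", "))
  if (!(cfg$model$arch %in% c("attianet", "resnet1d")))
    stop_ecg("model arch must be attianet or resnet1d")
  cfg$rates <- as.numeric(cfg$rates)
  if (any(cfg$rates <= 0)) stop_ecg("rates must be positive (Hz)")
  cfg$durations <- as.numeric(cfg$durations)
  if (any(cfg$durations <= 0)) stop_ecg("durations must be positive (s)")
  cfg$cohort$rate <- as.numeric(cfg$cohort$rate)
  cfg$cohort$duration <- as.numeric(cfg$cohort$duration)
  check_number(cfg$cohort$rate, "cohort$rate", 0, strict = TRUE)
  check_number(cfg$cohort$duration, "cohort$duration", 0, strict = TRUE)
  cfg$train <- do.call(train_config, c(cfg$train, list(seed = cfg$seed)))
  class(cfg) <- "run_config"
  cfg
}

config_builder <- function(model) {
  if (model$arch == "attianet") {
    conf <- if (isTRUE(model$reduced)) reduced_attianet_config()
            else attianet_config()
    function(input_len) build_attianet(conf, input_len)
  } else {
    conf <- if (isTRUE(model$reduced)) reduced_resnet1d_config()
            else resnet1d_config()
    function(input_len) build_resnet1d(conf, input_len)
  }
}

grid_len <- function(n) as.integer(ceiling(n / 1024) * 1024)

experiment_cohort <- function(cfg) {
  ch <- cfg$cohort
  if (!is.null(ch$metadata))
    return(load_cohort(ch$metadata, ch$records_dir))
  co <- generate_cohort(ch$n_patients, ch$records_per_patient,
                        rate = ch$rate, duration = ch$duration,
                        seed = cfg$seed)
  cohort_cache(co$records, co$table)
}

log_line <- function(con, event, data = list()) {
  writeLines(jsonlite::toJSON(c(list(event = event, time = format(Sys.time())),
                                data), auto_unbox = TRUE), con)
}

#' Run a named experiment template
#'
#' Dispatches on \code{config$experiment} (\code{sampling_rate},
#' \code{duration}, \code{augmentation}, \code{corruption},
#' \code{transfer}), generates or loads the cohort, trains with 10-fold
#' cross-validation per condition and writes one CSV of per-condition mean
#' test errors plus a JSON-lines log (config and seeds) into the output
#' directory.
#'
#' @param config a \code{\link{validate_config}} result, list or YAML path.
#' @return Invisibly, the result data frame (also written to
#'   \code{<outdir>/<experiment>.csv} when \code{outdir} is set).
#' @export
run_experiment <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  logcon <- NULL
  if (!is.null(cfg$outdir)) {
    if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
    logcon <- file(file.path(cfg$outdir, "run_log.jsonl"), "w")
    on.exit(close(logcon), add = TRUE)
    log_line(logcon, "start",
             list(experiment = cfg$experiment, seed = cfg$seed))
  }
  builder <- config_builder(cfg$model)
  res <- switch(cfg$experiment,
    sampling_rate = exp_sampling_rate(cfg, builder),
    duration = exp_duration(cfg, builder),
    augmentation = exp_augmentation(cfg, builder),
    corruption = exp_corruption(cfg, builder),
    transfer = exp_transfer(cfg, builder))
  if (!is.null(cfg$outdir)) {
    out <- file.path(cfg$outdir, paste0(cfg$experiment, ".csv"))
    write.csv(res, out, row.names = FALSE)
    log_line(logcon, "done", list(rows = nrow(res), csv = out))
  }
  invisible(res)
}

cv_condition <- function(builder, cache_rate, cfg, policy = NULL,
                         scheme = NULL, duration = NULL) {
  dur <- duration %||% cfg$cohort$duration
  len <- grid_len(round(dur * cache_rate$rate))
  cv <- cross_validate(builder, cache_rate, len, cfg$train,
                       policy = policy, scheme = scheme, folds = cfg$folds)
  c(mean_test_mse = cv$mean_test_mse, mean_test_mae = cv$mean_test_mae)
}

exp_sampling_rate <- function(cfg, builder) {
  master <- with_seed(cfg$seed, generate_cohort(
    cfg$cohort$n_patients, cfg$cohort$records_per_patient, rate = 500,
    duration = cfg$cohort$duration))
  rec100 <- lapply(master$records, interpolate_rate, target_rate = 100)
  rows <- lapply(cfg$rates, function(r) {
    recs <- if (r == 500) master$records
            else if (r == 100) rec100
            else lapply(rec100, interpolate_rate, target_rate = r)
    cache <- cohort_cache(recs, master$table)
    m <- cv_condition(builder, cache, cfg)
    data.frame(rate_hz = r, mean_test_mse = m[1], mean_test_mae = m[2])
  })
  do.call(rbind, rows)
}

exp_duration <- function(cfg, builder) {
  master <- with_seed(cfg$seed, generate_cohort(
    cfg$cohort$n_patients, cfg$cohort$records_per_patient,
    rate = cfg$cohort$rate, duration = cfg$cohort$duration))
  rows <- lapply(cfg$durations, function(k) {
    recs <- lapply(master$records, take_first_seconds, k = k)
    cache <- cohort_cache(recs, master$table)
    m <- cv_condition(builder, cache, cfg, duration = k)
    data.frame(duration_s = k, mean_test_mse = m[1], mean_test_mae = m[2])
  })
  do.call(rbind, rows)
}

exp_augmentation <- function(cfg, builder) {
  cache <- experiment_cohort(cfg)
  schemes <- c("none", "flip", "reverse", "flip_reverse")
  rows <- lapply(schemes, function(s) {
    pol <- if (s == "none") NULL else augment_policy(s)
    m <- cv_condition(builder, cache, cfg, policy = pol)
    data.frame(scheme = s, mean_test_mse = m[1], mean_test_mae = m[2])
  })
  do.call(rbind, rows)
}

exp_corruption <- function(cfg, builder) {
  cache <- experiment_cohort(cfg)
  kinds <- c("none", "PR", "QRS", "QT", "random")
  pol <- if (cfg$augment$scheme == "none") NULL
         else do.call(augment_policy, cfg$augment)
  rows <- lapply(kinds, function(k) {
    sch <- if (k == "none") NULL
           else mask_scheme(k, p_lead = cfg$corrupt$p_lead,
                            fill = cfg$corrupt$fill,
                            match = cfg$corrupt$match,
                            when = cfg$corrupt$when)
    m <- cv_condition(builder, cache, cfg, policy = pol, scheme = sch)
    data.frame(kind = k, mean_test_mse = m[1], mean_test_mae = m[2])
  })
  do.call(rbind, rows)
}

exp_transfer <- function(cfg, builder) {
  model_a <- age_morphology_model()
  model_b <- shift_population(model_a, seed = cfg$seed + 1L)
  ch <- cfg$cohort
  co_a <- generate_cohort(ch$n_patients, ch$records_per_patient,
                          rate = ch$rate, duration = ch$duration,
                          model = model_a, seed = cfg$seed + 2L)
  co_b <- generate_cohort(ch$n_patients, ch$records_per_patient,
                          rate = ch$rate, duration = ch$duration,
                          model = model_b, seed = cfg$seed + 3L)
  len <- grid_len(round(ch$duration * ch$rate))
  rc <- regime_curve(builder, cohort_cache(co_a$records, co_a$table),
                     cohort_cache(co_b$records, co_b$table), len,
                     schedule = cfg$schedule, cfg_pre = cfg$train,
                     cfg_ft = cfg$train)
  rc$table
}
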