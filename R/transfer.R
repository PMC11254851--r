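#' Uniformly subsample training records
#'
#' Draws \code{n} record indices uniformly without replacement from the
#' training portion of the cohort (all folds except the test/validation
#' folds), used to emulate fine-tuning with shrinking dataset sizes.
#'
#' @param cache an \code{ecg_cohort_cache}.
#' @param n subset size.
#' @param exclude_folds folds excluded from sampling (test/validation).
#' @param seed optional seed.
#' @return Integer vector of record indices into the cache.
#' @export
subsample_train <- function(cache, n, exclude_folds = integer(0),
                            seed = NULL) {
  ord <- order(cache$record_id)
  pool <- ord[!(cache$fold[ord] %in% exclude_folds)]
  if (n > length(pool))
    stop_ecg("requested %d records but only %d are available", n,
             length(pool))
  if (n == length(pool)) return(pool)
  with_seed(seed, sort(pool[sample.int(length(pool), n)]))
}

# restrict a cache to a subset of records (keeps alignment of all vectors)
cache_subset <- function(cache, idx) {
  structure(list(signals = cache$signals[idx, , , drop = FALSE],
                 valid_len = cache$valid_len[idx], age = cache$age[idx],
                 fold = cache$fold[idx], record_id = cache$record_id[idx],
                 patient_id = cache$patient_id[idx], rate = cache$rate,
                 annotations = cache$annotations[idx]),
            class = "ecg_cohort_cache")
}

#' Fine-tune a pretrained residual network on a (subsampled) cohort
#'
#' Freezes the network through the third residual block (the fourth block
#' and the head stay trainable), optionally restricts the training split to
#' \code{n} uniformly drawn records, and otherwise trains exactly like
#' \code{\link{train_fold}}.
#'
#' @param pretrained an \code{ecg_model} carrying pretrained weights.
#' @param cache target-population \code{ecg_cohort_cache}.
#' @param fold test fold id.
#' @param cfg a \code{\link{train_config}}.
#' @param n optional training-subset size (default: full training split).
#' @param boundary freeze boundary passed to \code{\link{freeze_scope}}.
#' @param ... passed to \code{\link{train_fold}}.
#' @return An \code{ecgage_fit}.
#' @export
finetune <- function(pretrained, cache, fold, cfg = train_config(),
                     n = NULL, boundary = "through_resblock3", ...) {
  graph <- freeze_scope(pretrained, boundary)
  if (!is.null(n)) {
    folds_all <- sort(unique(cache$fold))
    nxt <- (fold + 1L) %% 10L
    val_fold <- if (nxt %in% folds_all) nxt
                else folds_all[(match(fold, folds_all) %% length(folds_all)) + 1L]
    ord <- order(cache$record_id)
    keep_eval <- ord[cache$fold[ord] %in% c(fold, val_fold)]
    tr <- subsample_train(cache, n, exclude_folds = c(fold, val_fold),
                          seed = cfg$seed)
    cache <- cache_subset(cache, sort(c(keep_eval, tr)))
  }
  train_fold(graph, cache, fold, cfg, pretrained = TRUE, ...)
}

#' Fine-tuning versus scratch-training regime curve
#'
#' Pretrains on a source cohort, then for every subset size of the schedule
#' fine-tunes the pretrained network and trains a fresh network from
#' scratch on the same target subsets, evaluating both on the identical
#' target test fold (paired design). The zero-shot row (pretrained network
#' evaluated untouched) is included as size \code{NA}.
#'
#' @param builder function \code{(input_len) -> ecg_model} for the residual
#'   architecture.
#' @param cache_source,cache_target source/target cohort caches (the two
#'   populations differ in their age-morphology maps).
#' @param input_len network input length.
#' @param schedule subset sizes, by default halving from 8,000 to 125.
#' @param cfg_pre,cfg_ft train configs for pretraining and for the
#'   fine-tune/scratch arms.
#' @param fold target test fold.
#' @return An object of class \code{ecgage_regime}: list with the result
#'   \code{table} (columns \code{n, regime, test_mse, test_mae}) and the
#'   pretrained graph.
#' @export
regime_curve <- function(builder, cache_source, cache_target, input_len,
                         schedule = c(8000, 4000, 2000, 1000, 500, 250, 125),
                         cfg_pre = train_config(), cfg_ft = cfg_pre,
                         fold = 0L) {
  pre_fit <- with_seed(cfg_pre$seed, {
    g <- builder(input_len)
    train_fold(g, cache_source, fold = sort(unique(cache_source$fold))[1],
               cfg = cfg_pre)
  })
  pretrained <- pre_fit$graph
  folds_all <- sort(unique(cache_target$fold))
  nxt <- (fold + 1L) %% 10L
  val_fold <- if (nxt %in% folds_all) nxt
              else folds_all[(match(fold, folds_all) %% length(folds_all)) + 1L]
  idx_test <- which(cache_target$fold == fold)
  zs_pred <- eval_indices(pretrained, cache_target, idx_test, cfg_ft,
                          NULL, NULL)
  zs <- age_metrics(zs_pred, cache_target$age[idx_test])
  rows <- list(data.frame(n = NA_integer_, regime = "zero_shot",
                          test_mse = zs$mse, test_mae = zs$mae_mean))
  for (n in schedule) {
    ft <- finetune(pretrained, cache_target, fold, cfg_ft, n = n)
    sc_graph <- with_seed(cfg_ft$seed, builder(input_len))
    tr <- subsample_train(cache_target, n,
                          exclude_folds = c(fold, val_fold),
                          seed = cfg_ft$seed)
    keep_eval <- which(cache_target$fold %in% c(fold, val_fold))
    sub <- cache_subset(cache_target, sort(c(keep_eval, tr)))
    sc <- train_fold(sc_graph, sub, fold, cfg_ft)
    rows <- c(rows, list(
      data.frame(n = n, regime = "finetune", test_mse = ft$test$mse,
                 test_mae = ft$test$mae_mean),
      data.frame(n = n, regime = "scratch", test_mse = sc$test$mse,
                 test_mae = sc$test$mae_mean)))
  }
  structure(list(table = do.call(rbind, rows), pretrained = pretrained,
                 schedule = schedule, fold = fold),
            class = "ecgage_regime")
}

#' @export
print.ecgage_regime <- function(x, ...) {
  cat("<ecgage_regime> fine-tune vs scratch on the target population\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Shift an age-morphology model to emulate a second population
#'
#' Perturbs the age-to-interval slopes by a relative factor and redraws the
#' lead projection around the source population's weights, the controllable
#' analog of cross-ethnicity ECG waveform variability. The default
#' perturbation scale is set so a network pretrained on the source
#' population degrades markedly — but not catastrophically — when evaluated
#' untouched on the target, the regime in which transfer-learning
#' comparisons are meaningful.
#'
#' @param model an \code{\link{age_morphology_model}}.
#' @param slope_shift relative slope perturbation (default +/-20 percent,
#'   alternating sign across quantities).
#' @param projection_jitter half-width of the uniform perturbation added to
#'   each lead weight when redrawing the projection (clipped to \[-1, 1\]).
#' @param seed seed for the redrawn lead projection.
#' @return A shifted \code{age_morphology_model}.
#' @export
shift_population <- function(model, slope_shift = 0.2,
                             projection_jitter = 0.3, seed = NULL) {
  with_seed(seed, {
    sgn <- c(1, -1, 1, -1, 1, -1)
    qs <- c("hr", "pr", "qrs", "qt", "r_amp", "t_amp")
    for (i in seq_along(qs))
      model[[qs[i]]][2] <- model[[qs[i]]][2] * (1 + sgn[i] * slope_shift)
    w <- model$lead_weights + runif(12L, -projection_jitter,
                                    projection_jitter)
    w <- pmin(pmax(w, -1), 1)
    if (!any(w < 0)) w[which.min(w)] <- -abs(w[which.min(w)])
    model$lead_weights <- w
    validate_age_morphology_model(model)
  })
}
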