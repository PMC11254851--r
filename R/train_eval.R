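#' Training configuration
#'
#' Defaults follow the study protocol: mean-squared-error loss, Adam,
#' 200 epochs, batch size 96, initial learning rate 0.001 decayed by a
#' factor of 10 every 80 epochs, with the network weights checkpointed at
#' the epoch of minimum validation MSE.
#'
#' @param epochs training epochs.
#' @param batch_size records per batch.
#' @param lr initial learning rate.
#' @param decay_factor multiplicative learning-rate decay.
#' @param decay_every epochs between decays.
#' @param bn_momentum running-statistics momentum of batch normalization.
#' @param init_output_bias initialize the output bias at the mean training
#'   age (ignored for pretrained graphs)?
#' @param eval_crop evaluation input for crop-trained models:
#'   deterministic \code{"first"}-k crop (default) or \code{"none"}.
#' @param seed integer seed controlling fold training end to end.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(epochs = 200L, batch_size = 96L, lr = 1e-3,
                         decay_factor = 0.1, decay_every = 80L,
                         bn_momentum = 0.1, init_output_bias = TRUE,
                         eval_crop = c("first", "none"), seed = NULL) {
  check_number(epochs, "epochs", 0)
  check_number(batch_size, "batch_size", 1)
  check_number(lr, "lr", 0, strict = TRUE)
  check_number(decay_every, "decay_every", 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 decay_factor = decay_factor,
                 decay_every = as.integer(decay_every),
                 bn_momentum = bn_momentum,
                 init_output_bias = isTRUE(init_output_bias),
                 eval_crop = match.arg(eval_crop), seed = seed),
            class = "train_config")
}

#' Learning rate at a given epoch under the step-decay schedule
#' @param cfg a \code{\link{train_config}}.
#' @param epoch 1-based epoch index.
#' @return The learning rate (e.g. 1e-3 for epochs 1-80, 1e-4 from 81,
#'   1e-5 from 161 under defaults).
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$lr * cfg$decay_factor^floor((epoch - 1) / cfg$decay_every)
}

# copy the raw (valid-length) signals for `idx` into an (n, 12, len) array
gather_batch <- function(cache, idx, len = NULL) {
  vl <- min(cache$valid_len[idx])
  if (is.null(len)) len <- vl
  out <- array(0, dim = c(length(idx), 12L, len))
  take <- min(vl, len)
  out[, , seq_len(take)] <- cache$signals[idx, , seq_len(take), drop = FALSE]
  out
}

pad_batch <- function(batch, input_len) {
  n_samp <- dim(batch)[3]
  if (n_samp == input_len) return(batch)
  if (n_samp > input_len)
    stop_ecg("batch length %d exceeds graph input length %d",
             n_samp, input_len)
  out <- array(0, dim = c(dim(batch)[1], dim(batch)[2], input_len))
  out[, , seq_len(n_samp)] <- batch
  out
}

adam_init <- function() new.env(parent = emptyenv())

adam_step <- function(graph, grads, opt, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    ly <- graph$layers[[nm]]
    if (isTRUE(ly$frozen)) next
    for (p in names(grads[[nm]])) {
      key <- paste(nm, p, sep = ".")
      g <- grads[[nm]][[p]]
      st <- opt[[key]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      opt[[key]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      graph$layers[[nm]][[p]] <- ly[[p]] - upd
    }
  }
  graph
}

snapshot_params <- function(graph) {
  lapply(graph$layers, function(ly) {
    out <- lapply(param_names(ly), function(p) ly[[p]])
    names(out) <- param_names(ly)
    if (ly$kind == "batchnorm") {
      out$rmean <- ly$rmean; out$rvar <- ly$rvar
    }
    out
  })
}

restore_params <- function(graph, snap) {
  for (nm in names(snap))
    for (p in names(snap[[nm]]))
      graph$layers[[nm]][[p]] <- snap[[nm]][[p]]
  graph
}

# one evaluation pass over `idx`, honoring crop/corruption settings
eval_indices <- function(graph, cache, idx, cfg, policy, scheme,
                         batch_size = 128L) {
  preds <- numeric(length(idx))
  crop <- !is.null(policy) && policy$scheme == "random_crop" &&
    cfg$eval_crop == "first"
  for (s in split(seq_along(idx), ceiling(seq_along(idx) / batch_size))) {
    b <- gather_batch(cache, idx[s])
    if (!is.null(scheme) && scheme$when == "both")
      b <- corrupt_batch(b, cache$annotations[idx[s]], scheme)
    if (crop) {
      w <- round(policy$crop_seconds * cache$rate)
      b <- b[, , seq_len(min(w, dim(b)[3])), drop = FALSE]
    }
    b <- pad_batch(b, graph$input_len)
    preds[s] <- model_forward(graph, b, training = FALSE)$pred
  }
  preds
}

#' Regression metrics for ECG age estimation
#'
#' @param pred predicted ages.
#' @param ages chronological ages.
#' @return List with \code{mse}, \code{mae_mean}, \code{mae_sd} (SD of the
#'   absolute errors), \code{pred_mean}, \code{pred_sd} and \code{n}.
#' @export
age_metrics <- function(pred, ages) {
  if (length(pred) != length(ages))
    stop_ecg("length mismatch: %d predictions vs %d ages",
             length(pred), length(ages))
  err <- pred - ages
  list(mse = mean(err^2), mae_mean = mean(abs(err)), mae_sd = sd(abs(err)),
       pred_mean = mean(pred), pred_sd = sd(pred), n = length(pred))
}

#' Evaluate a model on preprocessed records
#'
#' @param graph an \code{ecg_model}.
#' @param x array of dim (records, 12, input_len).
#' @param ages chronological ages aligned with \code{x}.
#' @param batch_size evaluation batch size.
#' @return Metrics as in \code{\link{age_metrics}}.
#' @export
evaluate <- function(graph, x, ages, batch_size = 128L) {
  check_batch(x)
  if (dim(x)[1] != length(ages))
    stop_ecg("length mismatch: %d records vs %d ages", dim(x)[1],
             length(ages))
  preds <- numeric(length(ages))
  for (s in split(seq_along(ages), ceiling(seq_along(ages) / batch_size)))
    preds[s] <- model_forward(graph, x[s, , , drop = FALSE],
                              training = FALSE)$pred
  age_metrics(preds, ages)
}

#' Metrics of the mean-age (constant) predictor
#'
#' Baseline against which learned models are judged: predicts the training
#' mean for every test record.
#' @param train_ages,test_ages age vectors.
#' @return List with \code{mse} and \code{mae}.
#' @export
mean_predictor_metrics <- function(train_ages, test_ages) {
  m <- mean(train_ages)
  list(mse = mean((test_ages - m)^2), mae = mean(abs(test_ages - m)))
}

#' Train one cross-validation fold
#'
#' Fold \code{fold} is held out as the test set, fold
#' \code{(fold + 1) mod 10} as the validation set and the remaining folds
#' train the network with MSE loss and Adam under the step-decay schedule.
#' Weights are checkpointed at the epoch of minimum validation MSE and
#' restored before test evaluation. Fully deterministic given
#' \code{cfg$seed}.
#'
#' @param graph an initialized \code{ecg_model} (its input length fixes the
#'   padded batch length).
#' @param cache an \code{ecg_cohort_cache}.
#' @param fold test fold id.
#' @param cfg a \code{\link{train_config}}.
#' @param policy optional \code{\link{augment_policy}} applied to training
#'   batches.
#' @param scheme optional \code{\link{mask_scheme}} (corruption experiment).
#' @param val_fold validation fold id; defaults to \code{(fold + 1) mod 10}
#'   restricted to the folds present.
#' @param pretrained set \code{TRUE} when \code{graph} carries pretrained
#'   weights (keeps the output bias untouched).
#' @return An object of class \code{ecgage_fit}.
#' @export
train_fold <- function(graph, cache, fold, cfg = train_config(),
                       policy = NULL, scheme = NULL, val_fold = NULL,
                       pretrained = FALSE) {
  folds_all <- sort(unique(cache$fold))
  if (!(fold %in% folds_all)) stop_ecg("fold %s not present in cohort", fold)
  if (is.null(val_fold)) {
    nxt <- (fold + 1L) %% 10L
    val_fold <- if (nxt %in% folds_all) nxt
                else folds_all[(match(fold, folds_all) %% length(folds_all)) + 1L]
  }
  ord <- order(cache$record_id)
  idx_test <- ord[cache$fold[ord] == fold]
  idx_val <- ord[cache$fold[ord] == val_fold]
  idx_train <- ord[!(cache$fold[ord] %in% c(fold, val_fold))]
  if (!length(idx_train)) stop_ecg("empty training split")
  run <- function() {
    if (cfg$init_output_bias && !pretrained)
      graph$layers$out$b <- mean(cache$age[idx_train])
    opt <- adam_init()
    t_step <- 0L
    best <- list(val = Inf, epoch = 0L, snap = snapshot_params(graph))
    hist <- vector("list", cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      lr <- lr_at_epoch(cfg, ep)
      sh <- idx_train[sample.int(length(idx_train))]
      nb <- ceiling(length(sh) / cfg$batch_size)
      tr_loss <- 0
      for (bi in seq_len(nb)) {
        ids <- sh[((bi - 1L) * cfg$batch_size + 1L):
                    min(bi * cfg$batch_size, length(sh))]
        b <- gather_batch(cache, ids)
        if (!is.null(scheme))
          b <- corrupt_batch(b, cache$annotations[ids], scheme)
        if (!is.null(policy))
          b <- apply_policy(b, policy, rate = cache$rate)
        b <- pad_batch(b, graph$input_len)
        fw <- model_forward(graph, b, training = TRUE,
                            bn_momentum = cfg$bn_momentum)
        for (nm in names(fw$bn_stats)) {
          graph$layers[[nm]]$rmean <- fw$bn_stats[[nm]]$rmean
          graph$layers[[nm]]$rvar <- fw$bn_stats[[nm]]$rvar
        }
        err <- fw$pred - cache$age[ids]
        tr_loss <- tr_loss + sum(err^2)
        dpred <- 2 * err / length(ids)
        grads <- model_backward(graph, dpred, fw$caches)
        t_step <- t_step + 1L
        graph <- adam_step(graph, grads, opt, lr, t_step)
      }
      val_pred <- eval_indices(graph, cache, idx_val, cfg, policy, scheme)
      val_mse <- mean((val_pred - cache$age[idx_val])^2)
      hist[[ep]] <- data.frame(epoch = ep,
                               train_mse = tr_loss / length(idx_train),
                               val_mse = val_mse, lr = lr)
      if (val_mse < best$val)
        best <- list(val = val_mse, epoch = ep,
                     snap = snapshot_params(graph))
    }
    graph <- restore_params(graph, best$snap)
    test_pred <- eval_indices(graph, cache, idx_test, cfg, policy, scheme)
    metrics <- age_metrics(test_pred, cache$age[idx_test])
    structure(list(fold = fold, val_fold = val_fold,
                   best_val_mse = if (cfg$epochs > 0) best$val else NA_real_,
                   best_epoch = best$epoch,
                   history = if (cfg$epochs > 0) do.call(rbind, hist),
                   test = metrics, pred = test_pred,
                   test_ages = cache$age[idx_test],
                   baseline = mean_predictor_metrics(cache$age[idx_train],
                                                     cache$age[idx_test]),
                   graph = graph),
              class = "ecgage_fit")
  }
  with_seed(cfg$seed, run())
}

#' @export
print.ecgage_fit <- function(x, ...) {
  cat(sprintf("<ecgage_fit> fold %d: test MSE %.2f, MAE %.2f +/- %.2f y (best val MSE %.2f @ epoch %d)\n",
              x$fold, x$test$mse, x$test$mae_mean, x$test$mae_sd,
              x$best_val_mse, x$best_epoch))
  invisible(x)
}

#' @export
predict.ecgage_fit <- function(object, newdata, ...)
  predict(object$graph, newdata, ...)

#' @export
residuals.ecgage_fit <- function(object, ...) object$pred - object$test_ages

#' Cross-validate a model over the cohort folds
#'
#' Runs \code{\link{train_fold}} for every fold (a fresh network per fold)
#' and reports the unweighted mean of the per-fold test errors, the
#' study's headline reporting convention.
#'
#' @param builder function \code{(input_len) -> ecg_model} building and
#'   initializing a network.
#' @param cache an \code{ecg_cohort_cache}.
#' @param input_len network input length (samples on the 1,024 grid).
#' @param cfg a \code{\link{train_config}}.
#' @param policy,scheme see \code{\link{train_fold}}.
#' @param folds fold ids to run (defaults to all folds in the cohort).
#' @return An object of class \code{ecgage_cv}.
#' @export
cross_validate <- function(builder, cache, input_len, cfg = train_config(),
                           policy = NULL, scheme = NULL, folds = NULL) {
  folds_all <- sort(unique(cache$fold))
  if (is.null(folds)) folds <- folds_all
  if (!all(folds %in% folds_all))
    stop_ecg("missing folds: %s",
             paste(setdiff(folds, folds_all), collapse = ", "))
  fits <- lapply(folds, function(f) {
    cfg_f <- cfg
    if (!is.null(cfg$seed)) cfg_f$seed <- cfg$seed + 1009L * (f + 1L)
    g <- with_seed(cfg_f$seed, builder(input_len))
    train_fold(g, cache, f, cfg_f, policy = policy, scheme = scheme)
  })
  res <- structure(list(
    fits = fits, folds = folds,
    mean_test_mse = mean(vapply(fits, function(f) f$test$mse, numeric(1))),
    mean_test_mae = mean(vapply(fits, function(f) f$test$mae_mean,
                                numeric(1))),
    mean_baseline_mse = mean(vapply(fits, function(f) f$baseline$mse,
                                    numeric(1)))),
    class = "ecgage_cv")
  res
}

#' @export
print.ecgage_cv <- function(x, ...) {
  cat(sprintf("<ecgage_cv> %d folds: mean test MSE %.2f, mean test MAE %.2f (mean-age baseline MSE %.2f)\n",
              length(x$folds), x$mean_test_mse, x$mean_test_mae,
              x$mean_baseline_mse))
  invisible(x)
}

#' @export
summary.ecgage_cv <- function(object, ...) {
  df <- do.call(rbind, lapply(object$fits, function(f)
    data.frame(fold = f$fold, test_mse = f$test$mse,
               test_mae = f$test$mae_mean, test_mae_sd = f$test$mae_sd,
               pred_mean = f$test$pred_mean, pred_sd = f$test$pred_sd,
               best_val_mse = f$best_val_mse, best_epoch = f$best_epoch)))
  print(object)
  df
}

#' @export
plot.ecgage_cv <- function(x, ...) {
  pred <- unlist(lapply(x$fits, `[[`, "pred"))
  ages <- unlist(lapply(x$fits, `[[`, "test_ages"))
  plot(ages, pred, xlab = "chronological age (y)",
       ylab = "estimated ECG age (y)",
       main = sprintf("10-fold test predictions (MAE %.2f y)",
                      x$mean_test_mae), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}
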