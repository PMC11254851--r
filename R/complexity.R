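## Analytic, framework-independent complexity accounting.
##
## Conventions (chosen so the printed per-rate scaling of an all-convolution
## body is exactly linear in input length, and documented prominently since
## they are never universal): one "mult-add" is one fused multiply-accumulate;
## convolution cost = out_len * out_ch * in_ch * kernel (bias additions
## excluded); temporal convolutions that share weights across the 12 leads
## cost 12x; linear cost = in * out; normalization, activation and pooling
## are excluded; batch size 1. Serialized size is decimal MB at 4
## bytes/parameter.

layer_param_counts <- function(ly) {
  switch(ly$kind,
    conv1d = c(train = ly$out_ch * ly$in_ch * ly$k +
                 (if (is.null(ly$b)) 0L else ly$out_ch), buffer = 0L),
    spatial_conv = c(train = ly$out_ch * ly$in_ch * ly$leads + ly$out_ch,
                     buffer = 0L),
    linear = c(train = ly$n_out * ly$n_in + ly$n_out, buffer = 0L),
    batchnorm = c(train = 2L * ly$ch, buffer = 2L * ly$ch),
    c(train = 0L, buffer = 0L))
}

#' Count parameters of a layer graph
#'
#' Convolutions count \code{in_ch * out_ch * kernel + out_ch} (bias, when
#' present); linear layers \code{in * out + out}; batch normalization
#' contributes 2 trainable parameters per channel, with its running
#' statistics reported separately as buffers; pooling, activation and
#' dropout contribute nothing.
#'
#' @param graph an \code{ecg_model}.
#' @return An object of class \code{complexity_report} with fields
#'   \code{total}, \code{trainable}, \code{frozen}, \code{buffers} and a
#'   per-layer breakdown data frame.
#' @export
count_params <- function(graph) {
  if (!inherits(graph, "ecg_model")) stop_ecg("`graph` must be an ecg_model")
  rows <- lapply(graph$layers, function(ly) {
    cnt <- layer_param_counts(ly)
    data.frame(layer = ly$name, kind = ly$kind, block = ly$block,
               params = cnt[["train"]], buffers = cnt[["buffer"]],
               frozen = isTRUE(ly$frozen))
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  structure(list(total = sum(per$params),
                 trainable = sum(per$params[!per$frozen]),
                 frozen = sum(per$params[per$frozen]),
                 buffers = sum(per$buffers),
                 per_layer = per),
            class = "complexity_report")
}

# walk the graph replicating the executor's length arithmetic; returns the
# per-layer mult-add vector aligned with graph$layers
macs_per_layer <- function(graph, input_len) {
  out <- setNames(numeric(length(graph$layers)), names(graph$layers))
  conv_macs <- function(ly, len) {
    lo <- ceiling(len / ly$stride)
    list(macs = lo * ly$out_ch * ly$in_ch * ly$k *
           (if (isTRUE(ly$per_lead)) graph$n_leads else 1), len = lo)
  }
  if (graph$arch == "attianet") {
    len <- input_len
    for (ly in graph$layers) {
      if (ly$kind == "conv1d") {
        r <- conv_macs(ly, len); out[ly$name] <- r$macs; len <- r$len
      } else if (ly$kind == "maxpool") len <- floor(len / ly$pool)
      else if (ly$kind == "spatial_conv")
        out[ly$name] <- len * ly$out_ch * ly$in_ch * ly$leads
      else if (ly$kind == "linear") out[ly$name] <- ly$n_in * ly$n_out
    }
  } else {
    len <- input_len
    lys <- graph$layers
    for (ly in lys) if (ly$block == "stem" && ly$kind == "conv1d") {
      r <- conv_macs(ly, len); out[ly$name] <- r$macs; len <- r$len
    }
    n_blocks <- length(graph$config$channels) - 1L
    for (i in seq_len(n_blocks)) {
      blk <- sprintf("res%d", i)
      c1 <- lys[[paste0(blk, "_conv1")]]
      r1 <- conv_macs(c1, len); out[c1$name] <- r1$macs
      c2 <- lys[[paste0(blk, "_conv2")]]
      r2 <- conv_macs(c2, r1$len); out[c2$name] <- r2$macs
      ck <- lys[[paste0(blk, "_conv_skip")]]
      skip_len <- floor(len / lys[[paste0(blk, "_pool_skip")]]$pool)
      out[ck$name] <- skip_len * ck$out_ch * ck$in_ch * ck$k
      len <- r2$len
    }
    for (ly in lys) if (ly$kind == "linear")
      out[ly$name] <- ly$n_in * ly$n_out
  }
  out
}

#' Count forward-pass multiply-adds of a layer graph
#'
#' Batch size 1, fused multiply-accumulate convention (see the package
#' vignette): convolutions cost \code{out_len * out_ch * in_ch * kernel}
#' (times 12 for lead-shared temporal convolutions), linear layers
#' \code{in * out}; normalization, activation and pooling are excluded.
#'
#' @param graph an \code{ecg_model}.
#' @param input_len input length in samples (defaults to the graph's).
#' @return A \code{complexity_report} with fields \code{macs} (count),
#'   \code{macs_g} (units of 1e9, 2 decimals) and the per-layer breakdown.
#' @export
count_macs <- function(graph, input_len = graph$input_len) {
  if (input_len != graph$input_len) {
    builder <- if (graph$arch == "attianet") build_attianet else build_resnet1d
    graph <- builder(graph$config, input_len, init = FALSE)
  }
  m <- macs_per_layer(graph, input_len)
  per <- data.frame(layer = names(m),
                    kind = vapply(graph$layers, `[[`, character(1), "kind"),
                    macs = as.numeric(m))
  rownames(per) <- NULL
  structure(list(macs = sum(m), macs_g = round(sum(m) / 1e9, 2),
                 input_len = input_len, per_layer = per),
            class = "complexity_report")
}

#' Serialized model size in decimal megabytes
#'
#' @param graph an \code{ecg_model}.
#' @return \code{4 * total parameters / 1e6}, rounded to 2 decimals.
#' @export
disk_mb <- function(graph) round(4 * count_params(graph)$total / 1e6, 2)

#' Full complexity report for a model
#'
#' @param graph an \code{ecg_model}.
#' @param input_len input length for the mult-add accounting.
#' @return A \code{complexity_report} combining parameter, mult-add and
#'   disk-size accounting with a per-layer table.
#' @export
complexity_report <- function(graph, input_len = graph$input_len) {
  p <- count_params(graph)
  m <- count_macs(graph, input_len)
  per <- merge(p$per_layer, m$per_layer[, c("layer", "macs")], by = "layer",
               sort = FALSE)
  structure(list(total = p$total, trainable = p$trainable,
                 frozen = p$frozen, buffers = p$buffers,
                 macs = m$macs, macs_g = m$macs_g, disk_mb = disk_mb(graph),
                 input_len = input_len, per_layer = per),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  if (!is.null(x$total))
    cat(sprintf("parameters: %s total (%s trainable, %s frozen), %s buffers\n",
                format(x$total, big.mark = ","),
                format(x$trainable, big.mark = ","),
                format(x$frozen, big.mark = ","),
                format(x$buffers, big.mark = ",")))
  if (!is.null(x$macs))
    cat(sprintf("mult-adds @ %d samples: %s (%.2f G)\n", x$input_len,
                format(x$macs, big.mark = ","), x$macs / 1e9))
  if (!is.null(x$disk_mb))
    cat(sprintf("serialized size: %.2f MB at 4 bytes/parameter\n", x$disk_mb))
  invisible(x)
}

#' Complexity table across acquisition configurations
#'
#' Convenience wrapper reproducing the per-sampling-rate accounting tables:
#' one row per rate with parameter count, mult-adds (G) and disk MB.
#'
#' @param arch \code{"attianet"} or \code{"resnet1d"}.
#' @param rates sampling rates (Hz).
#' @param duration signal duration (s).
#' @return A data frame with one row per rate.
#' @export
complexity_table <- function(arch = c("attianet", "resnet1d"),
                             rates = c(100, 200, 300, 400, 500),
                             duration = 10) {
  arch <- match.arg(arch)
  builder <- if (arch == "attianet") build_attianet else build_resnet1d
  cfg <- if (arch == "attianet") attianet_config() else resnet1d_config()
  rows <- lapply(rates, function(r) {
    len <- ncol(pad_to_grid(matrix(0, 12, round(duration * r))))
    g <- builder(cfg, len, init = FALSE)
    rep <- complexity_report(g, len)
    data.frame(rate_hz = r, input_len = len, parameter_count = rep$total,
               disk_mb = rep$disk_mb, mult_adds_g = rep$macs_g)
  })
  do.call(rbind, rows)
}
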