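#!/usr/bin/env Rscript
# Emit the analytic complexity report for one architecture/acquisition
# configuration as CSV on stdout:
#   Rscript scripts/complexity.R --model attianet --rate 500 --duration 10

suppressPackageStartupMessages({
  library(optparse)
  library(ecgage)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--model", type = "character", default = "attianet",
              help = "attianet or resnet1d"),
  make_option("--rate", type = "double", default = 500),
  make_option("--duration", type = "double", default = 10),
  make_option("--per-layer", action = "store_true", default = FALSE,
              dest = "per_layer", help = "emit the per-layer breakdown")
)))

len <- ncol(pad_to_grid(matrix(0, 12, round(opts$rate * opts$duration))))
builder <- switch(opts$model, attianet = build_attianet,
                  resnet1d = build_resnet1d,
                  stop("--model must be attianet or resnet1d"))
cfg <- switch(opts$model, attianet = attianet_config(),
              resnet1d = resnet1d_config())
rep <- complexity_report(builder(cfg, len, init = FALSE), len)

if (opts$per_layer) {
  write.csv(rep$per_layer, stdout(), row.names = FALSE)
} else {
  write.csv(data.frame(model = opts$model, rate_hz = opts$rate,
                       duration_s = opts$duration, input_len = len,
                       parameter_count = rep$total,
                       disk_mb = rep$disk_mb,
                       mult_adds_g = rep$macs_g),
            stdout(), row.names = FALSE)
}
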