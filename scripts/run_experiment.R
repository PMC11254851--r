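#!/usr/bin/env Rscript
# Run one of the named experiment templates from a YAML config:
#   Rscript scripts/run_experiment.R --config run.yaml

suppressPackageStartupMessages({
  library(optparse)
  library(ecgage)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character",
              help = "path of a YAML experiment config")
)))
if (is.null(opts$config)) stop("--config is required")

res <- run_experiment(validate_config(opts$config))
write.csv(res, stdout(), row.names = FALSE)
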