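#!/usr/bin/env Rscript
# Thin command-line wrapper over starvalue::run_pipeline().
#
# Usage: Rscript scripts/pipeline.R --config cfg.yaml --out DIR [--seed N]

suppressPackageStartupMessages({
  library(optparse)
  library(starvalue)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character",
              help = "YAML/JSON pipeline configuration file"),
  make_option("--out", type = "character", default = "pipeline_out",
              help = "output directory [default %default]"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the seed in the config file")
)))

`%||%` <- function(a, b) if (is.null(a)) b else a

if (is.null(opts$config)) {
  cfg <- sim_config(seed = opts$seed %||% 1L)
  plan <- NULL
} else {
  loaded <- read_pipeline_config(opts$config)
  cfg <- loaded$config
  plan <- loaded$plan
  if (!is.null(opts$seed)) {
    cfg$seed <- opts$seed
  }
}
run_pipeline(cfg, opts$out, plan = plan)
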