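#!/usr/bin/env Rscript
# Thin shell wrapper over ssrpop::run_full_analysis().
#
# Usage: Rscript scripts/pipeline.R --config <config.yaml> [--seed <int>]
#                                   [--out <dir>]
# The config file follows the format documented in ?run_full_analysis;
# --seed and --out override the file's `seed` and `out_dir`.

suppressPackageStartupMessages(library(ssrpop))

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
cfg_path <- get_opt("--config")
if (is.null(cfg_path)) {
  message("usage: Rscript scripts/pipeline.R --config <config.yaml> [--seed <int>] [--out <dir>]")
  quit(status = 2L)
}
config <- yaml::read_yaml(cfg_path)
seed <- get_opt("--seed")
if (!is.null(seed)) config$seed <- as.integer(seed)
out <- get_opt("--out")
if (!is.null(out)) config$out_dir <- out

report <- run_full_analysis(config)
print(report)
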