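#!/usr/bin/env Rscript
# Thin command-line wrapper over the installed package's experiment runner.
#
# Usage:
#   Rscript scripts/run_experiment.R <experiment> [--seeds 1,2,3] [--out DIR]
#   Rscript scripts/run_experiment.R report --out DIR
#
# Experiments: equivalence | incremental | longtail | fewshot | sweep | report

suppressMessages({
  library(pcnet)
  library(optparse)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  cat("usage: Rscript scripts/run_experiment.R <equivalence|incremental|longtail|fewshot|sweep|report> [--seeds 1,2,3] [--out DIR]\n")
  quit(status = 1)
}
command <- args[1]
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seeds", type = "character", default = "1,2,3,4,5"),
  make_option("--out", type = "character", default = "pcnet_results")
)), args = args[-1])
seeds <- as.integer(strsplit(opts$seeds, ",")[[1]])

if (command == "report") {
  cat(render_tables(opts$out), sep = "\n")
} else if (command %in% c("equivalence", "incremental", "longtail", "fewshot")) {
  cfg <- experiment_config(command, seeds = seeds)
  run_experiment(cfg, opts$out)
  cat("results written to", opts$out, "\n")
} else if (command == "sweep") {
  cfg <- experiment_config("stability_sweep", seeds = seeds)
  print(stability_sweep(cfg, opts$out))
  cat("results written to", opts$out, "\n")
} else {
  cat("unknown experiment:", command, "\n")
  quit(status = 1)
}
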