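#!/usr/bin/env Rscript
# Thin command-line wrapper over ifnic::run_pipeline().
#
# Usage: Rscript scripts/run_pipeline.R --config <yaml|json> --outdir <dir>
#          [--seed <int>] [--log-level info|quiet]
# Exit codes: 0 ok, 2 validation error, 3 stage failure.

suppressPackageStartupMessages({
  library(optparse)
  library(ifnic)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--outdir", type = "character", default = "ifnic_out"),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--log-level", type = "character", default = "info",
              dest = "log_level")
)))

cfg <- if (is.null(opts$config)) list() else opts$config
if (!is.null(opts$seed)) {
  if (is.character(cfg)) {
    cfg <- ifnic:::read_pipeline_config(cfg)
  }
  cfg$seed <- opts$seed    # flag overrides the config value
}

log_msg <- function(...) {
  if (opts$log_level != "quiet")
    message(sprintf("[ifnic] %s", sprintf(...)))
}

log_msg("writing report bundle to %s", opts$outdir)
res <- tryCatch(
  run_pipeline(cfg, outdir = opts$outdir),
  error = function(e) e
)
if (inherits(res, "error")) {
  message(conditionMessage(res))
  if (grepl("validate|exactly one|required", conditionMessage(res)))
    quit(status = 2)
  quit(status = 3)
}
log_msg("completed stages: %s", paste(res$stages_completed, collapse = ", "))
quit(status = 0)
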