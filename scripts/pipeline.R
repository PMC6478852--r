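#!/usr/bin/env Rscript

# Thin command-line wrapper over gainlossr's pipeline. Subcommands:
#   generate  -- write a synthetic cohort to --out
#   fit       -- fit models to a cohort directory, write fits.csv
#   stats     -- behavioural metrics + statistics on a cohort directory
#   run-all   -- full generate/ingest -> fit -> stats -> report
# Example:
#   Rscript scripts/pipeline.R run-all --seed 1 --out gl-report

suppressPackageStartupMessages({
  library(optparse)
  library(gainlossr)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("generate", "fit", "stats", "run-all")) {
  message("usage: Rscript scripts/pipeline.R <generate|fit|stats|run-all> [options]")
  quit(status = 2)
}
cmd <- args[1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1),
  make_option("--out", type = "character", default = "gl-out"),
  make_option("--cohort", type = "character", default = NULL,
              help = "cohort directory to ingest (default: generate synthetic)"),
  make_option("--n-subjects", type = "integer", default = 31),
  make_option("--models", type = "character", default = "qlearning",
              help = "comma-separated subset of: qlearning,opal"),
  make_option("--n-starts", type = "integer", default = 10),
  make_option("--bf-prior-scale", type = "double", default = 0.707),
  make_option("--include-early-phases", action = "store_true", default = FALSE),
  make_option("--threshold-rule", type = "character", default = NULL)
)), args = args[-1])

models <- strsplit(opts$models, ",")[[1]]

if (cmd == "generate") {
  coh <- generate_cohort(cohort_config(n_subjects = opts$`n-subjects`,
                                       seed = opts$seed))
  write_cohort(coh, opts$out)
  message("cohort written to ", opts$out)
} else if (cmd == "fit") {
  if (is.null(opts$cohort)) stop("--cohort is required for 'fit'")
  coh <- read_cohort(opts$cohort)
  fits <- dplyr::bind_rows(lapply(models, function(m) {
    fit_cohort(coh$trials, m, n_starts = opts$`n-starts`,
               seed = substream_seed(opts$seed, paste("fit", m)),
               include_early_phases = opts$`include-early-phases`)
  }))
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(fits, file.path(opts$out, "fits.csv"))
  message("fits written to ", file.path(opts$out, "fits.csv"))
} else {
  cohort <- opts$cohort  # NULL -> synthetic
  run_pipeline(opts$out, cohort = cohort,
               cohort_cfg = cohort_config(n_subjects = opts$`n-subjects`,
                                          seed = substream_seed(opts$seed, "cohort")),
               models = if (cmd == "stats") models[0] else models,
               n_starts = opts$`n-starts`,
               bf_prior_scale = opts$`bf-prior-scale`,
               include_early_phases = opts$`include-early-phases`,
               threshold_rule = opts$`threshold-rule`,
               seed = opts$seed)
}
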