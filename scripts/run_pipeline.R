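#!/usr/bin/env Rscript
# Thin command-line wrapper over oudcontrols::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R --preset smoke --seed 1 --out runs/smoke
#   Rscript scripts/run_pipeline.R --config my_generator.yaml --seed 1 --out runs/custom
#
# --preset  smoke | desk | full   (problem size; default smoke)
# --config  optional YAML/JSON generator configuration overriding the
#           preset's generator (see oudcontrols::read_generator_config)
# --seed    top-level integer seed (default 1)
# --out     output directory (required)

suppressMessages(library(oudcontrols))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
preset <- get_arg("--preset", "smoke")
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out")
config_path <- get_arg("--config")
if (is.null(out)) stop("--out <dir> is required", call. = FALSE)

cfg <- preset_config(preset, seed = seed)
if (!is.null(config_path)) {
  gen <- read_generator_config(config_path)
  gen$seed <- seed
  cfg$generator <- gen
}
res <- run_pipeline(cfg, out_dir = out)
print(res$comparison)
for (mode in names(res$dilution)) {
  cat(sprintf("dilution (%s vs reference): ", mode))
  print(res$dilution[[mode]])
}
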