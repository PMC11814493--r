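#!/usr/bin/env Rscript
# Sensitivity of the simulation-grid summary to the error-event mix:
#   Rscript scripts/sensitivity.R [--seed S] [--replicates N] [--out path.tsv]
#
# The per-base error model leaves the substitution/insertion/deletion split
# free; this sweep re-runs the grid under several splits so the dependence
# of the two headline counts on that choice is visible.

suppressPackageStartupMessages(library(teloscan))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 1L, replicates = 50L, out = "")
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  if (key %in% names(opt) && i < length(args)) {
    opt[[key]] <- args[i + 1L]; i <- i + 2L
  } else {
    stop(sprintf("unknown argument: %s", args[i]))
  }
}

mixes <- list(
  uniform      = c(1 / 3, 1 / 3, 1 / 3),
  sub_only     = c(1, 0, 0),
  indel_only   = c(0, 0.5, 0.5),
  sub_heavy    = c(0.8, 0.1, 0.1),
  del_heavy    = c(0.2, 0.2, 0.6))

rows <- lapply(names(mixes), function(name) {
  m <- mixes[[name]]
  g <- run_grid(n_replicates = as.integer(opt$replicates),
                cfg = explore_config(4L, 12L, threshold = 50L),
                seed = as.integer(opt$seed),
                sub_frac = m[1], ins_frac = m[2], del_frac = m[3])
  message(sprintf("%-10s top==true: %2d/21   absent: %2d/21", name,
                  g$n_top_match, g$n_absent))
  c(name, m, g$n_top_match, g$n_absent)
})

write_tsv(rows,
          c("mix", "sub_frac", "ins_frac", "del_frac",
            "n_top_match", "n_absent"),
          opt$out)
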