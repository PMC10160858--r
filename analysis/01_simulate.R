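#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study datasets.
#
# The real surveillance (COMSA-role) and reference-standard (CHAMPS-role)
# records are not public, so every downstream stage runs on synthetic data
# with known ground truth: the post-exclusion child dataset (1,589 deaths,
# 7 broad causes, two algorithms), the neonatal analogue (632 deaths,
# 5 causes), and the large-sample two-cause worked example.

suppressMessages(library(vacalibrate))

out_root <- "results/data"
for (name in c("two_cause_worked_example", "child_like", "neonate_like")) {
  sc <- preset_scenario(name)
  g <- generate(sc)
  dir <- file.path(out_root, name)
  write_scenario(g, dir)
  cat(sprintf(
    "%-26s seed %-3d: %5d unpaired, %4d paired (%s per cause), %d causes -> %s\n",
    name, sc$seed, n_records(g$unpaired), n_records(g$paired),
    paste(unique(sc$paired_per_cause), collapse = "/"), sc$causes$C, dir))
}

# the two presets emulate datasets *after* the complete-case exclusion, so
# the filter must be a no-op on them
g <- generate(preset_scenario("child_like"))
stopifnot(complete_case_filter(g$unpaired)$n_excluded == 0)
cat("complete-case filter confirms presets are already complete cases\n")
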