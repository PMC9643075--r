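#!/usr/bin/env Rscript
# Stage 5 — ordered logistic regression of red-list status on the traits.
#
# Runs the full pipeline (alignment, collinearity screen, signal,
# decomposition, and the three proportional-odds blocks: S-components,
# P-components, raw traits) on the simulated study and reports the
# coefficient tables. The expected finding mirrors the generating model:
# a negative, significant range-size effect in the S-block only.

suppressMessages(library(traitrisk))

report <- run_pipeline(list(tree = "results/data/tree.nwk",
                            traits = "results/data/traits.csv",
                            out_dir = "results/models",
                            seed = 20220908))

for (b in c("S", "P", "raw")) {
  cat(sprintf("\n%s block (proportional-odds, joint 4-predictor fit):\n", b))
  print(transform(report$blocks[[b]], estimate = round(estimate, 3),
                  std_error = round(std_error, 3), z_value = round(z_value, 2),
                  p_value = signif(p_value, 2)), row.names = FALSE)
}

rs <- report$blocks$S
rs <- rs[rs$predictor == "range_occupancy", ]
cat(sprintf(paste0(
  "\nspecies-specific range-size effect: %.2f +/- %.2f (z = %.2f, p = %.3g)\n",
  "=> %s\n"),
  rs$estimate, rs$std_error, rs$z_value, rs$p_value,
  if (rs$estimate < 0 && rs$p_value < 0.05)
    "extinction risk rises as species-specific range size shrinks"
  else "no significant species-specific range-size effect in this replicate"))
cat("tables written under results/models/\n")
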