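#!/usr/bin/env Rscript
# Synthetic ADE2 pigmentation assay end to end, for both transition
# scenarios: normalize plates, fit 1- and 2-component Gaussian mixtures,
# project the selected means on the leading principal direction of on/off
# differences, and find where and how the branches merge.

library(sirswitch)
library(jsonlite)

seed <- 20260930L
dir.create("results", showWarnings = FALSE)

for (scenario in c("pitchfork", "saddle")) {
  demo <- pipeline_pigment_demo(seed = seed, scenario = scenario)
  write_colors_tsv(demo$colors,
                   sprintf("results/colony_colors_%s.tsv", scenario),
                   comments = sprintf("scenario %s, global seed %d",
                                      scenario, seed))
  write.table(demo$trace$table,
              sprintf("results/branch_trace_%s.tsv", scenario),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_json(list(scenario = scenario,
                  merge_uM = demo$merge$estimate,
                  merge_uncertainty_uM = demo$merge$uncertainty,
                  generating_merge_uM = demo$merge$truth,
                  merge_type = demo$merge_type,
                  axis = as.numeric(demo$trace$axis), seed = seed),
             sprintf("results/pigment_report_%s.json", scenario),
             auto_unbox = TRUE, digits = NA)
  cat(sprintf("%s: merge at %g uM (generator %g uM), loss of bimodality by %s\n",
              scenario, demo$merge$estimate, demo$merge$truth,
              demo$merge_type))
}
cat("\nThe continuous (pitchfork-like) scenario loses bimodality by the",
    "branch means collapsing; the saddle-like scenario by the 'off'",
    "component's weight dying out at roughly constant separation.\n")
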