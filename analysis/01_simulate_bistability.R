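#!/usr/bin/env Rscript
# History dependence of the silencing lattice at the study conditions:
# the same model, started silenced or active, holds different
# intermediate-time occupancies at I = 0, and both histories collapse to
# the derepressed state at I = 4.

library(sirswitch)

seed <- 20260930L
dir.create("results", showWarnings = FALSE)

runs <- expand.grid(I = c(0, 4), init = c("telomere_silenced", "all_active"),
                    rep = 1:8, stringsAsFactors = FALSE)
runs$occupancy <- NA_real_
for (i in seq_len(nrow(runs))) {
  cfg <- sim_config(I = runs$I[i],
                    seed = derive_seed(seed, paste0("bistab_", i)))
  tr <- simulate_lattice(cfg, init_lattice(cfg, runs$init[i]))
  runs$occupancy[i] <- sir_occupancy(tr)
  if (runs$rep[i] == 1) {
    write_trajectory_tsv(tr, sprintf("results/trajectory_I%g_%s.tsv",
                                     runs$I[i], runs$init[i]))
  }
}

summ <- aggregate(occupancy ~ I + init, runs,
                  function(x) c(mean = mean(x), sd = sd(x)))
summ <- do.call(data.frame, summ)
names(summ) <- c("I", "init", "occupancy_mean", "occupancy_sd")
write.table(summ, "results/bistability_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Mean locus occupancy (sites 5-50), 8 replicates each:\n")
print(summ, row.names = FALSE)
cat("\nAt I = 0 the silenced and active histories stay far apart",
    "(bistable memory); at I = 4 both relax to the derepressed state.\n")
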