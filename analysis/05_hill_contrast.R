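#!/usr/bin/env Rscript
# The single-molecule-cooperativity straw man: how cooperatively would the
# inhibitor have to bind Sir2 to explain a five-orders survival drop over
# one concentration decade? Contrast a Hill coefficient of 5-6 with a
# low-micromolar dissociation constant against the measured in-vitro
# behaviour (no cooperativity, IC50 near 60 uM).

library(sirswitch)

dir.create("results", showWarnings = FALSE)

coop <- hill_model(K_d = 5, n = 6)
flat <- hill_model(K_d = 60, n = 1)
tab <- cooperativity_contrast(coop, flat, c_range = seq(2.5, 25, by = 2.5))
write.table(format(tab, digits = 4), "results/hill_contrast.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

print(format(tab, digits = 3), row.names = FALSE)
fd <- attr(tab, "fold_drop")
cat(sprintf("\nFold drop of active Sir2 from 2.5 to 25 uM: %.3g (n = 6, K_d = 5 uM) vs %.3g (n = 1, K_d = 60 uM)\n",
            fd[["coop"]], fd[["flat"]]))
cat("Only the highly cooperative law produces a drop of the required size;",
    "the measured non-cooperative in-vitro response cannot, so the sharp",
    "transition must come from supra-molecular cooperativity.\n")
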