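#!/usr/bin/env Rscript
# Stage 4: D_FOIL direction tests on the symmetric quintet.
#
# The quintet ((esc1,esc2),(per1,per2)) + outgroup satisfies the
# method's requirements (symmetric topology, (esc1,esc2) split more
# recent).  Windows overlapping the simulated per1 -> esc1 block should
# be called "P3=>P1"; everything else should stay quiet.

library(radscan)
out <- "results/demo"
vm <- read_variant_matrix(file.path(out, "variants.tsv"))
hm <- resolve_heterozygotes(vm, seed = 99)
sst <- demo_species_tree()

windows <- partition_windows(vm, 100000, min_sites = 10)
res <- dfoil(hm, "esc1", "esc2", "per1", "per2", "out",
             windows = windows, sst = sst)
write_report(res, file.path(out, "dfoil_windows.tsv"))

called <- res[res$direction != "none", ]
cat(sprintf("%d of %d windows receive a direction call:\n",
            nrow(called), nrow(res)))
print(called[, c("chrom", "start", "end", "DFO", "DIL", "DFI", "DOL",
                 "direction")], digits = 2)
cat("stage 4 complete\n")
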