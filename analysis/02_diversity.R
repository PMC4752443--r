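#!/usr/bin/env Rscript
# Stage 2: within-accession diversity and allele sorting.
#
# Per-accession heterozygosity, the proportion of heterozygous sites
# whose allele pair is also sorting in other species (the signature of
# shared ancestral variation), per-group specific-allele sharing, and
# the pairwise distance matrix from the random-allele haploid
# projection.

library(radscan)
out <- "results/demo"
vm <- read_variant_matrix(file.path(out, "variants.tsv"))
sst <- demo_species_tree()

hh <- heterozygosity(vm)
prof <- shared_het_profile(vm, sst$accessions)
div <- merge(hh, prof, by = "accession")
write_report(div, file.path(out, "diversity.tsv"))
cat(sprintf("heterozygosity: %.2f%% - %.2f%% across accessions\n",
            100 * min(hh$H, na.rm = TRUE), 100 * max(hh$H, na.rm = TRUE)))
cat(sprintf("het sites sorting in other species: mean %.0f%%\n",
            100 * mean(prof$shared_prop, na.rm = TRUE)))

share <- group_specific_allele_share(vm, "esc1", sst$groups)
cat("group-specific allele share of esc1 het sites:\n")
print(round(share, 3))

hm <- resolve_heterozygotes(vm, seed = 99)
d <- pairwise_distance(hm)
write_distance_matrix(d, file.path(out, "distances.tsv"))
ing <- setdiff(rownames(d), "out")
cat(sprintf("ingroup pairwise distances: %.2f%% - %.2f%%; to outgroup %.2f%% - %.2f%%\n",
            100 * min(d[ing, ing][upper.tri(d[ing, ing])]),
            100 * max(d[ing, ing]),
            100 * min(d[ing, "out"]), 100 * max(d[ing, "out"])))
cat("stage 2 complete\n")
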