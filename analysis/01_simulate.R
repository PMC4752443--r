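#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system.
#
# A nine-species, four-group radiation plus outgroup (ILS-rich, burst
# internodes of 1-2 coalescent units), sampled as diploid accessions:
# 300 genes on one synthetic chromosome, a localized recent
# introgression block (per1 -> esc1, genes 51-70, emulating a
# chromosomally restricted recent transfer), and 8 environment-sorted
# ancestral alleles injected for a wet/dry contrast that cuts across
# the phylogeny.  Writes the variant matrix (VCF + flat TSV), gene
# trees, and the truth tables downstream stages must recover.

library(radscan)
out <- "results/demo"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20160216

sst <- demo_species_tree()
sst_pulse <- inject_introgression(sst, "per1", "esc1", 30000, 1,
                                  genes = 51:70)
cat("species tree:", ape::write.tree(sst$tree), "\n")

trees <- simulate_gene_trees(sst_pulse, 300, seed = seed)
vm0 <- simulate_variants(trees, sites_per_gene = 150, seed = seed + 1)

part <- c(esc1 = "wet", arc1 = "wet", per1 = "wet",
          esc2 = "dry", arc2 = "dry", per2 = "dry")
inj <- inject_environment_alleles(vm0, part, n_sites = 8,
                                  seed = seed + 2, sst = sst)
vm <- inj$matrix
cat(sprintf("simulated %d sites x %d accessions (%d genes)\n",
            n_sites(vm), length(vm$accessions),
            length(unique(vm$gene))))

write_variant_matrix(vm, file.path(out, "variants.vcf"), "vcf")
write_variant_matrix(vm, file.path(out, "variants.tsv"), "tsv")
writeLines(vapply(trees, ape::write.tree, character(1)),
           file.path(out, "gene_trees.nwk"))
write_report(attr(vm0, "truth"), file.path(out, "truth_introgression.tsv"))
write_report(inj$truth, file.path(out, "truth_env_alleles.tsv"))
write_report(data.frame(accession = names(part), factor = "wetdry",
                        group = unname(part)),
             file.path(out, "partition.tsv"))
write_report(attr(vm0, "gene_coords"), file.path(out, "gene_coords.tsv"))
cat("stage 1 complete:", out, "\n")
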