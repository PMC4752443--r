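#!/usr/bin/env Rscript
# Stage 8: gene-tree discordance profile.
#
# Distinct-topology counting, per-branch bipartition support against
# the species tree, the branch-length/concordance relationship, and
# per-taxon instability scores (rogue-taxon detection).

library(radscan)
out <- "results/demo"
trees <- lapply(readLines(file.path(out, "gene_trees.nwk")),
                function(x) ape::read.tree(text = x))
sst <- demo_species_tree()

# one haploid lineage per accession for taxon-level comparisons
trees1 <- lapply(trees, function(tr) {
  keep <- grep("\\.h1$", tr$tip.label, value = TRUE)
  t2 <- ape::keep.tip(tr, keep)
  t2$tip.label <- sub("\\.h1$", "", t2$tip.label)
  t2
})

nd <- count_distinct_topologies(trees1)
cat(sprintf("%d distinct topologies among %d gene trees\n",
            as.integer(nd), length(trees1)))

sup <- bipartition_support(trees1, sst$tree)
write_report(sup, file.path(out, "bipartition_support.tsv"))
cat("bipartition support of species-tree branches:\n")
print(sup[order(-sup$support), ], digits = 2)

bl <- branchlen_vs_concordance(sup)
cat(sprintf("branch length vs support: Spearman rho = %.2f (p = %.3g)\n",
            bl$rho, bl$p))

inst <- taxon_instability(trees1)
write_report(data.frame(taxon = names(inst), instability = inst),
             file.path(out, "taxon_instability.tsv"))
cat("most unstable taxa:\n")
print(head(round(inst, 3)))
cat("stage 8 complete\n")
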