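test_that("3-taxon gene-tree discordance follows the coalescent law", {
  # internal branch t = 1 coalescent unit (80 ky at default scaling);
  # expected discordance 2/3 * exp(-1)
  tri <- sim_species_tree("((A:160000,B:160000):80000,C:240000);")
  n <- 4000
  gt <- simulate_gene_trees(tri, n, seed = 5, lineages_per_accession = 1)
  tc <- count_topologies(gt, "A", "B", "C")
  disc <- 1 - tc$proportions[["concordant"]]
  expected <- (2 / 3) * exp(-1)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(disc - expected), 3 * se)
  # the two discordant classes are exchangeable
  d13 <- tc$counts[["disc_p1p3"]]; d23 <- tc$counts[["disc_p2p3"]]
  expect_gt(binom.test(d13, d13 + d23)$p.value, 0.001)
})

test_that("a long internal branch gives essentially complete concordance", {
  tri <- sim_species_tree("((A:100000,B:100000):800000,C:900000);")
  gt <- simulate_gene_trees(tri, 400, seed = 6, lineages_per_accession = 1)
  tc <- count_topologies(gt, "A", "B", "C")
  expect_gte(tc$proportions[["concordant"]], 0.99)
})

test_that("gene-tree simulation is seed-deterministic", {
  sst <- demo_species_tree()
  g1 <- simulate_gene_trees(sst, 20, seed = 77)
  g2 <- simulate_gene_trees(sst, 20, seed = 77)
  expect_identical(vapply(g1, ape::write.tree, character(1)),
                   vapply(g2, ape::write.tree, character(1)))
  g3 <- simulate_gene_trees(sst, 20, seed = 78)
  expect_false(identical(vapply(g1, ape::write.tree, character(1)),
                         vapply(g3, ape::write.tree, character(1))))
})

test_that("no inter-species coalescence predates the species divergence", {
  sim <- demo_sim()
  expect_silent(check_msc_consistency(sim$gts, genes = 1:100))
})

test_that("variant simulation respects the genealogy and the mutation model", {
  # two species, one haploid lineage each: every derived allele private
  two <- sim_species_tree("(A:400000,B:400000);")
  gt <- simulate_gene_trees(two, 30, seed = 9, lineages_per_accession = 1)
  vm <- simulate_variants(gt, sites_per_gene = 10, seed = 10)
  hm <- resolve_heterozygotes(vm, seed = 11)
  derived_per_site <- rowSums(hm$h != hm$ref)
  expect_true(all(derived_per_site == 1))
  # zero mutations -> empty matrix
  vm0 <- simulate_variants(gt, sites_per_gene = 0, seed = 10)
  expect_equal(n_sites(vm0), 0L)
  # positions strictly increasing, genes laid out on the synthetic chromosome
  expect_true(all(diff(vm$pos) > 0))
  expect_equal(length(unique(vm$gene)), 30L)
})

test_that("heterozygosity rises with effective population size", {
  h_of <- function(Ne, seed) {
    sst <- demo_species_tree(Ne = Ne)
    gt <- simulate_gene_trees(sst, 150, seed = seed)
    vm <- simulate_variants(gt, sites_per_gene = 20, seed = seed + 1)
    mean(heterozygosity(vm)$H)
  }
  reps <- vapply(1:5, function(r)
    c(h_of(5e4, 100 + r), h_of(2e5, 200 + r)), numeric(2))
  expect_true(all(reps[2, ] > reps[1, ]))
})

test_that("a zero-proportion pulse is a no-op and gamma = 1 reroutes everything", {
  sst <- demo_species_tree()
  sst0 <- inject_introgression(sst, "per1", "esc3", 30000, 0)
  expect_identical(
    vapply(simulate_gene_trees(sst0, 15, seed = 3), ape::write.tree, ""),
    vapply(simulate_gene_trees(sst, 15, seed = 3), ape::write.tree, ""))
  sst1 <- inject_introgression(sst, "per1", "esc3", 30000, 1)
  gt <- simulate_gene_trees(sst1, 200, seed = 4,
                            lineages_per_accession = 1)
  expect_true(all(attr(gt, "introgressed")$introgressed))
  tc <- count_topologies(gt, "esc3", "esc2", "per1")
  expect_gt(tc$proportions[["disc_p1p3"]], 0.85)  # esc3 rides with per1
})

test_that("pulse timing outside the branches' lifetime is rejected", {
  sst <- demo_species_tree()
  expect_error(inject_introgression(sst, "per1", "esc1", 500000, 0.5),
               "lifetime")
  expect_error(inject_introgression(sst, "per1", "per1", 10000, 0.5),
               "distinct")
})

test_that("injected environment alleles are disjoint and recorded", {
  sim <- demo_sim()
  part <- c(esc1 = "wet", arc1 = "wet", per1 = "wet",
            esc2 = "dry", arc2 = "dry", per2 = "dry")
  inj <- inject_environment_alleles(sim$vm, part, n_sites = 5, seed = 21,
                                    sst = sim$sst)
  expect_equal(nrow(inj$truth), 5L)
  expect_equal(n_sites(inj$matrix), n_sites(sim$vm) + 5L)
  for (i in seq_len(5)) {
    row <- which(inj$matrix$pos == inj$truth$pos[i] &
                 inj$matrix$gene == inj$truth$gene[i])
    g1 <- names(part)[part == "wet"]; g2 <- names(part)[part == "dry"]
    al1 <- unique(c(inj$matrix$a1[row, g1], inj$matrix$a2[row, g1]))
    al2 <- unique(c(inj$matrix$a1[row, g2], inj$matrix$a2[row, g2]))
    expect_length(intersect(al1, al2), 0)
    expect_equal(inj$matrix$class[row], "nonsynonymous")
  }
  # n_sites = 0 leaves the matrix untouched
  inj0 <- inject_environment_alleles(sim$vm, part, n_sites = 0)
  expect_identical(inj0$matrix$a1, sim$vm$a1)
})

test_that("clade-congruent environment partitions are refused", {
  sim <- demo_sim()
  bad <- c(esc1 = "x", esc2 = "x", esc3 = "x",
           per1 = "y", per2 = "y", arc1 = "y", arc2 = "y",
           hab1 = "y", hab2 = "y")
  expect_error(
    inject_environment_alleles(sim$vm, bad, n_sites = 2, sst = sim$sst),
    "congruent")
})
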