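test_that("partition validation enforces phylogenetic incongruence", {
  sst <- demo_species_tree()
  # congruent with the Esculentum-analog clade: rejected
  bad <- env_partition("f", c(esc1 = "hi", esc2 = "hi", esc3 = "hi",
                              arc1 = "lo", arc2 = "lo", per1 = "lo",
                              per2 = "lo", hab1 = "lo", hab2 = "lo"))
  expect_true(any(grepl("clade", validate_partition(bad, sst))))
  # splitting species across sides: accepted (needs >1 accession/species)
  sst3 <- demo_species_tree(accessions_per_species = 2)
  ok <- env_partition("f", c(esc1_1 = "hi", esc1_2 = "lo",
                             per1_1 = "hi", per1_2 = "lo",
                             arc1_1 = "hi", arc1_2 = "lo"))
  expect_length(validate_partition(ok, sst3), 0L)
  expect_error(env_partition("f", c(a = "hi", b = "hi")), "two")
  expect_error(validate_partition(
    env_partition("f", c(ghost = "hi", esc1 = "lo")), sst), "unknown")
})

test_that("perfect association requires disjoint allele sets and full data", {
  p <- env_partition("metal", c(a = "hi", b = "hi", c = "lo", d = "lo"))
  hm <- toy_hm(cbind(a = c("G", "G", "G", "G"),
                     b = c("G", "G", "A", "-"),
                     c = c("A", "A", "A", "A"),
                     d = c("A", "A", "A", "A")),
               class = rep("nonsynonymous", 4),
               gene = paste0("g", 1:4))
  scan <- scan_perfect_association(hm, p)
  # site 1: hit; site 2 identical: hit; site 3: b carries the lo allele;
  # site 4: missing data -> not even examined
  expect_equal(scan$m, 2L)
  expect_equal(scan$n_variants_examined, 3L)
  expect_equal(scan$hits$gene, c("g1", "g2"))
  # class filter: synonymous scan sees nothing here
  expect_equal(scan_perfect_association(hm, p, class = "synonymous")$m, 0L)
})

test_that("adding accessions to a partition can only lose hits", {
  sim <- demo_sim()
  base <- c(esc1 = "hi", per1 = "hi", arc1 = "lo", hab1 = "lo")
  wider <- c(base, esc2 = "hi", arc2 = "lo")
  m1 <- scan_perfect_association(sim$hm,
                                 env_partition("f", base), "any")$m
  m2 <- scan_perfect_association(sim$hm,
                                 env_partition("f", wider), "any")$m
  expect_lte(m2, m1)
})

test_that("injected environment-sorted sites are recovered exactly", {
  sim <- demo_sim()
  part <- c(esc1 = "wet", arc1 = "wet", per1 = "wet",
            esc2 = "dry", arc2 = "dry", per2 = "dry")
  inj <- inject_environment_alleles(sim$vm, part, n_sites = 5, seed = 91,
                                    sst = sim$sst)
  hm <- resolve_heterozygotes(inj$matrix, seed = 92)
  scan <- scan_perfect_association(hm, env_partition("wetdry", part))
  found <- paste(scan$hits$gene, scan$hits$pos)
  want <- paste(inj$truth$gene, inj$truth$pos)
  expect_true(all(want %in% found))
})

test_that("the null probability matches a brute-force 4-taxon oracle", {
  # species tree (((A,B):t2,C):t3,D); partition {B,C} vs {A,D} can only
  # be matched through incomplete lineage sorting
  sst <- sim_species_tree(
    "(((A:80000,B:80000):80000,C:160000):160000,D:320000);")
  p <- env_partition("f", c(A = "x", B = "y", C = "y", D = "x"))
  est <- estimate_null_probability(sst, p, n_genes = 20000, seed = 5)
  orc <- oracle_q4(20000, seed = 99)
  expect_lt(abs(est$q - orc$q), 3 * sqrt(est$se^2 + orc$se^2))
  # the two estimator modes agree with each other as well
  est2 <- estimate_null_probability(sst, p, n_genes = 20000, seed = 6,
                                    method = "expected")
  expect_lt(abs(est2$q - orc$q), 3 * sqrt(est2$se^2 + orc$se^2))
  expect_gt(est$q, 0)
})

test_that("q is invariant under swapping the partition labels", {
  sst <- sim_species_tree(
    "(((A:80000,B:80000):80000,C:160000):160000,D:320000);")
  pa <- env_partition("f", c(A = "x", B = "y", C = "y", D = "x"))
  pb <- env_partition("f", c(A = "y", B = "x", C = "x", D = "y"))
  qa <- estimate_null_probability(sst, pa, n_genes = 5000, seed = 7)
  qb <- estimate_null_probability(sst, pb, n_genes = 5000, seed = 7)
  expect_equal(qa$q, qb$q)
})

test_that("degenerate partitions give the limiting null probabilities", {
  two <- sim_species_tree("(A:100000,B:100000);")
  p2 <- env_partition("f", c(A = "x", B = "y"))
  est <- estimate_null_probability(two, p2, n_genes = 500, seed = 3)
  expect_equal(est$q, 1)  # any single mutation splits two accessions
  # grouping two distant non-sisters against their own sisters on a
  # long-internode tree essentially never happens
  deep <- sim_species_tree(paste0(
    "(((A:80000,B:80000):800000,(C:80000,D:80000):800000):800000,",
    "O:1680000);"))
  pd <- env_partition("f", c(A = "x", C = "x", B = "y", D = "y", O = "y"))
  estd <- estimate_null_probability(deep, pd, n_genes = 4000, seed = 4)
  expect_lt(estd$q, 0.001)
})

test_that("dataset p-values behave at the edges and across methods", {
  expect_equal(dataset_pvalue(0, 100, 0), 1)   # nothing can exceed 0 hits
  expect_equal(dataset_pvalue(10, 100, 0), 0)
  expect_equal(dataset_pvalue(2, 50, 0.01),
               pbinom(1, 50, 0.01, lower.tail = FALSE))
  # at-least-as-extreme vs strictly-greater conventions
  expect_gt(dataset_pvalue(2, 50, 0.05),
            dataset_pvalue(2, 50, 0.05, exceedance = "greater"))
  # binomial vs fast resimulation
  pb <- dataset_pvalue(3, 200, 0.01)
  pr <- dataset_pvalue(3, 200, 0.01, method = "resim",
                       n_datasets = 20000, seed = 11)
  expect_lt(abs(pb - pr), 2 * sqrt(pb * (1 - pb) / 20000) + 1e-6)
})

test_that("linked synonymous variants flag introgression-like blocks", {
  p <- env_partition("f", c(a = "hi", b = "hi", c = "lo", d = "lo"))
  # gene gA: lone nonsynonymous hit (standing variation pattern);
  # gene gB: a haplotype block, nonsyn + 2 syn all tracking the split
  hm <- toy_hm(cbind(a = c("G", "G", "G", "G", "T"),
                     b = c("G", "G", "G", "G", "T"),
                     c = c("A", "A", "A", "A", "T"),
                     d = c("A", "A", "A", "A", "C")),
               class = c("nonsynonymous", "nonsynonymous", "synonymous",
                         "synonymous", "synonymous"),
               gene = c("gA", "gB", "gB", "gB", "gB"))
  scan <- scan_perfect_association(hm, p)
  chk <- linked_synonymous_check(scan, hm)
  expect_equal(chk$n_assoc_syn[chk$gene == "gA"], 0L)
  expect_equal(chk$n_assoc_syn[chk$gene == "gB"], 2L)
  expect_false(chk$introgression_ambiguous[chk$gene == "gA"])
  expect_true(chk$introgression_ambiguous[chk$gene == "gB"])
})
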