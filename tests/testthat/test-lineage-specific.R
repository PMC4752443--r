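sp_map <- c(a1 = "spA", a2 = "spA", b1 = "spB", c1 = "spC")

test_that("the best-covered accession represents its species", {
  cov <- c(a1 = 300, a2 = 250, b1 = 200, c1 = 180, og1 = 150, og2 = 90)
  sel <- select_representatives(cov, sp_map, outgroup = c("og1", "og2"))
  expect_true(sel$testable)
  reps <- sel$representatives
  expect_equal(reps$accession[reps$species == "spA"], "a1")
  expect_equal(sel$outgroup_accession, "og1")
  # tie at 300 codons: lexicographically first id wins
  cov2 <- cov; cov2["a2"] <- 300
  sel2 <- select_representatives(cov2, sp_map, outgroup = c("og1", "og2"))
  expect_equal(sel2$representatives$accession[
    sel2$representatives$species == "spA"], "a1")
  # a species entirely missing makes the gene untestable
  cov3 <- cov; cov3[c("b1")] <- 0
  sel3 <- select_representatives(cov3, sp_map, outgroup = c("og1", "og2"))
  expect_false(sel3$testable)
  expect_match(sel3$reason, "spB")
})

test_that("codon coverage counts codons unbroken by missing data", {
  gm <- gene_model("g1", "chr1", "+", rbind(c(0L, 9L)))
  hm <- toy_hm(cbind(x = c("A", "G", "-"), y = c("A", "G", "C")),
               pos = c(1, 4, 5))  # codons 0, 1, 1
  cov <- codon_coverage(hm, gm)
  expect_equal(unname(cov["x"]), 2L)  # codon 1 broken for x
  expect_equal(unname(cov["y"]), 3L)
})

test_that("clade-diagnostic sites require completely disjoint allele sets", {
  gm <- gene_model("g1", "chr1", "+", rbind(c(0L, 6L)))
  cds <- "GAAGAA"
  # pos 1 (second codon base): target all T (GTA=Val), others all A (GAA=Glu)
  # pos 2: target {T, C} overlaps nothing but others {C} -> overlap with C
  hm <- toy_hm(cbind(a1 = c("T", "T"), a2 = c("T", "C"),
                     b1 = c("A", "C"), c1 = c("A", "C"),
                     og = c("A", "C")),
               pos = c(1, 2))
  rec <- clade_diagnostic_sites(hm, gm, cds, target = c("a1", "a2"),
                                species = sp_map[c("a1", "a2", "b1", "c1")],
                                outgroup = "og")
  expect_equal(rec$n_nonsyn, 1L)
  expect_equal(rec$n_syn, 0L)
  expect_equal(rec$sites$pos, 1L)
  expect_equal(rec$sites$aa_target, "V")
  expect_equal(rec$sites$aa_other, "E")
})

test_that("the coverage rule excludes sites without full species sampling", {
  gm <- gene_model("g1", "chr1", "+", rbind(c(0L, 6L)))
  cds <- "GAAGAA"
  # spC missing at site 1; outgroup missing at site 2; site 3 fine (syn)
  hm <- toy_hm(cbind(a1 = c("T", "T", "G"), a2 = c("T", "T", "G"),
                     b1 = c("A", "A", "A"), c1 = c("-", "A", "A"),
                     og = c("A", "-", "A")),
               pos = c(0, 1, 2))
  rec <- clade_diagnostic_sites(hm, gm, cds, target = c("a1", "a2"),
                                species = sp_map[c("a1", "a2", "b1", "c1")],
                                outgroup = "og")
  expect_equal(nrow(rec$sites), 1L)
  expect_equal(rec$sites$pos, 2L)   # GAA -> GAG, synonymous
  expect_equal(rec$n_syn, 1L)
  expect_equal(rec$n_nonsyn, 0L)
})

test_that("polymorphism is tolerated only while the sets stay disjoint", {
  gm <- gene_model("g1", "chr1", "+", rbind(c(0L, 6L)))
  cds <- "GAAGAA"
  # target {T,G}, others {A}: disjoint despite polymorphism
  hm <- toy_hm(cbind(a1 = "T", a2 = "G", b1 = "A", c1 = "A", og = "A"),
               pos = 1)
  rec <- clade_diagnostic_sites(hm, gm, cds, c("a1", "a2"),
                                sp_map[c("a1", "a2", "b1", "c1")], "og")
  expect_equal(nrow(rec$sites), 1L)
  # any cross-pair changing the amino acid marks it nonsynonymous
  expect_equal(rec$sites$class, "nonsynonymous")
})

test_that("counting is invariant to accession order and reference labeling", {
  sim <- demo_sim()
  gm <- gene_model("g0001", "chr1", "+", rbind(c(0L, 10002L)))
  cds <- paste(rep("GAA", 3334), collapse = "")
  target <- c("esc1", "esc2", "esc3")
  species <- sim$sst$accessions[setdiff(names(sim$sst$accessions), "out")]
  r1 <- clade_diagnostic_sites(sim$hm, gm, cds, target, species, "out")
  perm <- rev(sim$hm$accessions)
  hm2 <- haploid_matrix(sim$hm$chrom, sim$hm$pos, sim$hm$ref,
                        sim$hm$h[, perm], accessions = perm,
                        class = sim$hm$class, gene = sim$hm$gene)
  r2 <- clade_diagnostic_sites(hm2, gm, cds, rev(target), species, "out")
  expect_equal(r1$sites$pos, r2$sites$pos)
  expect_equal(r1$n_nonsyn, r2$n_nonsyn)
})

test_that("substitutions placed on a clade stem are recovered exactly", {
  # build a matrix by hand: 4 diagnostic sites for {a1,a2}, background
  # polymorphic sites that overlap between the sides
  gm <- gene_model("g1", "chr1", "+", rbind(c(0L, 30L)))
  cds <- paste(rep("GAAGA", 6), collapse = "")
  hm <- toy_hm(cbind(a1 = c("T", "C", "T", "G", "A", "C"),
                     a2 = c("T", "C", "T", "G", "G", "C"),
                     b1 = c("A", "A", "A", "A", "G", "C"),
                     c1 = c("A", "A", "A", "A", "A", "A"),
                     og = c("A", "A", "A", "A", "A", "C")),
               pos = c(1, 4, 7, 10, 13, 16))
  rec <- clade_diagnostic_sites(hm, gm, cds, c("a1", "a2"),
                                sp_map[c("a1", "a2", "b1", "c1")], "og")
  expect_equal(rec$sites$pos, c(1, 4, 7, 10))
  # sites 13/16 overlap between sides and are never counted
  other <- clade_diagnostic_sites(hm, gm, cds, c("b1"),
                                  sp_map[c("a1", "a2", "b1", "c1")], "og")
  expect_equal(nrow(other$sites), 0L)
})

test_that("monophyly eligibility follows the rooted gene tree", {
  t1 <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,(c1:1,og:1):1):1);")
  expect_true(monophyly_eligibility(t1, c("a1", "a2"), "og")$eligible)
  t2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,(c1:1,og:1):1):1);")
  expect_false(monophyly_eligibility(t2, c("a1", "a2"), "og")$eligible)
  miss <- monophyly_eligibility(t2, c("a1", "zz"), "og")
  expect_false(miss$eligible)
  expect_match(miss$reason, "missing")
})

test_that("short internodes drastically cut monophyly eligibility", {
  # a clade subtended by a 0.25-cu internode is seldom monophyletic
  sst <- sim_species_tree(paste0(
    "(((A1:100000,A2:100000):20000,B:120000):400000,O:520000);"))
  gt <- simulate_gene_trees(sst, 400, seed = 55,
                            lineages_per_accession = 1)
  elig <- mean(vapply(gt, function(tr)
    monophyly_eligibility(tr, c("A1", "A2"), "O")$eligible, logical(1)))
  expect_lt(elig, 0.6)
  expect_gt(elig, 0.05)
})

test_that("positive-selection proportions and FDR match the definitions", {
  mk <- function(n, k) c(runif(k, 0, 0.0099), runif(n - k, 0.011, 1))
  set.seed(3)
  s1 <- significance_summary(mk(4447, 137))
  expect_equal(s1$n_significant, 137L)
  expect_equal(round(100 * s1$proportion, 2), 3.08)
  expect_equal(round(100 * s1$fdr, 1), 32.5)
  s2 <- significance_summary(mk(3819, 179))
  expect_equal(round(100 * s2$proportion, 2), 4.69)
  expect_equal(round(100 * s2$fdr, 1), 21.3)
  s3 <- significance_summary(mk(958, 38))
  expect_equal(round(100 * s3$fdr, 1), 25.2)
  s0 <- significance_summary(runif(100, 0.5, 1))
  expect_equal(s0$n_significant, 0L)
  expect_true(is.na(s0$fdr))
})

test_that("the built-in excess-nonsynonymous screen behaves sanely", {
  expect_lt(excess_nonsyn_test(30, 0, 0.75), 0.01)
  expect_gt(excess_nonsyn_test(3, 1, 0.75), 0.3)
  expect_true(is.na(excess_nonsyn_test(0, 0)))
})
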