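test_that("heterozygosity is counted per accession over assayed sites", {
  vm <- toy_vm(cbind(s1 = c("A/G", "A/A", "C/T", "G/G", "A/A",
                            "A/A", "T/T", "C/C", "G/G", "A/C"),
                     s2 = c("A/A", "A/A", "-", "G/G", "A/A",
                            "A/A", "T/T", "C/C", "G/G", "A/A"),
                     s3 = rep("-", 10)))
  hh <- heterozygosity(vm)
  expect_equal(hh$H[hh$accession == "s1"], 3 / 10)  # 3 het of 10
  expect_equal(hh$H[hh$accession == "s2"], 0)
  expect_true(is.na(hh$H[hh$accession == "s3"]))    # no assayed sites
  vm2 <- toy_vm(cbind(s1 = c("A/G", "A/G", "A/A", "A/A", "A/A",
                             "A/A", "A/A", "A/A", "A/A", "A/A")))
  expect_equal(heterozygosity(vm2)$H, 0.2)
})

test_that("inbred accessions are less heterozygous than outcrossers", {
  sst <- demo_species_tree()
  gt <- cached("div_gt", simulate_gene_trees(sst, 150, seed = 61))
  f <- c(esc1 = 1, esc2 = 0, esc3 = 1, arc1 = 0, arc2 = 1,
         per1 = 0, per2 = 0, hab1 = 0, hab2 = 0, out = 0)
  vm <- simulate_variants(gt, sites_per_gene = 20, seed = 62,
                          inbreeding = f)
  hh <- heterozygosity(vm)
  selfers <- hh$H[hh$accession %in% c("esc1", "esc3", "arc2")]
  outx <- hh$H[hh$accession %in% c("esc2", "arc1", "per1", "per2")]
  expect_true(all(selfers == 0))
  expect_true(all(outx > 0))
})

test_that("allele sorting in other species is recognised", {
  species <- c(s1 = "spA", s2 = "spA", s3 = "spB", s4 = "spC")
  # site 1: s1 het A/G, spB segregates A and G -> shared
  # site 2: s1 het A/C, C seen nowhere else   -> private
  vm <- toy_vm(cbind(s1 = c("A/G", "A/C"), s2 = c("A/A", "A/A"),
                     s3 = c("A/G", "A/A"), s4 = c("G/G", "A/A")))
  prof <- shared_het_profile(vm, species)
  expect_equal(prof$n_shared[prof$accession == "s1"], 1L)
  expect_equal(prof$shared_prop[prof$accession == "s1"], 0.5)
  # strict variant: both alleles must sort within one other species
  profs <- shared_het_profile(vm, species, strict = TRUE)
  expect_equal(profs$n_shared[profs$accession == "s1"], 1L)
})

test_that("shared-het proportion is far more uniform than H itself", {
  # deep coalescence: species split 0.1-0.5 cu ago, so most
  # heterozygosity is ancestral polymorphism still sorting everywhere;
  # an inbreeding gradient then spreads H while sharing stays put
  sst <- sim_species_tree(paste0(
    "((((s1:16000,s2:16000):8000,s3:24000):8000,",
    "(s4:20000,s5:20000):12000):8000,s6:40000);"))
  gt <- simulate_gene_trees(sst, 250, seed = 61)
  f <- c(s1 = 0.8, s2 = 0.6, s3 = 0.4, s4 = 0.2, s5 = 0, s6 = 0.7)
  vm <- simulate_variants(gt, sites_per_gene = 40, seed = 63,
                          inbreeding = f)
  hh <- heterozygosity(vm)
  prof <- shared_het_profile(vm, sst$accessions)
  cv <- function(x) sd(x, na.rm = TRUE) / mean(x, na.rm = TRUE)
  expect_gt(mean(prof$shared_prop), 0.4)  # sharing is pervasive
  expect_lt(cv(prof$shared_prop), cv(hh$H))
})

test_that("a synthetic F1 carries both parents' group-specific alleles", {
  groups <- c(p1 = "G1", p2 = "G1", q1 = "G2", q2 = "G2",
              r1 = "G3", f1 = NA)
  # ten sites fixed G1 = A, G2 = G, G3 = C; F1 het A/G everywhere
  n <- 10
  geno <- cbind(p1 = rep("A/A", n), p2 = rep("A/A", n),
                q1 = rep("G/G", n), q2 = rep("G/G", n),
                r1 = rep("C/C", n), f1 = rep("A/G", n))
  vm <- toy_vm(geno)
  share <- group_specific_allele_share(vm, "f1", groups[1:5])
  expect_equal(unname(share["G1"]), 1)
  expect_equal(unname(share["G2"]), 1)
  expect_equal(unname(share["G3"]), 0)
  # a non-admixed control accession has no het sites at all
  ctrl <- group_specific_allele_share(vm, "p1", groups[c(2:5)])
  expect_true(all(is.na(ctrl)))
  expect_equal(attr(ctrl, "n_het"), 0L)
})

test_that("pairwise distances are symmetric, zero-diagonal and exact", {
  hm <- toy_hm(cbind(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "A"),
                     c = c("A", "-", "G", "T")))
  d <- pairwise_distance(hm)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)      # 3 joint sites, all equal
  hm2 <- toy_hm(cbind(a = c("A", "-"), b = c("-", "G")))
  expect_true(is.na(pairwise_distance(hm2)["a", "b"]))
})

test_that("distances match the Jukes-Cantor expectation on simulated pairs", {
  # two sequences diverged t = 0.15 substitutions/site each from the
  # ancestor; expected observed distance (3/4)(1 - exp(-4*0.3/3))
  set.seed(77)
  L <- 20000
  jc_evolve <- function(seq, t) {
    p_diff <- 3 / 4 * (1 - exp(-4 * t / 3))
    hit <- runif(L) < p_diff
    seq[hit] <- vapply(seq[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    seq
  }
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  s1 <- jc_evolve(anc, 0.15)
  s2 <- jc_evolve(anc, 0.15)
  hm <- toy_hm(cbind(x = s1, y = s2))
  d <- pairwise_distance(hm)["x", "y"]
  # JC is Markov: two branches of 0.15 compose to a 0.3 path, so the
  # expected observed distance is the closed form at t = 0.3
  jc_total <- 3 / 4 * (1 - exp(-4 * 0.3 / 3))
  se <- sqrt(jc_total * (1 - jc_total) / L)
  expect_lt(abs(d - jc_total), 3 * se)
})

test_that("distances are equivariant under accession reordering", {
  sim <- demo_sim()
  d1 <- pairwise_distance(sim$hm)
  perm <- rev(sim$hm$accessions)
  hm2 <- haploid_matrix(sim$hm$chrom, sim$hm$pos, sim$hm$ref,
                        sim$hm$h[, perm], accessions = perm)
  d2 <- pairwise_distance(hm2)
  expect_equal(d2[sim$hm$accessions, sim$hm$accessions], d1)
})
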