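test_that("site patterns are read off a toy alignment", {
  # rows: ABBA, ABBA, BABA, BBBA, AABA over (p1, p2, p3, o); A="A", B="G"
  hm <- toy_hm(cbind(p1 = c("A", "A", "G", "G", "A"),
                     p2 = c("G", "G", "A", "G", "A"),
                     p3 = c("G", "G", "G", "G", "G"),
                     o  = c("A", "A", "A", "A", "A")))
  cnt <- count_patterns(hm, "p1", "p2", "p3", "o")
  expect_equal(cnt$n_abba, 2L)
  expect_equal(cnt$n_baba, 1L)
})

test_that("sites missing in any trio taxon or multiallelic are excluded", {
  hm <- toy_hm(cbind(p1 = c("A", "A", "A"),
                     p2 = c("G", "G", "C"),
                     p3 = c("G", "G", "G"),
                     o  = c("-", "A", "A")))
  cnt <- count_patterns(hm, "p1", "p2", "p3", "o")
  # site 1: outgroup missing; site 3: three alleles; only site 2 counts
  expect_equal(cnt$n_abba, 1L)
  expect_equal(cnt$n_baba, 0L)
})

test_that("D arithmetic and the undefined case behave as specified", {
  expect_equal(d_statistic(30, 10)$D, 0.5)
  expect_equal(d_statistic(15, 15)$D, 0)
  und <- d_statistic(0, 0)
  expect_true(is.na(und$D))
  expect_true(is.na(und$p))
  expect_equal(d_statistic(30, 10)$p, binom.test(30, 40)$p.value)
  expect_lt(abs(d_statistic(30, 10, test = "chisq")$p -
                chisq.test(c(30, 10))$p.value), 1e-12)
})

test_that("swapping P1 and P2 negates D exactly", {
  sim <- demo_sim()
  for (tri in list(c("esc1", "esc2", "per1"), c("arc1", "arc2", "hab1"),
                   c("esc1", "arc1", "per2"))) {
    a <- count_patterns(sim$hm, tri[1], tri[2], tri[3], "out")
    b <- count_patterns(sim$hm, tri[2], tri[1], tri[3], "out")
    expect_equal(a$n_abba, b$n_baba)
    expect_equal(a$n_baba, b$n_abba)
    if (a$n_abba + a$n_baba > 0)
      expect_equal(d_statistic(a$n_abba, a$n_baba)$D,
                   -d_statistic(b$n_abba, b$n_baba)$D)
  }
})

test_that("ILS alone leaves ABBA and BABA balanced", {
  # a quartet with a 1-cu internode and a moderate outgroup keeps a
  # useful fraction of sites trio-informative
  sst <- sim_species_tree(
    "(((P1:120000,P2:120000):80000,P3:200000):400000,O:600000);")
  gt <- simulate_gene_trees(sst, 1500, seed = 71,
                            lineages_per_accession = 1)
  vm <- simulate_variants(gt, sites_per_gene = 8, seed = 72)
  hm <- resolve_heterozygotes(vm, seed = 73)
  cnt <- count_patterns(hm, "P1", "P2", "P3", "O")
  expect_gt(cnt$n_abba + cnt$n_baba, 50)
  expect_gt(binom.test(cnt$n_abba, cnt$n_abba + cnt$n_baba)$p.value, 0.01)
})

test_that("bootstrap CIs collapse for degenerate window sets", {
  counts <- data.frame(n_abba = rep(13L, 8), n_baba = rep(7L, 8))
  bs <- bootstrap_d(counts, n_replicates = 500, seed = 2)
  expect_equal(bs$ci, c(0.3, 0.3))
  expect_true(bs$excludes_zero)
  one <- bootstrap_d(data.frame(n_abba = 5L, n_baba = 10L),
                     n_replicates = 100, seed = 2)
  expect_equal(one$ci, c(-1 / 3, -1 / 3))
  expect_error(bootstrap_d(data.frame(n_abba = 0L, n_baba = 0L)),
               "informative")
})

test_that("bootstrap CIs cover zero on null window counts", {
  # 20 null replicates: windowed pattern counts under symmetric ILS
  set.seed(404)
  cover <- vapply(1:20, function(r) {
    n <- rpois(40, 6)
    counts <- data.frame(n_abba = rbinom(40, n, 0.5))
    counts$n_baba <- n - counts$n_abba
    bs <- bootstrap_d(counts, n_replicates = 400, seed = r)
    !bs$excludes_zero
  }, logical(1))
  expect_gte(sum(cover), 17L)
})

test_that("the clade-wide summary applies the joint thresholds", {
  scan <- data.frame(
    trio = rep(1:2, each = 4), window = rep(1:4, 2),
    n_abba = c(30, 8, 3, 0, 25, 40, 3, 0),
    n_baba = c(2, 1, 3, 0, 2, 39, 3, 0))
  ds <- t(mapply(function(a, b) unlist(d_statistic(a, b)[c("D", "p")]),
                 scan$n_abba, scan$n_baba))
  scan$D <- ds[, 1]; scan$p <- ds[, 2]
  s <- cladewide_summary(scan, n_branches = 5, n_windows = 4)
  # window 1 passes for both trios (counted once); window 2 trio 2 has
  # |D| tiny; others fail count/threshold rules
  expect_equal(s$n_significant, 1L)
  expect_equal(s$frac_significant, 0.25)
  expect_equal(s$per_branch_fraction, 1 / 20)
  # invariant to window ordering
  sh <- cladewide_summary(scan[sample(nrow(scan)), ], n_branches = 5,
                          n_windows = 4)
  expect_equal(sh$n_significant, s$n_significant)
  # zero significant windows
  s0 <- cladewide_summary(scan[scan$window == 4, ], n_branches = 5,
                          n_windows = 4)
  expect_equal(s0$n_significant, 0L)
  expect_equal(s0$per_branch_fraction, 0)
})
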