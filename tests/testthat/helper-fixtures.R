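# Shared fixtures, built in code.  Expensive simulations are cached in
# this environment so several test files can reuse them.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# A small multisample VCF with controllable per-genotype DP and a
# site-level MQ, written to a temp file.
write_toy_vcf <- function(path, samples, records) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, mq, gts, dps) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS",
          sprintf("MQ=%s", mq), "GT:DP",
          paste0(gts, ":", dps)), collapse = "\t")
}

# construct a variant_matrix from genotype strings like "A/G", "-"
toy_vm <- function(geno, chrom = "chr1", pos = NULL, ref = NULL,
                   class = NULL, gene = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  split1 <- function(g, k) ifelse(g == "-", NA_character_,
                                  vapply(strsplit(g, "/"), `[`, "", k))
  a1 <- apply(geno, 2, split1, k = 1L)
  a2 <- apply(geno, 2, split1, k = 2L)
  if (n == 1L) { a1 <- t(a1); a2 <- t(a2) }
  colnames(a1) <- colnames(a2) <- colnames(geno)
  variant_matrix(rep(chrom, n), pos %||% seq_len(n),
                 ref %||% rep("A", n), a1, a2,
                 accessions = colnames(geno), class = class, gene = gene)
}

# haploid matrix straight from single-allele strings
toy_hm <- function(h, chrom = "chr1", pos = NULL, ref = NULL,
                   class = NULL, gene = NULL) {
  h <- as.matrix(h)
  h[h == "-"] <- NA_character_
  haploid_matrix(rep(chrom, nrow(h)), pos %||% seq_len(nrow(h)),
                 ref %||% rep("A", nrow(h)), h,
                 accessions = colnames(h), class = class, gene = gene)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quintet simulations for the five-taxon direction tests: a localized
# per1 -> esc1 block pulse (genes 51-70) and a matched pulse-free run
dfoil_sim <- function() {
  cached("dfoil_sim", {
    sst <- demo_species_tree()
    sstI <- inject_introgression(sst, "per1", "esc1", 30000, 1,
                                 genes = 51:70)
    gt <- simulate_gene_trees(sstI, 200, seed = 21)
    vm <- simulate_variants(gt, sites_per_gene = 150, seed = 22)
    hm <- resolve_heterozygotes(vm, seed = 23)
    w <- partition_windows(vm, 100000, min_sites = 10)
    gt0 <- simulate_gene_trees(sst, 200, seed = 31)
    vm0 <- simulate_variants(gt0, sites_per_gene = 150, seed = 32)
    hm0 <- resolve_heterozygotes(vm0, seed = 33)
    w0 <- partition_windows(vm0, 100000, min_sites = 10)
    list(sst = sst, hm = hm, w = w, hm0 = hm0, w0 = w0)
  })
}

# shared demo-clade simulation (pulse-free)
demo_sim <- function() {
  cached("demo_sim", {
    sst <- demo_species_tree()
    gts <- simulate_gene_trees(sst, 300, seed = 42)
    vm <- simulate_variants(gts, sites_per_gene = 25, seed = 43)
    list(sst = sst, gts = gts, vm = vm,
         hm = resolve_heterozygotes(vm, seed = 44))
  })
}
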