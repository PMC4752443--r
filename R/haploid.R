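#' Resolve heterozygous genotypes to a haploid matrix
#'
#' At each heterozygous genotype one of the two alleles is selected at
#' random; homozygous genotypes map to their single allele unchanged.
#' One global seeded RNG stream is consumed in site-major,
#' accession-minor order (one draw per cell, whether or not the cell is
#' heterozygous), so the resolution is reproducible and stable under any
#' change that does not alter matrix shape.
#'
#' @param x a `variant_matrix` (a `haploid_matrix` is returned as-is,
#'   making the operation idempotent).
#' @param seed integer seed recorded in the result.
#' @return a `haploid_matrix`: fields `chrom`, `pos`, `ref`, `h` (sites x
#'   accessions single-allele matrix), `accessions`, `seed`, plus any
#'   `class`/`gene` annotations carried over.
#' @export
resolve_heterozygotes <- function(x, seed) {
  if (inherits(x, "haploid_matrix")) return(x)
  stopifnot(inherits(x, "variant_matrix"))
  n <- n_sites(x); m <- length(x$accessions)
  u <- with_seed(seed, matrix(stats::runif(n * m), nrow = n, byrow = TRUE))
  h <- ifelse(u < 0.5, x$a1, x$a2)
  dimnames(h) <- list(NULL, x$accessions)
  structure(list(chrom = x$chrom, pos = x$pos, ref = x$ref, h = h,
                 accessions = x$accessions, seed = as.integer(seed),
                 class = x$class, gene = x$gene),
            class = "haploid_matrix")
}

#' @export
print.haploid_matrix <- function(x, ...) {
  cat(sprintf("haploid_matrix: %d sites x %d accessions (seed %d)\n",
              n_sites(x), length(x$accessions), x$seed))
  invisible(x)
}

#' Treat an already-haploid allele table as a haploid matrix
#'
#' @param chrom,pos,ref site coordinates as in [variant_matrix()].
#' @param h character matrix (sites x accessions) of single alleles.
#' @param accessions accession ids.
#' @param class,gene optional per-site annotations.
#' @param seed seed to record (`NA` when not derived from a resolution).
#' @return a `haploid_matrix`.
#' @export
haploid_matrix <- function(chrom, pos, ref, h, accessions = colnames(h),
                           class = NULL, gene = NULL, seed = NA_integer_) {
  h <- as.matrix(h)
  colnames(h) <- accessions
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), h = h, accessions = accessions,
                 seed = seed, class = class, gene = gene),
            class = "haploid_matrix")
}

#' @export
subset_sites.haploid_matrix <- function(vm, i) {
  haploid_matrix(vm$chrom[i], vm$pos[i], vm$ref[i],
                 vm$h[i, , drop = FALSE], accessions = vm$accessions,
                 class = vm$class[i], gene = vm$gene[i], seed = vm$seed)
}
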