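#' Multisample diploid variant matrix
#'
#' The central data container: a table of variable (or assayed) sites by
#' accessions, holding an unordered diploid allele pair per cell.
#' Coordinates are 0-based half-open internally; all human-readable output
#' uses 1-based positions (the VCF display convention).
#'
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 0-based site positions, strictly increasing
#'   within each chromosome.
#' @param ref character vector of reference (or ancestral) alleles.
#' @param a1,a2 character matrices (sites x accessions) holding the two
#'   alleles of each genotype; `NA` marks missing data.  Pairs are stored
#'   unordered and are normalised so that `a1 <= a2`.
#' @param accessions character vector of accession identifiers (column
#'   names of `a1`/`a2`).
#' @param class optional per-site substitution class
#'   (`"synonymous"`, `"nonsynonymous"`, `"noncoding"` or `NA`).
#' @param gene optional per-site gene identifier.
#' @param dp,mq optional numeric matrices of per-genotype sequencing depth
#'   and mapping quality, same shape as `a1`.
#' @return an object of class `variant_matrix`.
#' @export
variant_matrix <- function(chrom, pos, ref, a1, a2, accessions = colnames(a1),
                           class = NULL, gene = NULL, dp = NULL, mq = NULL) {
  n <- length(pos)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (length(chrom) != n || length(ref) != n)
    stopf("chrom, pos and ref must have equal length")
  if (nrow(a1) != n || nrow(a2) != n || ncol(a1) != ncol(a2))
    stopf("allele matrices must be sites x accessions")
  if (is.null(accessions)) stopf("accession identifiers are required")
  # normalise unordered pairs so a1 <= a2
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  bad <- (is.na(a1) != is.na(a2))
  if (any(bad)) stopf("half-missing genotypes at %d cells", sum(bad))
  alleles <- c(a1, a2)
  if (!all(alleles %in% c("A", "C", "G", "T", NA)))
    stopf("alleles must be A, C, G, T or NA")
  colnames(a1) <- colnames(a2) <- accessions
  pos <- as.integer(pos)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0))
      stopf("positions must be strictly increasing within chromosome %s", ch)
  }
  structure(list(chrom = as.character(chrom), pos = pos,
                 ref = as.character(ref), a1 = a1, a2 = a2,
                 accessions = accessions,
                 class = if (!is.null(class)) as.character(class) else NULL,
                 gene = if (!is.null(gene)) as.character(gene) else NULL,
                 dp = dp, mq = mq),
            class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("variant_matrix: %d sites x %d accessions (%s)\n",
              n_sites(x), length(x$accessions),
              paste(unique(x$chrom), collapse = ", ")))
  invisible(x)
}

#' Number of sites in a variant or haploid matrix
#' @param x a `variant_matrix` or `haploid_matrix`.
#' @return integer site count.
#' @export
n_sites <- function(x) length(x$pos)

#' Subset a variant or haploid matrix by site index
#' @param vm a `variant_matrix` or `haploid_matrix`.
#' @param i integer or logical site index.
#' @return the subsetted object.
#' @export
subset_sites <- function(vm, i) UseMethod("subset_sites")

#' @export
subset_sites.variant_matrix <- function(vm, i) {
  variant_matrix(vm$chrom[i], vm$pos[i], vm$ref[i],
                 vm$a1[i, , drop = FALSE], vm$a2[i, , drop = FALSE],
                 accessions = vm$accessions,
                 class = vm$class[i], gene = vm$gene[i],
                 dp = if (!is.null(vm$dp)) vm$dp[i, , drop = FALSE],
                 mq = if (!is.null(vm$mq)) vm$mq[i, , drop = FALSE])
}

#' Per-site count of distinct alleles across all accessions
#' @param vm a `variant_matrix` or `haploid_matrix`.
#' @return integer vector of allele counts (reference allele not implied).
#' @export
site_allele_count <- function(vm) {
  al <- if (inherits(vm, "haploid_matrix")) cbind(vm$h)
        else cbind(vm$a1, vm$a2)
  vapply(seq_len(n_sites(vm)), function(i) {
    length(unique(stats::na.omit(al[i, ])))
  }, integer(1))
}

#' Genotype filtering profile
#'
#' Presets follow the two alignments used throughout: the high-quality
#' `HQ` set (depth >= 3, mapping quality >= 30) and the high-depth `HD`
#' set (depth >= 10, mapping quality >= 30).
#'
#' @param name `"HQ"`, `"HD"` or `"custom"`.
#' @param min_depth,min_mq per-genotype thresholds (used for `"custom"`,
#'   overriding a preset if supplied).
#' @param min_accessions minimum number of accessions with data a site
#'   must retain to be kept.
#' @return a `filter_profile` object.
#' @export
filter_profile <- function(name = c("HQ", "HD", "custom"),
                           min_depth = NULL, min_mq = NULL,
                           min_accessions = 1L) {
  name <- match.arg(name)
  preset <- switch(name, HQ = c(3L, 30L), HD = c(10L, 30L), custom = c(0L, 0L))
  structure(list(name = name,
                 min_depth = as.integer(min_depth %||% preset[1]),
                 min_mq = as.integer(min_mq %||% preset[2]),
                 min_accessions = as.integer(min_accessions)),
            class = "filter_profile")
}

#' Apply a filter profile to a variant matrix
#'
#' Genotypes failing the depth or mapping-quality threshold become
#' missing; sites left with fewer than `profile$min_accessions`
#' non-missing accessions are dropped.  Filtering is monotone: raising
#' `min_depth` (or `min_mq`) can only remove genotypes.
#'
#' @param vm a `variant_matrix` carrying `dp`/`mq` matrices (sites
#'   without them are treated as passing).
#' @param profile a [filter_profile()].
#' @return the filtered `variant_matrix`.
#' @export
apply_filter <- function(vm, profile) {
  stopifnot(inherits(profile, "filter_profile"))
  fail <- matrix(FALSE, n_sites(vm), length(vm$accessions))
  if (!is.null(vm$dp)) fail <- fail | (!is.na(vm$dp) & vm$dp < profile$min_depth)
  if (!is.null(vm$mq)) fail <- fail | (!is.na(vm$mq) & vm$mq < profile$min_mq)
  vm$a1[fail] <- NA_character_
  vm$a2[fail] <- NA_character_
  keep <- rowSums(!is.na(vm$a1)) >= profile$min_accessions
  subset_sites(vm, keep)
}

#' Read a multisample VCF into a variant matrix
#'
#' Parses a VCF 4.x file (via the vcfR parser), applies a genotype
#' filter profile using per-sample `DP` and the site `MQ` (a per-sample
#' `MQ` FORMAT field is used when present), and returns the retained
#' sites.  Multiallelic sites are kept in the matrix; pattern-counting
#' and association operations exclude them downstream.
#'
#' @param path VCF file.
#' @param profile a [filter_profile()].
#' @param accessions optional expected sample names; a sample in the VCF
#'   that is not listed (or vice versa) raises a metadata mismatch error.
#' @return a `variant_matrix` (positions converted to the 0-based
#'   internal convention).
#' @export
read_vcf <- function(path, profile = filter_profile("HQ"), accessions = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(v@gt) == 0) stopf("VCF %s has no genotype records", path)
  samples <- colnames(v@gt)[-1]
  if (!is.null(accessions)) {
    extra <- setdiff(samples, accessions)
    miss <- setdiff(accessions, samples)
    if (length(extra) || length(miss))
      stopf("sample metadata mismatch (unknown: %s; absent: %s)",
            paste(extra, collapse = ","), paste(miss, collapse = ","))
    samples <- accessions
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  fmt_mq <- if (any(grepl("MQ", v@gt[, "FORMAT"])))
    suppressWarnings(vcfR::extract.gt(v, element = "MQ", as.numeric = TRUE))
  else NULL
  info_mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  n <- nrow(gt)
  alleles_site <- lapply(seq_len(n), function(i)
    c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]))
  a1 <- a2 <- matrix(NA_character_, n, length(samples),
                     dimnames = list(NULL, samples))
  gt <- gt[, samples, drop = FALSE]
  for (j in seq_along(samples)) {
    g <- gt[, j]
    parts <- strsplit(ifelse(is.na(g), ".", g), "[/|]")
    i1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    i2 <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2) p[2] else p[1], "")))
    ok <- !is.na(i1) & !is.na(i2)
    a1[ok, j] <- mapply(function(i, k) alleles_site[[i]][k + 1],
                        which(ok), i1[ok])
    a2[ok, j] <- mapply(function(i, k) alleles_site[[i]][k + 1],
                        which(ok), i2[ok])
  }
  mqm <- if (!is.null(fmt_mq)) fmt_mq[, samples, drop = FALSE]
  else matrix(rep(info_mq, length(samples)), n,
              dimnames = list(NULL, samples))
  vm <- variant_matrix(chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]) - 1L,
                       ref = fix[, "REF"], a1 = a1, a2 = a2,
                       accessions = samples,
                       dp = dp[, samples, drop = FALSE], mq = mqm)
  apply_filter(vm, profile)
}

#' Write a variant matrix to disk
#'
#' Two plain-text dialects are supported: `"tsv"`, a flat
#' one-line-per-site table (header of accession ids; columns chromosome,
#' 1-based position, reference allele, optional class/gene annotations,
#' then one `X/Y` allele-pair column per accession, `-` for missing), and
#' `"vcf"`, a minimal VCF 4.2 rendering.  A write-then-read round trip
#' reproduces sites, accessions and genotypes exactly.
#'
#' @param vm a `variant_matrix`.
#' @param path output file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_variant_matrix <- function(vm, path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  n <- n_sites(vm)
  pair <- function(i) {
    p <- ifelse(is.na(vm$a1[i, ]), "-", paste0(vm$a1[i, ], "/", vm$a2[i, ]))
    p
  }
  if (dialect == "tsv") {
    has_ann <- !is.null(vm$class) || !is.null(vm$gene)
    hdr <- c("#chrom", "pos", "ref",
             if (has_ann) c("class", "gene"), vm$accessions)
    lines <- vapply(seq_len(n), function(i) {
      ann <- if (has_ann)
        c(vm$class[i] %||% NA, vm$gene[i] %||% NA)
      else character(0)
      ann[is.na(ann)] <- "."
      paste(c(vm$chrom[i], vm$pos[i] + 1L, vm$ref[i], ann, pair(i)),
            collapse = "\t")
    }, character(1))
    writeLines(c(paste(hdr, collapse = "\t"), lines), path)
  } else {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
             "##INFO=<ID=VC,Number=1,Type=String,Description=\"Substitution class\">",
             "##INFO=<ID=GN,Number=1,Type=String,Description=\"Gene id\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", vm$accessions), collapse = "\t"))
    lines <- vapply(seq_len(n), function(i) {
      obs <- unique(stats::na.omit(c(vm$a1[i, ], vm$a2[i, ])))
      alt <- sort(setdiff(obs, vm$ref[i]))
      all_alleles <- c(vm$ref[i], alt)
      idx <- function(x) match(x, all_alleles) - 1L
      gts <- ifelse(is.na(vm$a1[i, ]), "./.:.",
                    paste0(idx(vm$a1[i, ]), "/", idx(vm$a2[i, ]), ":",
                           if (!is.null(vm$dp)) vm$dp[i, ] else 99L))
      info <- paste0("MQ=", if (!is.null(vm$mq)) max(vm$mq[i, ], na.rm = TRUE) else 60,
                     if (!is.null(vm$class) && !is.na(vm$class[i]))
                       paste0(";VC=", vm$class[i]) else "",
                     if (!is.null(vm$gene) && !is.na(vm$gene[i]))
                       paste0(";GN=", vm$gene[i]) else "")
      paste(c(vm$chrom[i], vm$pos[i] + 1L, ".", vm$ref[i],
              if (length(alt)) paste(alt, collapse = ",") else ".",
              ".", "PASS", info, "GT:DP", gts), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, lines), path)
  }
  invisible(path)
}

#' Read a variant matrix written by [write_variant_matrix()]
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf"`; `"auto"` sniffs the header.
#' @return a `variant_matrix`.
#' @export
read_variant_matrix <- function(path, dialect = c("auto", "tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    first <- readLines(path, n = 1)
    dialect <- if (startsWith(first, "##fileformat=VCF")) "vcf" else "tsv"
  }
  if (dialect == "vcf") {
    vm <- read_vcf(path, filter_profile("custom", 0, 0, 0))
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#")]
    if (length(body)) {
      info <- vapply(strsplit(body, "\t"), `[`, "", 8L)
      grab <- function(key) {
        m <- regmatches(info, regexpr(paste0(key, "=[^;\t]+"), info))
        out <- rep(NA_character_, length(info))
        hit <- grepl(paste0(key, "="), info)
        out[hit] <- sub(paste0(key, "="), "", m)
        out
      }
      cls <- grab("VC"); gn <- grab("GN")
      if (any(!is.na(cls))) vm$class <- cls
      if (any(!is.na(gn))) vm$gene <- gn
    }
    return(vm)
  }
  lines <- readLines(path)
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  has_ann <- length(hdr) >= 5 && hdr[4] == "class" && hdr[5] == "gene"
  acc <- hdr[(if (has_ann) 6 else 4):length(hdr)]
  body <- lines[-1]
  if (!length(body)) {
    empty <- matrix(character(0), 0, length(acc), dimnames = list(NULL, acc))
    return(variant_matrix(character(0), integer(0), character(0),
                          empty, empty, accessions = acc,
                          class = if (has_ann) character(0),
                          gene = if (has_ann) character(0)))
  }
  f <- strsplit(body, "\t")
  getcol <- function(k) vapply(f, `[`, "", k)
  off <- if (has_ann) 5L else 3L
  n <- length(body)
  a1 <- a2 <- matrix(NA_character_, n, length(acc),
                     dimnames = list(NULL, acc))
  for (j in seq_along(acc)) {
    g <- getcol(off + j)
    ok <- g != "-"
    halves <- strsplit(g[ok], "/", fixed = TRUE)
    a1[ok, j] <- vapply(halves, `[`, "", 1L)
    a2[ok, j] <- vapply(halves, `[`, "", 2L)
  }
  cls <- if (has_ann) { x <- getcol(4L); x[x == "."] <- NA; x }
  gn <- if (has_ann) { x <- getcol(5L); x[x == "."] <- NA; x }
  variant_matrix(getcol(1L), as.integer(getcol(2L)) - 1L, getcol(3L),
                 a1, a2, accessions = acc, class = cls, gene = gn)
}
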