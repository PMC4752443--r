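#' Count ABBA/BABA site patterns for an ordered trio plus outgroup
#'
#' Sites are used when all four taxa are non-missing, the site is
#' biallelic across the whole matrix, and the outgroup carries a single
#' allele, which is taken as the ancestral state A.  ABBA means
#' (P1=A, P2=B, P3=B, O=A); BABA means (P1=B, P2=A, P3=B, O=A); all
#' other patterns are ignored.
#'
#' @param h a `haploid_matrix`.
#' @param p1,p2,p3,outgroup accession ids.
#' @param windows optional data.frame from [partition_windows()]; when
#'   given, counts are returned per window row.
#' @param biallelic optional precomputed logical vector
#'   (`site_allele_count(h) == 2`), useful when scanning many trios.
#' @return with `windows`: data.frame `window`, `n_abba`, `n_baba`;
#'   without: list with `n_abba`, `n_baba`.
#' @export
count_patterns <- function(h, p1, p2, p3, outgroup, windows = NULL,
                           biallelic = NULL) {
  stopifnot(inherits(h, "haploid_matrix"))
  cols <- c(p1, p2, p3, outgroup)
  missing <- setdiff(cols, h$accessions)
  if (length(missing)) stopf("accessions not in matrix: %s",
                             paste(missing, collapse = ","))
  if (is.null(biallelic)) biallelic <- site_allele_count(h) == 2L
  x <- h$h[, cols, drop = FALSE]
  ok <- rowSums(is.na(x)) == 0 & biallelic
  o <- x[, 4L]
  abba <- ok & x[, 1L] == o & x[, 2L] != o & x[, 3L] != o
  baba <- ok & x[, 1L] != o & x[, 2L] == o & x[, 3L] != o
  if (is.null(windows))
    return(list(n_abba = sum(abba), n_baba = sum(baba)))
  wi <- window_index(h, windows)
  n_abba <- n_baba <- integer(nrow(windows))
  ta <- table(factor(wi[abba], levels = seq_len(nrow(windows))))
  tb <- table(factor(wi[baba], levels = seq_len(nrow(windows))))
  data.frame(window = seq_len(nrow(windows)),
             n_abba = as.integer(ta), n_baba = as.integer(tb))
}

#' The ABBA-BABA D-statistic and its significance
#'
#' D = (nABBA - nBABA) / (nABBA + nBABA); expected 0 under
#' incomplete lineage sorting alone.  Significance is a two-sided exact
#' binomial test of the ABBA count against equal expected pattern
#' frequencies (a chi-squared alternative is available).  With no
#' informative sites D is undefined (`NA`), not 0.
#'
#' @param n_abba,n_baba pattern counts (or a list/data.frame with these
#'   fields in `n_abba`).
#' @param test `"binomial"` (default) or `"chisq"`.
#' @return list: `D`, `p`, `n_abba`, `n_baba`.
#' @export
d_statistic <- function(n_abba, n_baba = NULL, test = c("binomial", "chisq")) {
  test <- match.arg(test)
  if (is.list(n_abba)) {
    n_baba <- sum(n_abba$n_baba)
    n_abba <- sum(n_abba$n_abba)
  }
  tot <- n_abba + n_baba
  if (tot == 0)
    return(list(D = NA_real_, p = NA_real_, n_abba = 0L, n_baba = 0L))
  D <- (n_abba - n_baba) / tot
  p <- if (test == "binomial")
    stats::binom.test(n_abba, tot, 0.5)$p.value
  else
    stats::chisq.test(c(n_abba, n_baba), p = c(0.5, 0.5))$p.value
  list(D = D, p = p, n_abba = n_abba, n_baba = n_baba)
}

#' Windowed D-statistic scan over many trios
#'
#' @param h a `haploid_matrix`.
#' @param trios data.frame from [enumerate_trios()] (columns `p1`, `p2`,
#'   `p3`, `outgroup`).
#' @param windows data.frame from [partition_windows()].
#' @param test significance test passed to [d_statistic()].
#' @return long-format data.frame: `trio`, `p1`, `p2`, `p3`, `window`,
#'   `chrom`, `start`, `end`, `n_abba`, `n_baba`, `D`, `p`.
#' @export
d_scan <- function(h, trios, windows, test = "binomial") {
  out <- vector("list", nrow(trios))
  bi <- site_allele_count(h) == 2L
  for (i in seq_len(nrow(trios))) {
    cnt <- count_patterns(h, trios$p1[i], trios$p2[i], trios$p3[i],
                          trios$outgroup[i], windows = windows,
                          biallelic = bi)
    ds <- mapply(function(a, b) unlist(d_statistic(a, b, test = test)[c("D", "p")]),
                 cnt$n_abba, cnt$n_baba)
    out[[i]] <- data.frame(trio = i, p1 = trios$p1[i], p2 = trios$p2[i],
                           p3 = trios$p3[i], window = cnt$window,
                           chrom = windows$chrom, start = windows$start,
                           end = windows$end,
                           n_abba = cnt$n_abba, n_baba = cnt$n_baba,
                           D = ds[1, ], p = ds[2, ])
  }
  do.call(rbind, out)
}

#' Block bootstrap of the genome-wide D-statistic
#'
#' Windows are resampled with replacement; each replicate D is computed
#' from the pooled pattern counts of the resampled windows.  The
#' percentile 95% CI of the replicate distribution is used to judge
#' whether a transcriptome-wide D is a genome-wide signal rather than
#' one driven by a few windows.
#'
#' @param counts data.frame with per-window `n_abba`, `n_baba`.
#' @param n_replicates bootstrap replicates (default 10,000).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list: `D` (pooled point estimate), `ci` (percentile
#'   interval), `excludes_zero`, `n_replicates`, `replicates` (the
#'   resampled D values).
#' @export
bootstrap_d <- function(counts, n_replicates = 10000L, seed = 1L,
                        conf = 0.95) {
  if (nrow(counts) == 0 || sum(counts$n_abba + counts$n_baba) == 0)
    stopf("no windows with informative sites")
  point <- d_statistic(sum(counts$n_abba), sum(counts$n_baba))$D
  reps <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(r) {
      i <- sample.int(nrow(counts), nrow(counts), replace = TRUE)
      a <- sum(counts$n_abba[i]); b <- sum(counts$n_baba[i])
      if (a + b == 0) NA_real_ else (a - b) / (a + b)
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(D = point, ci = ci, excludes_zero = ci[1] > 0 || ci[2] < 0,
       n_replicates = n_replicates, replicates = reps)
}

#' Clade-wide summary of windowed introgression evidence
#'
#' Counts the windows showing evidence of introgression for at least one
#' trio under joint thresholds on |D|, the binomial p-value and the raw
#' pattern-count imbalance, and expresses the result per branch queried:
#' per-branch fraction = n_significant / (n_windows x n_branches).
#'
#' @param scan long-format data.frame from [d_scan()] (or any frame with
#'   `window`, `D`, `p`, `n_abba`, `n_baba`).
#' @param n_windows total windows considered (defaults to
#'   `max(scan$window)`); supply the included-window count when windows
#'   below the aligned-site minimum were excluded.
#' @param n_branches number of branches queried.
#' @param min_abs_d,max_p,min_imbalance thresholds (defaults |D| >= 0.2,
#'   p < 1e-4, |ABBA-BABA| >= 10).
#' @param exclude_trios optional trio row indices to drop (e.g. trios
#'   involving known admixed accessions) before summarising.
#' @return list: `n_windows`, `n_significant`, `frac_significant`,
#'   `per_branch_fraction`, `thresholds`, `significant_windows`.
#' @export
cladewide_summary <- function(scan, n_branches, n_windows = NULL,
                              min_abs_d = 0.2, max_p = 1e-4,
                              min_imbalance = 10L, exclude_trios = NULL) {
  if (!is.null(exclude_trios)) scan <- scan[!scan$trio %in% exclude_trios, ]
  n_windows <- n_windows %||% length(unique(scan$window))
  sig <- !is.na(scan$D) & abs(scan$D) >= min_abs_d & scan$p < max_p &
    abs(scan$n_abba - scan$n_baba) >= min_imbalance
  sig_windows <- sort(unique(scan$window[sig]))
  cladewide_fraction(length(sig_windows), n_windows, n_branches,
                     significant_windows = sig_windows,
                     thresholds = list(min_abs_d = min_abs_d, max_p = max_p,
                                       min_imbalance = min_imbalance))
}

#' Clade-wide introgression fraction arithmetic
#'
#' The summary arithmetic of [cladewide_summary()], exposed directly so
#' published window counts can be re-expressed: fraction of windows with
#' evidence for at least one trio, and the per-branch fraction
#' n_significant / (n_windows x n_branches).
#'
#' @param n_significant windows significant for >= 1 trio.
#' @param n_windows total windows.
#' @param n_branches branches queried.
#' @param significant_windows,thresholds optional passthrough fields.
#' @return list: `n_windows`, `n_significant`, `frac_significant`,
#'   `per_branch_fraction`, plus passthrough fields.
#' @export
cladewide_fraction <- function(n_significant, n_windows, n_branches,
                               significant_windows = NULL,
                               thresholds = NULL) {
  list(n_windows = n_windows, n_significant = n_significant,
       frac_significant = n_significant / n_windows,
       per_branch_fraction = n_significant / (n_windows * n_branches),
       significant_windows = significant_windows, thresholds = thresholds)
}
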