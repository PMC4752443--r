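#' Partition a variant matrix into nonoverlapping genomic windows
#'
#' Tiles each chromosome from coordinate 0 in windows of `size` bp
#' (0-based half-open).  The terminal window of a chromosome is
#' truncated at the chromosome length.  Windows with fewer than
#' `min_sites` aligned sites are flagged as excluded rather than
#' dropped, so totals remain auditable; the default `min_sites = 100`
#' matches the convention for 100-kb windows.
#'
#' @param vm a `variant_matrix` (or `haploid_matrix`).
#' @param size window size in bp.
#' @param min_sites minimum aligned sites for a window to be included.
#' @param chrom_lengths optional named vector of chromosome lengths; by
#'   default the last observed site + 1 is used.
#' @return data.frame with columns `chrom`, `start`, `end`,
#'   `n_aligned_sites`, `included`.
#' @export
partition_windows <- function(vm, size, min_sites = 100L,
                              chrom_lengths = NULL) {
  stopifnot(size > 0)
  if (n_sites(vm) == 0 && is.null(chrom_lengths))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_aligned_sites = integer(0),
                      included = logical(0)))
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths)
            else unique(vm$chrom)
  out <- lapply(chroms, function(ch) {
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]]
           else max(vm$pos[vm$chrom == ch]) + 1L
    starts <- seq(0L, len - 1L, by = size)
    ends <- pmin(starts + size, len)
    p <- vm$pos[vm$chrom == ch]
    counts <- vapply(seq_along(starts), function(i)
      sum(p >= starts[i] & p < ends[i]), integer(1))
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(ends), n_aligned_sites = counts)
  })
  res <- do.call(rbind, out)
  res$included <- res$n_aligned_sites >= min_sites
  res
}

#' Assign each site of a matrix to a window row
#'
#' @param vm a `variant_matrix` or `haploid_matrix`.
#' @param windows data.frame from [partition_windows()].
#' @return integer vector: for each site, the row index of its window in
#'   `windows` (`NA` if none).
#' @export
window_index <- function(vm, windows) {
  idx <- rep(NA_integer_, n_sites(vm))
  for (ch in unique(vm$chrom)) {
    w <- which(windows$chrom == ch)
    if (!length(w)) next
    s <- which(vm$chrom == ch)
    j <- findInterval(vm$pos[s], windows$start[w])
    ok <- j >= 1 & vm$pos[s] < windows$end[w][pmax(j, 1)]
    idx[s[ok]] <- w[j[ok]]
  }
  idx
}
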