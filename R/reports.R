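#' Write a data frame as a TSV report
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a square distance matrix with header row and column
#' @param d numeric matrix from [pairwise_distance()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(accession = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read environmental partitions from a TSV file
#'
#' Expects columns `accession`, `factor`, `group`; returns one
#' [env_partition()] per factor level.
#'
#' @param path TSV file.
#' @return named list of `env_partition` objects.
#' @export
read_partition_file <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("accession", "factor", "group")
  if (!all(need %in% names(df)))
    stopf("partition file must have columns %s", paste(need, collapse = ", "))
  out <- lapply(split(df, df$factor), function(x)
    env_partition(x$factor[1],
                  stats::setNames(x$group, x$accession),
                  provenance = path))
  out
}
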