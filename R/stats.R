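# Assembly statistics matching the release-table semantics: statistics are
# computed over sequences strictly longer than `min_len` (500 bp by default),
# and the counts alongside N50/N90 are "number of sequences with lengths
# equal to or larger than" that value.

#' Assembly statistics for one set of sequence lengths
#'
#' Filters to lengths `> min_len`, then computes total length, sequence
#' count, N50/N90 and the count of sequences at least that long, and the
#' maximum length. N50 is the length of the sequence at which the cumulative
#' sum in descending order first reaches half the (filtered) total; when the
#' cumulative sum lands exactly on the boundary, the sequence reaching it
#' defines N50.
#'
#' @param lengths integer vector of sequence lengths in bp.
#' @param min_len sequences must be strictly longer than this to count.
#' @param label row label.
#' @return one-row data.frame: `label`, `total_length`, `number`, `n50`,
#'   `count_ge_n50`, `n90`, `count_ge_n90`, `max_len`.
#' @export
#' @examples
#' assembly_stats(c(5000, 4000, 3000, 2000, 1000))
assembly_stats <- function(lengths, min_len = 500L, label = "All") {
  if (any(lengths < 0)) stop("negative sequence length")
  lens <- sort(as.numeric(lengths[lengths > min_len]), decreasing = TRUE)
  if (!length(lens)) {
    return(data.frame(label = label, total_length = 0, number = 0L, n50 = 0,
                      count_ge_n50 = 0L, n90 = 0, count_ge_n90 = 0L, max_len = 0))
  }
  total <- sum(lens)
  cum <- cumsum(lens)
  nx <- function(frac) {
    i <- which(cum >= frac * total)[1L]
    v <- lens[i]
    c(v, sum(lens >= v))
  }
  a <- nx(0.5)
  b <- nx(0.9)
  data.frame(label = label, total_length = total, number = length(lens),
             n50 = a[1L], count_ge_n50 = as.integer(a[2L]),
             n90 = b[1L], count_ge_n90 = as.integer(b[2L]), max_len = lens[1L])
}

#' Per-chromosome statistics table with an "All" row
#'
#' One row per chromosome plus a pooled "All" row. By construction the All
#' row's total equals the sum of per-chromosome totals, its number the sum of
#' numbers, and its maximum the maximum of maxima.
#'
#' @param per_chrom named list mapping chromosome -> length vector.
#' @param min_len strict lower length bound (see [assembly_stats()]).
#' @return data.frame of [assembly_stats()] rows.
#' @export
stats_table <- function(per_chrom, min_len = 500L) {
  rows <- lapply(names(per_chrom), function(cn)
    assembly_stats(per_chrom[[cn]], min_len, label = cn))
  all_row <- assembly_stats(unlist(per_chrom, use.names = FALSE), min_len, label = "All")
  do.call(rbind, c(rows, list(all_row)))
}

#' Combine per-group summary rows into an "All" row
#'
#' For inputs available only as summary rows (no raw lengths): total and
#' number are sums, the maximum is the maximum of maxima. N50-family columns
#' are not derivable from summaries and are returned as NA.
#'
#' @param rows data.frame of [assembly_stats()]-shaped rows.
#' @return one-row data.frame.
#' @export
combine_stats_rows <- function(rows) {
  data.frame(label = "All", total_length = sum(rows$total_length),
             number = sum(rows$number), n50 = NA_real_, count_ge_n50 = NA_integer_,
             n90 = NA_real_, count_ge_n90 = NA_integer_,
             max_len = max(rows$max_len))
}

#' Read-filtering percentages
#'
#' Percentage of reads and of total bases retained by filtering, rounded
#' half-up to two decimals, as in the sequencing summary tables.
#'
#' @param raw_reads,clean_reads read counts before/after filtering.
#' @param raw_bp,clean_bp total bases before/after filtering.
#' @return list `pct_reads`, `pct_bp` (either may be NA when its pair of
#'   inputs is missing).
#' @export
#' @examples
#' filter_report(338293782, 34167671982, 299201824, 29652703238)
filter_report <- function(raw_reads = NA, raw_bp = NA, clean_reads = NA,
                          clean_bp = NA) {
  pct <- function(clean, raw) {
    if (is.na(clean) || is.na(raw)) return(NA_real_)
    if (raw == 0) stop("raw count is zero")
    if (clean > raw) stop("clean exceeds raw")
    round_half_up(100 * clean / raw, 2L)
  }
  list(pct_reads = pct(clean_reads, raw_reads), pct_bp = pct(clean_bp, raw_bp))
}
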