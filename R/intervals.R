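#' @import methods
#' @importFrom stats median quantile var cor rnorm runif rbinom rpois rnbinom rhyper
#'   p.adjust pchisq pnorm lm kmeans setNames complete.cases sd dnbinom dpois
#' @importFrom utils head tail read.table write.table
NULL

# All internal coordinates are 0-based, half-open [start, end). GTF I/O converts
# to/from 1-based inclusive; BED/bedGraph/chain are natively 0-based half-open.

#' Construct a genomic interval table
#'
#' Plain-data representation of a set of genomic intervals in 0-based,
#' half-open coordinates, the coordinate substrate for all region operations.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `start < end`, 0-based half-open.
#' @param strand character vector in `c("+", "-", "*")`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop("interval start must be < end")
  if (any(start < 0)) stop("negative interval start")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = rep_len(as.character(strand), length(chrom)),
             stringsAsFactors = FALSE)
}

#' Union of intervals
#'
#' Merges a set of intervals on a single chromosome into the minimal sorted
#' set of disjoint intervals covering the same bases. Touching intervals
#' (`end == next start`) are merged, matching base-set union.
#'
#' @param df interval data.frame (columns `start`, `end`; single chromosome).
#' @return merged data.frame sorted by `start`.
#' @export
interval_union <- function(df) {
  if (nrow(df) == 0L) return(df)
  o <- order(df$start, df$end)
  s <- df$start[o]; e <- df$end[o]
  ms <- s[1]; me <- e[1]; out_s <- numeric(0); out_e <- numeric(0)
  if (length(s) > 1L) for (i in 2:length(s)) {
    if (s[i] <= me) { me <- max(me, e[i]) }
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  res <- df[rep(o[1], length(out_s)), , drop = FALSE]
  res$start <- out_s; res$end <- out_e
  rownames(res) <- NULL
  res
}

# total length of a union of intervals (may overlap)
interval_union_len <- function(start, end) {
  if (length(start) == 0L) return(0)
  u <- interval_union(data.frame(start = start, end = end))
  sum(u$end - u$start)
}

# length of intersection of one interval [s,e) with a set of intervals
interval_overlap_len <- function(s, e, starts, ends) {
  if (length(starts) == 0L) return(0)
  sum(pmax(0, pmin(e, ends) - pmax(s, starts)))
}

# set difference [s,e) minus a union of intervals; returns data.frame start/end
interval_subtract <- function(s, e, sub_start, sub_end) {
  if (length(sub_start) == 0L) return(data.frame(start = s, end = e))
  u <- interval_union(data.frame(start = sub_start, end = sub_end))
  u <- u[u$end > s & u$start < e, , drop = FALSE]
  if (nrow(u) == 0L) return(data.frame(start = s, end = e))
  starts <- c(s, pmin(pmax(u$end, s), e))
  ends <- c(pmin(pmax(u$start, s), e), e)
  keep <- starts < ends
  data.frame(start = starts[keep], end = ends[keep])
}

# convert a 0-based half-open interval df to GRanges (1-based closed)
intervals_to_granges <- function(df) {
  strand <- df$strand
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand)
}

granges_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read a BED file
#'
#' @param path BED3/BED6 file.
#' @return interval data.frame (0-based half-open) with optional `name`, `score`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- granges_to_intervals(gr)
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$name)) df$name <- as.character(mc$name)
  if (!is.null(mc$score)) df$score <- as.numeric(mc$score)
  df
}

#' Write intervals as BED6
#'
#' @param df interval data.frame; optional `name`, `score` columns.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  gr <- intervals_to_granges(df)
  S4Vectors::mcols(gr)$name <- if (!is.null(df$name)) df$name else "."
  S4Vectors::mcols(gr)$score <- if (!is.null(df$score)) df$score else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
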