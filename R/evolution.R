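# Sequence-conservation aggregation over gene regions, the expression
# conservation index with bootstrap envelopes, per-gene expression
# divergence and its per-condition decomposition, and species-specific
# locus detection.

#' Read a bedGraph conservation track
#'
#' @param path bedGraph file (0-based half-open, per-base scores).
#' @return object of class `conservation_track`: per-chromosome sorted
#'   data.frames `start`, `end`, `score`. Unscored bases are missing.
#' @export
read_bedgraph <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "score"),
                   stringsAsFactors = FALSE)
  conservation_track(df)
}

#' Build a conservation track from a scored interval table
#'
#' @param df data.frame `chrom`, `start`, `end`, `score`; intervals must not
#'   overlap within a chromosome.
#' @return a `conservation_track`.
#' @export
conservation_track <- function(df) {
  by_chrom <- lapply(split(df[, c("start", "end", "score")], df$chrom),
                     function(d) {
                       d <- d[order(d$start), , drop = FALSE]
                       if (nrow(d) > 1L &&
                           any(d$start[-1L] < d$end[-nrow(d)]))
                         stop("overlapping scored intervals")
                       rownames(d) <- NULL
                       d
                     })
  structure(list(by_chrom = by_chrom), class = "conservation_track")
}

#' Write a conservation track as bedGraph
#'
#' @param track a `conservation_track`.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$by_chrom), function(ch) {
    d <- track$by_chrom[[ch]]
    data.frame(chrom = ch, d, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# per-base sum and count of scores over one interval, minus a mask
track_interval_sum <- function(track, chrom, s, e, mask = NULL) {
  d <- track$by_chrom[[chrom]]
  if (is.null(d)) return(c(sum = 0, n = 0))
  pieces <- if (!is.null(mask) && nrow(mask) > 0L) {
    m <- mask[mask$chrom == chrom, , drop = FALSE]
    if (nrow(m) > 0L) interval_subtract(s, e, m$start, m$end)
    else data.frame(start = s, end = e)
  } else data.frame(start = s, end = e)
  total <- 0; n <- 0
  for (i in seq_len(nrow(pieces))) {
    a <- pieces$start[i]; b <- pieces$end[i]
    hit <- d[d$end > a & d$start < b, , drop = FALSE]
    if (nrow(hit) == 0L) next
    w <- pmin(b, hit$end) - pmax(a, hit$start)
    total <- total + sum(w * hit$score)
    n <- n + sum(w)
  }
  c(sum = total, n = n)
}

#' Mean conservation score over gene regions
#'
#' Per gene, the mean per-base track score over the given intervals,
#' excluding masked bases (typically exonic regions of other genes) and
#' bases without a defined score. Genes with no scoreable bases are NA.
#'
#' @param track a `conservation_track`.
#' @param intervals interval data.frame with a `gene_id` column.
#' @param mask_intervals optional interval data.frame to exclude.
#' @return named numeric vector of per-gene scores.
#' @export
region_conservation <- function(track, intervals, mask_intervals = NULL) {
  out <- vapply(split(intervals, intervals$gene_id), function(d) {
    acc <- c(sum = 0, n = 0)
    for (i in seq_len(nrow(d)))
      acc <- acc + track_interval_sum(track, d$chrom[i], d$start[i],
                                      d$end[i], mask_intervals)
    if (acc["n"] == 0) NA_real_ else unname(acc["sum"] / acc["n"])
  }, 0)
  out
}

#' Median conservation per expressed gene group, with bootstrap CI
#'
#' @param per_gene_scores named numeric vector ([region_conservation()]).
#' @param expressed_sets named list of gene-id vectors per condition
#'   ([expressed_above_noise()]).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95, percentile bootstrap).
#' @return data.frame `condition`, `n_genes`, `median`, `ci_lo`, `ci_hi`,
#'   `unstable` (fewer than 10 genes).
#' @export
conservation_by_group <- function(per_gene_scores, expressed_sets,
                                  n_boot = 1000, seed = 1, conf = 0.95) {
  set.seed(seed)
  alpha <- (1 - conf) / 2
  rows <- lapply(names(expressed_sets), function(cn) {
    sc <- per_gene_scores[intersect(expressed_sets[[cn]],
                                    names(per_gene_scores))]
    sc <- sc[!is.na(sc)]
    n <- length(sc)
    if (n == 0L)
      return(data.frame(condition = cn, n_genes = 0L, median = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_, unstable = TRUE))
    meds <- vapply(seq_len(n_boot), function(b)
      median(sc[sample.int(n, n, replace = TRUE)]), 0)
    data.frame(condition = cn, n_genes = n, median = median(sc),
               ci_lo = quantile(meds, alpha, names = FALSE),
               ci_hi = quantile(meds, 1 - alpha, names = FALSE),
               unstable = n < 10L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# mean Spearman rho over column pairs of two matrices (genes x replicates);
# `exclude_matched` drops pairs with equal column index
mean_pair_rho <- function(xa, xb, exclude_matched = FALSE) {
  rhos <- c()
  for (i in seq_len(ncol(xa))) for (j in seq_len(ncol(xb))) {
    if (exclude_matched && i == j) next
    rhos <- c(rhos, suppressWarnings(
      cor(xa[, i], xb[, j], method = "spearman")))
  }
  mean(rhos, na.rm = TRUE)
}

#' Expression conservation index for one organ/stage condition
#'
#' The ratio of the between-species to the within-species mean Spearman
#' correlation of log2(TPM+1) across orthologous genes. Between-species
#' correlations average over cross-species replicate pairs with distinct
#' replicate indices (so that comparing a species with a copy of itself
#' yields exactly 1); within-species correlations average over all distinct
#' replicate pairs, both species pooled. The bootstrap resamples gene pairs
#' with replacement and reports the envelope (min and max) of the index.
#'
#' @param em_a,em_b TPM [expression_matrix()] objects.
#' @param pairs data.frame `gene_a`, `gene_b` (>= 20 pairs advised).
#' @param organ,stage the condition.
#' @param n_boot bootstrap replicates (default 100).
#' @param seed integer seed.
#' @return list: `ec`, `rho_between`, `rho_within`, `bootstrap_min`,
#'   `bootstrap_max`, `n_pairs`; `ec` is NA with a flag when
#'   `rho_within <= 0`.
#' @export
expression_conservation_index <- function(em_a, em_b, pairs, organ, stage,
                                          n_boot = 100, seed = 1) {
  sel_a <- em_a$meta$organ == organ & em_a$meta$stage == stage
  sel_b <- em_b$meta$organ == organ & em_b$meta$stage == stage
  if (sum(sel_a) < 2L || sum(sel_b) < 2L)
    stop("need >= 2 replicates per species in the condition")
  xa <- log_transform(em_a$values[pairs$gene_a, sel_a, drop = FALSE])
  xb <- log_transform(em_b$values[pairs$gene_b, sel_b, drop = FALSE])
  compute_ec <- function(rows) {
    a <- xa[rows, , drop = FALSE]; b <- xb[rows, , drop = FALSE]
    between <- mean_pair_rho(a, b, exclude_matched = TRUE)
    within <- mean(c(
      vapply(utils::combn(ncol(a), 2, simplify = FALSE), function(p)
        suppressWarnings(cor(a[, p[1]], a[, p[2]], method = "spearman")), 0),
      vapply(utils::combn(ncol(b), 2, simplify = FALSE), function(p)
        suppressWarnings(cor(b[, p[1]], b[, p[2]], method = "spearman")), 0)),
      na.rm = TRUE)
    c(between = between, within = within,
      ec = if (within <= 0) NA_real_ else between / within)
  }
  n <- nrow(pairs)
  point <- compute_ec(seq_len(n))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b)
    compute_ec(sample.int(n, n, replace = TRUE))["ec"], 0)
  list(ec = unname(point["ec"]), rho_between = unname(point["between"]),
       rho_within = unname(point["within"]),
       bootstrap_min = min(boots, na.rm = TRUE),
       bootstrap_max = max(boots, na.rm = TRUE), n_pairs = n)
}

#' Relative expression profile (sum-normalized)
#'
#' @param condition_means genes x conditions matrix (or vector for one gene).
#' @return profiles summing to 1 per gene; all-zero genes get NA.
#' @export
relative_profile_sum <- function(condition_means) {
  if (is.null(dim(condition_means))) {
    s <- sum(condition_means)
    if (s == 0) return(rep(NA_real_, length(condition_means)))
    return(condition_means / s)
  }
  s <- rowSums(condition_means)
  out <- sweep(condition_means, 1, s, "/")
  out[s == 0, ] <- NA_real_
  out
}

#' Euclidean expression divergence between relative profiles
#'
#' @param profile_a,profile_b matrices (or vectors) over identical condition
#'   sets.
#' @return per-gene Euclidean distance.
#' @export
expression_divergence <- function(profile_a, profile_b) {
  if (is.null(dim(profile_a))) {
    if (length(profile_a) != length(profile_b))
      stop("profiles over different condition sets")
    return(sqrt(sum((profile_a - profile_b)^2)))
  }
  if (!identical(colnames(profile_a), colnames(profile_b)))
    stop("profiles over different condition sets")
  sqrt(rowSums((profile_a - profile_b)^2))
}

#' Residual expression divergence after regressing out expression level
#'
#' Ordinary least squares of the divergence on the average log2 expression;
#' residuals quantify divergence in excess of the level-dependent trend.
#'
#' @param d per-gene divergence.
#' @param avg_log2_expr per-gene average log2-transformed expression.
#' @return list: `residuals`, `slope`, `intercept`, `fitted`.
#' @export
residual_divergence <- function(d, avg_log2_expr) {
  ok <- !is.na(d) & !is.na(avg_log2_expr)
  if (sum(ok) < 10L) stop("need >= 10 records")
  if (var(avg_log2_expr[ok]) == 0) stop("zero variance in predictor")
  fit <- lm(d[ok] ~ avg_log2_expr[ok])
  res <- rep(NA_real_, length(d))
  fitted <- rep(NA_real_, length(d))
  res[ok] <- stats::residuals(fit)
  fitted[ok] <- stats::fitted(fit)
  list(residuals = res, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), fitted = fitted)
}

#' Per-condition contributions to expression divergence
#'
#' `contribution_c = (p_Ac - p_Bc)^2 / d^2`, the unique decomposition of the
#' squared Euclidean distance into condition shares summing to 1. Genes with
#' zero divergence are NA.
#'
#' @param profile_a,profile_b profile matrices over identical conditions.
#' @return matrix of per-gene condition fractions.
#' @export
divergence_contributions <- function(profile_a, profile_b) {
  if (is.null(dim(profile_a))) {
    profile_a <- matrix(profile_a, 1); profile_b <- matrix(profile_b, 1)
  }
  sq <- (profile_a - profile_b)^2
  d2 <- rowSums(sq)
  out <- sweep(sq, 1, d2, "/")
  out[d2 == 0, ] <- NA_real_
  out
}

#' Candidate species-specific loci
#'
#' Loci with at least `min_reads` total unique reads in the focal species
#' and exactly zero reads over the predicted homologous region in the other
#' species. Loci without a resolvable projection are excluded.
#'
#' @param reads_focal named vector of total unique reads per locus.
#' @param reads_projected named vector of unique reads over the projected
#'   region in the other species; NA marks unresolvable projections.
#' @param min_reads focal-species support threshold (default 100).
#' @return character vector of locus ids.
#' @export
species_specific_loci <- function(reads_focal, reads_projected,
                                  min_reads = 100) {
  ids <- intersect(names(reads_focal), names(reads_projected))
  rp <- reads_projected[ids]; rf <- reads_focal[ids]
  ids[!is.na(rp) & rf >= min_reads & rp == 0]
}
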