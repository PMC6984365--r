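# Differential expression across developmental stages with a
# negative-binomial likelihood engine referenced to an F distribution,
# cross-species DE concordance, and K-means clustering of relative temporal
# profiles.
#
# The engine uses a closed-form NB likelihood: with the dispersion fixed by a
# method-of-moments estimate from the full (per-stage) model, the maximum-
# likelihood mean of each group is its sample mean, so the likelihood-ratio
# statistic needs no iterative fit. Genes whose moment estimate of the
# dispersion is non-positive fall back to a Poisson likelihood.

# NB log-likelihood with dispersion a (var = mu + a mu^2); a <= 0 -> Poisson
nb_loglik <- function(x, mu, a) {
  if (mu <= 0) return(if (all(x == 0)) 0 else -Inf)
  if (a <= 1e-12) return(sum(dpois(x, mu, log = TRUE)))
  sum(dnbinom(x, size = 1 / a, mu = mu, log = TRUE))
}

# method-of-moments dispersion from full-model groups, df-corrected
mom_dispersion <- function(x, groups) {
  a_num <- 0; a_den <- 0
  for (g in unique(groups)) {
    xi <- x[groups == g]
    ni <- length(xi)
    if (ni < 2L) next
    mu <- mean(xi)
    if (mu <= 0) next
    v <- sum((xi - mu)^2) / (ni - 1)
    a_num <- a_num + (ni - 1) * (v - mu) / mu^2
    a_den <- a_den + (ni - 1)
  }
  if (a_den == 0) return(0)
  max(0, a_num / a_den)
}

#' Stage differential-expression test (likelihood ratio)
#'
#' Contrasts a negative-binomial model with one mean per developmental stage
#' against homogeneous expression across stages, per gene, within one organ
#' and species. P-values come from the chi-square likelihood-ratio test with
#' stages-1 degrees of freedom; FDR is Benjamini-Hochberg across tested
#' genes. All-zero genes are untested.
#'
#' @param em counts [expression_matrix()].
#' @param organ,species condition selectors.
#' @return data.frame `gene_id`, `organ`, `species`, `lrt_statistic`,
#'   `p_value`, `fdr`, `max_stage`, `dispersion`.
#' @export
stage_de_test <- function(em, organ, species) {
  stopifnot(em$kind == "counts")
  keep <- em$meta$organ == organ & em$meta$species == species
  vals <- em$values[, keep, drop = FALSE]
  if (any(vals != round(vals))) stop("counts must be integral")
  stages <- em$meta$stage[keep]
  ustage <- sort(unique(stages))
  if (length(ustage) < 2L) stop("need >= 2 stages")
  if (any(table(stages) < 2L)) stop("need >= 2 replicates per stage")
  res <- lapply(seq_len(nrow(vals)), function(i) {
    x <- vals[i, ]
    if (all(x == 0))
      return(data.frame(gene_id = rownames(vals)[i], lrt_statistic = NA_real_,
                        p_value = NA_real_, max_stage = NA_integer_,
                        dispersion = NA_real_))
    a <- mom_dispersion(x, stages)
    mus <- tapply(x, stages, mean)
    ll_full <- sum(vapply(ustage, function(st)
      nb_loglik(x[stages == st], mus[[as.character(st)]], a), 0))
    ll_null <- nb_loglik(x, mean(x), a)
    lrt <- max(0, 2 * (ll_full - ll_null))
    # F reference (LRT / df1 vs F(df1, n - k)): accounts for the plug-in
    # moment dispersion, which leaves the chi-square reference anticonservative
    # at few replicates
    k <- length(ustage)
    p <- stats::pf(lrt / (k - 1L), k - 1L, length(x) - k, lower.tail = FALSE)
    data.frame(gene_id = rownames(vals)[i], lrt_statistic = lrt, p_value = p,
               max_stage = ustage[which.max(mus)], dispersion = a)
  })
  out <- do.call(rbind, res)
  out$fdr <- NA_real_
  tested <- !is.na(out$p_value)
  out$fdr[tested] <- p.adjust(out$p_value[tested], method = "BH")
  out$organ <- organ; out$species <- species
  rownames(out) <- NULL
  out[, c("gene_id", "organ", "species", "lrt_statistic", "p_value", "fdr",
          "max_stage", "dispersion")]
}

#' Wald test between two consecutive stages
#'
#' Tests the log fold change between two stages per gene under the
#' negative-binomial variance model, with a delta-method standard error.
#' Swapping the stage labels flips the direction and preserves the p-value.
#'
#' @param em counts [expression_matrix()].
#' @param organ,species condition selectors.
#' @param stage_i,stage_j the two stages (direction reported as j vs i).
#' @return data.frame `gene_id`, `log2fc`, `wald_z`, `p_value`, `fdr`,
#'   `direction`.
#' @export
consecutive_stage_test <- function(em, organ, species, stage_i, stage_j) {
  stopifnot(em$kind == "counts")
  keep <- em$meta$organ == organ & em$meta$species == species &
    em$meta$stage %in% c(stage_i, stage_j)
  vals <- em$values[, keep, drop = FALSE]
  stages <- em$meta$stage[keep]
  res <- lapply(seq_len(nrow(vals)), function(i) {
    x <- vals[i, ]
    xi <- x[stages == stage_i]; xj <- x[stages == stage_j]
    mi <- mean(xi); mj <- mean(xj)
    if (mi <= 0 || mj <= 0)
      return(data.frame(gene_id = rownames(vals)[i], log2fc = NA_real_,
                        wald_z = NA_real_, p_value = NA_real_,
                        direction = NA_integer_))
    a <- mom_dispersion(x, stages)
    beta <- log(mj / mi)
    vi <- (mi + a * mi^2) / length(xi)
    vj <- (mj + a * mj^2) / length(xj)
    se <- sqrt(vi / mi^2 + vj / mj^2)
    z <- beta / se
    data.frame(gene_id = rownames(vals)[i], log2fc = beta / log(2),
               wald_z = z, p_value = 2 * pnorm(-abs(z)),
               direction = sign(beta))
  })
  out <- do.call(rbind, res)
  out$fdr <- NA_real_
  tested <- !is.na(out$p_value)
  out$fdr[tested] <- p.adjust(out$p_value[tested], method = "BH")
  rownames(out) <- NULL
  out
}

#' Orthologous gene pairs differentially expressed in both species
#'
#' @param de_a,de_b [stage_de_test()] results for the same organ.
#' @param pairs data.frame `gene_a`, `gene_b` of 1-to-1 orthologs.
#' @param fdr FDR threshold (default 0.01, strict in both species).
#' @return subset of `pairs` DE in both species.
#' @export
shared_de_genes <- function(de_a, de_b, pairs, fdr = 0.01) {
  fa <- de_a$fdr[match(pairs$gene_a, de_a$gene_id)]
  fb <- de_b$fdr[match(pairs$gene_b, de_b$gene_id)]
  keep <- !is.na(fa) & !is.na(fb) & fa < fdr & fb < fdr
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-species concordance of maximum-expression stages
#'
#' Rows index the species-A maximum stage; each row gives the percentage of
#' orthologous pairs attaining each species-B maximum stage and sums to 100.
#' Stages absent from species A are omitted.
#'
#' @param max_a,max_b named integer vectors (stage of maximum expression per
#'   gene, within the organ).
#' @param pairs data.frame `gene_a`, `gene_b`.
#' @param stages stage levels defining the table axes.
#' @return percentage matrix (rows: A stages present; columns: all stages).
#' @export
stage_concordance <- function(max_a, max_b, pairs, stages) {
  sa <- max_a[pairs$gene_a]; sb <- max_b[pairs$gene_b]
  ok <- !is.na(sa) & !is.na(sb)
  tab <- table(factor(sa[ok], levels = stages),
               factor(sb[ok], levels = stages))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  100 * sweep(unclass(tab), 1, rowSums(tab), "/")
}

#' Relative temporal profile (maximum-normalized)
#'
#' @param stage_means genes x stages matrix of replicate-averaged values.
#' @return matrix of profiles with per-gene maximum 1; all-zero genes get NA
#'   rows.
#' @export
relative_profile_max <- function(stage_means) {
  mx <- apply(stage_means, 1, max)
  out <- sweep(stage_means, 1, mx, "/")
  out[mx == 0, ] <- NA_real_
  out
}

# k-means++ style farthest-point seeding
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L)) {
    p <- d2 / sum(d2)
    if (all(d2 == 0)) i <- sample.int(n, 1)
    else i <- sample.int(n, 1, prob = p)
    centers[j + 1L, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1L, ])^2))
  }
  centers
}

#' K-means clustering of combined cross-species temporal profiles
#'
#' Concatenates each ortholog pair's species-A and species-B
#' maximum-normalized stage profiles into one vector and clusters with
#' Euclidean K-means, taking the best of `restarts` k-means++-seeded runs by
#' within-cluster sum of squares. Deterministic given `seed`.
#'
#' @param profiles_a,profiles_b genes x stages profile matrices
#'   ([relative_profile_max()]), rows aligned to `pairs`.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param restarts number of seeded restarts (default 50).
#' @return list: `cluster` (per pair), `centers_a`, `centers_b`,
#'   `tot_withinss`.
#' @export
kmeans_profiles <- function(profiles_a, profiles_b, k, seed = 1,
                            restarts = 50) {
  x <- cbind(profiles_a, profiles_b)
  ok <- complete.cases(x)
  x <- x[ok, , drop = FALSE]
  if (k > nrow(x)) stop("k exceeds the number of complete profile pairs")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(x, k)
    centers <- centers[!duplicated(centers), , drop = FALSE]
    fit <- suppressWarnings(
      kmeans(x, centers = centers, iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  na <- ncol(profiles_a)
  cluster <- rep(NA_integer_, length(ok))
  cluster[ok] <- best$cluster
  list(cluster = cluster,
       centers_a = best$centers[, seq_len(na), drop = FALSE],
       centers_b = best$centers[, -seq_len(na), drop = FALSE],
       tot_withinss = best$tot.withinss)
}
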