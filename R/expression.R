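# Expression-matrix handling: rank-based scaling normalization of TPM,
# log transform, replicate aggregation, detection counts under read
# resampling, proportional down-sampling for class-balanced DE, and
# specificity/maximum-expression summaries.

ORGAN_ORDER <- c("brain", "kidney", "liver", "testes")

#' Construct an expression matrix bound to sample metadata
#'
#' @param values numeric matrix, genes x samples; column names must match
#'   `meta$sample_id`.
#' @param meta data.frame with `sample_id`, `species`, `organ`, `stage`,
#'   `replicate`; the combination must be unique.
#' @param kind `"counts"` or `"tpm"`.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, meta, kind = c("tpm", "counts")) {
  kind <- match.arg(kind)
  stopifnot(!is.null(rownames(values)), !is.null(colnames(values)))
  if (!identical(colnames(values), meta$sample_id))
    stop("column names must equal meta$sample_id, in order")
  if (any(values < 0)) stop("negative expression values")
  if (kind == "counts" && any(values != round(values)))
    stop("counts must be integral")
  key <- paste(meta$species, meta$organ, meta$stage, meta$replicate)
  if (anyDuplicated(key)) stop("duplicated (species, organ, stage, replicate)")
  structure(list(values = values, meta = meta, kind = kind),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix (", x$kind, "): ", nrow(x$values), " genes x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

# condition label for each sample
condition_key <- function(meta) paste(meta$organ, meta$stage, sep = "_")

#' Rank-based scaling normalization
#'
#' Ranks genes within each sample, finds the 100 genes with the least
#' across-sample rank variance among genes whose average expression lies in
#' the across-gene interquartile range (25-75\%), and rescales each sample so
#' the median expression of those genes is identical across samples. All
#' selection statistics and the target median are computed on a copy of the
#' matrix whose columns are standardized to a common total, which makes the
#' procedure exactly idempotent and equivariant to per-sample rescaling;
#' for genuine TPM input the standardization is a no-op.
#'
#' @param em an [expression_matrix()] of TPM values.
#' @param n_genes number of reference genes selected (default 100).
#' @return list: `em` (normalized matrix), `coefficients` (per sample),
#'   `selected_genes`, `target` (common median).
#' @export
scaling_normalize <- function(em, n_genes = 100) {
  x <- em$values
  if (ncol(x) < 2L) stop("need >= 2 samples")
  totals <- colSums(x)
  if (any(totals == 0)) stop("sample with zero total expression")
  std <- sweep(x, 2, totals, "/") * 1e6  # fixed-total (TPM-like) copy
  ranks <- apply(std, 2, rank, ties.method = "average")
  rank_var <- apply(ranks, 1, var)
  gene_means <- rowMeans(std)
  qs <- quantile(gene_means, c(0.25, 0.75), names = FALSE)
  candidates <- which(gene_means >= qs[1] & gene_means <= qs[2])
  if (length(candidates) < n_genes) {
    warning("only ", length(candidates), " candidate genes in the IQR; ",
            "using all of them")
    sel <- candidates
  } else {
    o <- candidates[order(rank_var[candidates],
                          rownames(x)[candidates])]
    sel <- o[seq_len(n_genes)]
  }
  selected <- rownames(x)[sel]
  med_std <- apply(std[sel, , drop = FALSE], 2, median)
  target <- mean(med_std)
  med_orig <- apply(x[sel, , drop = FALSE], 2, median)
  if (any(med_orig == 0)) stop("zero median of selected genes in a sample")
  coef <- target / med_orig
  out <- sweep(x, 2, coef, "*")
  em$values <- out
  list(em = em, coefficients = coef, selected_genes = selected,
       target = target)
}

#' Elementwise log2(x + 1) transform
#'
#' @param x numeric matrix or vector with nonnegative values.
#' @return transformed object.
#' @export
log_transform <- function(x) {
  if (any(x < 0)) stop("negative values in log_transform")
  log2(x + 1)
}

#' Replicate-averaged expression per organ/stage condition
#'
#' @param em an [expression_matrix()] (one species, or filter by `species`).
#' @param species optional species to subset.
#' @return list: `means` (genes x conditions matrix, columns
#'   `organ_stage`), `conditions` (data.frame `organ`, `stage`, ordered by
#'   organ then stage).
#' @export
condition_means <- function(em, species = NULL) {
  meta <- em$meta; vals <- em$values
  if (!is.null(species)) {
    keep <- meta$species == species
    meta <- meta[keep, , drop = FALSE]; vals <- vals[, keep, drop = FALSE]
  }
  key <- condition_key(meta)
  conds <- unique(data.frame(organ = meta$organ, stage = meta$stage,
                             stringsAsFactors = FALSE))
  org_rank <- match(conds$organ, ORGAN_ORDER)
  org_rank[is.na(org_rank)] <- length(ORGAN_ORDER) + 1L
  conds <- conds[order(org_rank, conds$stage), , drop = FALSE]
  rownames(conds) <- NULL
  cond_labels <- paste(conds$organ, conds$stage, sep = "_")
  means <- vapply(cond_labels, function(cl)
    rowMeans(vals[, key == cl, drop = FALSE]), numeric(nrow(vals)))
  colnames(means) <- cond_labels
  list(means = means, conditions = conds)
}

#' Condition of maximum expression per gene
#'
#' Ties are broken by the fixed condition order (organs brain, kidney, liver,
#' testes, then ascending stage) and flagged. All-zero genes are unassigned.
#'
#' @param cm result of [condition_means()].
#' @return data.frame `gene_id`, `organ`, `stage`, `condition`, `tie`;
#'   all-zero genes get NA.
#' @export
max_expression_condition <- function(cm) {
  m <- cm$means
  idx <- apply(m, 1, function(r) if (all(r == 0)) NA_integer_
               else which.max(r))
  tie <- apply(m, 1, function(r) !all(r == 0) && sum(r == max(r)) > 1L)
  data.frame(gene_id = rownames(m),
             organ = cm$conditions$organ[idx],
             stage = cm$conditions$stage[idx],
             condition = colnames(m)[idx],
             tie = tie, stringsAsFactors = FALSE)
}

# multivariate hypergeometric draw: sample `k` of `sum(n)` items without
# replacement, stratified by the cells of `n`
rmvhyper <- function(n, k) {
  out <- numeric(length(n))
  remaining <- sum(n)
  for (i in seq_along(n)) {
    if (k <= 0) break
    remaining <- remaining - n[i]
    x <- rhyper(1, n[i], remaining, k)
    out[i] <- x
    k <- k - x
  }
  out
}

#' Down-sample counts to a common depth per condition
#'
#' Within each species, conditions (organ x stage) with more total reads than
#' the shallowest condition are down-sampled without replacement
#' (multivariate hypergeometric over all gene x replicate cells of the
#' condition) to exactly that depth. Zero counts stay zero.
#'
#' @param em an [expression_matrix()] of counts.
#' @param seed integer seed.
#' @return an [expression_matrix()] of resampled counts.
#' @export
resample_reads_to_depth <- function(em, seed = 1) {
  stopifnot(em$kind == "counts")
  set.seed(seed)
  vals <- em$values
  for (sp in unique(em$meta$species)) {
    in_sp <- em$meta$species == sp
    key <- condition_key(em$meta)
    conds <- unique(key[in_sp])
    tot <- vapply(conds, function(cl)
      sum(vals[, in_sp & key == cl, drop = FALSE]), 0)
    depth <- min(tot)
    for (cl in conds) {
      cols <- which(in_sp & key == cl)
      cur <- sum(vals[, cols, drop = FALSE])
      if (cur <= depth) next
      flat <- as.vector(vals[, cols, drop = FALSE])
      res <- rmvhyper(flat, depth)
      vals[, cols] <- matrix(res, nrow = nrow(vals))
    }
  }
  em$values <- vals
  em
}

#' Detected genes per sample and gene class
#'
#' @param em counts [expression_matrix()] (typically resampled).
#' @param gene_class named character vector over the matrix genes.
#' @param min_reads detection threshold (default 10, inclusive).
#' @return data.frame `sample_id`, `gene_class`, `n_detected`.
#' @export
detected_genes <- function(em, gene_class, min_reads = 10) {
  classes <- gene_class[rownames(em$values)]
  rows <- list()
  for (cl in unique(classes)) {
    sub <- em$values[classes == cl, , drop = FALSE]
    n <- colSums(sub >= min_reads)
    rows[[cl]] <- data.frame(sample_id = colnames(em$values),
                             gene_class = cl, n_detected = as.integer(n),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Down-sample protein-coding counts to the lncRNA read-depth
#'
#' Per sample, protein-coding counts are thinned by the ratio
#' `r = mean(lnc) / mean(pc)` so that the per-sample protein-coding mean
#' matches the lncRNA mean in expectation while staying directly
#' proportional to the original counts. The default `"binomial"` method
#' keeps each read independently with probability `r` — the read-level
#' down-sampling operation, which maps a negative-binomial count with mean
#' `mu` and dispersion `a` exactly onto one with mean `r * mu` and the same
#' dispersion, so depth-matched classes share their full count
#' distribution. The `"proportional"` method instead scales
#' deterministically and rounds stochastically (floor plus a Bernoulli on
#' the fractional part), preserving proportionality gene by gene. Samples
#' where the protein-coding mean does not exceed the lncRNA mean are left
#' unchanged with a warning. Zeros never become positive.
#'
#' @param pc_counts,lnc_counts matrices over the same samples.
#' @param seed integer seed.
#' @param method `"binomial"` (default) or `"proportional"`.
#' @return adjusted protein-coding count matrix.
#' @export
downsample_counts_to_match <- function(pc_counts, lnc_counts, seed = 1,
                                       method = c("binomial",
                                                  "proportional")) {
  stopifnot(identical(colnames(pc_counts), colnames(lnc_counts)))
  method <- match.arg(method)
  set.seed(seed)
  out <- pc_counts
  for (s in seq_len(ncol(pc_counts))) {
    mp <- mean(pc_counts[, s]); ml <- mean(lnc_counts[, s])
    if (mp <= ml) {
      warning("sample ", colnames(pc_counts)[s],
              ": protein-coding mean <= lncRNA mean; left unchanged")
      next
    }
    r <- ml / mp
    if (method == "binomial") {
      out[, s] <- rbinom(nrow(pc_counts), pc_counts[, s], r)
    } else {
      scaled <- pc_counts[, s] * r
      fl <- floor(scaled)
      out[, s] <- fl + rbinom(length(scaled), 1, scaled - fl)
    }
  }
  out
}

#' Tissue-specificity index tau
#'
#' `tau = sum(1 - x_i / max(x)) / (n - 1)` over conditions: 1 for expression
#' confined to one condition, 0 for uniform expression.
#'
#' @param x nonnegative vector of condition means.
#' @return tau in [0, 1], NA for all-zero input.
#' @export
tau_specificity <- function(x) {
  if (all(x == 0)) return(NA_real_)
  sum(1 - x / max(x)) / (length(x) - 1)
}

#' Cross-species marker genes
#'
#' Orthologous gene pairs with narrow expression distributions
#' (tau >= `tau_threshold` in both species) whose maximum expression falls in
#' the same organ/stage combination in both species.
#'
#' @param cm_a,cm_b [condition_means()] results over identical condition sets.
#' @param pairs data.frame `gene_a`, `gene_b`.
#' @param tau_threshold minimum specificity (default 0.8).
#' @return subset of `pairs` with `tau_a`, `tau_b`, `condition`.
#' @export
marker_genes <- function(cm_a, cm_b, pairs, tau_threshold = 0.8) {
  stopifnot(identical(colnames(cm_a$means), colnames(cm_b$means)))
  ok <- logical(nrow(pairs)); tau_a <- tau_b <- numeric(nrow(pairs))
  cond <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    xa <- cm_a$means[pairs$gene_a[i], ]
    xb <- cm_b$means[pairs$gene_b[i], ]
    if (all(xa == 0) || all(xb == 0)) next
    ta <- tau_specificity(xa); tb <- tau_specificity(xb)
    ia <- which.max(xa); ib <- which.max(xb)
    tau_a[i] <- ta; tau_b[i] <- tb
    cond[i] <- colnames(cm_a$means)[ia]
    ok[i] <- ta >= tau_threshold && tb >= tau_threshold && ia == ib
  }
  out <- pairs[ok, , drop = FALSE]
  out$tau_a <- tau_a[ok]; out$tau_b <- tau_b[ok]
  out$condition <- cond[ok]
  rownames(out) <- NULL
  out
}

#' Read an expression matrix and its sample metadata from TSV
#'
#' @param matrix_path genes x samples TSV with a header of sample ids.
#' @param meta_path sample metadata TSV.
#' @param kind `"tpm"` or `"counts"`.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(matrix_path, meta_path,
                                kind = c("tpm", "counts")) {
  vals <- as.matrix(read.table(matrix_path, sep = "\t", header = TRUE,
                               row.names = 1, check.names = FALSE))
  meta <- read.table(meta_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  expression_matrix(vals, meta, match.arg(kind))
}

#' Write an expression matrix and metadata as TSV
#'
#' @param em an [expression_matrix()].
#' @param matrix_path,meta_path output files.
#' @export
write_expression_tsv <- function(em, matrix_path, meta_path) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(em$meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(matrix_path)
}
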