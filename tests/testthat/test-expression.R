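test_that("scaling normalization equalizes reference-gene medians exactly", {
  set.seed(31)
  meta <- mk_meta(organs = c("brain", "kidney"), stages = 1:2, reps = 2)
  x <- matrix(rexp(400 * 8, 1 / 50), 400, 8)
  x <- sweep(x, 2, colSums(x), "/") * 1e6  # TPM-scaled input
  em <- mk_em(x, meta)
  nr <- scaling_normalize(em)
  meds <- apply(nr$em$values[nr$selected_genes, ], 2, median)
  expect_lt(max(abs(meds - mean(meds))), 1e-9)
  expect_length(nr$selected_genes, 100L)
  # homogeneous TPM matrix (identical columns) -> all coefficients 1
  same <- mk_em(matrix(rep(x[, 1], 8), ncol = 8), meta)
  expect_equal(unname(scaling_normalize(same)$coefficients), rep(1, 8))
})

test_that("normalization is idempotent and equivariant to sample rescaling", {
  set.seed(32)
  meta <- mk_meta(organs = c("brain", "kidney"), stages = 1:2, reps = 2)
  for (rep in 1:5) {
    x <- matrix(rexp(300 * 8, 1 / 20), 300, 8)
    em <- mk_em(x, meta)
    nr <- scaling_normalize(em)
    nr2 <- scaling_normalize(nr$em)
    expect_lt(max(abs(nr2$coefficients - 1)), 1e-9)
    scaled <- em
    scaled$values <- sweep(em$values, 2, runif(8, 0.25, 4), "*")
    nr3 <- scaling_normalize(scaled)
    expect_equal(nr3$em$values, nr$em$values, tolerance = 1e-9)
    # doubling one sample halves its coefficient
    dbl <- em; dbl$values[, 3] <- dbl$values[, 3] * 2
    nr4 <- scaling_normalize(dbl)
    expect_equal(unname(nr4$coefficients[3] / nr$coefficients[3]), 0.5,
                 tolerance = 1e-12)
  }
})

test_that("log transform is log2(x + 1)", {
  expect_equal(log_transform(c(0, 1, 7)), c(0, 1, 3))
  expect_error(log_transform(-1), "negative")
})

test_that("condition means equal a naive group-by mean", {
  set.seed(33)
  meta <- mk_meta(organs = c("brain", "testes"), stages = 1:3, reps = 2)
  x <- matrix(rpois(50 * nrow(meta), 20), 50)
  em <- mk_em(x, meta, "tpm")
  cm <- condition_means(em)
  for (ci in seq_len(nrow(cm$conditions))) {
    cols <- meta$organ == cm$conditions$organ[ci] &
      meta$stage == cm$conditions$stage[ci]
    expect_equal(unname(cm$means[, ci]), unname(rowMeans(x[, cols])))
  }
  expect_equal(unname(cm$means["g1", 1]),
               mean(x[1, meta$organ == "brain" & meta$stage == 1]))
})

test_that("maximum-expression condition breaks ties by fixed organ order", {
  meta <- mk_meta(organs = c("brain", "kidney"), stages = 1, reps = 1)
  x <- rbind(c(5, 9), c(7, 7), c(0, 0))
  rownames(x) <- c("a", "b", "c")
  em <- mk_em(x, meta, "tpm")
  mx <- max_expression_condition(condition_means(em))
  expect_equal(mx$organ[mx$gene_id == "a"], "kidney")
  expect_equal(mx$organ[mx$gene_id == "b"], "brain")  # tie -> first in order
  expect_true(mx$tie[mx$gene_id == "b"])
  expect_true(is.na(mx$organ[mx$gene_id == "c"]))
})

test_that("read resampling equalizes condition depths and keeps zeros zero", {
  set.seed(34)
  meta <- mk_meta(organs = c("brain", "testes"), stages = 1:2, reps = 2)
  x <- matrix(rpois(200 * nrow(meta), 50), 200)
  x[1:20, 1] <- 0
  em <- mk_em(x, meta, "counts")
  rs <- resample_reads_to_depth(em, seed = 9)
  key <- paste(meta$organ, meta$stage)
  depths <- tapply(colSums(rs$values), key, sum)
  expect_true(all(depths == min(tapply(colSums(x), key, sum))))
  expect_true(all(rs$values[x == 0] == 0))
  expect_true(all(rs$values <= x))
  # the shallowest condition is untouched
  shallow <- names(which.min(tapply(colSums(x), key, sum)))
  expect_equal(rs$values[, key == shallow], x[, key == shallow],
               ignore_attr = TRUE)
})

test_that("resampling preserves expected gene shares", {
  set.seed(35)
  meta <- mk_meta(organs = c("brain", "testes"), stages = 1, reps = 1)
  x <- matrix(c(rpois(40, 200), rpois(40, 100)), ncol = 2)
  em <- mk_em(x, meta, "counts")
  props <- replicate(200, {
    rs <- resample_reads_to_depth(em, seed = sample.int(1e6, 1))
    rs$values[, 1] / sum(rs$values[, 1])
  })
  orig <- x[, 1] / sum(x[, 1])
  se <- apply(props, 1, sd) / sqrt(ncol(props))
  dev <- abs(rowMeans(props) - orig)
  expect_true(all(dev <= pmax(3 * se, 1e-12)))
})

test_that("detection counts use the 10-read boundary per class", {
  meta <- mk_meta(organs = "brain", stages = 1, reps = 2)
  x <- rbind(c(10, 9), c(9, 10), c(100, 0))
  rownames(x) <- c("a", "b", "c")
  em <- mk_em(x, meta, "counts")
  det <- detected_genes(em, c(a = "lncRNA", b = "lncRNA", c = "pc"))
  lnc <- det[det$gene_class == "lncRNA", ]
  expect_equal(lnc$n_detected, c(1L, 1L))
  pc <- det[det$gene_class == "pc", ]
  expect_equal(pc$n_detected, c(1L, 0L))
})

test_that("class down-sampling is proportional with stochastic rounding", {
  meta <- mk_meta(organs = "brain", stages = 1, reps = 1)
  pc <- matrix(c(400, 10, 190), ncol = 1)
  lnc <- matrix(rep(50, 4), ncol = 1)
  colnames(pc) <- colnames(lnc) <- meta$sample_id
  rownames(pc) <- paste0("p", 1:3); rownames(lnc) <- paste0("l", 1:4)
  # r = 50 / 200 = 0.25: proportional mode maps the 400-read gene to 100
  out <- downsample_counts_to_match(pc, lnc, seed = 1,
                                    method = "proportional")
  expect_equal(unname(out[1, 1]), 100)
  expect_true(out[2, 1] %in% c(2, 3))
  # zeros never become positive; Monte-Carlo mean matches the lncRNA mean
  # in both modes
  for (m in c("binomial", "proportional")) {
    draws <- vapply(1:500, function(s)
      mean(downsample_counts_to_match(pc, lnc, seed = s, method = m)), 0)
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - mean(lnc)), 3 * se + 0.3)
    zero <- downsample_counts_to_match(pc * 0 + c(0, 8, 400), lnc,
                                       seed = 2, method = m)
    expect_equal(unname(zero[1, 1]), 0)
  }
  # pc mean below lnc mean: unchanged with a warning
  expect_warning(out2 <- downsample_counts_to_match(lnc * 0 + 1, lnc),
                 "unchanged")
  expect_equal(unname(out2[, 1]), rep(1, 4))
})

test_that("tau specificity and marker selection behave at the extremes", {
  expect_equal(tau_specificity(c(0, 0, 5)), 1)
  expect_equal(tau_specificity(c(4, 4, 4)), 0)
  expect_true(is.na(tau_specificity(c(0, 0, 0))))
  conds <- c("brain_1", "testes_1")
  mk_cm <- function(m) list(means = m, conditions = data.frame(
    organ = c("brain", "testes"), stage = 1))
  ma <- rbind(a = c(0, 10), b = c(5, 6), c = c(10, 0))
  mb <- rbind(a = c(0, 8), b = c(5, 6), c = c(0, 10))
  colnames(ma) <- colnames(mb) <- conds
  pairs <- data.frame(gene_a = c("a", "b", "c"), gene_b = c("a", "b", "c"))
  mk <- marker_genes(mk_cm(ma), mk_cm(mb), pairs, tau_threshold = 0.8)
  # a: specific & concordant; b: not specific; c: argmax differs
  expect_equal(mk$gene_a, "a")
})

test_that("expression TSV round-trips with metadata", {
  set.seed(36)
  meta <- mk_meta()
  em <- mk_em(matrix(rpois(20 * nrow(meta), 30), 20), meta, "counts")
  mp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(em, mp, sp)
  em2 <- read_expression_tsv(mp, sp, "counts")
  expect_equal(em2$values, em$values)
  expect_equal(em2$meta, em$meta)
})

test_that("genes expressed above noise use an inclusive TPM threshold", {
  m <- rbind(a = c(1.0, 0.2), b = c(0.99, 5), c = c(0, 0))
  colnames(m) <- c("brain_1", "testes_1")
  sets <- expressed_above_noise(m)
  expect_equal(sets$brain_1, "a")
  expect_equal(sets$testes_1, "b")
})
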