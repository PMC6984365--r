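test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(seed = 99, n_pc = 10, n_lnc = 10, n_dup = 1,
                    n_transloc = 1, n_order = 1, n_del = 1, n_size = 1,
                    n_consensus = 1, n_ins = 1, n_expr_specific = 1)
  s1 <- simulate_genomes(cfg)
  s2 <- simulate_genomes(cfg)
  expect_identical(as.character(s1$species$sp1$genome),
                   as.character(s2$species$sp1$genome))
  expect_identical(s1$truth$families, s2$truth$families)
  e1 <- simulate_expression(cfg, s1)
  e2 <- simulate_expression(cfg, s2)
  expect_identical(e1$sp1$counts$values, e2$sp1$counts$values)
})

test_that("zero divergence and no events give identity chains and full recovery", {
  cfg <- sim_config(seed = 7, n_pc = 8, n_lnc = 8, n_dup = 0, n_transloc = 0,
                    n_order = 0, n_del = 0, n_size = 0, n_consensus = 0,
                    n_ins = 0, n_expr_specific = 0, subst_rate = 0,
                    indel_jitter = 0)
  sim <- simulate_genomes(cfg)
  expect_identical(as.character(sim$species$sp1$genome),
                   as.character(sim$species$sp2$genome))
  for (ch in sim$chains$ab$chains)
    expect_equal(ch$blocks$ref_start, ch$blocks$tgt_start)
  res <- predict_orthologs(sim$species$sp1$ann, sim$species$sp2$ann,
                           sim$chains$ab, sim$species$sp1$genome,
                           sim$species$sp2$genome,
                           chain_ba = sim$chains$ba)
  truth <- sim$truth$one2one
  expect_setequal(paste(res$rbh$ref_gene, res$rbh$target_gene),
                  paste(truth$sp1_gene, truth$sp2_gene))
})

test_that("emitted files round-trip through the package readers", {
  cfg <- sim_config(seed = 8, n_pc = 6, n_lnc = 6, n_dup = 1, n_transloc = 1,
                    n_order = 1, n_del = 1, n_size = 1, n_consensus = 1,
                    n_ins = 1, n_expr_specific = 1)
  sim <- simulate_genomes(cfg)
  expr <- simulate_expression(cfg, sim)
  trk <- simulate_conservation(cfg, sim)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir, expr = expr, track = trk)
  g2 <- Biostrings::readDNAStringSet(file.path(dir, "sp1.fa"))
  expect_equal(as.character(g2), as.character(sim$species$sp1$genome))
  ann2 <- read_gtf(file.path(dir, "sp1.gtf"))
  expect_setequal(names(ann2$genes), names(sim$species$sp1$ann$genes))
  cm2 <- read_chain(file.path(dir, "sp1_to_sp2.chain"))
  expect_length(cm2$chains, length(sim$chains$ab$chains))
  blocks0 <- do.call(rbind, lapply(sim$chains$ab$chains, `[[`, "blocks"))
  blocks1 <- do.call(rbind, lapply(cm2$chains, `[[`, "blocks"))
  expect_equal(blocks1[order(blocks1$ref_start), ],
               blocks0[order(blocks0$ref_start), ], ignore_attr = TRUE)
  trk2 <- read_bedgraph(file.path(dir, "conservation.bedGraph"))
  expect_equal(trk2$by_chrom$chr1, trk$by_chrom$chr1, tolerance = 1e-9)
  em2 <- read_expression_tsv(file.path(dir, "sp1_counts.tsv"),
                             file.path(dir, "sp1_meta.tsv"), "counts")
  expect_equal(em2$values, expr$sp1$counts$values)
})

test_that("every projection failure mode is planted and observed", {
  ds <- default_sim()
  sim <- ds$sim
  fam <- sim$truth$families
  ann <- sim$species$sp1$ann
  status_of <- function(gid) project_gene(ann$genes[[gid]], sim$chains$ab)
  # deletion -> no projected blocks
  del <- fam$sp1_gene[fam$event == "del_sp2"][1]
  expect_equal(status_of(del)$reason, "no_projected_blocks")
  # duplication -> ambiguous blocks
  dup <- fam$sp1_gene[fam$event == "dup"][1]
  expect_true("ambiguous" %in% status_of(dup)$block_statuses)
  # insertion -> size_fail
  siz <- fam$sp1_gene[fam$event == "size"][1]
  expect_true("size_fail" %in% status_of(siz)$block_statuses)
  # order event -> gene eliminated
  ord <- fam$sp1_gene[fam$event == "order"][1]
  expect_equal(status_of(ord)$reason, "order_fail")
  # consensus event -> one block dropped, gene kept
  con <- fam$sp1_gene[fam$event == "consensus"][1]
  gp <- status_of(con)
  expect_equal(gp$status, "projected")
  expect_gt(length(gp$dropped), 0L)
  # translocated exon -> dropped by the order rule, gene kept
  tra <- fam$sp1_gene[fam$event == "transloc"][1]
  gp2 <- status_of(tra)
  expect_equal(gp2$status, "projected")
})

test_that("conservation track covers each base once and boosts stand out", {
  cfg <- sim_config(seed = 9, n_pc = 6, n_lnc = 6, n_dup = 0, n_transloc = 0,
                    n_order = 0, n_del = 0, n_size = 0, n_consensus = 0,
                    n_ins = 0, n_expr_specific = 0)
  sim <- simulate_genomes(cfg)
  trk <- simulate_conservation(cfg, sim)
  for (ch in names(trk$by_chrom)) {
    d <- trk$by_chrom[[ch]]
    expect_equal(d$start[1], 0)
    expect_equal(d$start[-1], d$end[-nrow(d)])  # contiguous, no overlap
    expect_equal(d$end[nrow(d)],
                 Biostrings::width(sim$species$sp1$genome[ch]))
  }
  ann <- sim$species$sp1$ann
  fam <- sim$truth$families
  cons <- fam$sp1_gene[fam$conserved]
  noncons <- setdiff(names(ann$genes), cons)
  block_df <- function(gids) do.call(rbind, lapply(gids, function(g) {
    d <- exon_blocks(ann$genes[[g]]); d$gene_id <- g; d }))
  sc_cons <- region_conservation(trk, block_df(cons))
  expect_true(all(sc_cons > cfg$cons_baseline + cfg$cons_exon - 1e-9))
  if (length(noncons)) {
    sc_non <- region_conservation(trk, block_df(noncons))
    expect_true(all(sc_non == cfg$cons_baseline))
  }
  # promoter-only boost separates promoters from exons for conserved genes
  prom_df <- do.call(rbind, lapply(cons, function(g) {
    d <- promoter_region(ann$genes[[g]]); d$gene_id <- g; d }))
  sc_prom <- region_conservation(trk, prom_df)
  expect_true(all(abs(sc_prom - (cfg$cons_baseline + cfg$cons_promoter))
                  < 1e-9))
})

test_that("near-zero dispersion counts approach Poisson behaviour", {
  cfg <- sim_config(seed = 10, n_pc = 40, n_lnc = 40, n_dup = 0,
                    n_transloc = 0, n_order = 0, n_del = 0, n_size = 0,
                    n_consensus = 0, n_ins = 0, n_expr_specific = 0,
                    dispersion = 1e-8, expr_div_sd = 0, de_frac = 0)
  sim <- simulate_genomes(cfg)
  expr <- simulate_expression(cfg, sim)
  x <- expr$sp1$counts$values
  meta <- expr$sp1$counts$meta
  key <- condition_key(meta)
  # variance/mean ratio across replicates pools near 1 over many genes
  ratios <- unlist(lapply(unique(key), function(cl) {
    m <- x[, key == cl, drop = FALSE]
    mu <- rowMeans(m); v <- apply(m, 1, var)
    (v / mu)[mu > 20]
  }))
  expect_lt(abs(mean(ratios, na.rm = TRUE) - 1), 0.1)
})

test_that("CSF training pairs have no planted in-frame stops and zero rate is identity", {
  cfg <- sim_config(seed = 11)
  tr0 <- simulate_csf_training(cfg, n_pairs = 5, len_codons = 30,
                               codon_sub_rate = 0, nt_rate = 0)
  for (p in tr0$coding) expect_identical(p[1], p[2])
  for (p in tr0$noncoding) expect_identical(p[1], p[2])
  tr <- simulate_csf_training(cfg, n_pairs = 20, len_codons = 50)
  stops <- c("TAA", "TAG", "TGA")
  for (p in tr$coding) {
    for (s in p) {
      cods <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
      expect_false(any(cods %in% stops))
    }
  }
})
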