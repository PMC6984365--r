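test_that("chain files round-trip through the reader and writer", {
  cm <- chain_map(list(
    mk_chain(data.frame(ref_start = c(100, 400), ref_end = c(300, 600),
                        tgt_start = c(1100, 1500), tgt_end = c(1300, 1700)),
             score = 5000, id = "1"),
    mk_chain(data.frame(ref_start = 2000, ref_end = 2500,
                        tgt_start = 200, tgt_end = 700),
             tgt_chrom = "chr2", score = 800, id = "2")))
  path <- withr::local_tempfile(fileext = ".chain")
  write_chain(cm, path)
  cm2 <- read_chain(path)
  expect_length(cm2$chains, 2L)
  for (i in 1:2) {
    expect_equal(cm2$chains[[i]]$blocks, cm$chains[[i]]$blocks,
                 ignore_attr = TRUE)
    expect_equal(cm2$chains[[i]]$score, cm$chains[[i]]$score)
    expect_equal(cm2$chains[[i]]$tgt_chrom, cm$chains[[i]]$tgt_chrom)
  }
})

test_that("minus-strand chains parse to forward-strand coordinates", {
  lines <- c("chain 900 chr1 1000 + 100 200 chrT 1000 - 300 400 7",
             "100", "")
  path <- withr::local_tempfile(fileext = ".chain")
  writeLines(lines, path)
  cm <- read_chain(path)
  b <- cm$chains[[1]]$blocks
  # reverse coords [300,400) on a 1000 bp target = forward [600,700)
  expect_equal(c(b$tgt_start, b$tgt_end), c(600, 700))
  expect_equal(cm$chains[[1]]$tgt_strand, "-")
})

test_that("interval projection reports fractions and liftOver statuses", {
  main <- mk_chain(data.frame(ref_start = 1000, ref_end = 2000,
                              tgt_start = 5000, tgt_end = 6000),
                   score = 1e6, id = "main")
  cm <- chain_map(list(main))
  p <- project_interval(genomic_intervals("chr1", 1200, 1400, "+"), cm)
  expect_equal(p$status, "ok")
  expect_equal(p$fraction_remapped, 1)
  expect_equal(c(p$target_intervals$start, p$target_intervals$end),
               c(5200, 5400))
  # 9% coverage -> unmapped
  p2 <- project_interval(genomic_intervals("chr1", 1910, 2910, "+"), cm)
  expect_equal(p2$status, "unmapped")
  expect_equal(p2$fraction_remapped, 0.09)
  # two qualifying chains on different chromosomes -> ambiguous
  dup <- mk_chain(data.frame(ref_start = 1000, ref_end = 2000,
                             tgt_start = 100, tgt_end = 1100),
                  tgt_chrom = "chr9", score = 1e4, id = "dup")
  p3 <- project_interval(genomic_intervals("chr1", 1200, 1400, "+"),
                         chain_map(list(main, dup)))
  expect_equal(p3$status, "ambiguous")
  # absent chromosome -> unmapped
  p4 <- project_interval(genomic_intervals("chrZ", 0, 100, "+"), cm)
  expect_equal(p4$status, "unmapped")
})

test_that("size-ratio filter applies inclusive per-pair bounds", {
  mkp <- function(tgt_span) {
    ch <- mk_chain(data.frame(ref_start = 0, ref_end = 300,
                              tgt_start = 0, tgt_end = 300))
    p <- project_interval(genomic_intervals("chr1", 0, 300, "+"),
                          chain_map(list(ch)))
    p$target_intervals <- data.frame(chrom = "chr1", start = 0,
                                     end = tgt_span, strand = "+")
    p
  }
  expect_equal(size_ratio_filter(mkp(100))$status, "ok")      # 0.333 passes
  expect_equal(size_ratio_filter(mkp(95))$status, "size_fail") # 0.317 fails
  expect_equal(size_ratio_filter(mkp(1350), size_bounds("chicken"))$status,
               "ok")                                          # 4.5 in 0.2-5
  expect_equal(size_ratio_filter(mkp(1350))$status, "size_fail")
})

# block projection at a given target midpoint (for resolution tests)
mk_block_proj <- function(mid, chrom = "chr1", strand = "+", len = 100) {
  ref <- genomic_intervals("chr1", mid, mid + len, "+")
  structure(list(ref_block = ref,
                 target_intervals = data.frame(chrom = chrom,
                                               start = mid - len / 2,
                                               end = mid + len / 2,
                                               strand = strand),
                 fraction_remapped = 1, status = "ok", chain_id = "c",
                 tgt_chrom = chrom, tgt_strand = strand, chain_score = 1),
            class = "block_projection")
}

test_that("gene projection resolves consensus and single-block rearrangements", {
  # one block on another chromosome is dropped, gene kept
  gp <- resolve_gene_projection(list(mk_block_proj(1000),
                                     mk_block_proj(2000, chrom = "chr9"),
                                     mk_block_proj(3000)))
  expect_equal(gp$status, "projected")
  expect_length(gp$blocks, 2L)
  expect_equal(gp$consensus_chrom, "chr1")
  # order (1,3,2,4): one removal restores monotonicity -> block dropped
  gp2 <- resolve_gene_projection(lapply(c(1000, 3000, 2000, 4000),
                                        mk_block_proj))
  expect_equal(gp2$status, "projected")
  expect_length(gp2$blocks, 3L)
  # order (2,1,4,3): no single removal works -> gene eliminated
  gp3 <- resolve_gene_projection(lapply(c(2000, 1000, 4000, 3000),
                                        mk_block_proj))
  expect_equal(gp3$status, "discarded")
  expect_equal(gp3$reason, "order_fail")
})

test_that("gene projection agrees with the exhaustive single-removal oracle", {
  oracle <- function(mids) {
    if (!is.unsorted(mids, strictly = TRUE)) return("projected")
    for (i in seq_along(mids))
      if (!is.unsorted(mids[-i], strictly = TRUE)) return("projected")
    "discarded"
  }
  set.seed(21)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    mids <- sample(seq(1000, 8000, by = 100), n)
    gp <- resolve_gene_projection(lapply(mids, mk_block_proj))
    expect_equal(gp$status, oracle(mids),
                 info = paste(mids, collapse = ","))
  }
})

test_that("single-link clustering equals brute-force transitive closure", {
  set.seed(22)
  for (rep in 1:10) {
    n_ref <- sample(3:6, 1); n_tgt <- sample(3:6, 1)
    edges <- matrix(runif(n_ref * n_tgt) < 0.3, n_ref, n_tgt)
    # brute-force closure over the bipartite graph
    labels <- seq_len(n_ref + n_tgt)
    repeat {
      changed <- FALSE
      for (i in seq_len(n_ref)) for (j in seq_len(n_tgt)) if (edges[i, j]) {
        l <- min(labels[i], labels[n_ref + j])
        if (labels[i] != l || labels[n_ref + j] != l) {
          labels[labels == labels[i]] <- l
          labels[labels == labels[n_ref + j]] <- l
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    # build projections/annotation realizing exactly these overlaps
    projs <- list(); tgenes <- list()
    for (j in seq_len(n_tgt)) {
      tgenes[[j]] <- mk_gene(paste0("T", j), list(mk_tx(
        paste0("T", j, ".t"), paste0("T", j),
        exons = data.frame(start = j * 10000, end = j * 10000 + 500))))
    }
    for (i in seq_len(n_ref)) {
      hits <- which(edges[i, ])
      tis <- if (length(hits)) data.frame(
        chrom = "chr1", start = hits * 10000, end = hits * 10000 + 100,
        strand = "+") else
        data.frame(chrom = "chr1", start = 900000 + i * 10,
                   end = 900000 + i * 10 + 5, strand = "+")
      projs[[paste0("R", i)]] <- structure(list(
        gene_id = paste0("R", i), blocks = list(structure(list(
          ref_block = genomic_intervals("chr1", i * 100, i * 100 + 100, "+"),
          target_intervals = tis, fraction_remapped = 1, status = "ok",
          chain_id = "c", tgt_chrom = "chr1", tgt_strand = "+",
          chain_score = 1), class = "block_projection")),
        consensus_chrom = "chr1", consensus_strand = "+",
        status = "projected", target_strand = "+"),
        class = "gene_projection")
    }
    clusters <- cluster_candidates(projs, annotation_set(tgenes))
    # expected components among nodes that have at least one edge
    node_lab <- c(paste0("R", seq_len(n_ref)), paste0("T", seq_len(n_tgt)))
    has_edge <- c(rowSums(edges) > 0, colSums(edges) > 0)
    expected <- split(node_lab[has_edge], labels[has_edge])
    got <- lapply(clusters, function(cl) sort(c(cl$ref_genes,
                                                cl$target_genes)))
    expect_setequal(lapply(expected, sort), got)
  }
})

test_that("alignment statistics measure gapless and identical fractions", {
  s <- paste(rep("ACGT", 75), collapse = "")  # 300 bp
  st <- alignment_stats(s, s)
  expect_equal(st$pct_aligned_ungapped, 100)
  expect_equal(st$pct_identity, 100)
  # 30 bp deletion in the target: 90% of reference aligned without gaps
  del <- paste0(substr(s, 1, 135), substr(s, 166, 300))
  st2 <- alignment_stats(s, del)
  expect_equal(st2$pct_aligned_ungapped, 90)
  expect_true(st2$pct_identity <= st2$pct_aligned_ungapped)
  expect_error(alignment_stats("", s), "empty")
})

test_that("best hits require a >1.1 identity ratio over the runner-up", {
  cands <- function(ids) data.frame(target_gene = paste0("t", seq_along(ids)),
                                    pct_identity = ids)
  expect_equal(best_hit(cands(c(88, 70))), "t1")     # ratio 1.257
  expect_true(is.na(best_hit(cands(c(88, 85)))))     # ratio 1.035
  expect_equal(best_hit(cands(42)), "t1")            # single candidate
})

test_that("reciprocal best hits form a partial bijection", {
  bh_ab <- c(a1 = "b1", a2 = "b2", a3 = NA)
  bh_ba <- c(b1 = "a1", b2 = "a9")
  rbh <- reciprocal_best_hits(bh_ab, bh_ba)
  expect_equal(rbh$ref_gene, "a1")
  expect_equal(rbh$target_gene, "b1")
  expect_false(anyDuplicated(rbh$ref_gene) > 0)
})

test_that("families discard components with two genes of one species", {
  tabs <- list(
    data.frame(ref_gene = c("m1", "m2"), target_gene = c("r1", "r1"),
               ref_species = "mouse", target_species = "rat"),
    data.frame(ref_gene = "m3", target_gene = "r3",
               ref_species = "mouse", target_species = "rat"),
    data.frame(ref_gene = "r3", target_gene = "c3",
               ref_species = "rat", target_species = "chicken"))
  fams <- three_species_families(tabs)
  sizes <- vapply(fams, nrow, 0L)
  expect_length(fams, 1L)  # the m1/m2/r1 component is discarded
  expect_equal(sort(fams[[1]]$gene), c("c3", "m3", "r3"))
  expect_equal(sizes, 3L)
})

test_that("conservation classes are ordered and use the 10-read boundary", {
  cls <- conservation_class(projected = c(FALSE, TRUE, TRUE, TRUE, TRUE),
                            target_reads = c(NA, 9, 12, 12, 12),
                            has_rbh = c(FALSE, FALSE, FALSE, TRUE, TRUE),
                            same_class = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(cls, c("unprojected", "projected", "projected_transcribed",
                      "ortholog", "ortholog_same_class"))
})
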