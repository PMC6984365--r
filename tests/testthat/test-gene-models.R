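test_that("GTF coordinates convert between 1-based inclusive and internal", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste0("chr1\tsrc\texon\t101\t200\t.\t+\t.\t",
                    'gene_id "g1"; transcript_id "g1.t1"; gene_biotype "lincRNA";'),
             path)
  ann <- read_gtf(path)
  tx <- ann$genes$g1$transcripts[[1]]
  expect_equal(tx$exons$start, 100)
  expect_equal(tx$exons$end, 200)
  expect_equal(ann$genes$g1$biotype, "lincRNA")
})

test_that("transcripts sharing gene_id group into one gene", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\texon\t1\t100\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\tsrc\texon\t201\t300\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t2";')), path)
  ann <- read_gtf(path)
  expect_length(ann$genes, 1L)
  expect_length(ann$genes$g1$transcripts, 2L)
})

test_that("GTF round-trip preserves genes, transcripts, exons, coordinates", {
  set.seed(7)
  genes <- lapply(1:8, function(i) random_gene(paste0("g", i)))
  ann <- annotation_set(genes)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, path)
  ann2 <- read_gtf(path)
  expect_setequal(names(ann2$genes), names(ann$genes))
  for (gid in names(ann$genes)) {
    g1 <- ann$genes[[gid]]; g2 <- ann2$genes[[gid]]
    expect_setequal(names(g2$transcripts), names(g1$transcripts))
    for (tid in names(g1$transcripts))
      expect_equal(g2$transcripts[[tid]]$exons, g1$transcripts[[tid]]$exons)
  }
  # second round-trip is identical
  path2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann2, path2)
  expect_identical(sort(readLines(path)), sort(readLines(path2)))
})

test_that("malformed GTF lines are rejected with a useful error", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("chr1\tsrc\texon\t1\t100\t.\t+\t.", "not a gtf line"), path)
  expect_error(read_gtf(path), "line")
})

test_that("reference pre-filter drops long spans and noncoding isoforms", {
  long_tx <- mk_tx("tl", "g1", exons = data.frame(start = 0, end = 3.0e6))
  ri_tx <- mk_tx("tr", "g2", exons = data.frame(start = 0, end = 1000),
                 biotype = "retained_intron")
  edge_tx <- mk_tx("te", "g3", exons = data.frame(start = 0, end = 2.5e6))
  ann <- annotation_set(list(
    mk_gene("g1", list(long_tx, mk_tx("tk", "g1"))),
    mk_gene("g2", list(ri_tx)),
    mk_gene("g3", list(edge_tx))))
  out <- prefilter_reference(ann)
  expect_false("tl" %in% names(out$genes$g1$transcripts))  # > 2.5 Mb removed
  expect_true("tk" %in% names(out$genes$g1$transcripts))
  expect_false("g2" %in% names(out$genes))  # only isoform dropped -> gene out
  expect_true("g3" %in% names(out$genes))   # exactly 2.5 Mb kept (strict >)
})

test_that("exon blocks are the minimal disjoint union across isoforms", {
  g <- mk_gene("g1", list(
    mk_tx("t1", "g1", exons = data.frame(start = c(100, 300),
                                         end = c(200, 400))),
    mk_tx("t2", "g1", exons = data.frame(start = 150, end = 250))))
  b <- exon_blocks(g)
  expect_equal(b$start, c(100, 300))
  expect_equal(b$end, c(250, 400))
})

test_that("exon blocks equal brute-force base-set union on random genes", {
  set.seed(11)
  for (i in 1:20) {
    g <- random_gene(paste0("r", i))
    b <- exon_blocks(g)
    bases <- unlist(lapply(seq_len(nrow(b)), function(j)
      seq(b$start[j], b$end[j] - 1L)))
    expect_setequal(bases, exon_base_set(g))
    expect_false(is.unsorted(b$start, strictly = TRUE))
    # idempotent: re-unioning changes nothing
    expect_equal(interval_union(b[, c("start", "end")])[, c("start", "end")],
                 b[, c("start", "end")])
  }
})

test_that("promoter regions follow strand and truncate at the chromosome", {
  gp <- mk_gene("gp", list(mk_tx("t", "gp", strand = "+",
    exons = data.frame(start = 1000, end = 1500))))
  expect_equal(promoter_region(gp, 400)[, c("start", "end")],
               data.frame(start = 600, end = 1000))
  gm <- mk_gene("gm", list(mk_tx("t", "gm", strand = "-",
    exons = data.frame(start = 500, end = 1000))))
  expect_equal(promoter_region(gm, 400)[, c("start", "end")],
               data.frame(start = 1000, end = 1400))
  ge <- mk_gene("ge", list(mk_tx("t", "ge", strand = "+",
    exons = data.frame(start = 100, end = 600))))
  pr <- promoter_region(ge, 400)
  expect_equal(c(pr$start, pr$end), c(0, 100))
  expect_true(attr(pr, "truncated"))
})

test_that("splice sites are the first and last two intronic bases", {
  tx <- mk_tx("t", "g", exons = data.frame(start = c(0, 200), end = c(100, 300)))
  ss <- splice_sites(tx)
  expect_equal(ss$start, c(100, 198))
  expect_equal(ss$end, c(102, 200))
  tx3 <- mk_tx("t3", "g", exons = data.frame(start = c(0, 200, 400),
                                             end = c(100, 300, 500)))
  expect_equal(sum(splice_sites(tx3)$end - splice_sites(tx3)$start), 8)
  mono <- mk_tx("tm", "g", exons = data.frame(start = 0, end = 100))
  expect_equal(nrow(splice_sites(mono)), 0L)
})

test_that("promoters and splice sites avoid the transcript's own exons", {
  set.seed(13)
  for (i in 1:10) {
    g <- random_gene(paste0("p", i), n_tx = 1)
    tx <- g$transcripts[[1]]
    ex <- tx$exons
    ss <- splice_sites(tx)
    if (nrow(ss))
      for (j in seq_len(nrow(ss)))
        expect_equal(interval_overlap_len(ss$start[j], ss$end[j],
                                          ex$start, ex$end), 0)
    pr <- promoter_region(g)
    if (pr$end > pr$start)
      expect_equal(interval_overlap_len(pr$start, pr$end, ex$start, ex$end), 0)
  }
})

test_that("bidirectional promoter classification prefers protein-coding", {
  g <- mk_gene("x", list(mk_tx("t", "x", strand = "+",
    exons = data.frame(start = 10000, end = 10500))))
  pc <- mk_gene("pc", list(mk_tx("tp", "pc", strand = "-",
    exons = data.frame(start = 9000, end = 9500))))
  lnc <- mk_gene("ln", list(mk_tx("tl", "ln", strand = "-",
    exons = data.frame(start = 9200, end = 9700))),
    biotype = "lincRNA")
  # pc TSS (- strand) at 9500, 500 bp from x's TSS at 10000
  ann <- annotation_set(list(g, pc, lnc))
  expect_equal(classify_promoter_type(g, ann, 1000), "bidirectional_pc")
  ann2 <- annotation_set(list(g, lnc))
  expect_equal(classify_promoter_type(g, ann2, 1000), "bidirectional_other")
  expect_equal(classify_promoter_type(g, ann, 100), "unidirectional")
})
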