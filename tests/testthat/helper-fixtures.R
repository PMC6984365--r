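# Small in-code fixtures shared across test files.

mk_tx <- function(id = "t1", gene_id = "g1", chrom = "chr1", strand = "+",
                  exons = data.frame(start = c(0, 200), end = c(100, 300)),
                  biotype = "protein_coding") {
  transcript_model(id, gene_id, chrom, strand, exons, biotype)
}

mk_gene <- function(id = "g1", txs = list(mk_tx(gene_id = id)),
                    biotype = "protein_coding", source = "reference") {
  gene_model(id, txs, biotype = biotype, source = source)
}

# random gene model on one chromosome for property tests
random_gene <- function(id, n_tx = 2, chrom = "chr1", strand = "+") {
  txs <- lapply(seq_len(n_tx), function(j) {
    n_ex <- sample(1:4, 1)
    starts <- sort(sample(seq(0, 5000, by = 10), n_ex))
    lens <- sample(20:200, n_ex, replace = TRUE)
    ends <- starts + lens
    # enforce >= 1 bp introns
    for (i in seq_len(n_ex - 1))
      if (ends[i] >= starts[i + 1]) starts[i + 1] <- ends[i] + sample(1:50, 1)
    ends <- starts + lens
    mk_tx(paste0(id, ".t", j), id, chrom, strand,
          data.frame(start = starts, end = ends))
  })
  mk_gene(id, txs)
}

# brute-force base set of a gene's exons across isoforms
exon_base_set <- function(gene) {
  unique(unlist(lapply(gene$transcripts, function(tx)
    unlist(lapply(seq_len(nrow(tx$exons)), function(i)
      seq(tx$exons$start[i], tx$exons$end[i] - 1L))))))
}

# one-chain chain map builder: blocks as data.frame(ref_start, ref_end,
# tgt_start, tgt_end)
mk_chain <- function(blocks, ref_chrom = "chr1", tgt_chrom = "chr1",
                     tgt_strand = "+", score = 1000, id = "1",
                     ref_size = 1e6, tgt_size = 1e6) {
  list(score = score, id = id, ref_chrom = ref_chrom, ref_size = ref_size,
       tgt_chrom = tgt_chrom, tgt_size = tgt_size, tgt_strand = tgt_strand,
       blocks = blocks)
}

# deterministic sample metadata: one species, organs x stages x reps
mk_meta <- function(species = "sp1", organs = c("brain", "testes"),
                    stages = 1:2, reps = 2) {
  g <- expand.grid(replicate = seq_len(reps), stage = stages, organ = organs,
                   stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%s_s%d_r%d", species, g$organ, g$stage,
                                 g$replicate),
             species = species, organ = g$organ, stage = g$stage,
             replicate = g$replicate, stringsAsFactors = FALSE)
}

mk_em <- function(values, meta, kind = "tpm") {
  colnames(values) <- meta$sample_id
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  expression_matrix(values, meta, kind)
}

# shared default simulation for the heavier tests (built once per run)
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 1)
      cache <<- list(cfg = cfg, sim = simulate_genomes(cfg))
    }
    cache
  }
})
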