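# Deterministic multi-species simulator with planted ground truth.
# Genomes are small (two chromosomes, ~0.5 Mb each) with short genes; chain
# files are emitted directly from the true base-level homology rather than by
# re-alignment, so tests target pipeline logic. Planted structural events
# exercise every projection failure mode: tandem-like duplications on another
# chromosome (ambiguous), relocated exon blocks (order violations and
# consensus mismatches), large insertions (size-ratio failures), deletions
# and species-specific insertions (unmapped).

#' Simulation configuration
#'
#' Defaults define the package's standard study conditions: two species, four
#' organs (brain, kidney, liver, testes), three developmental stages, three
#' replicates; ~110 clean protein-coding and ~110 clean lncRNA ortholog
#' families plus planted structural and expression events; 5\% sequence
#' divergence; lncRNAs expressed about eightfold below protein-coding genes
#' with a testis bias.
#'
#' @param seed master seed; every simulate_* call derives its randomness
#'   from it.
#' @param n_pc,n_lnc clean ortholog families per class.
#' @param n_dup,n_transloc,n_order,n_del,n_size,n_consensus,n_ins,n_expr_specific
#'   planted event counts (per species where applicable).
#' @param subst_rate nucleotide substitution rate between species.
#' @param dup_subst_rate divergence of duplicate copies from their template.
#' @param indel_jitter max +/- bp change of intergenic spacer lengths.
#' @param organs,stages,n_reps expression design.
#' @param pc_scale,lnc_scale log-scale mean expression per class.
#' @param organ_sd,expr_div_sd log-normal spread of organ effects and
#'   between-species divergence.
#' @param testis_factor,testis_frac lncRNA testis bias.
#' @param de_frac,de_log2fc fraction and effect of stage-DE genes.
#' @param dispersion negative-binomial dispersion of replicate counts.
#' @param lib_size expected reads per sample.
#' @param cons_baseline,cons_exon,cons_promoter,cons_splice conservation
#'   track baseline and boosts.
#' @param conserved_lnc_frac fraction of lncRNAs with constrained elements.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_pc = 110, n_lnc = 110,
                       n_dup = 10, n_transloc = 6, n_order = 4, n_del = 6,
                       n_size = 3, n_consensus = 3, n_ins = 4,
                       n_expr_specific = 5,
                       subst_rate = 0.05, dup_subst_rate = 0.005,
                       indel_jitter = 150,
                       organs = c("brain", "kidney", "liver", "testes"),
                       stages = 1:3, n_reps = 3,
                       pc_scale = log(80), lnc_scale = log(10),
                       organ_sd = 0.8, expr_div_sd = 0.3,
                       testis_factor = 4, testis_frac = 0.5,
                       de_frac = 0.3, de_log2fc = 2,
                       dispersion = 0.05, lib_size = 3e5,
                       cons_baseline = 0.1, cons_exon = 0.6,
                       cons_promoter = 0.4, cons_splice = 0.8,
                       conserved_lnc_frac = 0.5) {
  cfg <- as.list(environment())
  stopifnot(cfg$subst_rate >= 0, cfg$de_frac >= 0, cfg$de_frac <= 1)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) paste(sample(CODON_BASES, n, replace = TRUE),
                                collapse = "")

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  x <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(x)) < rate)
  for (i in hit) x[i] <- sample(setdiff(CODON_BASES, x[i]), 1)
  paste(x, collapse = "")
}

# family table with planted events
build_family_table <- function(cfg) {
  ev <- c(rep("none", cfg$n_pc + cfg$n_lnc),
          rep("dup", cfg$n_dup), rep("transloc", cfg$n_transloc),
          rep("order", cfg$n_order), rep("del_sp2", cfg$n_del),
          rep("size", cfg$n_size), rep("consensus", cfg$n_consensus),
          rep("ins_sp1", cfg$n_ins), rep("ins_sp2", cfg$n_ins),
          rep("expr_sp1", cfg$n_expr_specific),
          rep("expr_sp2", cfg$n_expr_specific))
  cls <- c(rep("protein_coding", cfg$n_pc), rep("lncRNA", cfg$n_lnc),
           rep("lncRNA", length(ev) - cfg$n_pc - cfg$n_lnc))
  n <- length(ev)
  fam <- data.frame(family = sprintf("fam%03d", seq_len(n)),
                    class = cls, event = ev, stringsAsFactors = FALSE)
  fam <- fam[sample.int(n), , drop = FALSE]
  fam$chrom <- rep(c("chr1", "chr2"), length.out = n)
  fam$strand <- sample(c("+", "-"), n, replace = TRUE)
  fam$conserved <- fam$class == "protein_coding" |
    runif(n) < cfg$conserved_lnc_frac
  fam$n_exons <- sample(1:5, n, replace = TRUE)
  fam$n_exons[fam$event %in% c("transloc", "consensus")] <-
    pmax(3L, fam$n_exons[fam$event %in% c("transloc", "consensus")])
  fam$n_exons[fam$event == "order"] <- 4L
  fam$n_exons[fam$event == "size"] <- 1L
  rownames(fam) <- NULL
  fam
}

# exon/intron layout for one gene; returns list(exons = start/end offsets
# within the gene, length = total span)
gene_layout <- function(n_exons, equal_exons = FALSE) {
  ex_len <- if (equal_exons) rep(150L, n_exons)
    else sample(120:400, n_exons, replace = TRUE)
  in_len <- if (n_exons > 1L) sample(200:600, n_exons - 1L, replace = TRUE)
    else integer(0)
  starts <- cumsum(c(0L, head(ex_len, -1L) + in_len))
  list(starts = starts, ends = starts + ex_len, length = sum(ex_len) +
         sum(in_len), ex_len = ex_len)
}

#' Simulate two species' genomes, annotations and chain maps
#'
#' Builds an ancestral gene layout, derives two descendant genomes with
#' nucleotide substitutions, spacer indels and the configured planted events,
#' and emits chain maps expressing the true homology (main chain per
#' chromosome plus one chain per relocated or duplicated segment).
#'
#' @param cfg a [sim_config()].
#' @return list of class `lncevo_sim`: `species` (per species `genome`
#'   DNAStringSet and `ann` annotation set), `chains` (`ab`, `ba`),
#'   `truth` (family table with per-species gene ids and the planted
#'   1-to-1 ortholog map), `config`.
#' @export
simulate_genomes <- function(cfg) {
  set.seed(cfg$seed)
  fam <- build_family_table(cfg)
  n <- nrow(fam)
  # per-chromosome assembly state
  seqs1 <- list(); seqs2 <- list()
  pos1 <- c(chr1 = 0, chr2 = 0); pos2 <- c(chr1 = 0, chr2 = 0)
  for (ch in c("chr1", "chr2")) { seqs1[[ch]] <- list(); seqs2[[ch]] <- list() }
  push1 <- function(ch, s) { seqs1[[ch]][[length(seqs1[[ch]]) + 1L]] <<- s
    pos1[ch] <<- pos1[ch] + nchar(s) }
  push2 <- function(ch, s) { seqs2[[ch]][[length(seqs2[[ch]]) + 1L]] <<- s
    pos2[ch] <<- pos2[ch] + nchar(s) }
  ledger <- list()   # chain_key, c1, s1, e1, c2, s2, e2
  add_seg <- function(key, c1, s1, e1, c2, s2, e2)
    ledger[[length(ledger) + 1L]] <<- data.frame(
      chain_key = key, c1 = c1, s1 = s1, e1 = e1, c2 = c2, s2 = s2, e2 = e2,
      stringsAsFactors = FALSE)
  genes1 <- list(); genes2 <- list()
  extras <- list()  # deferred sp2 segments: seq, chrom, chain info, annotation
  fam$sp1_gene <- NA_character_; fam$sp2_gene <- NA_character_
  fam$sp1_start <- NA_real_; fam$sp2_start <- NA_real_
  fam$dup_gene <- NA_character_
  other_chrom <- c(chr1 = "chr2", chr2 = "chr1")

  for (i in seq_len(n)) {
    f <- fam[i, ]
    ch <- f$chrom
    lay <- gene_layout(f$n_exons, equal_exons = f$event == "order")
    if (f$event %in% c("transloc", "consensus")) {
      # keep the relocated exon (index 2) a clear base-count minority so the
      # consensus vote always sides with the unmoved blocks
      ex_len <- rep(300L, f$n_exons); ex_len[2] <- 120L
      in_len <- sample(200:600, f$n_exons - 1L, replace = TRUE)
      starts <- cumsum(c(0L, head(ex_len, -1L) + in_len))
      lay <- list(starts = starts, ends = starts + ex_len,
                  length = sum(ex_len) + sum(in_len), ex_len = ex_len)
    }
    spacer1 <- sample(1500:3000, 1)
    spacer2 <- spacer1 + if (cfg$indel_jitter > 0)
      sample(-cfg$indel_jitter:cfg$indel_jitter, 1) else 0L
    present1 <- !f$event %in% "ins_sp2"
    present2 <- !f$event %in% c("del_sp2", "ins_sp1")
    spacer_seq <- random_dna(max(spacer1, spacer2))
    if (present1) push1(ch, substr(spacer_seq, 1, spacer1))
    if (present2) push2(ch, substr(spacer_seq, 1, spacer2))
    g1s <- unname(pos1[ch]); g2s <- unname(pos2[ch])
    seq1 <- if (present1) random_dna(lay$length) else NULL
    gid1 <- paste0("sp1.", f$family); gid2 <- paste0("sp2.", f$family)
    biotype <- if (f$class == "protein_coding") "protein_coding" else
      "lincRNA"
    mk_gene <- function(gid, chrom, start, starts, ends, strand) {
      tx <- transcript_model(paste0(gid, ".t1"), gid, chrom, strand,
                             data.frame(start = start + starts,
                                        end = start + ends),
                             biotype = biotype)
      gene_model(gid, list(tx), biotype = biotype,
                 gene_class = if (biotype == "protein_coding")
                   "protein_coding" else "lncRNA",
                 source = "reference")
    }
    if (present1 && !is.null(seq1)) {
      push1(ch, seq1)
      genes1[[gid1]] <- mk_gene(gid1, ch, g1s, lay$starts, lay$ends,
                                f$strand)
      fam$sp1_gene[i] <- gid1; fam$sp1_start[i] <- g1s
    }
    if (!present2) next
    ev <- f$event
    if (ev %in% c("none", "dup", "expr_sp1", "expr_sp2") ||
        (ev == "ins_sp2")) {
      seq2 <- if (ev == "ins_sp2") random_dna(lay$length)
        else mutate_dna(seq1, cfg$subst_rate)
      push2(ch, seq2)
      genes2[[gid2]] <- mk_gene(gid2, ch, g2s, lay$starts, lay$ends,
                                f$strand)
      fam$sp2_gene[i] <- gid2; fam$sp2_start[i] <- g2s
      if (ev != "ins_sp2")
        add_seg(paste0("main_", ch), ch, g1s, g1s + lay$length,
                ch, g2s, g2s + lay$length)
      if (ev == "dup") {
        dup_seq <- mutate_dna(seq2, cfg$dup_subst_rate)
        extras[[length(extras) + 1L]] <- list(
          seq = dup_seq, chrom = other_chrom[ch],
          src = c(chrom = ch, start = g1s, end = g1s + lay$length),
          annotate = list(gid = paste0(gid2, "dup"), starts = lay$starts,
                          ends = lay$ends, strand = f$strand,
                          biotype = biotype),
          key = paste0("dup_", f$family))
        fam$dup_gene[i] <- paste0(gid2, "dup")
      }
    } else if (ev %in% c("transloc", "consensus")) {
      k <- 2L  # excised exon index
      exon_s <- lay$starts[k]; exon_e <- lay$ends[k]
      m2 <- mutate_dna(seq1, cfg$subst_rate)
      body <- paste0(substr(m2, 1, exon_s), substr(m2, exon_e + 1,
                                                   nchar(m2)))
      moved <- substr(m2, exon_s + 1, exon_e)
      push2(ch, body)
      keep <- setdiff(seq_len(f$n_exons), k)
      shift <- ifelse(lay$starts[keep] >= exon_e, exon_e - exon_s, 0)
      genes2[[gid2]] <- mk_gene(gid2, ch, g2s, lay$starts[keep] - shift,
                                lay$ends[keep] - shift, f$strand)
      fam$sp2_gene[i] <- gid2; fam$sp2_start[i] <- g2s
      add_seg(paste0("main_", ch), ch, g1s, g1s + exon_s, ch, g2s,
              g2s + exon_s)
      add_seg(paste0("main_", ch), ch, g1s + exon_e, g1s + lay$length,
              ch, g2s + exon_s, g2s + lay$length - (exon_e - exon_s))
      extras[[length(extras) + 1L]] <- list(
        seq = moved,
        chrom = if (ev == "consensus") other_chrom[ch] else ch,
        src = c(chrom = ch, start = g1s + exon_s, end = g1s + exon_e),
        annotate = NULL, key = paste0(ev, "_", f$family))
    } else if (ev == "order") {
      perm <- c(2L, 1L, 4L, 3L)
      x1 <- strsplit(seq1, "")[[1]]
      x2 <- strsplit(mutate_dna(seq1, cfg$subst_rate), "")[[1]]
      # exon slot j receives the homolog of sp1 exon perm[j] (perm is its
      # own inverse)
      for (j in 1:4) {
        src <- (lay$starts[perm[j]] + 1):lay$ends[perm[j]]
        dst <- (lay$starts[j] + 1):lay$ends[j]
        x2[dst] <- vapply(x1[src], function(b)
          if (runif(1) < cfg$subst_rate) sample(setdiff(CODON_BASES, b), 1)
          else b, "")
      }
      push2(ch, paste(x2, collapse = ""))
      genes2[[gid2]] <- mk_gene(gid2, ch, g2s, lay$starts, lay$ends,
                                f$strand)
      fam$sp2_gene[i] <- gid2; fam$sp2_start[i] <- g2s
      for (j in 1:4)
        add_seg(paste0("order_", f$family, "_", j), ch,
                g1s + lay$starts[j], g1s + lay$ends[j],
                ch, g2s + lay$starts[perm[j]], g2s + lay$ends[perm[j]])
    } else if (ev == "size") {
      ins_len <- as.integer(3.5 * lay$length)
      half <- lay$length %/% 2
      m2 <- mutate_dna(seq1, cfg$subst_rate)
      seq2 <- paste0(substr(m2, 1, half), random_dna(ins_len),
                     substr(m2, half + 1, nchar(m2)))
      push2(ch, seq2)
      genes2[[gid2]] <- mk_gene(gid2, ch, g2s, 0L, lay$length + ins_len,
                                f$strand)
      fam$sp2_gene[i] <- gid2; fam$sp2_start[i] <- g2s
      add_seg(paste0("main_", ch), ch, g1s, g1s + half, ch, g2s, g2s + half)
      add_seg(paste0("main_", ch), ch, g1s + half, g1s + lay$length,
              ch, g2s + half + ins_len, g2s + lay$length + ins_len)
    }
  }
  # deferred sp2 segments (duplicate copies, relocated exon blocks)
  for (ex in extras) {
    ch2 <- ex$chrom
    push2(ch2, random_dna(1000L))
    s2 <- unname(pos2[ch2])
    push2(ch2, ex$seq)
    add_seg(ex$key, ex$src["chrom"], as.numeric(ex$src["start"]),
            as.numeric(ex$src["end"]), ch2, s2, s2 + nchar(ex$seq))
    if (!is.null(ex$annotate)) {
      a <- ex$annotate
      tx <- transcript_model(paste0(a$gid, ".t1"), a$gid, ch2, a$strand,
                             data.frame(start = s2 + a$starts,
                                        end = s2 + a$ends),
                             biotype = a$biotype)
      genes2[[a$gid]] <- gene_model(a$gid, list(tx), biotype = a$biotype,
        gene_class = if (a$biotype == "protein_coding") "protein_coding"
          else "lncRNA", source = "reference")
    }
  }
  # trailing spacer so promoters/tracks never hit the chromosome edge
  for (ch in c("chr1", "chr2")) { tail_seq <- random_dna(1000L)
    push1(ch, tail_seq); push2(ch, tail_seq) }
  genome1 <- Biostrings::DNAStringSet(vapply(seqs1, function(p)
    paste(unlist(p), collapse = ""), ""))
  genome2 <- Biostrings::DNAStringSet(vapply(seqs2, function(p)
    paste(unlist(p), collapse = ""), ""))
  sizes1 <- setNames(Biostrings::width(genome1), names(genome1))
  sizes2 <- setNames(Biostrings::width(genome2), names(genome2))
  # assemble chains from the ledger
  led <- do.call(rbind, ledger)
  chains <- lapply(split(led, led$chain_key), function(d) {
    d <- d[order(d$s1), , drop = FALSE]
    main <- grepl("^main_", d$chain_key[1])
    list(score = if (main) 1e6 else 1e4,
         id = d$chain_key[1],
         ref_chrom = d$c1[1], ref_size = sizes1[[d$c1[1]]],
         tgt_chrom = d$c2[1], tgt_size = sizes2[[d$c2[1]]],
         tgt_strand = "+",
         blocks = data.frame(ref_start = d$s1, ref_end = d$e1,
                             tgt_start = d$s2, tgt_end = d$e2))
  })
  chain_ab <- chain_map(unname(chains))
  truth_pairs <- fam[!is.na(fam$sp1_gene) & !is.na(fam$sp2_gene) &
                       !fam$event %in% "dup", c("sp1_gene", "sp2_gene",
                                                "family", "class", "event")]
  rownames(truth_pairs) <- NULL
  structure(list(
    species = list(
      sp1 = list(genome = genome1, ann = annotation_set(unname(genes1))),
      sp2 = list(genome = genome2, ann = annotation_set(unname(genes2)))),
    chains = list(ab = chain_ab, ba = invert_chain_map(chain_ab)),
    truth = list(families = fam, one2one = truth_pairs),
    config = cfg), class = "lncevo_sim")
}

#' Simulate replicate expression matrices with planted structure
#'
#' Condition means follow log-normal organ effects shared between species,
#' class-specific expression scales (lncRNAs low, optionally testis-biased),
#' planted stage-DE profiles (monotone up, monotone down, or mid-peak), and
#' log-normal between-species divergence. Replicate counts are negative
#' binomial; TPM is derived from counts and exonic lengths. Planted
#' expression-species-specific loci have zero counts in the off species.
#'
#' @param cfg a [sim_config()].
#' @param sim result of [simulate_genomes()].
#' @return list per species of `counts` and `tpm` [expression_matrix()]s,
#'   plus `truth` (`de_genes`, `shapes`, `expr_specific`).
#' @export
simulate_expression <- function(cfg, sim) {
  set.seed(cfg$seed + 1L)
  fam <- sim$truth$families
  out <- list()
  # family-level shared structure
  all_fams <- fam$family
  base_fam <- setNames(exp(rnorm(length(all_fams),
    ifelse(fam$class == "protein_coding", cfg$pc_scale, cfg$lnc_scale), 1)),
    all_fams)
  organ_eff <- matrix(exp(rnorm(length(all_fams) * length(cfg$organs), 0,
                                cfg$organ_sd)),
                      nrow = length(all_fams),
                      dimnames = list(all_fams, cfg$organs))
  testis_bias <- setNames(fam$class == "lncRNA" &
                            runif(length(all_fams)) < cfg$testis_frac,
                          all_fams)
  organ_eff[testis_bias, "testes"] <-
    organ_eff[testis_bias, "testes"] * cfg$testis_factor
  is_de <- setNames(runif(length(all_fams)) < cfg$de_frac, all_fams)
  shape <- setNames(sample(c("up", "down", "peak"), length(all_fams),
                           replace = TRUE), all_fams)
  S <- length(cfg$stages)
  shape_mult <- function(sh) {
    g <- switch(sh,
      up = seq(0, 1, length.out = S),
      down = seq(1, 0, length.out = S),
      peak = { v <- rep(0, S); v[ceiling(S / 2)] <- 1; v })
    2^(cfg$de_log2fc * g)
  }
  # expression-specific loci: on only in the named species
  on_only <- setNames(rep(NA_character_, length(all_fams)), all_fams)
  on_only[fam$event == "expr_sp1"] <- "sp1"
  on_only[fam$event == "expr_sp2"] <- "sp2"
  base_fam[!is.na(on_only)] <- pmax(base_fam[!is.na(on_only)], 30)
  for (sp in c("sp1", "sp2")) {
    ann <- sim$species[[sp]]$ann
    gids <- names(ann$genes)
    gfam <- sub("^sp[12]\\.", "", gids)
    gfam <- sub("dup$", "", gfam)
    lens <- vapply(ann$genes, exonic_length, 0)
    meta <- expand.grid(replicate = seq_len(cfg$n_reps), stage = cfg$stages,
                        organ = cfg$organs, stringsAsFactors = FALSE)
    meta <- data.frame(sample_id = sprintf("%s_%s_s%d_r%d", sp, meta$organ,
                                           meta$stage, meta$replicate),
                       species = sp, organ = meta$organ, stage = meta$stage,
                       replicate = meta$replicate, stringsAsFactors = FALSE)
    mu_cond <- matrix(0, length(gids), nrow(meta),
                      dimnames = list(gids, meta$sample_id))
    for (gi in seq_along(gids)) {
      f <- gfam[gi]
      lambda <- base_fam[f] * organ_eff[f, meta$organ]
      if (is_de[f]) {
        sm <- shape_mult(shape[f])
        lambda <- lambda * sm[match(meta$stage, cfg$stages)]
      }
      if (sp == "sp2")
        lambda <- lambda * exp(rnorm(length(lambda), 0, cfg$expr_div_sd))
      if (!is.na(on_only[f]) && on_only[f] != sp) lambda <- lambda * 0
      mu_cond[gi, ] <- lambda
    }
    # species-2 divergence drawn per condition, shared across replicates
    if (sp == "sp2") {
      key <- condition_key(meta)
      for (cl in unique(key)) {
        cols <- which(key == cl)
        mu_cond[, cols] <- mu_cond[, cols[1]]
      }
    }
    # scale transcript abundance to expected library size
    read_rate <- sweep(mu_cond, 1, lens / mean(lens), "*")
    read_rate <- sweep(read_rate, 2, colSums(read_rate), "/") * cfg$lib_size
    counts <- matrix(rnbinom(length(read_rate), mu = read_rate,
                             size = 1 / cfg$dispersion),
                     nrow = nrow(read_rate), dimnames = dimnames(read_rate))
    counts[read_rate == 0] <- 0L
    rate <- sweep(counts, 1, lens, "/")
    tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
    out[[sp]] <- list(
      counts = expression_matrix(counts, meta, "counts"),
      tpm = expression_matrix(tpm, meta, "tpm"))
  }
  out$truth <- list(de_genes = names(is_de)[is_de], shapes = shape,
                    expr_specific = on_only[!is.na(on_only)],
                    testis_biased = names(testis_bias)[testis_bias],
                    base = base_fam)
  out
}

#' Simulate a per-base conservation track
#'
#' Baseline score everywhere; exons, promoters (400 bp) and splice sites of
#' genes flagged `conserved` in the ground truth get the configured boosts.
#' The emitted track covers every base of each chromosome exactly once.
#'
#' @param cfg a [sim_config()].
#' @param sim result of [simulate_genomes()].
#' @param species which species' genome to score (default sp1).
#' @return a `conservation_track`.
#' @export
simulate_conservation <- function(cfg, sim, species = "sp1") {
  fam <- sim$truth$families
  ann <- sim$species[[species]]$ann
  genome <- sim$species[[species]]$genome
  gcol <- paste0(species, "_gene")
  conserved_genes <- fam[[gcol]][fam$conserved & !is.na(fam[[gcol]])]
  rows <- list()
  for (gid in conserved_genes) {
    g <- ann$genes[[gid]]
    eb <- exon_blocks(g); eb$score <- cfg$cons_baseline + cfg$cons_exon
    pr <- promoter_region(g, 400)
    pr$score <- cfg$cons_baseline + cfg$cons_promoter
    ss <- do.call(rbind, lapply(g$transcripts, splice_sites))
    rows[[length(rows) + 1L]] <- eb[, c("chrom", "start", "end", "score")]
    if (nrow(pr) && pr$end > pr$start)
      rows[[length(rows) + 1L]] <- pr[, c("chrom", "start", "end", "score")]
    if (!is.null(ss) && nrow(ss)) {
      ss$score <- cfg$cons_baseline + cfg$cons_splice
      rows[[length(rows) + 1L]] <- ss[, c("chrom", "start", "end", "score")]
    }
  }
  boosted <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               score = numeric(0))
  pieces <- list()
  for (ch in names(genome)) {
    L <- Biostrings::width(genome[ch])
    b <- boosted[boosted$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    pos <- 0
    for (i in seq_len(nrow(b))) {
      if (b$start[i] > pos)
        pieces[[length(pieces) + 1L]] <- data.frame(
          chrom = ch, start = pos, end = b$start[i],
          score = cfg$cons_baseline)
      pieces[[length(pieces) + 1L]] <- b[i, ]
      pos <- b$end[i]
    }
    if (pos < L)
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = ch, start = pos, end = L, score = cfg$cons_baseline)
  }
  conservation_track(do.call(rbind, pieces))
}

#' Simulate aligned training pairs for the CSF model
#'
#' Coding pairs evolve under a frame-preserving codon model biased toward
#' synonymous substitutions and never introducing in-frame stops; noncoding
#' pairs evolve under uniform nucleotide substitution at a matched per-base
#' rate.
#'
#' @param cfg a [sim_config()].
#' @param n_pairs pairs per class.
#' @param len_codons codons per coding sequence (nucleotide length is
#'   3 x this for both classes).
#' @param codon_sub_rate per-codon substitution probability (coding).
#' @param syn_frac fraction of codon substitutions that are synonymous.
#' @param nt_rate per-base substitution probability (noncoding).
#' @return list: `coding`, `noncoding` — lists of aligned pairs
#'   (length-2 character vectors).
#' @export
simulate_csf_training <- function(cfg, n_pairs = 150, len_codons = 100,
                                  codon_sub_rate = 0.3, syn_frac = 0.75,
                                  nt_rate = 0.2) {
  set.seed(cfg$seed + 2L)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  syn_of <- lapply(setNames(sense, sense), function(cd)
    setdiff(names(code)[code == code[[cd]]], cd))
  coding <- lapply(seq_len(n_pairs), function(i) {
    ref <- sample(sense, len_codons, replace = TRUE)
    alt <- vapply(ref, function(cd) {
      if (runif(1) >= codon_sub_rate) return(cd)
      syn <- syn_of[[cd]]
      if (length(syn) > 0 && runif(1) < syn_frac) sample(syn, 1)
      else {
        nonsyn <- setdiff(sense, c(cd, syn))
        sample(nonsyn, 1)
      }
    }, "")
    c(paste(ref, collapse = ""), paste(alt, collapse = ""))
  })
  noncoding <- lapply(seq_len(n_pairs), function(i) {
    ref <- random_dna(3L * len_codons)
    c(ref, mutate_dna(ref, nt_rate))
  })
  list(coding = coding, noncoding = noncoding)
}

#' Write a simulation to disk in standard formats
#'
#' Emits per-species FASTA and GTF, both chain files, a bedGraph conservation
#' track, count/TPM/metadata TSVs, and the ground-truth tables.
#'
#' @param sim result of [simulate_genomes()].
#' @param dir output directory (created).
#' @param expr optional [simulate_expression()] result.
#' @param track optional `conservation_track`.
#' @export
write_simulation <- function(sim, dir, expr = NULL, track = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(sim$species)) {
    Biostrings::writeXStringSet(sim$species[[sp]]$genome,
                                file.path(dir, paste0(sp, ".fa")))
    write_gtf(sim$species[[sp]]$ann, file.path(dir, paste0(sp, ".gtf")))
  }
  write_chain(sim$chains$ab, file.path(dir, "sp1_to_sp2.chain"))
  write_chain(sim$chains$ba, file.path(dir, "sp2_to_sp1.chain"))
  if (!is.null(track)) write_bedgraph(track, file.path(dir,
                                                       "conservation.bedGraph"))
  if (!is.null(expr)) {
    for (sp in c("sp1", "sp2")) {
      write_expression_tsv(expr[[sp]]$counts,
                           file.path(dir, paste0(sp, "_counts.tsv")),
                           file.path(dir, paste0(sp, "_meta.tsv")))
      write_expression_tsv(expr[[sp]]$tpm,
                           file.path(dir, paste0(sp, "_tpm.tsv")),
                           file.path(dir, paste0(sp, "_meta.tsv")))
    }
  }
  write.table(sim$truth$families, file.path(dir, "truth_families.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$one2one, file.path(dir, "truth_one2one.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Deterministic fixture planting exactly one violation per lncRNA filter
#'
#' Builds a small annotation with clean candidate loci plus one gene per
#' filter violating exactly that filter: a 480 bp monoexonic locus (length),
#' a locus 4.9 kb from a same-strand protein-coding gene (distance), 6\%
#' unmappable overlap, 55\% retrogene overlap, 30\% RNA-repeat overlap, a
#' tRNA overlap, 9 supporting reads, a sense/antisense ratio below 1\% in
#' every sample, an unsupported splice junction, a full-vs-nonoverlap
#' Spearman rho of ~0.886, and a locus flagged protein-coding.
#'
#' @return list: `ann`, `locus_evidence`, `region_sets`, `coding_flags`,
#'   `planted` (named vector gene id -> violated filter), `candidates`.
#' @export
simulate_filter_fixture <- function() {
  mk <- function(gid, exon_starts, exon_lens, strand = "+",
                 biotype = "novel", source = "novel") {
    tx <- transcript_model(paste0(gid, ".t1"), gid, "chr1", strand,
                           data.frame(start = exon_starts,
                                      end = exon_starts + exon_lens),
                           biotype = biotype)
    gene_model(gid, list(tx), biotype = biotype, source = source)
  }
  genes <- list(
    # reference protein-coding anchor for the distance filter
    mk("pc1", c(100000, 101000, 102000), c(300, 300, 300),
       biotype = "protein_coding", source = "reference"),
    # clean candidates (multi- and monoexonic)
    mk("clean1", c(10000, 10500), c(150, 150)),
    mk("clean2", 20000, 700),
    mk("clean3", c(30000, 30600, 31200), c(120, 120, 120)),
    # planted violations
    mk("v_len", 40000, 480),
    mk("v_unmap", 50000, 1000),
    mk("v_retro", 60000, 1000),
    mk("v_repeat", 70000, 1000),
    mk("v_trna", 80000, 1000),
    mk("v_dist", c(93000, 94990), c(110, 110)),
    mk("v_reads", 110000, 600),
    mk("v_saratio", 120000, 600),
    mk("v_junction", c(130000, 130600), c(150, 150)),
    mk("v_conc", 140000, 600),
    mk("v_coding", 150000, 600),
    # reference noncoding gene (novel-only filters NA)
    mk("rl1", c(160000, 160600), c(150, 150), biotype = "lincRNA",
       source = "reference"))
  ann <- annotation_set(genes)
  cand <- setdiff(names(ann$genes), "pc1")
  n <- length(cand)
  ev <- data.frame(gene_id = cand, stringsAsFactors = FALSE)
  ev$unique_reads_total <- ifelse(cand == "v_reads", 9L, 50L)
  ev$sa_ratio_per_sample <- lapply(cand, function(g)
    if (g == "v_saratio") rep(0.005, 6) else c(0.5, rep(0.002, 5)))
  ev$junctions_supported <- ifelse(cand == "v_junction", FALSE, TRUE)
  ev$has_antisense_overlap <- cand == "v_conc"
  ev$full_tpm <- lapply(cand, function(g) as.numeric(1:6))
  # rank permutation with Spearman rho = 1 - 24/210 ~ 0.886 (< 0.9)
  ev$nonoverlap_tpm <- lapply(cand, function(g)
    if (g == "v_conc") c(2, 1, 4, 3, 5, 6) else as.numeric(1:6))
  coding_flags <- setNames(rep("candidate_noncoding", n), cand)
  coding_flags["v_coding"] <- "protein_coding"
  region_sets <- list(
    unmappable = data.frame(chrom = "chr1", start = 50000, end = 50060),
    retrogenes = data.frame(chrom = "chr1", start = 60000, end = 60550),
    trna = data.frame(chrom = "chr1", start = 80100, end = 80200),
    rna_repeats = data.frame(chrom = "chr1", start = 70000, end = 70300))
  planted <- c(v_len = "exonic_length", v_unmap = "unmappable",
               v_retro = "retrogene", v_repeat = "rna_repeat",
               v_trna = "trna", v_dist = "intergenic",
               v_reads = "min_reads", v_saratio = "sense_antisense",
               v_junction = "junction_support",
               v_conc = "antisense_concordance", v_coding = "noncoding")
  list(ann = ann, locus_evidence = ev, region_sets = region_sets,
       coding_flags = coding_flags, planted = planted, candidates = cand)
}
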