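# Chain-guided homology prediction: exon-block projection with liftOver-like
# statuses, size-ratio filtering, consensus/collinearity resolution,
# single-link candidate clustering, exonic alignment statistics, best hits
# with an identity-ratio ambiguity guard, and reciprocal-best-hit 1-to-1
# orthologs.

#' Size-ratio bounds per species pair
#'
#' @param pair `"rodent"` (0.33-3) or `"chicken"` (0.2-5).
#' @return numeric length-2 vector `c(low, high)`.
#' @export
size_bounds <- function(pair = c("rodent", "chicken")) {
  switch(match.arg(pair), rodent = c(0.33, 3), chicken = c(0.2, 5))
}

# forward-strand mapping of ref subinterval [a,b) through one chain block
map_through_block <- function(a, b, blk, tgt_strand) {
  if (tgt_strand == "+") {
    c(blk$tgt_start + (a - blk$ref_start), blk$tgt_start + (b - blk$ref_start))
  } else {
    c(blk$tgt_start + (blk$ref_end - b), blk$tgt_start + (blk$ref_end - a))
  }
}

# bases of [s,e) covered by a chain's ref blocks
chain_coverage <- function(ch, chrom, s, e) {
  if (ch$ref_chrom != chrom) return(0)
  interval_overlap_len(s, e, ch$blocks$ref_start, ch$blocks$ref_end)
}

#' Project one interval through a chain map
#'
#' Projects via the highest-scoring chain covering at least `min_remap` of
#' the interval's bases. Status is `ambiguous` when two or more qualifying
#' chains reach distinct target loci (different chromosome, or more than
#' `locus_gap` apart), `split` when no single chain qualifies but chains on
#' distinct loci jointly cover `min_remap`, and `unmapped` otherwise.
#'
#' @param interval one-row interval data.frame.
#' @param chainmap a [chain_map()].
#' @param min_remap minimum fraction of reference bases remapped (default 0.10).
#' @param locus_gap distance beyond which same-chromosome projections count
#'   as distinct loci (default 1 Mb).
#' @return object of class `block_projection`: `ref_block`,
#'   `target_intervals`, `fraction_remapped`, `status`, plus chain
#'   descriptors for successful projections.
#' @export
project_interval <- function(interval, chainmap, min_remap = 0.10,
                             locus_gap = 1e6) {
  s <- interval$start; e <- interval$end; chrom <- interval$chrom
  len <- e - s
  proj <- structure(list(ref_block = interval,
                         target_intervals = NULL, fraction_remapped = 0,
                         status = "unmapped", chain_id = NA_character_,
                         tgt_chrom = NA_character_,
                         tgt_strand = NA_character_, chain_score = NA_real_),
                    class = "block_projection")
  cov <- vapply(chainmap$chains, chain_coverage, 0, chrom = chrom, s = s,
                e = e)
  if (all(cov == 0)) return(proj)
  project_via <- function(ch) {
    b <- ch$blocks
    hit <- b[b$ref_end > s & b$ref_start < e, , drop = FALSE]
    ti <- t(vapply(seq_len(nrow(hit)), function(j) {
      a2 <- max(s, hit$ref_start[j]); b2 <- min(e, hit$ref_end[j])
      map_through_block(a2, b2, hit[j, ], ch$tgt_strand)
    }, numeric(2)))
    df <- data.frame(chrom = ch$tgt_chrom, start = ti[, 1], end = ti[, 2],
                     strand = ch$tgt_strand, stringsAsFactors = FALSE)
    df[order(df$start), , drop = FALSE]
  }
  # locus descriptor of each covering chain: (chrom, midpoint of projection)
  covering <- which(cov > 0)
  locus <- lapply(covering, function(i) {
    ti <- project_via(chainmap$chains[[i]])
    c(chrom = chainmap$chains[[i]]$tgt_chrom,
      mid = mean(c(min(ti$start), max(ti$end))))
  })
  distinct_loci <- function(idx) {
    # count groups of chains whose projections are on distinct loci
    if (length(idx) <= 1L) return(length(idx))
    grp <- seq_along(idx)
    for (i in seq_along(idx)) for (j in seq_along(idx)) {
      if (i >= j) next
      li <- locus[[match(idx[i], covering)]]
      lj <- locus[[match(idx[j], covering)]]
      same <- li["chrom"] == lj["chrom"] &&
        abs(as.numeric(li["mid"]) - as.numeric(lj["mid"])) <= locus_gap
      if (same) grp[grp == grp[j]] <- grp[i]
    }
    length(unique(grp))
  }
  qual <- which(cov / len >= min_remap)
  if (length(qual) >= 1L) {
    if (distinct_loci(qual) >= 2L) {
      proj$status <- "ambiguous"
      proj$fraction_remapped <- max(cov) / len
      return(proj)
    }
    best <- qual[which.max(vapply(chainmap$chains[qual], `[[`, 0, "score"))]
    ch <- chainmap$chains[[best]]
    proj$target_intervals <- project_via(ch)
    proj$fraction_remapped <- cov[best] / len
    proj$status <- "ok"
    proj$chain_id <- ch$id
    proj$tgt_chrom <- ch$tgt_chrom
    proj$tgt_strand <- ch$tgt_strand
    proj$chain_score <- ch$score
    return(proj)
  }
  if (sum(cov) / len >= min_remap && distinct_loci(covering) >= 2L) {
    proj$status <- "split"
    proj$fraction_remapped <- sum(cov) / len
    return(proj)
  }
  proj$fraction_remapped <- max(cov) / len
  proj
}

#' Filter a projection by target/reference size ratio
#'
#' @param projection a `block_projection` with status `ok`.
#' @param bounds length-2 vector from [size_bounds()].
#' @return the projection, with status set to `size_fail` when the span ratio
#'   falls outside `[bounds[1], bounds[2]]`.
#' @export
size_ratio_filter <- function(projection, bounds = size_bounds("rodent")) {
  if (projection$status != "ok") return(projection)
  ti <- projection$target_intervals
  ref_span <- projection$ref_block$end - projection$ref_block$start
  tgt_span <- max(ti$end) - min(ti$start)
  ratio <- tgt_span / ref_span
  if (ratio < bounds[1] || ratio > bounds[2]) projection$status <- "size_fail"
  projection$size_ratio <- ratio
  projection
}

is_monotone <- function(x) all(diff(x) > 0)

#' Resolve a gene's block projections into a gene projection
#'
#' Defines the consensus target chromosome and strand as the one carrying the
#' majority of projected bases, drops blocks that do not match it, then checks
#' that the surviving blocks are collinear (target midpoints monotone in
#' reference order, orientation-corrected for minus-strand chains). A single
#' offending block is dropped; two or more eliminate the gene
#' (`order_fail`). Ties in the consensus vote discard the gene.
#'
#' @param block_projections list of `block_projection` objects in reference
#'   order (ascending genomic start).
#' @param gene_id optional id carried through.
#' @return object of class `gene_projection` with `status`
#'   (`projected`/`discarded`), `reason`, surviving `blocks`,
#'   `consensus_chrom`, `consensus_strand`, and `dropped` block indices.
#' @export
resolve_gene_projection <- function(block_projections, gene_id = NA) {
  gp <- structure(list(gene_id = gene_id, blocks = list(),
                       consensus_chrom = NA, consensus_strand = NA,
                       status = "discarded", reason = NA_character_,
                       dropped = integer(0)),
                  class = "gene_projection")
  ok <- vapply(block_projections, function(p) p$status == "ok", TRUE)
  if (!any(ok)) { gp$reason <- "no_projected_blocks"; return(gp) }
  idx <- which(ok)
  key <- vapply(block_projections[idx], function(p)
    paste(p$tgt_chrom, p$tgt_strand), "")
  bases <- vapply(block_projections[idx], function(p)
    sum(p$target_intervals$end - p$target_intervals$start), 0)
  vote <- tapply(bases, key, sum)
  top <- names(vote)[vote == max(vote)]
  if (length(top) > 1L) { gp$reason <- "consensus_tie"; return(gp) }
  match_consensus <- key == top
  gp$dropped <- idx[!match_consensus]
  idx <- idx[match_consensus]
  parts <- strsplit(top, " ")[[1]]
  gp$consensus_chrom <- parts[1]; gp$consensus_strand <- parts[2]
  mids <- vapply(block_projections[idx], function(p)
    mean(c(min(p$target_intervals$start), max(p$target_intervals$end))), 0)
  if (gp$consensus_strand == "-") mids <- -mids
  if (!is_monotone(mids)) {
    fix <- which(vapply(seq_along(mids), function(i)
      is_monotone(mids[-i]), TRUE))
    if (length(fix) == 0L) {
      gp$reason <- "order_fail"
      return(gp)
    }
    gp$dropped <- c(gp$dropped, idx[fix[1]])
    idx <- idx[-fix[1]]
  }
  gp$blocks <- block_projections[idx]
  gp$status <- "projected"
  gp
}

#' Project a gene's exon blocks into a target genome
#'
#' @param gene a [gene_model()].
#' @param chainmap a [chain_map()].
#' @param bounds size-ratio bounds ([size_bounds()]).
#' @param min_remap minimum remapped fraction per block.
#' @return a `gene_projection`; carries `target_strand`, the projected gene
#'   strand (reference strand composed with chain orientation).
#' @export
project_gene <- function(gene, chainmap, bounds = size_bounds("rodent"),
                         min_remap = 0.10) {
  blocks <- exon_blocks(gene)
  projs <- lapply(seq_len(nrow(blocks)), function(i) {
    size_ratio_filter(project_interval(blocks[i, ], chainmap, min_remap),
                      bounds)
  })
  gp <- resolve_gene_projection(projs, gene_id = gene$id)
  if (gp$status == "projected") {
    flip <- gp$consensus_strand == "-"
    gp$target_strand <- if (flip) setdiff(c("+", "-"), gene$strand)
      else gene$strand
  }
  gp$block_statuses <- vapply(projs, `[[`, "", "status")
  gp
}

# minimal union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) { while (parent[i] != i) i <- parent[i]; i }
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

#' Single-link clustering of projected genes and target annotations
#'
#' Builds the bipartite overlap graph between projected exon blocks and
#' target gene exon blocks (>= 1 bp overlap, strand-aware on the projected
#' gene strand) and decomposes it into connected components.
#'
#' @param gene_projections named list of `gene_projection` objects
#'   (status `projected`).
#' @param target_ann target [annotation_set()].
#' @return list of clusters, each `list(ref_genes, target_genes)`.
#' @export
cluster_candidates <- function(gene_projections, target_ann) {
  gene_projections <- Filter(function(gp) gp$status == "projected",
                             gene_projections)
  if (length(gene_projections) == 0L) return(list())
  tgt_blocks <- lapply(target_ann$genes, exon_blocks)
  ref_ids <- names(gene_projections)
  tgt_ids <- names(target_ann$genes)
  n <- length(ref_ids) + length(tgt_ids)
  parent <- uf_new(n)
  edge_any <- rep(FALSE, n)
  for (i in seq_along(ref_ids)) {
    gp <- gene_projections[[i]]
    pi_df <- do.call(rbind, lapply(gp$blocks, `[[`, "target_intervals"))
    for (j in seq_along(tgt_ids)) {
      tb <- tgt_blocks[[j]]
      tg <- target_ann$genes[[tgt_ids[j]]]
      if (tg$chrom != gp$consensus_chrom) next
      if (!is.null(gp$target_strand) && tg$strand != gp$target_strand) next
      ov <- sum(vapply(seq_len(nrow(pi_df)), function(k)
        interval_overlap_len(pi_df$start[k], pi_df$end[k], tb$start, tb$end),
        0))
      if (ov >= 1) {
        parent <- uf_union(parent, i, length(ref_ids) + j)
        edge_any[i] <- TRUE; edge_any[length(ref_ids) + j] <- TRUE
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), 0L)
  comps <- split(seq_len(n), roots)
  comps <- Filter(function(ix) any(edge_any[ix]), comps)
  lapply(unname(comps), function(ix) {
    list(ref_genes = ref_ids[ix[ix <= length(ref_ids)]],
         target_genes = tgt_ids[ix[ix > length(ref_ids)] - length(ref_ids)])
  })
}

#' Default pairwise global aligner
#'
#' Affine-gap Needleman-Wunsch via Biostrings, returning the two aligned
#' strings. Any function with this signature can be plugged into
#' [alignment_stats()].
#'
#' @param ref,tgt character scalars (DNA).
#' @return list with `pattern` and `subject` aligned strings.
#' @export
default_aligner <- function(ref, tgt) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref), Biostrings::DNAString(tgt),
    type = "global", substitutionMatrix = sm,
    gapOpening = 5, gapExtension = 2)
  list(pattern = as.character(Biostrings::alignedPattern(aln)),
       subject = as.character(Biostrings::alignedSubject(aln)))
}

#' Exonic alignment statistics for a candidate gene pair
#'
#' Globally aligns the two exonic sequences and reports the percentage of
#' reference exonic bases in gapless aligned columns and the percentage of
#' identical bases, both relative to the reference exonic length.
#'
#' @param ref_seq,tgt_seq exonic sequences (characters).
#' @param aligner pairwise global aligner (default [default_aligner()]).
#' @return list `pct_aligned_ungapped`, `pct_identity`.
#' @export
alignment_stats <- function(ref_seq, tgt_seq, aligner = default_aligner) {
  if (nchar(ref_seq) == 0L || nchar(tgt_seq) == 0L)
    stop("empty sequence in alignment_stats")
  aln <- aligner(ref_seq, tgt_seq)
  a <- strsplit(aln$pattern, "")[[1]]
  b <- strsplit(aln$subject, "")[[1]]
  gapless <- a != "-" & b != "-"
  ident <- gapless & a == b
  L <- nchar(ref_seq)
  list(pct_aligned_ungapped = 100 * sum(gapless) / L,
       pct_identity = 100 * sum(ident) / L)
}

#' Best target hit for a reference gene
#'
#' The candidate with the highest percent identity, required to exceed the
#' second-best by a ratio > `ratio_threshold`; otherwise no hit is called.
#'
#' @param candidates data.frame with `target_gene`, `pct_identity`.
#' @param ratio_threshold best/second-best identity ratio (default 1.1,
#'   strict).
#' @return target gene id, or `NA_character_` when ambiguous or empty.
#' @export
best_hit <- function(candidates, ratio_threshold = 1.1) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NA_character_)
  o <- order(-candidates$pct_identity)
  best <- candidates[o[1], ]
  if (best$pct_identity <= 0) return(NA_character_)
  if (nrow(candidates) == 1L) return(best$target_gene)
  second <- candidates$pct_identity[o[2]]
  ratio <- if (second == 0) Inf else best$pct_identity / second
  if (ratio > ratio_threshold) best$target_gene else NA_character_
}

#' Reciprocal best hits
#'
#' @param bh_ab named character vector: best target gene per reference gene.
#' @param bh_ba named character vector for the opposite direction.
#' @return data.frame `ref_gene`, `target_gene` — a partial bijection.
#' @export
reciprocal_best_hits <- function(bh_ab, bh_ba) {
  out <- data.frame(ref_gene = character(0), target_gene = character(0),
                    stringsAsFactors = FALSE)
  for (a in names(bh_ab)) {
    b <- bh_ab[[a]]
    if (is.na(b)) next
    back <- bh_ba[[b]]
    if (!is.null(back) && !is.na(back) && back == a)
      out <- rbind(out, data.frame(ref_gene = a, target_gene = b,
                                   stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Homologous gene families across species
#'
#' Single-link clustering of genes over reciprocal-best-hit edges from
#' pairwise species comparisons; components with more than one gene from any
#' species are discarded.
#'
#' @param rbh_tables list of data.frames with `ref_gene`, `target_gene`,
#'   `ref_species`, `target_species`.
#' @return list of family data.frames (`species`, `gene`).
#' @export
three_species_families <- function(rbh_tables) {
  edges <- do.call(rbind, lapply(rbh_tables, function(t)
    data.frame(a = paste0(t$ref_species, ":", t$ref_gene),
               b = paste0(t$target_species, ":", t$target_gene),
               stringsAsFactors = FALSE)))
  nodes <- unique(c(edges$a, edges$b))
  parent <- uf_new(length(nodes))
  for (i in seq_len(nrow(edges))) {
    parent <- uf_union(parent, match(edges$a[i], nodes),
                       match(edges$b[i], nodes))
  }
  roots <- vapply(seq_along(nodes), function(i) uf_find(parent, i), 0L)
  comps <- split(nodes, roots)
  fams <- lapply(unname(comps), function(nd) {
    sp <- sub(":.*", "", nd); gn <- sub("^[^:]*:", "", nd)
    data.frame(species = sp, gene = gn, stringsAsFactors = FALSE)
  })
  Filter(function(f) !anyDuplicated(f$species), fams)
}

#' Sequence-conservation class of a reference gene
#'
#' Ordered classes: `unprojected` < `projected` < `projected_transcribed`
#' (>= `min_reads` unique reads over the projected locus) < `ortholog`
#' (1-to-1 reciprocal best hit) < `ortholog_same_class` (partner shares the
#' gene class). Each gene is assigned the highest class it satisfies.
#'
#' @param projected logical: projection resolved.
#' @param target_reads unique reads over the projected region.
#' @param has_rbh logical: 1-to-1 ortholog assigned.
#' @param same_class logical: ortholog partner has the same gene class.
#' @param min_reads transcription-detection threshold (default 10).
#' @return character vector of classes.
#' @export
conservation_class <- function(projected, target_reads, has_rbh, same_class,
                               min_reads = 10) {
  n <- length(projected)
  out <- rep("unprojected", n)
  out[projected] <- "projected"
  out[projected & !is.na(target_reads) & target_reads >= min_reads] <-
    "projected_transcribed"
  out[projected & has_rbh %in% TRUE] <- "ortholog"
  out[projected & has_rbh %in% TRUE & same_class %in% TRUE] <-
    "ortholog_same_class"
  out
}

# concatenated exon-block sequence of a gene (5'->3')
gene_exonic_sequence <- function(gene, genome) {
  blocks <- exon_blocks(gene)
  seqs <- vapply(seq_len(nrow(blocks)), function(i)
    as.character(Biostrings::subseq(genome[[gene$chrom]],
                                    start = blocks$start[i] + 1L,
                                    end = blocks$end[i])), "")
  s <- paste(seqs, collapse = "")
  if (gene$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' One-directional homology prediction
#'
#' Runs projection, clustering, exonic alignment and best-hit extraction for
#' every reference gene (optionally a subset).
#'
#' @param ref_ann,target_ann annotation sets.
#' @param chainmap [chain_map()] from reference to target genome.
#' @param ref_genome,target_genome named `DNAStringSet`s.
#' @param bounds size-ratio bounds.
#' @param min_remap minimum remapped fraction per exon block.
#' @param gene_ids reference genes to process (default all).
#' @param ratio_threshold best-hit identity-ratio guard.
#' @return list: `projections`, `clusters`, `stats` (per candidate pair),
#'   `best_hits` (named vector).
#' @export
predict_homologs <- function(ref_ann, target_ann, chainmap, ref_genome,
                             target_genome, bounds = size_bounds("rodent"),
                             min_remap = 0.10, gene_ids = NULL,
                             ratio_threshold = 1.1) {
  genes <- if (is.null(gene_ids)) ref_ann$genes else ref_ann$genes[gene_ids]
  projections <- lapply(genes, project_gene, chainmap = chainmap,
                        bounds = bounds, min_remap = min_remap)
  names(projections) <- names(genes)
  clusters <- cluster_candidates(projections, target_ann)
  stats <- list()
  for (cl in clusters) {
    for (rg in cl$ref_genes) {
      rseq <- gene_exonic_sequence(ref_ann$genes[[rg]], ref_genome)
      for (tg in cl$target_genes) {
        tseq <- gene_exonic_sequence(target_ann$genes[[tg]], target_genome)
        st <- alignment_stats(rseq, tseq)
        stats[[length(stats) + 1L]] <- data.frame(
          ref_gene = rg, target_gene = tg,
          pct_aligned_ungapped = st$pct_aligned_ungapped,
          pct_identity = st$pct_identity, stringsAsFactors = FALSE)
      }
    }
  }
  stats <- if (length(stats)) do.call(rbind, stats) else
    data.frame(ref_gene = character(0), target_gene = character(0),
               pct_aligned_ungapped = numeric(0), pct_identity = numeric(0))
  bh <- vapply(names(genes), function(rg)
    best_hit(stats[stats$ref_gene == rg, , drop = FALSE], ratio_threshold),
    "")
  list(projections = projections, clusters = clusters, stats = stats,
       best_hits = bh)
}

#' Predict 1-to-1 orthologous loci between two species
#'
#' Runs [predict_homologs()] in both directions and intersects the best hits
#' into reciprocal best hits.
#'
#' @param ann_a,ann_b annotation sets for the two species.
#' @param chain_ab chain map from species A to species B (the B-to-A map is
#'   derived with [invert_chain_map()] unless given).
#' @param genome_a,genome_b named `DNAStringSet`s.
#' @param chain_ba optional chain map for the reverse direction.
#' @inheritParams predict_homologs
#' @return list: per-direction results `ab`, `ba`, and `rbh` data.frame.
#' @export
predict_orthologs <- function(ann_a, ann_b, chain_ab, genome_a, genome_b,
                              chain_ba = NULL,
                              bounds = size_bounds("rodent"),
                              min_remap = 0.10, ratio_threshold = 1.1) {
  if (is.null(chain_ba)) chain_ba <- invert_chain_map(chain_ab)
  ab <- predict_homologs(ann_a, ann_b, chain_ab, genome_a, genome_b,
                         bounds, min_remap, ratio_threshold = ratio_threshold)
  ba <- predict_homologs(ann_b, ann_a, chain_ba, genome_b, genome_a,
                         bounds, min_remap, ratio_threshold = ratio_threshold)
  rbh <- reciprocal_best_hits(ab$best_hits, ba$best_hits)
  list(ab = ab, ba = ba, rbh = rbh)
}
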