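# Post-assembly transcript filters and the lncRNA locus selection cascade.
# Every candidate gene receives a pass/fail/NA outcome for each filter; a
# locus is called lncRNA only when all applicable filters pass.

# Ensembl noncoding biotypes eligible for the lncRNA set
NONCODING_BIOTYPES <- c("lincRNA", "processed_transcript", "antisense", "TEC",
                        "macro_lncRNA", "bidirectional_promoter_lncRNA",
                        "sense_intronic")

# same-strand exonic overlap: gene ids of `ann` genes whose exons overlap the
# given exon set; strand-aware unless strand = "*"
overlapping_genes <- function(exons_df, ann, stranded = TRUE,
                              restrict_ids = NULL, multiexonic_only = FALSE) {
  ref <- exon_table(ann)
  if (!is.null(restrict_ids)) ref <- ref[ref$gene_id %in% restrict_ids, ,
                                         drop = FALSE]
  if (multiexonic_only) {
    nex <- vapply(ann$genes, function(g)
      max(vapply(g$transcripts, function(tx) nrow(tx$exons), 0L)), 0L)
    multi <- names(ann$genes)[nex >= 2L]
    ref <- ref[ref$gene_id %in% multi, , drop = FALSE]
  }
  if (nrow(ref) == 0L || nrow(exons_df) == 0L) return(character(0))
  q <- intervals_to_granges(exons_df)
  s <- intervals_to_granges(ref)
  hits <- GenomicRanges::findOverlaps(q, s,
    ignore.strand = !stranded)
  unique(ref$gene_id[S4Vectors::subjectHits(hits)])
}

#' Filter assembled transcripts against reference annotation and read evidence
#'
#' Removes (a) read-through transcripts whose exons overlap exons of two or
#' more multiexonic reference genes, (b) transcripts whose sense/antisense
#' unique-read ratio is below 0.01, and (c) multiexonic transcripts with any
#' intron lacking correct-strand splice-junction support. Transcripts with
#' missing evidence fail with an NA flag.
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param reference_ann reference [annotation_set()].
#' @param evidence data.frame with `transcript_id`, `sense_unique_reads`,
#'   `antisense_unique_reads`, and list-column `junction_supported` (logical
#'   vector per transcript, one entry per intron).
#' @return list with `kept` (transcript list) and `audit` (data.frame).
#' @export
filter_assembled_transcripts <- function(transcripts, reference_ann,
                                         evidence) {
  res <- lapply(transcripts, function(tx) {
    exdf <- genomic_intervals(tx$chrom, tx$exons$start, tx$exons$end,
                              tx$strand)
    ov <- overlapping_genes(exdf, reference_ann, stranded = TRUE,
                            multiexonic_only = TRUE)
    readthrough <- if (length(ov) >= 2L) "fail" else "pass"
    i <- match(tx$id, evidence$transcript_id)
    if (is.na(i)) {
      warning("no evidence for transcript ", tx$id, "; failing with NA")
      return(data.frame(transcript_id = tx$id, readthrough = readthrough,
                        antisense_ratio = NA, junction_support = NA,
                        kept = FALSE, stringsAsFactors = FALSE))
    }
    sense <- evidence$sense_unique_reads[i]
    anti <- evidence$antisense_unique_reads[i]
    ratio <- if (anti == 0) Inf else sense / anti
    ratio_flag <- if (ratio < 0.01) "fail" else "pass"
    n_introns <- nrow(tx$exons) - 1L
    if (n_introns >= 1L) {
      sup <- evidence$junction_supported[[i]]
      junc_flag <- if (length(sup) == n_introns && all(sup)) "pass" else "fail"
    } else junc_flag <- NA_character_
    kept <- readthrough == "pass" && ratio_flag == "pass" &&
      (is.na(junc_flag) || junc_flag == "pass")
    data.frame(transcript_id = tx$id, readthrough = readthrough,
               antisense_ratio = ratio_flag, junction_support = junc_flag,
               kept = kept, stringsAsFactors = FALSE)
  })
  audit <- do.call(rbind, res)
  rownames(audit) <- NULL
  list(kept = transcripts[audit$kept], audit = audit)
}

#' Merge novel transcripts into a reference annotation
#'
#' Novel transcripts with no same-strand exonic overlap with reference genes
#' found new loci (grouped by their own gene ids); transcripts overlapping
#' exactly one reference gene become isoforms of it; transcripts overlapping
#' two or more reference genes are discarded as potential read-throughs.
#'
#' @param novel_ann [annotation_set()] of novel genes.
#' @param reference_ann reference [annotation_set()].
#' @return merged [annotation_set()]; novel genes carry `source = "novel"`.
#' @export
merge_with_reference <- function(novel_ann, reference_ann) {
  genes <- reference_ann$genes
  new_loci <- list()
  for (g in novel_ann$genes) {
    for (tx in g$transcripts) {
      exdf <- genomic_intervals(tx$chrom, tx$exons$start, tx$exons$end,
                                tx$strand)
      ov <- overlapping_genes(exdf, reference_ann, stranded = TRUE)
      if (length(ov) == 0L) {
        if (is.null(new_loci[[g$id]])) new_loci[[g$id]] <- list()
        new_loci[[g$id]][[tx$id]] <- tx
      } else if (length(ov) == 1L) {
        host <- genes[[ov]]
        if (host$chrom == tx$chrom && host$strand == tx$strand) {
          tx$gene_id <- host$id
          host$transcripts[[tx$id]] <- tx
          genes[[ov]] <- host
        }
      } # >= 2 reference genes: discarded
    }
  }
  for (gid in names(new_loci)) {
    txs <- unname(new_loci[[gid]])
    genes[[gid]] <- gene_model(gid, txs, biotype = "novel",
                               gene_class = "other", source = "novel")
  }
  annotation_set(unname(genes))
}

#' Spearman concordance between full and non-overlapping expression estimates
#'
#' For loci with sense/antisense exonic overlap with other genes, expression
#' is estimated both on the complete annotation and on exonic regions free of
#' overlap; a low rank correlation between the two across samples indicates
#' contamination from the overlapping gene.
#'
#' @param full_tpm,nonoverlap_tpm numeric vectors over the same samples
#'   (length >= 3).
#' @return Spearman's rho, or NA when either vector has zero variance.
#' @export
antisense_concordance <- function(full_tpm, nonoverlap_tpm) {
  stopifnot(length(full_tpm) == length(nonoverlap_tpm),
            length(full_tpm) >= 3L)
  if (sd(full_tpm) == 0 || sd(nonoverlap_tpm) == 0) return(NA_real_)
  cor(full_tpm, nonoverlap_tpm, method = "spearman")
}

#' lncRNA locus selection cascade
#'
#' Applies the full filter set to candidate noncoding loci and records a
#' per-filter audit. Reference genes qualify via their noncoding biotype;
#' novel genes must be classified noncoding by both coding-potential
#' criteria. Novel-gene-only filters (exonic length, unmappable overlap,
#' intergenic distance, junction support) are NA for reference genes, as is
#' the antisense-concordance filter for loci without sense/antisense overlap.
#'
#' Filters and thresholds: exonic length >= 200 bp (multiexonic) or >= 500 bp
#' (monoexonic); unmappable overlap <= 5\% of exonic length; intergenic and
#' >= 5 kb from same-strand protein-coding genes; all splice junctions
#' supported with correct strand; retrogene overlap < 50\% of locus length;
#' no tRNA overlap; RNA-repeat overlap < 25\% of locus length; >= 10 unique
#' reads in total; sense/antisense ratio >= 1\% in at least one sample;
#' full-vs-nonoverlap Spearman rho >= 0.9.
#'
#' @param ann merged [annotation_set()].
#' @param locus_evidence data.frame keyed by `gene_id` with
#'   `unique_reads_total`, list-columns `sa_ratio_per_sample`, `full_tpm`,
#'   `nonoverlap_tpm`, and logical `has_antisense_overlap`, logical
#'   `junctions_supported` (all introns, novel multiexonic loci).
#' @param region_sets named list of interval data.frames:
#'   `unmappable`, `retrogenes`, `trna`, `rna_repeats`. Missing sets switch
#'   the corresponding filter to NA with a warning.
#' @param coding_flags named character vector from [gene_coding_status()]
#'   for novel genes.
#' @param noncoding_biotypes reference biotypes eligible as lncRNA.
#' @param min_exonic_multi,min_exonic_mono,max_unmappable_frac,min_pc_distance,
#'   max_retro_frac,max_repeat_frac,min_reads,min_sa_ratio,min_concordance
#'   thresholds, defaulting to the values above.
#' @return data.frame: `gene_id`, one column per filter
#'   (`"pass"`/`"fail"`/NA), and `final_class`.
#' @export
select_lncrnas <- function(ann, locus_evidence, region_sets, coding_flags,
                           noncoding_biotypes = NONCODING_BIOTYPES,
                           min_exonic_multi = 200, min_exonic_mono = 500,
                           max_unmappable_frac = 0.05, min_pc_distance = 5000,
                           max_retro_frac = 0.50, max_repeat_frac = 0.25,
                           min_reads = 10, min_sa_ratio = 0.01,
                           min_concordance = 0.9) {
  need <- c("unmappable", "retrogenes", "trna", "rna_repeats")
  for (nm in setdiff(need, names(region_sets))) {
    warning("region set '", nm, "' missing; its filter is NA")
    region_sets[[nm]] <- NULL
  }
  pc_genes <- Filter(function(g) g$biotype == "protein_coding", ann$genes)
  pc_ids <- vapply(pc_genes, `[[`, "", "id")
  frac_overlap <- function(target_df, set) {
    # fraction of target bases covered by the region set
    tot <- sum(target_df$end - target_df$start)
    if (tot == 0) return(0)
    cov <- 0
    for (i in seq_len(nrow(target_df))) {
      sub <- set[set$chrom == target_df$chrom[i], , drop = FALSE]
      if (nrow(sub) == 0L) next
      u <- interval_union(sub[, c("start", "end")])
      cov <- cov + interval_overlap_len(target_df$start[i], target_df$end[i],
                                        u$start, u$end)
    }
    cov / tot
  }
  filter_names <- c("noncoding", "exonic_length", "unmappable", "intergenic",
                    "junction_support", "retrogene", "trna", "rna_repeat",
                    "min_reads", "sense_antisense", "antisense_concordance")
  rows <- lapply(ann$genes, function(g) {
    out <- setNames(rep(NA_character_, length(filter_names)), filter_names)
    is_novel <- identical(g$source, "novel")
    # eligibility as a noncoding candidate
    if (is_novel) {
      flag <- coding_flags[g$id]
      out["noncoding"] <- if (identical(unname(flag), "candidate_noncoding"))
        "pass" else "fail"
    } else {
      out["noncoding"] <- if (g$biotype %in% noncoding_biotypes) "pass"
        else "fail"
    }
    blocks <- exon_blocks(g)
    span <- gene_span(g)
    span_df <- data.frame(chrom = g$chrom, start = span[1], end = span[2])
    exlen <- sum(blocks$end - blocks$start)
    monoexonic <- all(vapply(g$transcripts, function(tx) nrow(tx$exons), 0L)
                      == 1L)
    if (is_novel) {
      thr <- if (monoexonic) min_exonic_mono else min_exonic_multi
      out["exonic_length"] <- if (exlen >= thr) "pass" else "fail"
      if (!is.null(region_sets$unmappable))
        out["unmappable"] <-
          if (frac_overlap(blocks, region_sets$unmappable) >
              max_unmappable_frac) "fail" else "pass"
      # intergenic: no exonic overlap with protein-coding genes on either
      # strand, and >= 5 kb from same-strand protein-coding gene spans
      ov_pc <- overlapping_genes(blocks, ann, stranded = FALSE,
                                 restrict_ids = pc_ids)
      ov_pc <- setdiff(ov_pc, g$id)
      dist_ok <- TRUE
      for (pid in pc_ids) {
        pg <- ann$genes[[pid]]
        if (pid == g$id || pg$chrom != g$chrom || pg$strand != g$strand) next
        psp <- gene_span(pg)
        d <- if (psp[1] < span[2] && psp[2] > span[1]) 0  # spans overlap
          else max(psp[1] - span[2], span[1] - psp[2])
        if (d < min_pc_distance) { dist_ok <- FALSE; break }
      }
      out["intergenic"] <- if (length(ov_pc) == 0L && dist_ok) "pass"
        else "fail"
      if (!monoexonic) {
        i <- match(g$id, locus_evidence$gene_id)
        sup <- if (!is.na(i)) locus_evidence$junctions_supported[i] else NA
        out["junction_support"] <- if (isTRUE(sup)) "pass"
          else if (is.na(sup)) NA_character_ else "fail"
      }
    }
    if (!is.null(region_sets$retrogenes))
      out["retrogene"] <- if (frac_overlap(span_df, region_sets$retrogenes) >=
                              max_retro_frac) "fail" else "pass"
    if (!is.null(region_sets$trna))
      out["trna"] <- if (frac_overlap(span_df, region_sets$trna) > 0) "fail"
        else "pass"
    if (!is.null(region_sets$rna_repeats))
      out["rna_repeat"] <- if (frac_overlap(span_df,
                                            region_sets$rna_repeats) >=
                               max_repeat_frac) "fail" else "pass"
    i <- match(g$id, locus_evidence$gene_id)
    if (!is.na(i)) {
      out["min_reads"] <- if (locus_evidence$unique_reads_total[i] >=
                              min_reads) "pass" else "fail"
      sar <- locus_evidence$sa_ratio_per_sample[[i]]
      out["sense_antisense"] <- if (any(sar >= min_sa_ratio)) "pass"
        else "fail"
      if (isTRUE(locus_evidence$has_antisense_overlap[i])) {
        rho <- antisense_concordance(locus_evidence$full_tpm[[i]],
                                     locus_evidence$nonoverlap_tpm[[i]])
        out["antisense_concordance"] <-
          if (!is.na(rho) && rho >= min_concordance) "pass" else "fail"
      }
    }
    applicable <- !is.na(out)
    final <- if (all(out[applicable] == "pass") && out["noncoding"] %in%
                 "pass") "lncRNA" else "excluded"
    c(list(gene_id = g$id), as.list(out), list(final_class = final))
  })
  audit <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(audit) <- NULL
  audit
}

#' Genes expressed above noise per condition
#'
#' @param condition_means matrix genes x conditions of replicate-averaged TPM.
#' @param threshold minimum mean TPM (default 1; inclusive).
#' @return named list of gene-id vectors, one per condition.
#' @export
expressed_above_noise <- function(condition_means, threshold = 1) {
  lapply(setNames(colnames(condition_means), colnames(condition_means)),
         function(cn) {
           rownames(condition_means)[condition_means[, cn] >= threshold]
         })
}

#' Write a filter audit table as TSV
#'
#' @param audit data.frame from [select_lncrnas()].
#' @param path output file.
#' @export
write_filter_audit <- function(audit, path) {
  write.table(audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
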