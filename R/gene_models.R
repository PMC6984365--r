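# Genomic data model: transcripts, genes, annotation sets, and derived regions
# (exon blocks, promoters, splice sites). Coordinates 0-based half-open
# throughout; GTF I/O converts to/from the 1-based inclusive convention.

#' Construct a transcript model
#'
#' @param id transcript id.
#' @param gene_id parent gene id.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end` (0-based half-open); exons are
#'   sorted and must be separated by at least 1 bp of intron.
#' @param biotype transcript biotype (Ensembl vocabulary).
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(id, gene_id, chrom, strand, exons,
                             biotype = "protein_coding") {
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (any(exons$start >= exons$end)) stop("exon start must be < end: ", id)
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("exons must be separated by >= 1 bp intron: ", id)
  rownames(exons) <- NULL
  structure(list(id = id, gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, biotype = biotype),
            class = "transcript_model")
}

#' Construct a gene model
#'
#' A gene groups one or more transcript isoforms sharing chromosome and
#' strand. `gene_class` holds the pipeline's working classification.
#'
#' @param id gene id.
#' @param transcripts list of [transcript_model()] objects.
#' @param biotype gene biotype.
#' @param gene_class one of `protein_coding`, `lncRNA`, `other`, `excluded`.
#' @param source `reference` or `novel`.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(id, transcripts, biotype = "protein_coding",
                       gene_class = "other", source = "reference") {
  stopifnot(length(transcripts) >= 1L)
  chroms <- unique(vapply(transcripts, `[[`, "", "chrom"))
  strands <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(chroms) != 1L || length(strands) != 1L)
    stop("all transcripts of a gene must share chrom and strand: ", id)
  names(transcripts) <- vapply(transcripts, `[[`, "", "id")
  structure(list(id = id, chrom = chroms, strand = strands,
                 transcripts = transcripts, biotype = biotype,
                 gene_class = gene_class, source = source),
            class = "gene_model")
}

#' Construct an annotation set
#'
#' @param genes list of [gene_model()] objects with unique ids.
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(genes) {
  ids <- vapply(genes, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicated gene ids in annotation set")
  names(genes) <- ids
  structure(list(genes = genes), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  nt <- sum(vapply(x$genes, function(g) length(g$transcripts), 0L))
  cat("annotation_set:", length(x$genes), "genes,", nt, "transcripts\n")
  invisible(x)
}

# genomic span of a gene or transcript: c(start, end)
gene_span <- function(gene) {
  ex <- do.call(rbind, lapply(gene$transcripts, `[[`, "exons"))
  c(min(ex$start), max(ex$end))
}

transcript_span <- function(tx) c(min(tx$exons$start), max(tx$exons$end))

# TSS of a gene = 5'-most transcript start across isoforms on the gene strand,
# as a point coordinate (0-based): + strand, min exon start; - strand, max end.
gene_tss <- function(gene) {
  sp <- gene_span(gene)
  if (gene$strand == "+") sp[1] else sp[2]
}

# flat table of all exons in an annotation set
exon_table <- function(ann) {
  rows <- lapply(ann$genes, function(g) {
    do.call(rbind, lapply(g$transcripts, function(tx) {
      data.frame(chrom = g$chrom, start = tx$exons$start, end = tx$exons$end,
                 strand = g$strand, gene_id = g$id, transcript_id = tx$id,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read gene annotations from a GTF file
#'
#' Parses Ensembl-dialect GTF (attributes `gene_id`, `transcript_id`,
#' `gene_biotype`, `transcript_biotype`), converting 1-based inclusive
#' coordinates to the internal 0-based half-open convention. Only `exon`
#' features define models; other feature types are ignored.
#'
#' @param path GTF file.
#' @return an [annotation_set()].
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(annotation_set(list()))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GTF line ", idx[which(nf != 9L)[1]], ": expected 9 fields")
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  feat <- m[, 3L]
  is_exon <- feat == "exon"
  if (!any(is_exon)) return(annotation_set(list()))
  attr_str <- m[is_exon, 9L]
  get_attr <- function(key) {
    res <- regmatches(attr_str,
                      regexpr(paste0(key, ' "[^"]*"'), attr_str))
    out <- rep(NA_character_, length(attr_str))
    hit <- grepl(paste0(key, ' "'), attr_str)
    out[hit] <- sub('"$', "", sub(paste0(key, ' "'), "", res))
    out
  }
  gene_id <- get_attr("gene_id")
  tx_id <- get_attr("transcript_id")
  gene_bt <- get_attr("gene_biotype")
  tx_bt <- get_attr("transcript_biotype")
  bad_tx <- is.na(tx_id)
  if (any(bad_tx)) {
    warning(sum(bad_tx), " exon record(s) without transcript_id rejected")
  }
  df <- data.frame(
    chrom = m[is_exon, 1L],
    start = as.numeric(m[is_exon, 4L]) - 1,  # 1-based incl -> 0-based half-open
    end = as.numeric(m[is_exon, 5L]),
    strand = m[is_exon, 7L],
    gene_id = gene_id, transcript_id = tx_id,
    gene_biotype = ifelse(is.na(gene_bt), "protein_coding", gene_bt),
    transcript_biotype = ifelse(is.na(tx_bt),
                                ifelse(is.na(gene_bt), "protein_coding", gene_bt),
                                tx_bt),
    stringsAsFactors = FALSE)
  df <- df[!bad_tx, , drop = FALSE]
  if (any(is.na(df$start)) || any(df$start < 0) || any(df$start >= df$end))
    stop("malformed GTF coordinates")
  genes <- lapply(split(df, df$gene_id), function(gd) {
    txs <- lapply(split(gd, gd$transcript_id), function(td) {
      transcript_model(td$transcript_id[1], td$gene_id[1], td$chrom[1],
                       td$strand[1],
                       data.frame(start = td$start, end = td$end),
                       biotype = td$transcript_biotype[1])
    })
    gene_model(gd$gene_id[1], unname(txs), biotype = gd$gene_biotype[1],
               gene_class = if (gd$gene_biotype[1] == "protein_coding")
                 "protein_coding" else "other")
  })
  annotation_set(unname(genes))
}

#' Write an annotation set as GTF
#'
#' @param ann an [annotation_set()].
#' @param path output file.
#' @param source value for the GTF source column.
#' @export
write_gtf <- function(ann, path, source = "lncevo") {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in ann$genes) {
    for (tx in g$transcripts) {
      attrs <- sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_biotype "%s"; transcript_biotype "%s";',
        g$id, tx$id, g$biotype, tx$biotype)
      lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                       g$chrom, source, as.integer(tx$exons$start) + 1L,
                       as.integer(tx$exons$end), g$strand, attrs)
      writeLines(lines, con)
    }
  }
  invisible(path)
}

#' Pre-filter a reference annotation
#'
#' Removes transcripts whose genomic span exceeds `max_span_bp` (strictly) and,
#' for protein-coding genes, isoforms annotated with the listed non-coding
#' biotypes. Genes left with no transcripts are dropped.
#'
#' @param ann an [annotation_set()].
#' @param max_span_bp span threshold in bp (default 2.5 Mb).
#' @param drop_biotypes isoform biotypes removed from protein-coding genes.
#' @return filtered [annotation_set()].
#' @export
prefilter_reference <- function(ann, max_span_bp = 2.5e6,
                                drop_biotypes = c("retained_intron",
                                                  "processed_transcript")) {
  stopifnot(max_span_bp > 0)
  genes <- lapply(ann$genes, function(g) {
    keep <- vapply(g$transcripts, function(tx) {
      sp <- transcript_span(tx)
      if ((sp[2] - sp[1]) > max_span_bp) return(FALSE)
      if (g$biotype == "protein_coding" && tx$biotype %in% drop_biotypes)
        return(FALSE)
      TRUE
    }, TRUE)
    if (!any(keep)) return(NULL)
    g$transcripts <- g$transcripts[keep]
    g
  })
  annotation_set(unname(genes[!vapply(genes, is.null, TRUE)]))
}

#' Exon blocks of a gene
#'
#' The union of a gene's exon coordinates across all isoforms: the minimal
#' sorted set of disjoint intervals covering every exon base. Exon blocks are
#' the unit projected between genomes for homology prediction.
#'
#' @param gene a [gene_model()].
#' @return interval data.frame sorted by start, single chrom/strand.
#' @export
exon_blocks <- function(gene) {
  ex <- do.call(rbind, lapply(gene$transcripts, `[[`, "exons"))
  u <- interval_union(ex)
  genomic_intervals(gene$chrom, u$start, u$end, gene$strand)
}

# total exonic length of a gene (union over isoforms)
exonic_length <- function(gene) {
  b <- exon_blocks(gene)
  sum(b$end - b$start)
}

#' Promoter region of a gene
#'
#' The region immediately upstream of the gene's transcription start site
#' (5'-most isoform start). On `+` strand `[TSS - upstream_bp, TSS)`; on `-`
#' strand `[TSS, TSS + upstream_bp)`. Truncated at the chromosome start; a
#' fully truncated promoter is returned zero-length with attribute
#' `truncated = TRUE`.
#'
#' @param gene a [gene_model()].
#' @param upstream_bp upstream extent in bp (default 400).
#' @return one-row interval data.frame; attribute `truncated` flags clipping.
#' @export
promoter_region <- function(gene, upstream_bp = 400) {
  tss <- gene_tss(gene)
  if (gene$strand == "+") {
    s <- max(0, tss - upstream_bp); e <- tss
  } else {
    s <- tss; e <- tss + upstream_bp
  }
  truncated <- (e - s) < upstream_bp
  if (s >= e) {
    out <- data.frame(chrom = gene$chrom, start = s, end = s,
                      strand = gene$strand, stringsAsFactors = FALSE)
  } else {
    out <- genomic_intervals(gene$chrom, s, e, gene$strand)
  }
  attr(out, "truncated") <- truncated
  out
}

#' Splice-site intervals of a transcript
#'
#' For each intron, the first and last two intronic bases (donor and acceptor
#' sides), 4 bp per intron. Monoexonic transcripts yield an empty set.
#'
#' @param transcript a [transcript_model()].
#' @return interval data.frame (possibly 0 rows).
#' @export
splice_sites <- function(transcript) {
  ex <- transcript$exons
  n <- nrow(ex)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  intron_s <- ex$end[-n]; intron_e <- ex$start[-1L]
  starts <- c(intron_s, intron_e - 2)
  ends <- c(intron_s + 2, intron_e)
  genomic_intervals(transcript$chrom, starts, ends, transcript$strand)
}

#' Classify a gene's promoter as bidirectional or unidirectional
#'
#' A promoter is bidirectional when another gene's TSS lies on the opposite
#' strand within `window_bp` of this gene's TSS; protein-coding partners take
#' precedence over non-coding ones.
#'
#' @param gene a [gene_model()].
#' @param ann the [annotation_set()] providing candidate partner TSSs.
#' @param window_bp maximum TSS-to-TSS distance (default 1000).
#' @return `"bidirectional_pc"`, `"bidirectional_other"` or `"unidirectional"`.
#' @export
classify_promoter_type <- function(gene, ann, window_bp = 1000) {
  stopifnot(window_bp > 0)
  tss <- gene_tss(gene)
  partner_pc <- FALSE; partner_other <- FALSE
  for (g in ann$genes) {
    if (g$id == gene$id || g$chrom != gene$chrom || g$strand == gene$strand)
      next
    if (abs(gene_tss(g) - tss) <= window_bp) {
      if (g$biotype == "protein_coding") partner_pc <- TRUE
      else partner_other <- TRUE
    }
  }
  if (partner_pc) "bidirectional_pc"
  else if (partner_other) "bidirectional_other"
  else "unidirectional"
}

#' Export per-gene regions as BED6
#'
#' @param ann an [annotation_set()].
#' @param path output BED file.
#' @param region one of `"exon_blocks"`, `"promoters"`, `"splice_sites"`.
#' @param upstream_bp promoter extent when `region = "promoters"`.
#' @export
export_regions_bed <- function(ann, path,
                               region = c("exon_blocks", "promoters",
                                          "splice_sites"),
                               upstream_bp = 400) {
  region <- match.arg(region)
  rows <- lapply(ann$genes, function(g) {
    df <- switch(region,
      exon_blocks = exon_blocks(g),
      promoters = promoter_region(g, upstream_bp),
      splice_sites = {
        ss <- do.call(rbind, lapply(g$transcripts, splice_sites))
        if (is.null(ss) || nrow(ss) == 0L) return(NULL)
        interval_union(ss)
      })
    if (nrow(df) == 0L || any(df$start >= df$end)) return(NULL)
    df$name <- g$id
    df
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  write_bed(do.call(rbind, rows), path)
}
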