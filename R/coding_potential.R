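# Codon substitution frequency (CSF) coding-potential scoring and
# similarity-based classification. A CSF model holds frequencies of ordered
# codon pairs observed in alignments of coding vs neutrally evolving sequence;
# a window's score is the log-likelihood ratio of the two, maximised over the
# three frames of a strand. Stop codons are pooled into one state.

CODON_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# 62 states: 61 sense codons + pooled "STP"
csf_states <- function() {
  all_cod <- apply(expand.grid(CODON_BASES, CODON_BASES, CODON_BASES,
                               stringsAsFactors = FALSE)[, 3:1], 1, paste,
                   collapse = "")
  c(sort(setdiff(all_cod, STOP_CODONS)), "STP")
}

# map codon strings to state index; NA for gaps/ambiguity
codon_state_index <- function(codons, states) {
  codons <- toupper(codons)
  codons[codons %in% STOP_CODONS] <- "STP"
  idx <- match(codons, states)
  idx[!grepl("^[ACGT]{3}$|^STP$", codons)] <- NA_integer_
  idx
}

# split an aligned sequence into codon triplets starting at `offset` (0-based)
codons_at <- function(seq_chars, offset) {
  n <- length(seq_chars)
  nc <- (n - offset) %/% 3
  if (nc <= 0L) return(character(0))
  pos <- offset + seq(0L, by = 3L, length.out = nc)
  paste0(seq_chars[pos + 1L], seq_chars[pos + 2L], seq_chars[pos + 3L])
}

#' Train a codon substitution frequency model
#'
#' Estimates ordered codon-pair frequencies from in-frame aligned coding pairs
#' and from neutrally evolving aligned pairs, with additive smoothing. Codon
#' pairs containing gaps or ambiguity codes are skipped; alignment lengths not
#' a multiple of 3 lose their trailing bases.
#'
#' @param coding_pairs list of length-2 character vectors (aligned, equal
#'   length, frame starting at position 1).
#' @param noncoding_pairs list of aligned pairs evolving neutrally.
#' @param pseudocount additive smoothing constant (> 0).
#' @return object of class `csf_model` with the log-ratio matrix.
#' @export
train_csf_model <- function(coding_pairs, noncoding_pairs, pseudocount = 0.5) {
  if (length(coding_pairs) == 0L || length(noncoding_pairs) == 0L)
    stop("empty CSF training set")
  stopifnot(pseudocount > 0)
  states <- csf_states()
  ns <- length(states)
  count_pairs <- function(pairs) {
    m <- matrix(0, ns, ns, dimnames = list(states, states))
    for (p in pairs) {
      a <- strsplit(toupper(p[1]), "")[[1]]
      b <- strsplit(toupper(p[2]), "")[[1]]
      if (length(a) != length(b)) stop("aligned pair of unequal length")
      ca <- codon_state_index(codons_at(a, 0L), states)
      cb <- codon_state_index(codons_at(b, 0L), states)
      ok <- !is.na(ca) & !is.na(cb)
      if (any(ok)) {
        tab <- table(factor(ca[ok], levels = seq_len(ns)),
                     factor(cb[ok], levels = seq_len(ns)))
        m <- m + as.matrix(tab)
      }
    }
    m
  }
  fc <- count_pairs(coding_pairs) + pseudocount
  fn <- count_pairs(noncoding_pairs) + pseudocount
  fc <- fc / sum(fc)
  fn <- fn / sum(fn)
  structure(list(states = states, f_coding = fc, f_noncoding = fn,
                 logratio = log(fc) - log(fn), pseudocount = pseudocount),
            class = "csf_model")
}

# score one frame of an aligned pair: sum of log-ratios over gapless codons
csf_frame_score <- function(ca, cb, model) {
  ok <- !is.na(ca) & !is.na(cb)
  if (!any(ok)) return(0)
  sum(model$logratio[cbind(ca[ok], cb[ok])])
}

revcomp_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")
  out <- comp[x]
  out[is.na(out)] <- "N"
  rev(unname(out))
}

#' Scan an aligned pair with sliding CSF windows
#'
#' Computes CSF scores in sliding windows (default 75 bp, 3-bp step). For each
#' window the score on a strand is the maximum over that strand's three
#' reading frames of the summed codon-pair log-ratios; the minus strand is
#' scored on the reverse complement of both sequences and reported in the
#' coordinates of the input alignment. Windows extending past the end are
#' omitted.
#'
#' @param aligned_pair length-2 character vector (aligned, equal length).
#' @param model a [train_csf_model()] fit.
#' @param window window length in bp, a multiple of 3 (default 75).
#' @param step step in bp (default 3).
#' @return list with elements `plus` and `minus`, each a data.frame
#'   `start`, `end` (0-based alignment coordinates), `score`.
#' @export
csf_window_scan <- function(aligned_pair, model, window = 75, step = 3) {
  stopifnot(window %% 3 == 0)
  a <- strsplit(toupper(aligned_pair[1]), "")[[1]]
  b <- strsplit(toupper(aligned_pair[2]), "")[[1]]
  L <- length(a)
  empty <- data.frame(start = numeric(0), end = numeric(0), score = numeric(0))
  if (L < window) {
    message("alignment shorter than window (", L, " < ", window, ")")
    return(list(plus = empty, minus = empty))
  }
  scan_strand <- function(sa, sb) {
    # precompute codon states for the 3 frames
    states <- model$states
    frames <- lapply(0:2, function(f) {
      list(ca = codon_state_index(codons_at(sa, f), states),
           cb = codon_state_index(codons_at(sb, f), states))
    })
    starts <- seq(0L, L - window, by = step)
    score <- vapply(starts, function(s) {
      max(vapply(0:2, function(f) {
        # codons of frame f fully inside [s, s + window)
        first <- ceiling((s - f) / 3)
        first <- max(0L, as.integer(first))
        last <- (s + window - f) %/% 3 - 1L
        fr <- frames[[f + 1L]]
        if (last < first || first + 1L > length(fr$ca)) return(0)
        last <- min(last, length(fr$ca) - 1L)
        idx <- (first + 1L):(last + 1L)
        csf_frame_score(fr$ca[idx], fr$cb[idx], model)
      }, 0))
    }, 0)
    data.frame(start = starts, end = starts + window, score = score)
  }
  plus <- scan_strand(a, b)
  ra <- revcomp_chars(a); rb <- revcomp_chars(b)
  minus_rc <- scan_strand(ra, rb)
  # map minus-strand windows back to input coordinates
  minus <- data.frame(start = L - minus_rc$end, end = L - minus_rc$start,
                      score = minus_rc$score)
  minus <- minus[order(minus$start), , drop = FALSE]
  rownames(minus) <- NULL
  list(plus = plus, minus = minus)
}

#' Place alignment-coordinate window scores on the genome
#'
#' @param scan result of [csf_window_scan()].
#' @param chrom chromosome of the aligned reference segment.
#' @param genome_start 0-based genomic start of alignment column 0.
#' @return data.frame `chrom`, `start`, `end`, `strand`, `score`.
#' @export
window_scores_genomic <- function(scan, chrom, genome_start) {
  out <- rbind(
    if (nrow(scan$plus)) data.frame(strand = "+", scan$plus) else NULL,
    if (nrow(scan$minus)) data.frame(strand = "-", scan$minus) else NULL)
  if (is.null(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      score = numeric(0)))
  data.frame(chrom = chrom, start = out$start + genome_start,
             end = out$end + genome_start, strand = out$strand,
             score = out$score, stringsAsFactors = FALSE)
}

#' Classify a transcript as coding from CSF window scores
#'
#' A transcript is protein-coding when its exonic bases lying under at least
#' one strictly positive window on the transcript strand — after excluding
#' exonic regions that overlap other genes (`masked_regions`) — total at least
#' `min_overlap` bp.
#'
#' @param transcript a [transcript_model()].
#' @param window_scores genomic window scores ([window_scores_genomic()]).
#' @param min_overlap minimum positive-covered exonic bases (default 150).
#' @param masked_regions interval data.frame of other genes' exons, or NULL.
#' @return logical.
#' @export
classify_coding_by_csf <- function(transcript, window_scores,
                                   min_overlap = 150, masked_regions = NULL) {
  ws <- window_scores[window_scores$score > 0 &
                        window_scores$strand == transcript$strand &
                        window_scores$chrom == transcript$chrom, ,
                      drop = FALSE]
  if (nrow(ws) == 0L) return(FALSE)
  pos <- interval_union(ws[, c("start", "end")])
  mask <- if (!is.null(masked_regions))
    masked_regions[masked_regions$chrom == transcript$chrom, , drop = FALSE]
  else NULL
  covered <- 0
  for (i in seq_len(nrow(transcript$exons))) {
    s <- transcript$exons$start[i]; e <- transcript$exons$end[i]
    pieces <- if (!is.null(mask) && nrow(mask) > 0L)
      interval_subtract(s, e, mask$start, mask$end)
    else data.frame(start = s, end = e)
    for (j in seq_len(nrow(pieces)))
      covered <- covered + interval_overlap_len(pieces$start[j], pieces$end[j],
                                                pos$start, pos$end)
  }
  covered >= min_overlap
}

#' Read a BLAST tabular hit file
#'
#' Standard 12-column tabular format (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bit score). Query coordinates are converted to 0-based
#' half-open transcript coordinates.
#'
#' @param path tabular hit file.
#' @return data.frame with `transcript_id`, `hit_start`, `hit_end`,
#'   `pct_identity`, `e_value`.
#' @export
read_blast_tab <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  qs <- pmin(df[[7]], df[[8]]); qe <- pmax(df[[7]], df[[8]])
  data.frame(transcript_id = as.character(df[[1]]),
             subject = as.character(df[[2]]),
             hit_start = qs - 1, hit_end = qe,
             pct_identity = as.numeric(df[[3]]),
             e_value = as.numeric(df[[11]]),
             stringsAsFactors = FALSE)
}

#' Classify a transcript as coding from protein-similarity hits
#'
#' Hits passing the e-value and identity thresholds are unioned on the
#' transcript; the transcript is protein-coding when the union covers at
#' least `min_overlap` bp.
#'
#' @param hits data.frame as from [read_blast_tab()] (one transcript).
#' @param max_evalue keep hits with e-value <= this (default 1e-3).
#' @param min_identity keep hits with percent identity >= this (default 40).
#' @param min_overlap minimum covered bp (default 150).
#' @return logical.
#' @export
classify_coding_by_similarity <- function(hits, max_evalue = 1e-3,
                                          min_identity = 40,
                                          min_overlap = 150) {
  if (is.null(hits) || nrow(hits) == 0L) return(FALSE)
  keep <- hits$e_value <= max_evalue & hits$pct_identity >= min_identity
  if (!any(keep)) return(FALSE)
  interval_union_len(hits$hit_start[keep], hits$hit_end[keep]) >= min_overlap
}

#' Gene-level coding status from per-isoform flags
#'
#' A gene is protein-coding when at least one isoform is flagged by either
#' the CSF criterion or the similarity criterion.
#'
#' @param csf_flags named logical vector, one entry per isoform.
#' @param similarity_flags named logical vector over the same isoforms.
#' @return `"protein_coding"` or `"candidate_noncoding"`.
#' @export
gene_coding_status <- function(csf_flags, similarity_flags) {
  if (any(csf_flags %in% TRUE) || any(similarity_flags %in% TRUE))
    "protein_coding" else "candidate_noncoding"
}

#' Export window scores as bedGraph (one file per strand)
#'
#' @param ws genomic window scores.
#' @param prefix output path prefix; writes `<prefix>.plus.bedGraph` and
#'   `<prefix>.minus.bedGraph`.
#' @export
write_window_bedgraph <- function(ws, prefix) {
  for (st in c("plus", "minus")) {
    sym <- if (st == "plus") "+" else "-"
    sub <- ws[ws$strand == sym, , drop = FALSE]
    f <- paste0(prefix, ".", st, ".bedGraph")
    write.table(sub[, c("chrom", "start", "end", "score")], f,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(prefix)
}
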