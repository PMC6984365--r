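# UCSC chain format: co-linear gapped alignment blocks between two genomes.
# Parsed by hand because projection needs chain scores and ids for
# disambiguation of ambiguous/split liftOver cases. Block coordinates are
# stored on the forward strand of both genomes ('-'-strand target coordinates
# from the file are flipped using the chromosome size).

#' Read a UCSC chain file
#'
#' @param path chain file.
#' @return object of class `chain_map`: a list of chains, each with `score`,
#'   `id`, reference (`ref_chrom`, `ref_size`) and target (`tgt_chrom`,
#'   `tgt_size`, `tgt_strand`) descriptors and a `blocks` data.frame
#'   (`ref_start`, `ref_end`, `tgt_start`, `tgt_end`, forward-strand 0-based
#'   half-open coordinates; for `-`-strand chains blocks run in decreasing
#'   target order).
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!grepl("^chain\\b", ln)) { i <- i + 1L; next }
    h <- strsplit(trimws(ln), "\\s+")[[1]]
    # chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd id
    # reference = t fields, target = q fields
    score <- as.numeric(h[2])
    ref_chrom <- h[3]; ref_size <- as.numeric(h[4])
    ref_start <- as.numeric(h[6]); ref_end <- as.numeric(h[7])
    tgt_chrom <- h[8]; tgt_size <- as.numeric(h[9])
    tgt_strand <- h[10]
    tgt_start <- as.numeric(h[11]); tgt_end <- as.numeric(h[12])
    id <- if (length(h) >= 13) h[13] else as.character(length(chains) + 1L)
    rs <- ref_start; ts <- tgt_start
    bl <- list()
    i <- i + 1L
    repeat {
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      size <- as.numeric(parts[1])
      bl[[length(bl) + 1L]] <- c(rs, rs + size, ts, ts + size)
      if (length(parts) == 3L) {
        rs <- rs + size + as.numeric(parts[2])
        ts <- ts + size + as.numeric(parts[3])
        i <- i + 1L
      } else { i <- i + 1L; break }
    }
    blocks <- as.data.frame(do.call(rbind, bl))
    names(blocks) <- c("ref_start", "ref_end", "tgt_start", "tgt_end")
    if (tgt_strand == "-") {
      # flip target coordinates to the forward strand
      ts2 <- tgt_size - blocks$tgt_end
      te2 <- tgt_size - blocks$tgt_start
      blocks$tgt_start <- ts2; blocks$tgt_end <- te2
    }
    chains[[length(chains) + 1L]] <- list(
      score = score, id = id,
      ref_chrom = ref_chrom, ref_size = ref_size,
      tgt_chrom = tgt_chrom, tgt_size = tgt_size, tgt_strand = tgt_strand,
      blocks = blocks)
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  structure(list(chains = chains), class = "chain_map")
}

#' @export
print.chain_map <- function(x, ...) {
  cat("chain_map:", length(x$chains), "chains\n")
  invisible(x)
}

#' Build a chain map in memory
#'
#' @param chains list of chain descriptors as produced by [read_chain()].
#' @return a `chain_map`.
#' @export
chain_map <- function(chains) structure(list(chains = chains),
                                        class = "chain_map")

#' Write a chain map as a UCSC chain file
#'
#' @param cm a `chain_map`.
#' @param path output file.
#' @export
write_chain <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in cm$chains) {
    b <- ch$blocks
    if (ch$tgt_strand == "-") {
      ts <- ch$tgt_size - b$tgt_end
      te <- ch$tgt_size - b$tgt_start
      b$tgt_start <- ts; b$tgt_end <- te
      b <- b[order(b$ref_start), , drop = FALSE]
    }
    writeLines(sprintf("chain %d %s %d + %d %d %s %d %s %d %d %s",
                       as.integer(ch$score), ch$ref_chrom,
                       as.integer(ch$ref_size), as.integer(min(b$ref_start)),
                       as.integer(max(b$ref_end)), ch$tgt_chrom,
                       as.integer(ch$tgt_size), ch$tgt_strand,
                       as.integer(min(b$tgt_start)),
                       as.integer(max(b$tgt_end)), ch$id), con)
    n <- nrow(b)
    for (j in seq_len(n)) {
      size <- as.integer(b$ref_end[j] - b$ref_start[j])
      if (j < n) {
        dt <- as.integer(b$ref_start[j + 1] - b$ref_end[j])
        dq <- as.integer(b$tgt_start[j + 1] - b$tgt_end[j])
        writeLines(sprintf("%d\t%d\t%d", size, dt, dq), con)
      } else writeLines(sprintf("%d", size), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Invert a chain map
#'
#' Swaps reference and target genomes, yielding the chain map for the
#' opposite projection direction.
#'
#' @param cm a `chain_map`.
#' @return inverted `chain_map`.
#' @export
invert_chain_map <- function(cm) {
  chains <- lapply(cm$chains, function(ch) {
    b <- data.frame(ref_start = ch$blocks$tgt_start,
                    ref_end = ch$blocks$tgt_end,
                    tgt_start = ch$blocks$ref_start,
                    tgt_end = ch$blocks$ref_end)
    b <- b[order(b$ref_start), , drop = FALSE]
    rownames(b) <- NULL
    list(score = ch$score, id = ch$id,
         ref_chrom = ch$tgt_chrom, ref_size = ch$tgt_size,
         tgt_chrom = ch$ref_chrom, tgt_size = ch$ref_size,
         tgt_strand = ch$tgt_strand, blocks = b)
  })
  chain_map(chains)
}
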