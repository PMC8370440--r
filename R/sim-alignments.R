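#' Emit a SAM file realizing a junction-count table
#'
#' Writes toy single-end alignments for one sample so that the junction
#' counter recovers the requested per-intron counts exactly: EE reads are
#' split alignments whose skipped segment equals the intron, EI/IE reads are
#' contiguous alignments straddling the transcription-order 5'/3' boundary
#' with `min_overhang + 4` aligned bases on each side, and body reads lie
#' fully inside the intron. Fully deterministic (read placement cycles over
#' fixed offsets; no randomness is involved).
#'
#' @param counts `data.frame` with columns `intron_id`, `EI`, `IE`, `EE`,
#'   `body` (a `sample_id` column, if present, must be constant).
#' @param introns Intron table from [derive_introns()].
#' @param contig_lengths Named integer vector of contig lengths for the SAM
#'   header.
#' @param path Output SAM path.
#' @param min_overhang Overhang the downstream counter will require.
#' @return `path`, invisibly.
#' @export
emit_alignments <- function(counts, introns, contig_lengths, path, min_overhang = 8L) {
  counts <- data.table::as.data.table(counts)
  if ("sample_id" %in% names(counts) && data.table::uniqueN(counts$sample_id) > 1L)
    stopf("emit_alignments writes one sample per file; got %d sample_ids",
          data.table::uniqueN(counts$sample_id))
  tab <- merge(counts, introns, by = "intron_id")
  if (nrow(tab) < nrow(counts)) stopf("count table references unknown intron_id(s)")
  ov <- as.integer(min_overhang)
  side <- ov + 4L
  short <- tab[(end - start) < 2L * ov & (EI + IE + EE + body) > 0L]
  if (nrow(short) > 0L)
    stopf("requested reads on intron %s shorter than 2 x overhang (%d nt)",
          short$intron_id[1], 2L * ov)

  recs <- character(0)
  n_read <- 0L
  emit <- function(chrom, pos1, cigar, n) {
    if (n <= 0L) return(character(0))
    ids <- sprintf("r%07d", n_read + seq_len(n))
    n_read <<- n_read + n
    sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*", ids, chrom, pos1, cigar)
  }
  for (i in seq_len(nrow(tab))) {
    row <- tab[i]
    s <- row$start; e <- row$end; chrom <- row$chrom
    b5 <- if (row$strand == "+") s else e   # transcription-order 5' boundary
    b3 <- if (row$strand == "+") e else s
    cross <- function(b, n) {
      # contiguous read on [b-side, b+side), SAM pos is 1-based
      emit(chrom, b - side + 1L, sprintf("%dM", 2L * side),
           n)
    }
    recs <- c(recs,
              cross(b5, row$EI),
              cross(b3, row$IE),
              emit(chrom, s - side + 1L,
                   sprintf("%dM%dN%dM", side, e - s, side), row$EE))
    if (row$body > 0L) {
      bl <- min(e - s, 2L * ov)
      offs <- (seq_len(row$body) - 1L) %% (e - s - bl + 1L)
      recs <- c(recs, emit(chrom, s + offs + 1L, sprintf("%dM", bl), row$body))
    }
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  writeLines(c(hdr, recs), path)
  invisible(path)
}
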