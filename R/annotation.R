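#' Read a GTF gene annotation into a gene-model exon table
#'
#' Parses a GTF file (gene/transcript/exon features, 1-based closed
#' coordinates) and returns the exon structure of every transcript with
#' coordinates converted to 0-based half-open intervals, the convention used
#' throughout the package. Single-exon transcripts are retained (they simply
#' yield no introns downstream).
#'
#' @param path Path to a GTF file. Required attributes: `gene_id`,
#'   `transcript_id`; `gene_name` is optional and defaults to `gene_id`.
#' @return A `data.table` of exons with columns `gene_id`, `gene_name`,
#'   `transcript_id`, `chrom`, `start` (0-based), `end` (exclusive), `strand`,
#'   sorted by transcript and start. Exons within a transcript must be
#'   non-overlapping; a violation is an error.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (nrow(df) == 0L || !any(df$type == "exon")) {
    warnf("GTF contains no exon features: %s", path)
    return(data.table::data.table(
      gene_id = character(), gene_name = character(), transcript_id = character(),
      chrom = character(), start = integer(), end = integer(), strand = character()
    ))
  }
  ex <- df[df$type == "exon", , drop = FALSE]
  if (any(is.na(ex$transcript_id) | ex$transcript_id == ""))
    stopf("exon feature without a transcript_id parent in %s", path)
  gene_name <- ex$gene_name
  if (is.null(gene_name)) gene_name <- ex$gene_id
  gene_name[is.na(gene_name)] <- ex$gene_id[is.na(gene_name)]
  exons <- data.table::data.table(
    gene_id = as.character(ex$gene_id),
    gene_name = as.character(gene_name),
    transcript_id = as.character(ex$transcript_id),
    chrom = as.character(ex$seqnames),
    start = as.integer(ex$start) - 1L,  # GTF 1-based closed -> 0-based half-open
    end = as.integer(ex$end),
    strand = as.character(ex$strand)
  )
  data.table::setorder(exons, gene_id, transcript_id, start)
  validate_gene_models(exons)
  exons[]
}

# light structural validation so malformed lines can be reported by number;
# full attribute parsing is left to rtracklayer
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stopf("malformed GTF line %d: expected 9 tab-separated fields, got %d", i, length(f))
    if (is.na(suppressWarnings(as.integer(f[4]))) || is.na(suppressWarnings(as.integer(f[5]))))
      stopf("malformed GTF line %d: non-numeric coordinates", i)
  }
  invisible(TRUE)
}

validate_gene_models <- function(exons) {
  chk <- exons[, {
    o <- order(start)
    s <- start[o]; e <- end[o]
    list(bad_coord = any(s >= e), overlap = any(s[-1] < e[-length(e)]))
  }, by = .(gene_id, transcript_id)]
  if (any(chk$bad_coord)) stopf("exon with start >= end in transcript %s",
                                chk$transcript_id[which(chk$bad_coord)[1]])
  if (any(chk$overlap)) stopf("overlapping exons within transcript %s",
                              chk$transcript_id[which(chk$overlap)[1]])
  multi <- exons[, .(n_chrom = data.table::uniqueN(chrom),
                     n_strand = data.table::uniqueN(strand)), by = gene_id]
  if (any(multi$n_chrom > 1L) || any(multi$n_strand > 1L))
    stopf("gene %s has exons on multiple chromosomes or strands",
          multi$gene_id[which(multi$n_chrom > 1L | multi$n_strand > 1L)[1]])
  invisible(TRUE)
}

#' Derive introns from gene-model exon structure
#'
#' For each transcript, introns are the gaps between consecutive exons.
#' Identical intervals arising from multiple transcripts of the same gene are
#' collapsed to a single record; the intron's ordinal (1-based position in
#' transcription order, i.e. reverse of genomic order on the minus strand) is
#' taken from the first transcript containing it. Zero-length gaps (abutting
#' exons) are skipped with a warning.
#'
#' @param exons Exon table as returned by [read_gene_annotation()].
#' @return A `data.table` of introns: `intron_id`
#'   (`gene_id:chrom:start-end:strand`), `gene_id`, `gene_name`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `ordinal`.
#' @export
derive_introns <- function(exons) {
  if (nrow(exons) == 0L)
    return(data.table::data.table(
      intron_id = character(), gene_id = character(), gene_name = character(),
      chrom = character(), start = integer(), end = integer(),
      strand = character(), ordinal = integer()
    ))
  exons <- data.table::as.data.table(exons)
  gaps <- exons[, {
    o <- order(start)
    s <- start[o]; e <- end[o]
    n <- length(s)
    if (n < 2L) {
      list(start = integer(0), end = integer(0))
    } else {
      list(start = e[-n], end = s[-1])
    }
  }, by = .(gene_id, gene_name, transcript_id, chrom, strand)]
  if (nrow(gaps) == 0L) return(derive_introns(exons[0]))
  zero <- gaps$start >= gaps$end
  if (any(zero)) {
    warnf("%d zero-length intron gap(s) (abutting exons) skipped", sum(zero))
    gaps <- gaps[!zero]
  }
  # transcription-order ordinal within each transcript
  gaps[, ordinal := if (strand[1] == "-") rev(seq_len(.N)) else seq_len(.N),
       by = .(transcript_id)]
  # collapse identical intervals per gene, keeping the first transcript's ordinal
  gaps[, first_seen := seq_len(nrow(gaps))]
  introns <- gaps[, .SD[which.min(first_seen)], by = .(gene_id, chrom, start, end, strand)]
  introns[, intron_id := intron_identifier(gene_id, chrom, start, end, strand)]
  out <- introns[, .(intron_id, gene_id, gene_name, chrom, start, end, strand, ordinal)]
  data.table::setorder(out, gene_id, chrom, start)
  if (anyDuplicated(out$intron_id)) stopf("duplicate intron_id after deduplication")
  out[]
}

#' Load a genome FASTA as a sequence accessor
#'
#' @param path Path to a FASTA file; sequence names (up to the first
#'   whitespace) must match annotation chromosome names.
#' @return A `DNAStringSet` usable with [get_sequence()].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Extract an uppercase subsequence for a genomic interval
#'
#' Minus-strand requests return the reverse complement.
#'
#' @param genome `DNAStringSet` from [read_genome()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return Character scalar sequence.
#' @export
get_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stopf("chromosome %s absent from FASTA", chrom)
  if (start < 0 || end <= start) stopf("invalid interval [%d,%d)", start, end)
  len <- length(genome[[chrom]])
  if (end > len) stopf("interval [%d,%d) extends past end of %s (length %d)",
                       start, end, chrom, len)
  s <- Biostrings::subseq(genome[[chrom]], start = start + 1L, end = end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

#' Write derived introns as BED6
#'
#' BED is 0-based half-open, matching internal coordinates; name is the
#' `intron_id`, score 0.
#'
#' @param introns Intron table from [derive_introns()].
#' @param path Output path.
#' @export
write_introns_bed <- function(introns, path) {
  gr <- introns_to_granges(introns)
  names(gr) <- introns$intron_id
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED6 intron file back into an intron table
#'
#' @param path BED file written by [write_introns_bed()].
#' @return `data.table` with `intron_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_introns_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.table::data.table(
    intron_id = if (!is.null(gr$name)) as.character(gr$name) else names(gr),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}
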