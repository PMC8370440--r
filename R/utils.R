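#' @import data.table
#' @importFrom stats fisher.test p.adjust rbeta rbinom rnbinom rnorm rpois
#'   runif median quantile cor binom.test pnorm setNames sd
#' @importFrom utils head tail
NULL

# interval key used everywhere: chrom:start-end:strand with 0-based half-open coords
interval_key <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

intron_identifier <- function(gene_id, chrom, start, end, strand) {
  sprintf("%s:%s:%d-%d:%s", gene_id, chrom, as.integer(start), as.integer(end), strand)
}

#' Convert an intron table to GRanges (1-based, as GRanges requires)
#'
#' @param introns data.frame with chrom, start (0-based), end, strand columns.
#' @return `GRanges` with `intron_id` metadata when present.
#' @keywords internal
introns_to_granges <- function(introns) {
  gr <- GenomicRanges::GRanges(
    seqnames = introns$chrom,
    ranges = IRanges::IRanges(start = introns$start + 1L, end = introns$end),
    strand = introns$strand
  )
  if (!is.null(introns$intron_id)) S4Vectors::mcols(gr)$intron_id <- introns$intron_id
  gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# deterministic per-stage RNG scoping: every stochastic entry point calls this
# with its own offset so artifacts are reproducible independently of call order
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
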