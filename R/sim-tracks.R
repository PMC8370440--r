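#' Simulate per-RBP crosslink-event tracks
#'
#' Crosslink events (single-nucleotide intervals, stranded with their host
#' intron) are placed by a Poisson process at `crosslink_rate` events/kb
#' inside every intron; inside cytoplasmic-category introns the rate is
#' multiplied by `crosslink_fold` for the designated enriched RBPs only.
#'
#' @param config A [sim_config()].
#' @param structure A [simulate_structure()] result.
#' @param dir Optional directory; one BED6 file per RBP is written there.
#' @return Named list of `GRanges` (one per RBP, names = BED name column).
#' @export
simulate_crosslink_tracks <- function(config, structure = NULL, dir = NULL) {
  st <- structure %||% simulate_structure(config)
  with_seed(config$seed + 3L, {
    introns <- st$introns
    truth <- st$truth[match(introns$intron_id, st$truth$intron_id)]
    base_lambda <- config$crosslink_rate * (introns$end - introns$start) / 1000
    cyto <- truth$category == "cytoplasmic"
    tracks <- vector("list", nrow(st$rbps))
    names(tracks) <- st$rbps$rbp
    for (r in seq_len(nrow(st$rbps))) {
      lambda <- base_lambda
      if (st$rbps$enriched[r]) lambda[cyto] <- lambda[cyto] * config$crosslink_fold
      n_ev <- rpois(length(lambda), lambda)
      idx <- rep.int(seq_along(n_ev), n_ev)
      pos0 <- introns$start[idx] +
        floor(runif(length(idx)) * (introns$end[idx] - introns$start[idx]))
      gr <- GenomicRanges::GRanges(
        seqnames = introns$chrom[idx],
        ranges = IRanges::IRanges(start = pos0 + 1L, width = 1L),
        strand = introns$strand[idx]
      )
      names(gr) <- rep(st$rbps$rbp[r], length(gr))
      S4Vectors::mcols(gr)$score <- 1L
      tracks[[r]] <- gr
    }
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (r in names(tracks))
        rtracklayer::export(GenomicRanges::sort(tracks[[r]], ignore.strand = TRUE),
                            file.path(dir, paste0(r, ".bed")), format = "BED")
    }
    tracks
  })
}

#' Simulate a per-base conservation track (bedGraph)
#'
#' Scores in [0, 1] are drawn per `conservation_bin`-nt bin from a Beta
#' distribution with mean `conservation_mean`, shifted up by
#' `conservation_shift` inside cytoplasmic-only-category introns.
#'
#' @param config A [sim_config()].
#' @param structure A [simulate_structure()] result.
#' @param path Optional bedGraph output path.
#' @return `GRanges` with a `score` column (0-based start on export).
#' @export
simulate_conservation_track <- function(config, structure = NULL, path = NULL) {
  st <- structure %||% simulate_structure(config)
  with_seed(config$seed + 4L, {
    bin <- config$conservation_bin
    chroms <- names(st$contig_lengths)
    starts <- unlist(lapply(st$contig_lengths, function(L) seq(0L, L - 1L, by = bin)),
                     use.names = FALSE)
    lens <- vapply(st$contig_lengths, function(L) length(seq(0L, L - 1L, by = bin)), 1L)
    chrom <- rep(chroms, lens)
    ends <- pmin(starts + bin, rep(unname(st$contig_lengths), lens))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = starts + 1L, end = ends))

    mu <- rep(config$conservation_mean, length(gr))
    cyto_gr <- introns_to_granges(
      st$introns[st$introns$intron_id %in% st$truth[category == "cytoplasmic", intron_id], ])
    mid <- GenomicRanges::resize(gr, width = 1L, fix = "center")
    hit <- suppressWarnings(GenomicRanges::findOverlaps(mid, cyto_gr, ignore.strand = TRUE))
    mu[S4Vectors::queryHits(hit)] <- config$conservation_mean + config$conservation_shift
    conc <- config$conservation_conc
    score <- round(rbeta(length(gr), mu * conc, (1 - mu) * conc), 4)
    S4Vectors::mcols(gr)$score <- score
    if (!is.null(path)) rtracklayer::export(gr, path, format = "bedGraph")
    gr
  })
}
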