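#' Compute exact per-position k-mer mappability over a composite genome
#'
#' For every k-mer start position in every contig, the score is
#' `1 / (number of occurrences of that k-mer over both strands of the whole
#' genome)`: occurrences of the k-mer on the forward strands of all contigs
#' plus forward-strand occurrences of its reverse complement. A score of 1
#' means the k-mer (up to reverse complement) is unique genome-wide; only
#' such positions enter depth and chimera calculations downstream.
#' Palindromic k-mers are counted once per occurrence. Matching is exact
#' (no mismatches). Positions whose k-mer window covers a non-ACGT base, and
#' the trailing `k - 1` positions with no full window, are unscored (`NA`)
#' and treated as unmappable.
#'
#' @param genome a `composite_genome` or named [Biostrings::DNAStringSet].
#' @param k k-mer length in bp (default 150, the read length the track is
#'   meant to filter).
#' @return a `mappability_track`: list with `k` and `scores`, a named list of
#'   per-contig numeric vectors (length = contig length) of scores in
#'   `(0, 1]` or `NA`.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = "AACCGGTT"))
#' compute_mappability(g, k = 4)$scores$chr
#' @export
compute_mappability <- function(genome, k = 150) {
  stopifnot(k >= 1)
  seqs <- if (inherits(genome, "composite_genome")) genome$seq else genome
  stopifnot(!is.null(names(seqs)))
  chr <- as.character(seqs)
  counts <- kmer_occurrence_counts(toupper(chr), as.integer(k))
  scores <- lapply(counts, function(v) 1 / v)
  names(scores) <- names(seqs)
  structure(list(k = as.integer(k), scores = scores),
            class = "mappability_track")
}

#' @export
print.mappability_track <- function(x, ...) {
  cat("mappability_track: k =", x$k, "\n")
  for (nm in names(x$scores)) {
    sc <- x$scores[[nm]]
    cat(sprintf("  %s: %d positions, %d mappable\n", nm, length(sc),
                sum(!is.na(sc) & sc == 1)))
  }
  invisible(x)
}

#' Extract maximal mappable intervals from a mappability track
#'
#' Returns the maximal runs of positions with score exactly 1, merged per
#' contig, as a [GenomicRanges::GRanges] (1-based closed coordinates, the
#' Bioconductor convention; BED export via [write_mappable_bed()] converts
#' to 0-based half-open).
#'
#' @param track a `mappability_track`.
#' @return a `GRanges` of mappable intervals (may be empty).
#' @export
mappable_regions <- function(track) {
  stopifnot(inherits(track, "mappability_track"))
  per <- lapply(names(track$scores), function(nm) {
    sc <- track$scores[[nm]]
    ok <- !is.na(sc) & sc == 1
    if (!any(ok)) return(NULL)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(seqnames = nm, start = starts[r$values], end = ends[r$values])
  })
  per <- Filter(Negate(is.null), per)
  seqlens <- setNames(lengths(track$scores), names(track$scores))
  if (length(per) == 0) {
    return(GenomicRanges::GRanges(seqlengths = seqlens))
  }
  df <- do.call(rbind, per)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$seqnames, levels = names(track$scores)),
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    seqlengths = seqlens
  )
  GenomicRanges::reduce(gr)
}

#' Write mappable intervals to BED
#'
#' Three-column BED, 0-based half-open, via [rtracklayer::export.bed()].
#'
#' @param regions a `GRanges` (e.g. from [mappable_regions()]).
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_mappable_bed <- function(regions, path) {
  rtracklayer::export.bed(regions, path)
  invisible(path)
}

#' Read mappable intervals from BED
#'
#' @param path BED path (0-based half-open on disk).
#' @return a `GRanges` (1-based closed).
#' @export
read_mappable_bed <- function(path) {
  rtracklayer::import.bed(path)
}
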