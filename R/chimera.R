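#' Detect candidate inter-strain recombinant read pairs
#'
#' A read pair is a candidate recombinant ("chimeric") when its two mates
#' align to the two different symbiont strain genomes AND each mate's aligned
#' span overlaps (by at least 1 bp) a uniquely-mappable (mappability == 1)
#' interval on its own contig. The mappability anchor ensures each end sits
#' in sequence unique to one strain genome, so the cross-strain pairing is
#' not an artifact of the strains' shared sequence.
#'
#' Filtering ([filter_alignments()]) is applied before detection. Two
#' normalisations are reported: per alignment record (chimeric pairs divided
#' by total retained alignment records, each mate counting once) and per pair
#' (chimeric pairs divided by total retained read pairs) — the "1 in N
#' alignments" convention corresponds to `fraction_per_pair` when N counts
#' pair-level alignments.
#'
#' @param aln an `alignment_set` with mate information.
#' @param track a `mappability_track` over the composite genome.
#' @param strains character pair: the two symbiont contig names.
#' @param params [filter_params()] applied before detection.
#' @return a `chimera_report`: list with `chimeric_pair_count`,
#'   `total_alignments`, `total_pairs`, `fraction_per_alignment`,
#'   `fraction_per_pair`, and `pairs` (data frame: `qname`, per-mate contig
#'   and start).
#' @export
detect_chimeric_pairs <- function(aln, track, strains,
                                  params = filter_params()) {
  stopifnot(inherits(aln, "alignment_set"),
            inherits(track, "mappability_track"), length(strains) == 2L)
  if (strains[1] == strains[2]) stop("the two strain contigs must differ")
  aln <- filter_alignments(aln, params)
  total_alignments <- nrow(aln)
  total_pairs <- sum(aln$is_paired, na.rm = TRUE) / 2

  if (!any(aln$is_paired, na.rm = TRUE)) {
    warning("no paired records: chimeric pair count is 0")
  }

  # candidate mates: on one strain with the mate on the other
  onA <- aln$contig == strains[1] & aln$mate_contig %in% strains[2] &
    aln$is_paired
  onB <- aln$contig == strains[2] & aln$mate_contig %in% strains[1] &
    aln$is_paired
  cand <- aln[which(onA | onB), , drop = FALSE]

  empty_pairs <- data.frame(
    qname = character(0), contig_A = character(0), start_A = integer(0),
    contig_B = character(0), start_B = integer(0), stringsAsFactors = FALSE
  )
  result <- function(pairs) {
    n <- nrow(pairs)
    structure(list(
      chimeric_pair_count = n,
      total_alignments = total_alignments,
      total_pairs = total_pairs,
      fraction_per_alignment = if (total_alignments > 0) {
        n / total_alignments
      } else NA_real_,
      fraction_per_pair = if (total_pairs > 0) n / total_pairs else NA_real_,
      pairs = pairs
    ), class = "chimera_report")
  }
  if (nrow(cand) == 0) return(result(empty_pairs))

  # a mate is anchored when its span overlaps >= 1 mappable position
  overlaps_mappable <- function(rows) {
    out <- logical(nrow(rows))
    for (ct in unique(rows$contig)) {
      sc <- track$scores[[ct]]
      if (is.null(sc)) stop("contig not in mappability track: ", ct)
      ok <- !is.na(sc) & sc == 1
      if (!any(ok)) next
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      map_ir <- IRanges::IRanges(start = starts[r$values],
                                 end = ends[r$values])
      sel <- rows$contig == ct
      spans <- IRanges::IRanges(start = rows$start[sel],
                                width = rows$len[sel])
      out[sel] <- IRanges::overlapsAny(spans, map_ir)
    }
    out
  }
  cand <- cand[overlaps_mappable(cand), , drop = FALSE]
  if (nrow(cand) == 0) return(result(empty_pairs))

  # both anchored mates of a pair must have survived
  a <- cand[cand$contig == strains[1], c("qname", "contig", "start")]
  b <- cand[cand$contig == strains[2], c("qname", "contig", "start")]
  m <- merge(a, b, by = "qname", suffixes = c("_A", "_B"))
  names(m) <- c("qname", "contig_A", "start_A", "contig_B", "start_B")
  result(m[order(m$qname), , drop = FALSE])
}

#' @export
print.chimera_report <- function(x, ...) {
  cat(sprintf(
    "chimera_report: %d chimeric pair(s) / %d alignments (%d pairs)\n",
    x$chimeric_pair_count, x$total_alignments, x$total_pairs
  ))
  cat(sprintf("  fraction per alignment: %.3g\n  fraction per pair: %.3g\n",
              x$fraction_per_alignment, x$fraction_per_pair))
  invisible(x)
}

#' Write a chimera report to TSV
#'
#' @param report a `chimera_report`.
#' @param path summary TSV path.
#' @param detail_path optional per-pair detail TSV path.
#' @param sample optional sample label.
#' @return the summary data frame, invisibly.
#' @export
write_chimera_tsv <- function(report, path, detail_path = NULL,
                              sample = NA_character_) {
  df <- data.frame(
    sample = sample,
    chimeric_pairs = report$chimeric_pair_count,
    total_alignments = report$total_alignments,
    total_pairs = report$total_pairs,
    fraction_per_alignment = report$fraction_per_alignment,
    fraction_per_pair = report$fraction_per_pair
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(detail_path)) {
    write.table(report$pairs, detail_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(df)
}
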