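# SAM flag bits consumed/emitted here
FLAG_PAIRED <- 0x1
FLAG_MATE1 <- 0x40
FLAG_MATE2 <- 0x80
FLAG_SECONDARY <- 0x100
FLAG_DUP <- 0x400
FLAG_SUPPLEMENTARY <- 0x800

#' Write an alignment set as SAM
#'
#' Emits a valid header (`@SQ` line per contig) and one record per row.
#' Positions are written 1-based per the SAM standard; aligned spans become
#' fully-matching CIGARs (`<len>M`); sequences and qualities are omitted
#' (`*`). Duplicate, secondary and paired states map to flag bits 0x400,
#' 0x100 and 0x1 (+0x40/0x80 for first/second mate).
#'
#' @param aln an `alignment_set`.
#' @param contig_lengths named integer vector of all reference contig
#'   lengths (e.g. `Biostrings::width()` of the genome).
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, contig_lengths, path) {
  stopifnot(inherits(aln, "alignment_set"), !is.null(names(contig_lengths)))
  missing <- setdiff(unique(aln$contig), names(contig_lengths))
  if (length(missing) > 0) {
    stop("contig(s) not in header lengths: ", paste(missing, collapse = ", "))
  }
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
            as.integer(contig_lengths))
  )
  flag <- ifelse(aln$is_paired, FLAG_PAIRED, 0L) +
    ifelse(aln$is_secondary, FLAG_SECONDARY, 0L) +
    ifelse(aln$is_dup, FLAG_DUP, 0L)
  # first/second-of-pair by occurrence order of the query name
  second <- duplicated(aln$qname) & aln$is_paired
  flag <- flag + ifelse(aln$is_paired & !second, FLAG_MATE1, 0L) +
    ifelse(second, FLAG_MATE2, 0L)
  rnext <- ifelse(is.na(aln$mate_contig), "*",
                  ifelse(aln$mate_contig == aln$contig, "=", aln$mate_contig))
  pnext <- ifelse(is.na(aln$mate_start), 0L, aln$mate_start)
  qname <- ifelse(is.na(aln$qname), sprintf("r%d", seq_len(nrow(aln))),
                  aln$qname)
  recs <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t0\t*\t*",
    qname, as.integer(flag), aln$contig, as.integer(aln$start),
    as.integer(aln$mapq), as.integer(aln$len), rnext, as.integer(pnext)
  )
  writeLines(c(header, recs), path)
  invisible(path)
}

# reference-space width of a simple CIGAR (M/D/N/=/X consume reference)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    w <- 0L
    for (tk in toks) {
      op <- substr(tk, nchar(tk), nchar(tk))
      if (op %in% c("M", "D", "N", "=", "X")) {
        w <- w + as.integer(substr(tk, 1, nchar(tk) - 1))
      }
    }
    w
  }, integer(1), USE.NAMES = FALSE)
}

#' Read alignments from SAM/BAM into an alignment set
#'
#' Uses Rsamtools to parse the file (SAM input is converted to BAM in a
#' temporary location first). Unmapped records are dropped; 1-based SAM
#' positions are kept (the package convention); the duplicate flag (0x400)
#' and secondary/supplementary flags (0x100/0x800) populate `is_dup` and
#' `is_secondary`.
#'
#' @param path SAM or BAM path.
#' @return an `alignment_set`.
#' @export
read_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("read_sam() requires the Rsamtools package")
  }
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (is_bam) {
    path
  } else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
               "mpos")
    )
  )[[1]]
  mapped <- !is.na(res$pos)
  flag <- res$flag[mapped]
  df <- data.frame(
    qname = res$qname[mapped],
    contig = as.character(res$rname[mapped]),
    start = res$pos[mapped],
    len = cigar_ref_width(res$cigar[mapped]),
    mapq = res$mapq[mapped],
    is_dup = bitwAnd(flag, FLAG_DUP) > 0,
    is_secondary = bitwAnd(flag, FLAG_SECONDARY + FLAG_SUPPLEMENTARY) > 0,
    is_paired = bitwAnd(flag, FLAG_PAIRED) > 0,
    mate_contig = as.character(res$mrnm[mapped]),
    mate_start = res$mpos[mapped],
    stringsAsFactors = FALSE
  )
  as_alignment_set(df)
}
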