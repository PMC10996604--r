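#' Specification for a synthetic aligned read library
#'
#' Reads are emitted directly as alignment records with ground-truth
#' placement; there is no FASTQ stage and no aligner emulation beyond MAPQ
#' and flag plumbing. Two placement modes are available:
#'
#' * `"tiling"` — deterministic, evenly spaced starts treating each contig as
#'   circular (reads spanning the contig end are emitted as two truncated
#'   records). For an integer target depth on a contig whose length is a
#'   multiple of `read_length`, every position is covered by exactly the
#'   target number of reads, so mean depth over any subset of positions
#'   equals the target exactly.
#' * `"random"` — uniform-random start positions on the same circular
#'   convention, so expected coverage equals the target at every position;
#'   measured mean depth converges to the target as depth grows.
#'
#' Duplicate and secondary records are extra copies of existing reads carrying
#' the corresponding SAM flag, so default filtering restores the target depth.
#'
#' @param depths named numeric vector: target mean depth per contig
#'   (reads x read_length / contig_length). Contigs absent from the vector
#'   get no reads.
#' @param read_length read length in bp (default 150, matching the k used
#'   for mappability).
#' @param paired emit mate information (pairs of consecutive reads share a
#'   query name)?
#' @param mode `"tiling"` or `"random"`.
#' @param duplicate_fraction,secondary_fraction fraction of primary records
#'   to duplicate with the duplicate / secondary flag set.
#' @param mapq MAPQ assigned to records (default 60, above the default
#'   filtering threshold).
#' @param seed integer RNG seed (random mode and flag sampling).
#' @return an object of class `sim_library_spec`.
#' @export
sim_library_spec <- function(depths, read_length = 150, paired = TRUE,
                             mode = c("tiling", "random"),
                             duplicate_fraction = 0, secondary_fraction = 0,
                             mapq = 60, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(
    is.numeric(depths), !is.null(names(depths)), all(depths >= 0),
    read_length >= 1,
    duplicate_fraction >= 0, duplicate_fraction <= 1,
    secondary_fraction >= 0, secondary_fraction <= 1,
    mapq >= 0
  )
  structure(
    list(depths = depths, read_length = as.integer(read_length),
         paired = isTRUE(paired), mode = mode,
         duplicate_fraction = duplicate_fraction,
         secondary_fraction = secondary_fraction,
         mapq = as.integer(mapq), seed = as.integer(seed)),
    class = "sim_library_spec"
  )
}

# empty alignment table with the canonical column set
empty_alignments <- function() {
  as_alignment_set(data.frame(
    qname = character(0), contig = character(0), start = integer(0),
    len = integer(0), mapq = integer(0), is_dup = logical(0),
    is_secondary = logical(0), is_paired = logical(0),
    mate_contig = character(0), mate_start = integer(0),
    stringsAsFactors = FALSE
  ))
}

#' Coerce a data frame to an alignment set
#'
#' An alignment set is a data frame with one row per alignment record and
#' columns `qname`, `contig`, `start` (1-based leftmost aligned position),
#' `len` (aligned span in bp), `mapq`, `is_dup`, `is_secondary`, `is_paired`,
#' `mate_contig`, `mate_start`.
#'
#' @param df a data frame with at least `contig`, `start`, `len`, `mapq`.
#' @return the data frame with class `alignment_set`.
#' @export
as_alignment_set <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("contig", "start", "len", "mapq") %in% names(df)))
  defaults <- list(qname = NA_character_, is_dup = FALSE, is_secondary = FALSE,
                   is_paired = FALSE, mate_contig = NA_character_,
                   mate_start = NA_integer_)
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- rep(defaults[[nm]], nrow(df))
  }
  df <- df[, c("qname", "contig", "start", "len", "mapq", "is_dup",
               "is_secondary", "is_paired", "mate_contig", "mate_start")]
  class(df) <- c("alignment_set", "data.frame")
  df
}

# greedy decomposition of an integer depth into divisors of the read length,
# largest first; each term is one exactly-uniform circular tiling lane
tiling_lane_depths <- function(depth_int, read_length) {
  divs <- sort(Filter(function(d) read_length %% d == 0,
                      seq_len(read_length)), decreasing = TRUE)
  lane_depth <- read_length / divs # achievable per-lane depths, descending
  out <- integer(0)
  rem <- depth_int
  for (d in sort(unique(lane_depth), decreasing = TRUE)) {
    while (rem >= d) {
      out <- c(out, d)
      rem <- rem - d
    }
  }
  out
}

# Treating the contig as circular, split reads overhanging the end into an
# end piece and a start piece ("/w" suffix, left unpaired). Circularity makes
# expected (random mode) or realised (tiling mode) coverage uniform, so mean
# depth over any window is calibrated to the target, not just the
# whole-contig mean.
split_circular <- function(df, L, rl, contig) {
  over <- df$start0 + df$len > L
  main <- df
  main$len <- ifelse(over, L - main$start0, main$len)
  wrap <- df[over, , drop = FALSE]
  if (nrow(wrap) > 0) {
    wrap$len <- wrap$start0 + rl - L
    wrap$start0 <- 0L
    wrap$qname <- paste0(wrap$qname, "/w")
  }
  out <- rbind(main, wrap)
  out$contig <- contig
  out
}

# circular tiling reads for one contig: starts (0-based) on a grid of spacing
# `u`; reads overhanging the end wrap and are emitted as two truncated records
tile_contig <- function(contig, L, depth, rl, qprefix) {
  recs <- list()
  int_depth <- floor(depth + 1e-9)
  lanes <- tiling_lane_depths(int_depth, rl)
  lane_i <- 0L
  for (dl in lanes) {
    lane_i <- lane_i + 1L
    u <- rl / dl
    starts0 <- seq(0L, L - 1L, by = u)
    recs[[length(recs) + 1L]] <- data.frame(
      qname = sprintf("%s:%s:L%d:%d", qprefix, contig, lane_i,
                      seq_along(starts0)),
      start0 = starts0, len = rl, stringsAsFactors = FALSE
    )
  }
  frac <- depth - int_depth
  if (frac > 1e-9) {
    n <- round(frac * L / rl)
    if (n > 0) {
      starts0 <- floor((seq_len(n) - 1) * L / n)
      recs[[length(recs) + 1L]] <- data.frame(
        qname = sprintf("%s:%s:frac:%d", qprefix, contig, seq_len(n)),
        start0 = starts0, len = rl, stringsAsFactors = FALSE
      )
    }
  }
  if (length(recs) == 0) return(NULL)
  split_circular(do.call(rbind, recs), L, rl, contig)
}

#' Simulate an aligned read set over a composite genome
#'
#' See [sim_library_spec()] for the placement modes and the depth-calibration
#' guarantees. Pairing links consecutive tiled (or sampled) reads on the same
#' contig as mates; wrapped edge pieces in tiling mode stay unpaired.
#'
#' @param genome a `composite_genome`.
#' @param spec a [sim_library_spec()]; every contig named in `spec$depths`
#'   must exist in `genome`.
#' @return an `alignment_set` (see [as_alignment_set()]).
#' @examples
#' g <- generate_composite_genome(sim_genome_spec(
#'   host_autosome_lengths = c("2L" = 3000), symbiont_length = 1500,
#'   seed = 1
#' ))
#' aln <- simulate_alignments(g, sim_library_spec(depths = c("2L" = 2)))
#' nrow(aln)
#' @export
simulate_alignments <- function(genome, spec) {
  stopifnot(inherits(genome, "composite_genome"),
            inherits(spec, "sim_library_spec"))
  lens <- contig_lengths(genome)
  missing <- setdiff(names(spec$depths), names(lens))
  if (length(missing) > 0) {
    stop("target depth given for contig(s) absent from genome: ",
         paste(missing, collapse = ", "))
  }
  rl <- spec$read_length
  per_contig <- lapply(names(spec$depths), function(ct) {
    d <- spec$depths[[ct]]
    if (d <= 0) return(NULL)
    L <- lens[[ct]]
    if (spec$mode == "tiling") {
      tile_contig(ct, L, d, rl, "tile")
    } else {
      n <- round(d * L / rl)
      if (n == 0) return(NULL)
      if (L < rl) stop("contig ", ct, " shorter than read length")
      starts0 <- with_seed(
        derive_seed(spec$seed, paste0("reads:", ct)),
        sample.int(L, n, replace = TRUE) - 1L
      )
      split_circular(data.frame(
        qname = sprintf("rnd:%s:%d", ct, seq_len(n)),
        start0 = starts0, len = rl, stringsAsFactors = FALSE
      ), L, rl, ct)
    }
  })
  df <- do.call(rbind, Filter(Negate(is.null), per_contig))
  if (is.null(df) || nrow(df) == 0) return(empty_alignments())

  df$start <- as.integer(df$start0 + 1L) # 1-based
  df$mapq <- spec$mapq
  df$is_dup <- FALSE
  df$is_secondary <- FALSE
  df$is_paired <- FALSE
  df$mate_contig <- NA_character_
  df$mate_start <- NA_integer_

  if (spec$paired) {
    # pair consecutive non-wrapped reads per contig
    for (ct in unique(df$contig)) {
      idx <- which(df$contig == ct & !grepl("/w$", df$qname))
      npair <- length(idx) %/% 2L
      if (npair == 0) next
      i1 <- idx[seq_len(npair) * 2L - 1L]
      i2 <- idx[seq_len(npair) * 2L]
      pair_name <- sprintf("pair:%s:%d", ct, seq_len(npair))
      df$qname[i1] <- pair_name
      df$qname[i2] <- pair_name
      df$is_paired[c(i1, i2)] <- TRUE
      df$mate_contig[i1] <- ct
      df$mate_contig[i2] <- ct
      df$mate_start[i1] <- df$start[i2]
      df$mate_start[i2] <- df$start[i1]
    }
  }

  add_flagged_copies <- function(df, fraction, flag_col, tag) {
    n_extra <- round(fraction * nrow(df))
    if (n_extra == 0) return(df)
    pick <- with_seed(
      derive_seed(spec$seed, paste0("flag:", tag)),
      sample.int(nrow(df), n_extra, replace = n_extra > nrow(df))
    )
    extra <- df[pick, , drop = FALSE]
    extra[[flag_col]] <- TRUE
    extra$qname <- sprintf("%s/%s%d", extra$qname, tag, seq_len(n_extra))
    rbind(df, extra)
  }
  df <- add_flagged_copies(df, spec$duplicate_fraction, "is_dup", "dup")
  df <- add_flagged_copies(df, spec$secondary_fraction, "is_secondary", "sec")

  rownames(df) <- NULL
  as_alignment_set(df[, c("qname", "contig", "start", "len", "mapq", "is_dup",
                          "is_secondary", "is_paired", "mate_contig",
                          "mate_start")])
}

#' Inject cross-strain chimeric read pairs into an alignment set
#'
#' Adds exactly `n` read pairs whose two mates sit on the two different
#' symbiont contigs — the signature of a candidate inter-strain recombinant.
#' With `placement = "mappable"` both mates lie wholly inside runs of
#' mappability-1 positions (so the detector must find them); with
#' `placement = "unmappable"` each mate's span avoids every mappable position
#' (so a correct detector must not count them). Placement is deterministic:
#' intervals are used in genomic order, cycling as needed.
#'
#' @param aln an `alignment_set`.
#' @param n number of pairs to add (0 returns `aln` unchanged).
#' @param track a `mappability_track` over the same genome.
#' @param strains character pair of symbiont contig names.
#' @param placement `"mappable"` or `"unmappable"`.
#' @param read_length read length of injected mates.
#' @param mapq MAPQ of injected mates.
#' @return the augmented `alignment_set`.
#' @export
inject_chimeric_pairs <- function(aln, n, track, strains,
                                  placement = c("mappable", "unmappable"),
                                  read_length = 150, mapq = 60) {
  placement <- match.arg(placement)
  stopifnot(inherits(aln, "alignment_set"), n >= 0, length(strains) == 2L)
  if (strains[1] == strains[2]) stop("the two strain contigs must differ")
  if (n == 0) return(aln)

  anchor_starts <- function(contig) {
    sc <- track$scores[[contig]]
    if (is.null(sc)) stop("contig not in mappability track: ", contig)
    if (placement == "mappable") {
      ok <- !is.na(sc) & sc == 1
    } else {
      # span may not touch any mappable position; treat unscored tail as safe
      ok <- is.na(sc) | sc != 1
      ok[is.na(sc)] <- TRUE
      ok <- ok & seq_along(sc) <= length(sc) - read_length + 1L
      # every position of the span must be non-mappable
    }
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts, width = r$lengths)[r$values, ,
                                                          drop = FALSE]
    runs <- runs[runs$width >= read_length, , drop = FALSE]
    if (nrow(runs) == 0) {
      stop("no ", placement, " interval of length >= ", read_length,
           " on contig ", contig)
    }
    # one anchor per run start; cycle runs if n exceeds run count
    runs$start[((seq_len(n) - 1L) %% nrow(runs)) + 1L]
  }
  sA <- anchor_starts(strains[1])
  sB <- anchor_starts(strains[2])
  qn <- sprintf("chimera:%d", seq_len(n))
  extra <- data.frame(
    qname = rep(qn, 2L),
    contig = rep(strains, each = n),
    start = c(sA, sB),
    len = read_length, mapq = mapq,
    is_dup = FALSE, is_secondary = FALSE, is_paired = TRUE,
    mate_contig = rep(rev(strains), each = n),
    mate_start = c(sB, sA),
    stringsAsFactors = FALSE
  )
  out <- rbind(as.data.frame(aln), extra)
  rownames(out) <- NULL
  as_alignment_set(out)
}
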