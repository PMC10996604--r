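#' Alignment filtering parameters
#'
#' Defaults reproduce the standard titer-pipeline filter: keep primary,
#' non-duplicate alignments with MAPQ strictly greater than 20. The MAPQ
#' threshold is exclusive (`mapq > mapq_min`); `mapq_min = 0` is an inclusive
#' bypass that keeps every record regardless of MAPQ.
#'
#' @param mapq_min exclusive MAPQ threshold (default 20); 0 disables the
#'   MAPQ filter.
#' @param drop_duplicates drop duplicate-flagged records (default TRUE).
#' @param drop_secondary drop secondary/supplementary records (default TRUE).
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(mapq_min = 20, drop_duplicates = TRUE,
                          drop_secondary = TRUE) {
  stopifnot(mapq_min >= 0)
  structure(list(mapq_min = as.integer(mapq_min),
                 drop_duplicates = isTRUE(drop_duplicates),
                 drop_secondary = isTRUE(drop_secondary)),
            class = "filter_params")
}

#' Filter an alignment set
#'
#' Order-preserving subset of records passing the MAPQ and flag filters of
#' [filter_params()].
#'
#' @param aln an `alignment_set`.
#' @param params a [filter_params()].
#' @return the filtered `alignment_set` (possibly empty).
#' @examples
#' aln <- as_alignment_set(data.frame(
#'   contig = "c", start = 1, len = 10, mapq = c(10, 20, 21, 60)
#' ))
#' nrow(filter_alignments(aln, filter_params()))
#' @export
filter_alignments <- function(aln, params = filter_params()) {
  stopifnot(inherits(aln, "alignment_set"), inherits(params, "filter_params"))
  keep <- rep(TRUE, nrow(aln))
  if (params$mapq_min > 0) keep <- keep & aln$mapq > params$mapq_min
  if (params$drop_duplicates) keep <- keep & !aln$is_dup
  if (params$drop_secondary) keep <- keep & !aln$is_secondary
  out <- aln[keep, , drop = FALSE]
  rownames(out) <- NULL
  as_alignment_set(out)
}

#' Contig grouping for depth summaries
#'
#' @param host_autosomes host contig names pooled into the titer denominator.
#' @param symbionts character vector (typically length 2) of symbiont contig
#'   names; each forms its own group.
#' @return named list of contig-name vectors, one element per group
#'   (`host` plus one group per symbiont).
#' @export
contig_groups <- function(host_autosomes = c("2L", "2R", "3L", "3R", "4"),
                          symbionts = c("wMel", "wRi")) {
  stopifnot(length(intersect(host_autosomes, symbionts)) == 0)
  c(list(host = host_autosomes),
    setNames(as.list(symbionts), symbionts))
}

#' Mean depth over mappable positions, per contig and contig group
#'
#' Per-position depth is the number of (already filtered) alignments whose
#' aligned span covers that position; an alignment contributes to every
#' mappable position it overlaps even if it also covers unmappable ones.
#' Group means are pooled over all mappable positions of the group's contigs
#' (position-weighted), not means of per-contig means.
#'
#' @param aln a filtered `alignment_set`.
#' @param track a `mappability_track` covering every contig in the groups.
#' @param groups named list of contig-name vectors, as from
#'   [contig_groups()].
#' @return a `depth_summary`: list with `per_contig` and `per_group` data
#'   frames (`mappable_positions`, `depth_sum`, `mean_depth`; the mean is
#'   `NA` for a group with zero mappable positions).
#' @export
mean_mappable_depth <- function(aln, track, groups) {
  stopifnot(inherits(aln, "alignment_set"),
            inherits(track, "mappability_track"))
  all_contigs <- unlist(groups, use.names = FALSE)
  missing <- setdiff(all_contigs, names(track$scores))
  if (length(missing) > 0) {
    stop("contig(s) missing from mappability track: ",
         paste(missing, collapse = ", "))
  }
  per_contig <- do.call(rbind, lapply(names(groups), function(grp) {
    do.call(rbind, lapply(groups[[grp]], function(ct) {
      sc <- track$scores[[ct]]
      L <- length(sc)
      ok <- !is.na(sc) & sc == 1
      n_map <- sum(ok)
      rows <- aln[aln$contig == ct, , drop = FALSE]
      if (nrow(rows) > 0 && n_map > 0) {
        cov <- IRanges::coverage(
          IRanges::IRanges(start = rows$start, width = rows$len), width = L
        )
        r <- rle(ok)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        map_ir <- IRanges::IRanges(start = starts[r$values],
                                   end = ends[r$values])
        dsum <- sum(as.numeric(sum(IRanges::Views(cov, map_ir))))
      } else {
        dsum <- 0
      }
      data.frame(contig = ct, group = grp, mappable_positions = n_map,
                 depth_sum = dsum,
                 mean_depth = if (n_map > 0) dsum / n_map else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  per_group <- do.call(rbind, lapply(names(groups), function(grp) {
    rows <- per_contig[per_contig$group == grp, , drop = FALSE]
    n_map <- sum(rows$mappable_positions)
    dsum <- sum(rows$depth_sum)
    data.frame(group = grp, mappable_positions = n_map, depth_sum = dsum,
               mean_depth = if (n_map > 0) dsum / n_map else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per_contig) <- rownames(per_group) <- NULL
  structure(list(per_contig = per_contig, per_group = per_group),
            class = "depth_summary")
}

#' @export
print.depth_summary <- function(x, ...) {
  cat("depth_summary (mean depth over mappable positions):\n")
  print(x$per_group, row.names = FALSE)
  invisible(x)
}

#' Genomic titer and proportion of total coverage
#'
#' Genomic titer of a symbiont is its mean depth over mappable positions
#' divided by the pooled mean depth of the host autosomes — an estimate of
#' symbiont genome copies per host genome copy. The proportion of total
#' coverage of each group (host and each symbiont) is that group's mean
#' depth over the sum of all group mean depths; the proportions sum to 1.
#'
#' @param depths a `depth_summary` whose groups are `host` plus one group
#'   per symbiont.
#' @return a `titer_estimate`: list with `titer` (named numeric, one per
#'   symbiont), `proportion` (named numeric over all groups, summing to 1),
#'   and the group `mean_depth`s.
#' @examples
#' # symbiont at 45x over host at 10x gives titer 4.5
#' @export
genomic_titer <- function(depths) {
  stopifnot(inherits(depths, "depth_summary"))
  pg <- depths$per_group
  if (!"host" %in% pg$group) stop("depth summary lacks a 'host' group")
  host_mean <- pg$mean_depth[pg$group == "host"]
  if (is.na(host_mean)) stop("host group has no mappable positions")
  if (host_mean == 0) stop("host mean depth is 0: titer undefined")
  symb <- pg[pg$group != "host", , drop = FALSE]
  titer <- setNames(symb$mean_depth / host_mean, symb$group)
  means <- setNames(pg$mean_depth, pg$group)
  proportion <- means / sum(means)
  structure(list(titer = titer, proportion = proportion, mean_depth = means),
            class = "titer_estimate")
}

#' @export
print.titer_estimate <- function(x, ...) {
  cat("titer_estimate\n  genomic titer (symbiont/host):\n")
  for (nm in names(x$titer)) cat(sprintf("    %s: %.4g\n", nm, x$titer[[nm]]))
  cat("  proportion of total coverage:\n")
  for (nm in names(x$proportion)) {
    cat(sprintf("    %s: %.4g\n", nm, x$proportion[[nm]]))
  }
  invisible(x)
}

#' Write a per-sample titer summary as TSV
#'
#' One row per contig group with mappable position count, mean depth, titer
#' (symbionts only) and proportion of total coverage.
#'
#' @param depths a `depth_summary`.
#' @param titer the matching `titer_estimate`.
#' @param path output TSV path.
#' @param sample optional sample label column.
#' @return the written data frame, invisibly.
#' @export
write_titer_tsv <- function(depths, titer, path, sample = NA_character_) {
  pg <- depths$per_group
  df <- data.frame(
    sample = sample,
    contig_group = pg$group,
    mappable_positions = pg$mappable_positions,
    mean_depth = pg$mean_depth,
    titer = ifelse(pg$group %in% names(titer$titer),
                   unname(titer$titer[pg$group]), NA_real_),
    proportion_total_coverage = unname(titer$proportion[pg$group])
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
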