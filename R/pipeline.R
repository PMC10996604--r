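#' Titer time course over a set of per-week alignment sets
#'
#' Runs the core pipeline — filter, mean mappable depth, genomic titer,
#' symbiont-only frequency — for every sample and assembles one tidy row per
#' sample.
#'
#' @param alignments named list of `alignment_set`s, one per sample.
#' @param weeks numeric vector, the week of each sample (recycled names from
#'   `alignments` label rows).
#' @param track a `mappability_track` over the composite genome.
#' @param groups contig grouping from [contig_groups()]; the first symbiont
#'   listed is the focal strain for `p`.
#' @param params [filter_params()] applied to every sample.
#' @param replicates optional replicate label per sample (default 1).
#' @return a data frame with one row per sample: `sample`, `week`,
#'   `replicate`, per-group mean depths (`depth_<group>`), per-symbiont
#'   `titer_<strain>`, per-group `prop_<group>`, and `p` (focal-strain share
#'   of symbiont coverage; `NA` when both symbiont depths are 0).
#' @export
run_titer_timecourse <- function(alignments, weeks, track, groups,
                                 params = filter_params(),
                                 replicates = 1L) {
  stopifnot(is.list(alignments), length(alignments) == length(weeks))
  if (is.null(names(alignments))) {
    names(alignments) <- sprintf("sample%d", seq_along(alignments))
  }
  replicates <- rep_len(replicates, length(alignments))
  strains <- setdiff(names(groups), "host")
  rows <- lapply(seq_along(alignments), function(i) {
    aln <- filter_alignments(alignments[[i]], params)
    depths <- mean_mappable_depth(aln, track, groups)
    ti <- genomic_titer(depths)
    means <- setNames(depths$per_group$mean_depth, depths$per_group$group)
    dA <- means[[strains[1]]]
    dB <- means[[strains[2]]]
    row <- data.frame(sample = names(alignments)[i], week = weeks[i],
                      replicate = replicates[i])
    for (g in names(means)) row[[paste0("depth_", g)]] <- means[[g]]
    for (s in strains) row[[paste0("titer_", s)]] <- ti$titer[[s]]
    for (g in names(ti$proportion)) {
      row[[paste0("prop_", g)]] <- ti$proportion[[g]]
    }
    row$p <- if ((dA + dB) > 0) dA / (dA + dB) else NA_real_
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Competition report: selection, chimeras and titer fold change
#'
#' Composes the per-sample time course into the study's summary statistics:
#' the selection coefficient of the focal strain per replicate
#' ([estimate_selection()] on the symbiont-only frequencies), a chimeric
#' read-pair report per sample ([detect_chimeric_pairs()]), and the weekly
#' fold change of the focal strain's titer ([weekly_fold_change()]).
#'
#' @param timecourse output of [run_titer_timecourse()].
#' @param alignments the same named list of `alignment_set`s.
#' @param track the `mappability_track`.
#' @param groups contig grouping from [contig_groups()] (first symbiont =
#'   focal strain).
#' @param selection_window optional `c(t_start, t_end)` for the selection
#'   fit.
#' @param params [filter_params()].
#' @return a list with `selection` (a `selection_fit`), `chimera` (data
#'   frame, one row per sample) and `fold_change` (a `fold_change_fit`).
#' @export
run_competition_report <- function(timecourse, alignments, track, groups,
                                   selection_window = NULL,
                                   params = filter_params()) {
  strains <- setdiff(names(groups), "host")
  freq <- data.frame(week = timecourse$week, replicate = timecourse$replicate,
                     p = timecourse$p)
  freq <- freq[!is.na(freq$p), , drop = FALSE]
  freq$q <- 1 - freq$p
  class(freq) <- c("frequency_series", "data.frame")
  selection <- estimate_selection(freq, window = selection_window)

  chimera <- do.call(rbind, lapply(names(alignments), function(nm) {
    rep <- detect_chimeric_pairs(alignments[[nm]], track, strains, params)
    data.frame(sample = nm, chimeric_pairs = rep$chimeric_pair_count,
               total_alignments = rep$total_alignments,
               total_pairs = rep$total_pairs,
               fraction_per_alignment = rep$fraction_per_alignment,
               fraction_per_pair = rep$fraction_per_pair)
  }))

  titer_col <- paste0("titer_", strains[1])
  ts <- data.frame(week = timecourse$week, replicate = timecourse$replicate,
                   titer = timecourse[[titer_col]])
  fold <- weekly_fold_change(ts)

  list(selection = selection, chimera = chimera, fold_change = fold)
}

#' Run the full pipeline from a declarative config
#'
#' The config (a YAML file or an equivalent named list) names the inputs and
#' parameters; everything else is derived. Required fields: `genome_fasta`,
#' `strains` (two symbiont contig names), and `samples` — a list of
#' `(name, week, sam)` entries (optionally `replicate`). Optional fields with
#' defaults: `k` (150), `mapq_min` (20), `drop_duplicates`/`drop_secondary`
#' (true), `host_autosomes` (2L,2R,3L,3R,4), `selection_window`, `out_dir`.
#'
#' Outputs written to `out_dir`: `timecourse.tsv`, `selection.tsv`,
#' `chimera.tsv`, `fold_change.tsv`, `mappable.bed` and a `manifest.json`
#' recording inputs and parameters. Reruns on identical inputs are
#' byte-identical.
#'
#' @param config path to a YAML config or a named list.
#' @return invisibly, a list with `timecourse` and the
#'   [run_competition_report()] bundle.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config),
            all(c("genome_fasta", "strains", "samples") %in% names(config)))
  k <- config$k %||% 150
  host_autosomes <- config$host_autosomes %||% c("2L", "2R", "3L", "3R", "4")
  params <- filter_params(
    mapq_min = config$mapq_min %||% 20,
    drop_duplicates = config$drop_duplicates %||% TRUE,
    drop_secondary = config$drop_secondary %||% TRUE
  )
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  genome <- read_genome_fasta(config$genome_fasta,
                              symbiont_names = unlist(config$strains),
                              host_autosomes = host_autosomes)
  track <- compute_mappability(genome, k = k)
  groups <- contig_groups(host_autosomes = host_autosomes,
                          symbionts = unlist(config$strains))

  alignments <- lapply(config$samples, function(s) read_sam(s$sam))
  names(alignments) <- vapply(config$samples, `[[`, "", "name")
  weeks <- vapply(config$samples, function(s) as.numeric(s$week), 0)
  reps <- vapply(config$samples,
                 function(s) as.integer(s$replicate %||% 1L), 0L)

  tc <- run_titer_timecourse(alignments, weeks, track, groups, params, reps)
  window <- if (!is.null(config$selection_window)) {
    as.numeric(unlist(config$selection_window))
  } else NULL
  report <- run_competition_report(tc, alignments, track, groups,
                                   selection_window = window, params = params)

  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(tc, "timecourse.tsv")
  tsv(as.data.frame(report$selection), "selection.tsv")
  tsv(report$chimera, "chimera.tsv")
  tsv(as.data.frame(report$fold_change), "fold_change.tsv")
  write_mappable_bed(mappable_regions(track), file.path(out_dir,
                                                        "mappable.bed"))
  manifest <- list(
    genome_fasta = config$genome_fasta,
    k = k, mapq_min = params$mapq_min,
    drop_duplicates = params$drop_duplicates,
    drop_secondary = params$drop_secondary,
    host_autosomes = host_autosomes,
    strains = unlist(config$strains),
    selection_window = window,
    samples = lapply(config$samples, function(s) s[c("name", "week", "sam")])
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message("pipeline: ", length(alignments), " sample(s), outputs in ",
          out_dir)
  invisible(list(timecourse = tc, report = report))
}
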