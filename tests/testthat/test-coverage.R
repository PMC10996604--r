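test_that("MAPQ filter is strictly greater-than, with an inclusive bypass at 0", {
  aln <- as_alignment_set(data.frame(
    contig = "c", start = c(1, 5, 9, 13), len = 10, mapq = c(10, 20, 21, 60)
  ))
  kept <- filter_alignments(aln, filter_params())
  expect_equal(kept$mapq, c(21, 60))

  dup <- as_alignment_set(data.frame(
    contig = "c", start = 1, len = 10, mapq = 60, is_dup = TRUE
  ))
  expect_equal(nrow(filter_alignments(dup, filter_params())), 0L)
  expect_equal(nrow(filter_alignments(dup, filter_params(
    drop_duplicates = FALSE
  ))), 1L)

  # all filters disabled: identity, order preserved
  off <- filter_params(mapq_min = 0, drop_duplicates = FALSE,
                       drop_secondary = FALSE)
  mixed <- as_alignment_set(data.frame(
    contig = "c", start = c(3, 1, 2), len = 5, mapq = c(0, 60, 10),
    is_dup = c(TRUE, FALSE, FALSE), is_secondary = c(FALSE, TRUE, FALSE)
  ))
  expect_equal(as.data.frame(filter_alignments(mixed, off)),
               as.data.frame(mixed))
})

test_that("mean mappable depth matches trivial cases and the pileup oracle", {
  # one 10 bp alignment on a fully mappable 100-position contig
  track <- structure(list(k = 1L, scores = list(c1 = rep(1, 100))),
                     class = "mappability_track")
  aln <- as_alignment_set(data.frame(contig = "c1", start = 11, len = 10,
                                     mapq = 60))
  ds <- mean_mappable_depth(aln, track, list(host = "c1"))
  expect_equal(ds$per_group$mean_depth, 0.1)

  # alignment overlapping only unmappable positions contributes nothing
  sc <- rep(1, 100)
  sc[40:60] <- 0.5
  track2 <- structure(list(k = 1L, scores = list(c1 = sc)),
                      class = "mappability_track")
  aln2 <- as_alignment_set(data.frame(contig = "c1", start = 45, len = 10,
                                      mapq = 60))
  ds2 <- mean_mappable_depth(aln2, track2, list(host = "c1"))
  expect_equal(ds2$per_group$mean_depth, 0)

  # random alignment set equals the naive per-base pileup oracle exactly
  L <- 5000
  g <- generate_composite_genome(sim_genome_spec(
    host_autosome_lengths = c("2L" = L), symbiont_length = 1500,
    shared_fraction = 0.5, block_length = 300, seed = 17
  ))
  tr <- compute_mappability(g, k = 31)
  aln3 <- simulate_alignments(g, sim_library_spec(
    depths = c("2L" = 3, "wMel" = 2), mode = "random", read_length = 50,
    seed = 6
  ))
  ds3 <- mean_mappable_depth(aln3, tr, contig_groups(host_autosomes = "2L"))
  for (ct in c("2L", "wMel")) {
    sc <- tr$scores[[ct]]
    ok <- !is.na(sc) & sc == 1
    want <- mean(oracle_depth(aln3, ct, length(sc))[ok])
    got <- ds3$per_contig$mean_depth[ds3$per_contig$contig == ct]
    expect_equal(got, want, info = ct)
  }
  # a group with zero mappable positions is flagged undefined
  empty_track <- structure(list(k = 1L, scores = list(c1 = rep(0.5, 10))),
                           class = "mappability_track")
  ds4 <- mean_mappable_depth(empty_alignments_fixture(), empty_track,
                             list(host = "c1"))
  expect_true(is.na(ds4$per_group$mean_depth))
})

test_that("genomic titer and coverage proportions follow their definitions", {
  mk <- function(host, wMel, wRi) {
    pg <- data.frame(
      group = c("host", "wMel", "wRi"), mappable_positions = 100,
      depth_sum = c(host, wMel, wRi) * 100,
      mean_depth = c(host, wMel, wRi)
    )
    structure(list(per_contig = pg, per_group = pg),
              class = "depth_summary")
  }
  ti <- genomic_titer(mk(10, 0, 45))
  expect_equal(unname(ti$titer["wRi"]), 4.5)
  expect_equal(unname(ti$titer["wMel"]), 0)
  expect_equal(unname(ti$proportion["wMel"]), 0)

  ti2 <- genomic_titer(mk(1, 9, 0.5))
  expect_equal(unname(ti2$proportion[c("wMel", "wRi", "host")]),
               c(9, 0.5, 1) / 10.5)
  expect_equal(sum(ti2$proportion), 1)

  expect_error(genomic_titer(mk(0, 9, 0.5)), "host mean depth is 0")
})

test_that("scaling counts scales depths and titers but not proportions", {
  g <- small_genome(host_len = 1500, symbiont_length = 1500)
  tr <- compute_mappability(g, k = 31)
  groups <- contig_groups(host_autosomes = c("2L", "2R", "3L", "3R", "4"))
  run <- function(c_scale) {
    aln <- simulate_alignments(g, sim_library_spec(depths = c_scale * c(
      "2L" = 2, "2R" = 2, "3L" = 2, "3R" = 2, "4" = 2, "wMel" = 6, "wRi" = 1
    )))
    genomic_titer(mean_mappable_depth(aln, tr, groups))
  }
  t1 <- run(1)
  t2 <- run(2)
  expect_equal(t2$titer, t1$titer)
  expect_equal(t2$mean_depth, 2 * t1$mean_depth)
  expect_equal(t2$proportion, t1$proportion)
})

test_that("titer ignores host contigs outside the autosome group", {
  g <- generate_composite_genome(sim_genome_spec(
    host_autosome_lengths = c("2L" = 1500, "X" = 1500),
    symbiont_length = 1500, shared_fraction = 0.5, block_length = 300,
    seed = 19
  ))
  tr <- compute_mappability(g, k = 31)
  groups <- contig_groups(host_autosomes = "2L")
  base <- simulate_alignments(g, sim_library_spec(
    depths = c("2L" = 2, "wMel" = 6, "wRi" = 1)
  ))
  extra <- simulate_alignments(g, sim_library_spec(
    depths = c("2L" = 2, "X" = 50, "wMel" = 6, "wRi" = 1)
  ))
  t_base <- genomic_titer(mean_mappable_depth(base, tr, groups))
  t_extra <- genomic_titer(mean_mappable_depth(extra, tr, groups))
  expect_equal(t_extra$titer, t_base$titer)
})

test_that("pipeline round trip: tiling alignments at titer T return exactly T", {
  g <- small_genome(host_len = 1500, symbiont_length = 1500,
                    shared_fraction = 0.5, block_length = 300)
  tr <- compute_mappability(g, k = 150)
  groups <- contig_groups()
  aln <- simulate_alignments(g, sim_library_spec(depths = c(
    "2L" = 2, "2R" = 2, "3L" = 2, "3R" = 2, "4" = 2, "wMel" = 18, "wRi" = 3
  )))
  ti <- genomic_titer(mean_mappable_depth(
    filter_alignments(aln, filter_params()), tr, groups
  ))
  expect_identical(unname(ti$titer["wMel"]), 9)
  expect_identical(unname(ti$titer["wRi"]), 1.5)
})
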