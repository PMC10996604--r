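# genome + track + paired background library shared by the chimera tests
chimera_fixture <- function(shared_fraction = 0.5, depth = 2, seed = 23) {
  g <- small_genome(host_len = 1500, symbiont_length = 3000,
                    shared_fraction = shared_fraction, block_length = 500,
                    seed = seed)
  track <- compute_mappability(g, k = 150)
  aln <- simulate_alignments(g, sim_library_spec(
    depths = c("2L" = depth, "wMel" = depth, "wRi" = depth),
    paired = TRUE, seed = seed
  ))
  list(genome = g, track = track, aln = aln)
}

test_that("injected mappable pairs are recovered exactly; background is clean", {
  fx <- chimera_fixture()
  strains <- c("wMel", "wRi")
  base <- detect_chimeric_pairs(fx$aln, fx$track, strains)
  expect_equal(base$chimeric_pair_count, 0L)

  aug <- inject_chimeric_pairs(fx$aln, 2, fx$track, strains,
                               placement = "mappable")
  rep2 <- detect_chimeric_pairs(aug, fx$track, strains)
  expect_equal(rep2$chimeric_pair_count, 2L)
  expect_equal(nrow(rep2$pairs), 2L)
  expect_true(all(rep2$pairs$contig_A == "wMel"))
  expect_true(all(rep2$pairs$contig_B == "wRi"))

  # n = 0 leaves the alignment set untouched
  expect_identical(inject_chimeric_pairs(fx$aln, 0, fx$track, strains),
                   fx$aln)
})

test_that("pairs with an unmappable end are injected but not detected", {
  fx <- chimera_fixture()
  strains <- c("wMel", "wRi")
  aug <- inject_chimeric_pairs(fx$aln, 1, fx$track, strains,
                               placement = "unmappable")
  expect_equal(nrow(aug), nrow(fx$aln) + 2L)
  rep <- detect_chimeric_pairs(aug, fx$track, strains)
  expect_equal(rep$chimeric_pair_count, 0L)
})

test_that("fully shared symbionts leave nothing mappable, forcing count 0", {
  fx <- chimera_fixture(shared_fraction = 1)
  strains <- c("wMel", "wRi")
  # nothing on the symbionts is mappable, so mappable injection must fail ...
  expect_error(
    inject_chimeric_pairs(fx$aln, 1, fx$track, strains,
                          placement = "mappable"),
    "no mappable interval"
  )
  # ... and even hand-built cross-strain pairs are rejected by the detector
  fake <- as_alignment_set(rbind(
    as.data.frame(fx$aln),
    data.frame(qname = "x", contig = "wMel", start = 300, len = 150,
               mapq = 60, is_dup = FALSE, is_secondary = FALSE,
               is_paired = TRUE, mate_contig = "wRi", mate_start = 300),
    data.frame(qname = "x", contig = "wRi", start = 300, len = 150,
               mapq = 60, is_dup = FALSE, is_secondary = FALSE,
               is_paired = TRUE, mate_contig = "wMel", mate_start = 300)
  ))
  expect_equal(
    detect_chimeric_pairs(fake, fx$track, strains)$chimeric_pair_count, 0L
  )
})

test_that("normalised fractions use both conventions and shrink with background", {
  fx <- chimera_fixture()
  strains <- c("wMel", "wRi")
  aug <- inject_chimeric_pairs(fx$aln, 2, fx$track, strains)
  rep <- detect_chimeric_pairs(aug, fx$track, strains)
  expect_equal(rep$fraction_per_alignment,
               rep$chimeric_pair_count / rep$total_alignments)
  expect_equal(rep$fraction_per_pair,
               rep$chimeric_pair_count / rep$total_pairs)

  # adding non-chimeric alignments can only decrease the fractions
  denser <- chimera_fixture(depth = 4)
  aug2 <- inject_chimeric_pairs(denser$aln, 2, denser$track, strains)
  rep_dense <- detect_chimeric_pairs(aug2, denser$track, strains)
  expect_equal(rep_dense$chimeric_pair_count, 2L)
  expect_lt(rep_dense$fraction_per_alignment, rep$fraction_per_alignment)
  expect_lt(rep_dense$fraction_per_pair, rep$fraction_per_pair)
})

test_that("degenerate detector inputs are handled per contract", {
  fx <- chimera_fixture()
  expect_error(detect_chimeric_pairs(fx$aln, fx$track, c("wMel", "wMel")),
               "must differ")
  unpaired <- as_alignment_set(data.frame(
    contig = "wMel", start = 1, len = 150, mapq = 60
  ))
  expect_warning(
    rep <- detect_chimeric_pairs(unpaired, fx$track, c("wMel", "wRi")),
    "no paired records"
  )
  expect_equal(rep$chimeric_pair_count, 0L)
})

test_that("MAPQ/duplicate filtering is applied before detection", {
  fx <- chimera_fixture()
  strains <- c("wMel", "wRi")
  aug <- inject_chimeric_pairs(fx$aln, 1, fx$track, strains, mapq = 5)
  rep <- detect_chimeric_pairs(aug, fx$track, strains)
  expect_equal(rep$chimeric_pair_count, 0L)
  rep_loose <- detect_chimeric_pairs(aug, fx$track, strains,
                                     params = filter_params(mapq_min = 0))
  expect_equal(rep_loose$chimeric_pair_count, 1L)
})
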