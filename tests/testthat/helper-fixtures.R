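# Shared fixtures: small composite genomes and tracks built in code.

# a small two-strain genome with large unique blocks (useful mappable space)
small_genome <- function(host_len = 3000, symbiont_length = 3000,
                         shared_fraction = 0.5, block_length = 500,
                         seed = 42) {
  generate_composite_genome(sim_genome_spec(
    host_autosome_lengths = c(
      "2L" = host_len, "2R" = host_len, "3L" = host_len,
      "3R" = host_len, "4" = host_len
    ),
    symbiont_length = symbiont_length,
    shared_fraction = shared_fraction,
    block_length = block_length,
    seed = seed
  ))
}

# brute-force mappability oracle: enumerate every k-mer into a named count
# table (k-mer and reverse complement share a canonical key), then score
oracle_mappability <- function(seqs, k) {
  chr <- toupper(as.character(seqs))
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  all_kmers <- character(0)
  per_seq_kmers <- lapply(chr, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    vapply(seq_len(n - k + 1), function(i) substr(s, i, i + k - 1),
           character(1))
  })
  canon <- lapply(per_seq_kmers, function(km) {
    vapply(km, function(x) {
      if (grepl("[^ACGT]", x)) return(NA_character_)
      rc <- revcomp(x)
      if (rc < x) rc else x
    }, character(1), USE.NAMES = FALSE)
  })
  counts <- table(unlist(canon))
  lapply(seq_along(chr), function(i) {
    n <- nchar(chr[i])
    out <- rep(NA_real_, n)
    cn <- canon[[i]]
    if (length(cn) > 0) {
      out[seq_along(cn)] <- ifelse(is.na(cn), NA_real_,
                                   1 / as.numeric(counts[cn]))
    }
    out
  })
}

empty_alignments_fixture <- function() {
  as_alignment_set(data.frame(
    contig = character(0), start = integer(0), len = integer(0),
    mapq = integer(0)
  ))
}

# brute-force per-base pileup oracle
oracle_depth <- function(aln, contig, L) {
  depth <- numeric(L)
  rows <- aln[aln$contig == contig, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    span <- rows$start[i]:(rows$start[i] + rows$len[i] - 1)
    span <- span[span >= 1 & span <= L]
    depth[span] <- depth[span] + 1
  }
  depth
}
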