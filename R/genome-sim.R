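#' Specification for a synthetic composite genome
#'
#' Describes a composite reference genome made of named host autosomes plus
#' two closely related symbiont strain contigs. The two symbiont contigs are
#' built from alternating blocks: shared blocks carry identical sequence in
#' both strains (and are therefore unmappable at any k once both contigs are
#' in the reference), while unique blocks are drawn independently per strain
#' and provide the uniquely mappable sequence the depth and chimera analyses
#' rely on. Block structure, rather than scattered per-base substitutions,
#' keeps mappable and unmappable segments large enough to address in tests.
#'
#' Default contig sizes are desk-scale stand-ins: they preserve the structure
#' of a Drosophila host (five autosomal contigs 2L/2R/3L/3R/4, with 4 the
#' small dot chromosome) next to two near-identical megabase-class symbiont
#' genomes, scaled so whole-pipeline runs complete in seconds. All defaults
#' are multiples of the default read length so that tiling alignments cover
#' every position evenly.
#'
#' @param host_autosome_lengths named integer vector of host contig lengths
#'   (bp); names become contig names.
#' @param symbiont_names character pair of strain contig names.
#' @param symbiont_length length (bp) of each symbiont contig.
#' @param shared_fraction fraction of symbiont sequence identical between the
#'   two strains, in `[0, 1]`. The realised shared length is
#'   `round(shared_fraction * symbiont_length)`.
#' @param block_length target length (bp) of alternating shared/unique blocks.
#' @param seed integer RNG seed; identical spec + seed gives byte-identical
#'   genomes.
#' @return an object of class `sim_genome_spec`.
#' @seealso [generate_composite_genome()]
#' @export
sim_genome_spec <- function(host_autosome_lengths = c(
                              "2L" = 45000, "2R" = 45000,
                              "3L" = 45000, "3R" = 45000, "4" = 15000
                            ),
                            symbiont_names = c("wMel", "wRi"),
                            symbiont_length = 150000,
                            shared_fraction = 0.999,
                            block_length = 2000,
                            seed = 1L) {
  stopifnot(
    length(host_autosome_lengths) >= 1L,
    !is.null(names(host_autosome_lengths)),
    all(host_autosome_lengths > 0),
    length(symbiont_names) == 2L,
    symbiont_names[1] != symbiont_names[2],
    symbiont_length > 0,
    shared_fraction >= 0, shared_fraction <= 1,
    block_length >= 1
  )
  structure(
    list(
      host_autosome_lengths = host_autosome_lengths,
      symbiont_names = as.character(symbiont_names),
      symbiont_length = as.integer(symbiont_length),
      shared_fraction = shared_fraction,
      block_length = as.integer(block_length),
      seed = as.integer(seed)
    ),
    class = "sim_genome_spec"
  )
}

# Partition L bp into alternating unique/shared chunks whose shared total is
# exactly round(f * L). Chunks are at most `block` long; the pattern starts
# with a unique chunk so strain-diagnostic sequence sits at the contig start.
symbiont_block_plan <- function(L, f, block) {
  block <- as.integer(block)
  shared_total <- as.integer(round(f * L))
  unique_total <- as.integer(L) - shared_total
  lens <- integer(0)
  types <- character(0)
  s <- shared_total
  u <- unique_total
  take_unique <- TRUE
  while (s > 0 || u > 0) {
    if (take_unique && u > 0) {
      w <- min(block, u)
      lens <- c(lens, w); types <- c(types, "unique"); u <- u - w
    } else if (s > 0) {
      w <- min(block, s)
      lens <- c(lens, w); types <- c(types, "shared"); s <- s - w
    }
    take_unique <- !take_unique
  }
  data.frame(type = types, length = lens, stringsAsFactors = FALSE)
}

#' Generate a composite host + two-strain symbiont reference genome
#'
#' Host contigs are independent uniform-random DNA. The two symbiont contigs
#' share exactly `round(shared_fraction * symbiont_length)` bp of identical
#' sequence arranged in long blocks (see [sim_genome_spec()]) and differ
#' elsewhere. Generation is fully deterministic given the spec: each contig
#' draws from its own seed substream, so changing one contig's length leaves
#' the others' sequence unchanged.
#'
#' @param spec a [sim_genome_spec()].
#' @return an object of class `composite_genome`: a list with `seq` (a
#'   [Biostrings::DNAStringSet] of all contigs), `roles` (named character
#'   vector, `"host-autosome"` or `"symbiont"`), `symbiont_names`, and the
#'   generating `spec`.
#' @examples
#' g <- generate_composite_genome(sim_genome_spec(
#'   host_autosome_lengths = c("2L" = 3000), symbiont_length = 3000,
#'   shared_fraction = 0.5, block_length = 500, seed = 7
#' ))
#' names(g$seq)
#' @export
generate_composite_genome <- function(spec) {
  stopifnot(inherits(spec, "sim_genome_spec"))
  host <- lapply(names(spec$host_autosome_lengths), function(nm) {
    with_seed(
      derive_seed(spec$seed, paste0("host:", nm)),
      random_dna(spec$host_autosome_lengths[[nm]])
    )
  })
  names(host) <- names(spec$host_autosome_lengths)

  plan <- symbiont_block_plan(
    spec$symbiont_length, spec$shared_fraction, spec$block_length
  )
  shared_chunks <- with_seed(
    derive_seed(spec$seed, "symbiont:shared"),
    lapply(plan$length[plan$type == "shared"], random_dna)
  )
  strain_seq <- lapply(spec$symbiont_names, function(strain) {
    unique_chunks <- with_seed(
      derive_seed(spec$seed, paste0("symbiont:unique:", strain)),
      lapply(plan$length[plan$type == "unique"], random_dna)
    )
    chunks <- character(nrow(plan))
    chunks[plan$type == "shared"] <- unlist(shared_chunks) %||% character(0)
    chunks[plan$type == "unique"] <- unlist(unique_chunks) %||% character(0)
    paste(chunks, collapse = "")
  })
  names(strain_seq) <- spec$symbiont_names

  seqs <- Biostrings::DNAStringSet(c(unlist(host), unlist(strain_seq)))
  roles <- c(
    setNames(rep("host-autosome", length(host)), names(host)),
    setNames(rep("symbiont", 2L), spec$symbiont_names)
  )
  structure(
    list(seq = seqs, roles = roles,
         symbiont_names = spec$symbiont_names, spec = spec),
    class = "composite_genome"
  )
}

#' @export
print.composite_genome <- function(x, ...) {
  cat("composite_genome:", length(x$seq), "contigs\n")
  df <- data.frame(
    contig = names(x$seq),
    length = Biostrings::width(x$seq),
    role = unname(x$roles[names(x$seq)])
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a composite genome to FASTA
#'
#' @param genome a `composite_genome` (or any named
#'   [Biostrings::DNAStringSet]).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "composite_genome")) genome$seq else genome
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read a composite genome from FASTA
#'
#' Contig roles are assigned by name: `host_autosomes` become
#' `"host-autosome"`, `symbiont_names` become `"symbiont"`, everything else
#' `"host-other"` (present in the reference, excluded from titer
#' denominators).
#'
#' @param path FASTA path.
#' @param symbiont_names character vector of symbiont contig names.
#' @param host_autosomes names of the host contigs used in the titer
#'   denominator.
#' @return a `composite_genome`.
#' @export
read_genome_fasta <- function(path, symbiont_names,
                              host_autosomes = c("2L", "2R", "3L", "3R", "4")) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(symbiont_names, names(seqs))
  if (length(missing) > 0) {
    stop("symbiont contig(s) not in FASTA: ", paste(missing, collapse = ", "))
  }
  roles <- ifelse(
    names(seqs) %in% symbiont_names, "symbiont",
    ifelse(names(seqs) %in% host_autosomes, "host-autosome", "host-other")
  )
  names(roles) <- names(seqs)
  structure(
    list(seq = seqs, roles = roles,
         symbiont_names = as.character(symbiont_names), spec = NULL),
    class = "composite_genome"
  )
}

# named integer vector of contig lengths
contig_lengths <- function(genome) {
  setNames(Biostrings::width(genome$seq), names(genome$seq))
}
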