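#' Worked-example fixture: a direct-repeat-mediated in-frame deletion
#'
#' Builds a small synthetic strain pair whose only difference is the canonical
#' 24-bp in-frame deletion: the reference CDS carries the deleted allele
#' `ATACCATAAATAAATTATTTGGAT` immediately followed by a second copy of its
#' 8-bp prefix `ATACCATA` and a non-matching base, and the mutant has the
#' 24-bp allele removed (homologous recombination between the two repeat
#' copies leaves a single copy).  The comparison therefore yields exactly one
#' deletion call of 24 bases with flanking repeat `ATACCATA` (length 8),
#' in frame.
#'
#' @param seed RNG seed for the surrounding sequence (default 11).
#' @return `list(reference, mutant, annotations, truth)` as from
#'   [simulate_strain_pair()].
#' @export
spo0a_fixture <- function(seed = 11L) {
  profile <- generator_profile(
    genome_length = 3000L, gc_fraction = 0.35, n_genes = 2L,
    mean_gene_length = 900L,
    deletion_spec = list(deleted_sequence = "ATACCATAAATAAATTATTTGGAT",
                         repeat_sequence = "ATACCATA",
                         target_codon = 100L),
    seed = seed)
  simulate_strain_pair(profile)
}

#' Default kinetics simulation profile
#'
#' The cytosine-context parameter recovery needs thousands of `CGCG` sites; a
#' short AT-rich chromosome contains only a handful, so the kinetics stand-in
#' is a 600-kb random sequence of balanced composition (GC 0.5), which carries
#' roughly 2,300 `CGCG` duplex sites (about 4,700 first-C strand
#' observations).
#'
#' @param seed RNG seed (default 7), used for both the sequence and the
#'   kinetics draw.
#' @param genome_length Sequence length (default 600000).
#' @param gc_fraction Base composition (default 0.5).
#' @return `list(genome, model, track)` with `model = kinetics_model()` and
#'   `track = simulate_kinetics(...)`.
#' @export
kinetics_profile <- function(seed = 7L, genome_length = 600000L,
                             gc_fraction = 0.5) {
  set.seed(as.integer(seed))
  genome <- genome_record("synthetic_methylome",
                          random_dna(genome_length, gc_fraction))
  model <- kinetics_model()
  track <- simulate_kinetics(genome, model, default_m6a_motifs(),
                             seed = (as.integer(seed) %% 2000000000L) + 1L)
  list(genome = genome, model = model, track = track)
}
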