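# Shared fixtures, built in code.

# Miniature genome: 1 kb unique chromosome + a 2 x 100 bp collapsed array,
# small enough for brute-force enumeration.
mini_model <- function(physical_copies = 5L) {
  rdna <- rdna_annotation(
    "chrR", 0L, repeat_length = 100L, collapsed_copies = 2L,
    physical_copies = physical_copies,
    offsets = list(acs = 20L, mcm_nondisplaced = 10L, mcm_displaced = 25L,
                   nucleosome_dyads = c(5L, 40L, 55L), cpro_start = 2L,
                   rfb = 90L),
    timing_region = c(0L, 200L))
  genome_model(data.frame(name = c("chrU", "chrR"),
                          length = c(1000L, 200L)), rdna)
}

# Library with fragments of a fixed length centered on given midpoints.
lib_at <- function(mids, chrom = "chrU", len = 60L, assay = "sseq_g1",
                   genotype = "wt", timepoint = NA_real_) {
  start <- mids - len %/% 2L
  fragment_library(data.frame(chrom = chrom, start = start,
                              end = start + len),
                   assay = assay, genotype = genotype,
                   timepoint = timepoint)
}

default_spec <- function(genotype = "wt", n = 100000L, seed = 42L, ...) {
  m <- default_genome_model(150L)
  simulation_spec(m, genotype_preset(genotype, ...), n_fragments = n,
                  seed = seed)
}
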