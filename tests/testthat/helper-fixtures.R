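# Shared synthetic fixtures, generated once per test run.

mini_config <- function(...) {
  synthetic_config(seed = 11L, n_strains = 3L, n_chromosomes = 1L,
                   chromosome_length = 10000L, subtelomere_span = 2000L,
                   n_core_genes = 6L, n_novel_genes = 3L,
                   novel_subtelomeric_fraction = 1.0,
                   n_clusters = 1L, cluster_size = 2L,
                   n_pseudogenes = 1L, n_dubious = 1L,
                   gene_codons = c(30L, 50L),
                   n_shared_peptide_pairs = 1L, ...)
}

.fixture_cache <- new.env()

mini_panel <- function() {
  if (is.null(.fixture_cache$mini))
    .fixture_cache$mini <- generate_strain_panel(mini_config())
  .fixture_cache$mini
}

default_panel <- function() {
  if (is.null(.fixture_cache$default))
    .fixture_cache$default <- generate_strain_panel(synthetic_config())
  .fixture_cache$default
}

# placements of one strain as a gene_models data.frame, with status
# taken from the planted class
placement_models <- function(truth, strain) {
  pl <- truth$placements[truth$placements$strain == strain, ,
                         drop = FALSE]
  status <- ifelse(pl$class == "pseudogene", "pseudogene",
                   ifelse(pl$class == "dubious", "dubious",
                          "valid_coding"))
  gene_models(pl$gene_id, pl$contig, pl$start, pl$end, pl$strand,
              status = status)
}
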