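# Shared small simulation configurations. Tests use deliberately tiny
# genomes so the whole suite stays fast; the acceptance tests use the
# default study-scale scenario.

tiny_config <- function(...) {
  defaults <- list(n_chromosomes_A = 2L, n_chromosomes_B = 2L,
                   chromosome_length = 60000L, n_gene_pairs = 20L,
                   n_repeat_families_specific = 2L,
                   n_repeat_families_shared = 2L,
                   repeat_copy_number = 120L, gene_length = 300L,
                   te_shared_copies = 1000L,
                   te_specific_copies = c(A = 600L, B = 120L))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# ranked-hit table builder for synteny tests
make_hits <- function(qrank, srank, score = NULL,
                      qchrom = "q1", schrom = "s1") {
  data.table::data.table(
    query = paste0("q", qrank), subject = paste0("s", srank),
    score = score %||% rep(100, length(qrank)),
    qchrom = qchrom, qrank = qrank, schrom = schrom, srank = srank)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
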