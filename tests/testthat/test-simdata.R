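test_that("genome simulation is deterministic and matches its truth record", {
  cfg <- tiny_config()
  d1 <- tempfile(); d2 <- tempfile()
  g1 <- simulate_genome(cfg, 1, d1)
  g2 <- simulate_genome(cfg, 1, d2)
  expect_identical(readLines(g1$fasta), readLines(g2$fasta))
  expect_identical(readLines(g1$gff), readLines(g2$gff))

  truth <- g1$truth
  expect_length(truth$subgenome_of_chromosome, 4L)
  expect_equal(sum(truth$subgenome_of_chromosome == "A"), 2L)
  expect_equal(sum(truth$subgenome_of_chromosome == "B"), 2L)
  expect_identical(truth$phasing_signal, "strong")

  # every gene in the pair list exists in the emitted annotation
  genes <- read_gff_genes(g1$gff)
  expect_true(all(c(truth$homoeolog_pairs$gene_A,
                    truth$homoeolog_pairs$gene_B) %in% genes$gene_id))
  # truth te_window well-ordered
  expect_true(truth$te_window[1] < truth$te_window[2])
})

test_that("weak repeat copy number is flagged and capacity errors are explicit", {
  cfg <- tiny_config(repeat_copy_number = 60L)
  g <- simulate_genome(cfg, 1)
  expect_identical(g$truth$phasing_signal, "weak")

  too_small <- tiny_config(chromosome_length = 5000L)
  expect_error(simulate_genome(too_small, 1), "too small")
})

test_that("CDS pair simulation hits target Ks in expectation and flags saturation", {
  # degenerate mixture at 0 gives identical sequences
  cfg0 <- tiny_config(ks_mixture = list(c(mean = 0, sd = 0, weight = 1)),
                      n_gene_pairs = 5L)
  out0 <- simulate_cds_pairs(cfg0, 1)
  a <- Biostrings::readDNAStringSet(out0$fasta_A)
  b <- Biostrings::readDNAStringSet(out0$fasta_B)
  expect_identical(as.character(a), setNames(as.character(b), names(a)))

  # law of large numbers on the generator's own truth record
  cfgm <- sim_config(n_gene_pairs = 2000L, gene_length = 30L,
                     ks_mixture = list(c(mean = 0.46, sd = 0.10, weight = 1)))
  outm <- simulate_cds_pairs(cfgm, 2)
  expect_lt(abs(mean(outm$truth$true_ks) - 0.46), 0.01)

  # beyond the saturation bound -> flagged, not dropped
  cfgs <- tiny_config(ks_mixture = list(c(mean = 5, sd = 0, weight = 1)),
                      n_gene_pairs = 3L)
  outs <- simulate_cds_pairs(cfgs, 1)
  expect_true(all(outs$truth$saturated))
  expect_length(Biostrings::readDNAStringSet(outs$fasta_A), 3L)
})

test_that("TE table honours configured windows and shared-component null", {
  cfg <- tiny_config(te_specific_range = c(1, 5))
  out <- simulate_te_table(cfg, 1)
  expect_equal(out$truth$te_window, c(1, 5))
  tab <- read_te_table(out$te)
  expect_true(all(tab$perc_div >= 0 & tab$perc_div <= 100))

  # shared component alone: the two subgenome distributions are draws from
  # the same law (two-sample KS test does not reject across seeds)
  cfg0 <- tiny_config(te_specific_copies = c(A = 0L, B = 0L),
                      te_shared_copies = 2000L)
  pvals <- vapply(1:10, function(s) {
    tab <- read_te_table(simulate_te_table(cfg0, s)$te)
    stats::ks.test(tab[tab$subgenome == "A", perc_div],
                   tab[tab$subgenome == "B", perc_div])$p.value
  }, 0)
  expect_gte(sum(pvals > 0.01), 9L)
})

test_that("expression simulation controls bias fraction, direction and errors", {
  cfg0 <- tiny_config(expression_bias_fraction = 0)
  out0 <- simulate_expression(cfg0, 1)
  expect_equal(nrow(out0$truth$biased_pairs), 0L)

  cfg <- tiny_config(n_gene_pairs = 100L, n_replicates = 6L)
  out <- simulate_expression(cfg, 2)
  expr <- read_expression(out$expr)
  tb <- out$truth$biased_pairs
  expect_equal(nrow(tb), 30L)
  # mean ratio across biased pairs approximates the configured fold change
  pairs <- out$truth$homoeolog_pairs
  ratios <- vapply(seq_len(nrow(tb)), function(i) {
    p <- pairs[pairs$pair_id == tb$pair_id[i], ]
    ma <- mean(expr[expr$gene == p$gene_A, value])
    mb <- mean(expr[expr$gene == p$gene_B, value])
    if (tb$direction[i] == "A") ma / mb else mb / ma
  }, 0)
  expect_lt(abs(mean(ratios) - 2), 0.3)

  expect_error(simulate_expression(tiny_config(n_replicates = 1L), 1),
               "replicates")
  expect_error(tiny_config(fold_change = 0), "fold_change")
})

test_that("methylation counts follow the configured levels and are deterministic", {
  lv0 <- list(CG = c(upstream = 0, body = 0, downstream = 0),
              CHG = c(upstream = 0, body = 0, downstream = 0),
              CHH = c(upstream = 0, body = 0, downstream = 0))
  cfg0 <- suppressWarnings(tiny_config(methylation_levels = lv0, p_err = 0.01))
  out0 <- simulate_methylation(cfg0, 1)
  cx <- read_cx(out0$cx)
  expect_lt(abs(sum(cx$k) / sum(cx$n) - 0.01), 0.003)

  lv1 <- list(CG = c(upstream = 1, body = 1, downstream = 1),
              CHG = c(upstream = 1, body = 1, downstream = 1),
              CHH = c(upstream = 1, body = 1, downstream = 1))
  cfg1 <- tiny_config(methylation_levels = lv1, p_err = 0)
  out1 <- simulate_methylation(cfg1, 1)
  cx1 <- read_cx(out1$cx)
  expect_true(all(cx1$k == cx1$n))

  out1b <- simulate_methylation(cfg1, 1)
  expect_identical(readLines(out1$cx), readLines(out1b$cx))
})

test_that("emitted files round-trip through the package readers and truth JSON", {
  cfg <- tiny_config()
  out <- simulate_all(cfg, 5)
  expect_true(all(file.exists(unlist(out[c("fasta", "gff", "cds_A", "cds_B",
                                           "te", "expr", "cx", "hits",
                                           "truth_json")]))))
  tr <- read_truth(out$truth_json)
  expect_equal(tr$subgenome_of_chromosome, out$truth$subgenome_of_chromosome)
  expect_equal(unname(tr$true_ks), unname(out$truth$true_ks))
  expect_equal(tr$homoeolog_pairs$gene_A, out$truth$homoeolog_pairs$gene_A)
  hits <- read_blast_tab(out$hits)
  expect_true(all(c("query", "subject", "score") %in% names(hits)))
})
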