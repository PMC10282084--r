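test_that("canonical k-mer counting follows the lexicographic-minimum rule", {
  ct <- count_kmers(c(s = "ACGTA"), 3)
  tot <- kmer_totals(ct)
  # windows ACG, CGT, GTA; canonical(CGT) = ACG, canonical(GTA) = GTA
  # (GTA < its reverse complement TAC)
  expect_equal(tot[order(names(tot))], c(ACG = 2L, GTA = 1L))

  # windows containing non-ACGT symbols are skipped
  ct2 <- count_kmers(c(s = "ANGT"), 2)
  expect_equal(kmer_totals(ct2), c(AC = 1L))  # canonical(GT) = AC

  expect_length(kmer_totals(count_kmers(character(0), 3)), 0L)
  expect_warning(out <- count_kmers(c(s = "ACG"), 5), "longest")
  expect_equal(nrow(out$table), 0L)
})

test_that("counting a sequence and its reverse complement is identical", {
  set.seed(11)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    t1 <- kmer_totals(count_kmers(c(x = s), 5))
    t2 <- kmer_totals(count_kmers(c(x = rc), 5))
    expect_equal(t1[order(names(t1))], t2[order(names(t2))])
  }
})

test_that("genome size estimation follows total k-mers over the peak depth", {
  h <- kmer_histogram(depth = c(5, 10, 15), count = c(10, 85, 5))
  # total = 50 + 850 + 75 = 975, peak depth 10
  est <- estimate_genome_size(h)
  expect_equal(est$size_bp, 97.5)
  expect_equal(est$expected_depth, 10)

  expect_error(estimate_genome_size(kmer_histogram(1, 1e6)), "no peak")
  expect_error(estimate_genome_size(
    kmer_histogram(4:10, c(100, 50, 25, 12, 6, 3, 1))), "no peak")
})

test_that("differential k-mer selection applies both filters", {
  # hand-built counts: three k-mers across chromosomes c1 (pair member 1)
  # and c2 (pair member 2)
  tab <- data.table::data.table(
    code = c(1, 1, 2, 2, 3, 3),
    chrom = rep(c("c1", "c2"), 3),
    n = c(120, 30,   # total 150, 3.9-fold with pseudocount -> retained
          40, 40,    # total 80 (< 100) -> rejected regardless of fold
          90, 61))   # total 151, fold (91/62) = 1.47 -> rejected
  counts <- structure(list(table = tab, k = 5L, chroms = c("c1", "c2")),
                      class = "kmer_counts")
  pairs <- data.frame(chrom_A = "c1", chrom_B = "c2")
  m <- select_differential_kmers(counts, pairs, phasing_params(k = 5))
  expect_equal(nrow(m$counts), 1L)
  expect_equal(unname(m$counts[1, ]), c(120, 30))

  expect_error(select_differential_kmers(counts, pairs[0, ], phasing_params(k = 5)),
               "pair-relative")
  # z-scaled rows have mean 0 and unit variance
  expect_equal(mean(m$z[1, ]), 0)
  expect_equal(sd(m$z[1, ]), 1)
})

test_that("raising the selection thresholds never adds retained k-mers", {
  set.seed(7)
  tab <- data.table::data.table(
    code = rep(1:50, each = 4),
    chrom = rep(c("c1", "c2", "c3", "c4"), 50),
    n = sample(1:200, 200, replace = TRUE))
  counts <- structure(list(table = tab, k = 7L,
                           chroms = c("c1", "c2", "c3", "c4")),
                      class = "kmer_counts")
  pairs <- data.frame(chrom_A = c("c1", "c3"), chrom_B = c("c2", "c4"))
  base <- rownames(select_differential_kmers(
    counts, pairs, phasing_params(k = 7, min_total_count = 100, min_fold = 2))$counts)
  for (mtc in c(150, 300)) for (mf in c(2, 3, 5)) {
    got <- rownames(select_differential_kmers(
      counts, pairs, phasing_params(k = 7, min_total_count = mtc, min_fold = mf))$counts)
    expect_true(all(got %in% base))
  }
})

test_that("two-group clustering splits duplicate column patterns perfectly", {
  z <- matrix(c(5, 0, 5, 0, 0, 5, 0, 5,
                4, 1, 4, 1, 1, 4, 1, 4), nrow = 4,
              dimnames = list(NULL, c("c1", "c2", "c3", "c4")))
  m <- structure(list(counts = z, z = t(scale(t(z))),
                      params = phasing_params(), totals = rowSums(z)),
                 class = "diff_kmer_matrix")
  asg <- cluster_subgenomes(m)
  lab <- setNames(asg$subgenome, asg$chrom)
  expect_equal(lab[["c1"]], lab[["c3"]])
  expect_equal(lab[["c2"]], lab[["c4"]])
  expect_false(lab[["c1"]] == lab[["c2"]])
  expect_equal(lab[["c1"]], "A")  # smallest chromosome ID anchors the label

  single <- structure(list(counts = z[, 1, drop = FALSE],
                           z = z[, 1, drop = FALSE],
                           params = phasing_params(), totals = rowSums(z)),
                      class = "diff_kmer_matrix")
  expect_error(cluster_subgenomes(single), "two chromosomes")
})

test_that("phasing recovers the simulated subgenomes and reports weak signal", {
  cfg <- tiny_config()
  g <- simulate_genome(cfg, 3)
  rep <- phase_subgenomes(g$fasta, g$truth$homoeolog_chromosome_pairs)
  expect_identical(rep$params$k, 13L)
  truth <- g$truth$subgenome_of_chromosome
  asg <- setNames(rep$assignment$subgenome, rep$assignment$chrom)
  expect_equal(oracle_ari(asg[names(truth)], truth), 1)
  if (requireNamespace("mclust", quietly = TRUE))
    expect_equal(mclust::adjustedRandIndex(asg[names(truth)], truth), 1)

  weak <- simulate_genome(tiny_config(repeat_copy_number = 60L), 3)
  expect_warning(
    wrep <- phase_subgenomes(weak$fasta, weak$truth$homoeolog_chromosome_pairs),
    "weak")
  expect_true(wrep$weak_signal)
  expect_equal(nrow(wrep$assignment), 4L)
})
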