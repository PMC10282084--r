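test_that("site-level binomial calls follow the upper tail exactly", {
  s0 <- call_sites(data.table::data.table(n = 10L, k = 0L))
  expect_equal(s0$p_site, 1)
  expect_false(s0$methylated)

  s1 <- call_sites(data.table::data.table(n = 10L, k = 10L), p_err = 0.01)
  expect_equal(s1$p_site, 0.01^10, tolerance = 1e-12)
  expect_true(s1$methylated)

  expect_error(call_sites(data.table::data.table(n = 5L, k = 6L)), "exceeds")
})

test_that("sites at or below the coverage floor are excluded from gene stats", {
  genes <- data.frame(gene_id = "g1", chrom = "c1", start = 1L, end = 100L)
  sites <- data.table::data.table(
    chrom = "c1", pos = c(10L, 20L, 30L),
    context = "CG", n = c(5L, 6L, 20L), k = c(5L, 6L, 20L))
  called <- call_sites(sites, p_err = 0.01)
  st <- gene_methylation_stats(called, genes, min_cov = 5L)
  expect_equal(st$n_c, 2L)  # the n = 5 site is dropped (strict > 5)
})

test_that("the gene-body tail probability matches closed forms and the summation oracle", {
  expect_equal(gene_body_pvalue(10, 10, 0.3), 0.3^10, tolerance = 1e-12)
  expect_equal(gene_body_pvalue(25, 0, 0.3), 1)
  expect_error(gene_body_pvalue(10, 5, 0), "proportion")
  expect_error(gene_body_pvalue(10, 5, 1), "proportion")

  set.seed(71)
  for (i in 1:500) {
    n <- sample(1:400, 1)
    m <- sample(0:n, 1)
    p <- runif(1, 0.01, 0.99)
    expect_lt(abs(gene_body_pvalue(n, m, p) - oracle_binom_tail(n, m, p)),
              1e-12)
    # tail equals 1 - CDF(m - 1) for the same binomial
    expect_lt(abs(gene_body_pvalue(n, m, p) - (1 - pbinom(m - 1, n, p))),
              1e-12)
  }
})

test_that("under null methylation the site-level type-I error is controlled", {
  set.seed(72)
  n_sites <- 10000L
  cov <- 1L + rpois(n_sites, 20)
  k <- rbinom(n_sites, cov, 0.01)
  called <- call_sites(data.table::data.table(n = cov, k = k),
                       p_err = 0.01, alpha = 0.05)
  rate <- mean(called$methylated)
  ci_half <- 3 * sqrt(0.05 * 0.95 / n_sites)
  expect_lte(rate, 0.05 + ci_half)
})

test_that("CG body-methylated pair selection applies all three context gates", {
  mk_stats <- function(...) {
    rows <- list(...)
    data.table::rbindlist(lapply(rows, function(r)
      data.table::data.table(gene_id = r[[1]], context = r[[2]],
                             n_c = 30L, m_c = 15L, p_c = 0.3,
                             P_c = as.numeric(r[[3]]))))
  }
  pairs <- data.frame(pair_id = "p1", gene_A = "a", gene_B = "b")
  kept <- select_body_methylated_pairs(mk_stats(
    list("a", "CG", 0.01), list("a", "CHG", 0.5), list("a", "CHH", 0.5),
    list("b", "CG", 0.01), list("b", "CHG", 0.5), list("b", "CHH", 0.5)),
    pairs)
  expect_equal(nrow(kept), 1L)

  # one member with CHG body methylation excludes the pair
  excl <- select_body_methylated_pairs(mk_stats(
    list("a", "CG", 0.01), list("a", "CHG", 0.01), list("a", "CHH", 0.5),
    list("b", "CG", 0.01), list("b", "CHG", 0.5), list("b", "CHH", 0.5)),
    pairs)
  expect_equal(nrow(excl), 0L)

  # one member not CG body-methylated excludes the pair
  excl2 <- select_body_methylated_pairs(mk_stats(
    list("a", "CG", 0.2), list("a", "CHG", 0.5), list("a", "CHH", 0.5),
    list("b", "CG", 0.01), list("b", "CHG", 0.5), list("b", "CHH", 0.5)),
    pairs)
  expect_equal(nrow(excl2), 0L)
})

test_that("DmCG/C counts discordant comparable sites and is symmetric", {
  seq_a <- "ACGACGTTTACG"  # CG at positions 2, 5, 11
  seq_b <- "ACGACGTTTACG"
  calls <- function(pos, m) data.table::data.table(pos = pos, methylated = m)
  r0 <- dmcg_rate(seq_a, seq_b, calls(c(2, 5, 11), c(TRUE, TRUE, FALSE)),
                  calls(c(2, 5, 11), c(TRUE, TRUE, FALSE)))
  expect_equal(r0$dm, 0)

  r1 <- dmcg_rate(seq_a, seq_b, calls(c(2, 5, 11), c(TRUE, TRUE, FALSE)),
                  calls(c(2, 5, 11), c(FALSE, TRUE, FALSE)))
  expect_equal(r1$dm, 1 / 3)
  r1r <- dmcg_rate(seq_b, seq_a, calls(c(2, 5, 11), c(FALSE, TRUE, FALSE)),
                   calls(c(2, 5, 11), c(TRUE, TRUE, FALSE)))
  expect_equal(r1r$dm, r1$dm)

  # 3 discordant of 12 comparable
  pos12 <- seq(2, 35, 3)
  sq <- paste(rep("CGT", 12), collapse = "")  # CG at 1, 4, ..., 34
  cg <- seq(1, 34, 3)
  ma <- rep(TRUE, 12); mb <- ma; mb[1:3] <- FALSE
  r2 <- dmcg_rate(sq, sq, calls(cg, ma), calls(cg, mb))
  expect_equal(r2$n_comparable, 12L)
  expect_equal(r2$dm, 0.25)

  # no shared CG sites -> flagged undefined
  r3 <- dmcg_rate("AAAAAA", "AAAAAA", calls(integer(), logical()),
                  calls(integer(), logical()))
  expect_false(r3$defined)
  expect_true(is.na(r3$dm))
})

test_that("Dm vs Ks comparison reports direction and degenerate equality", {
  x <- runif(50, 0.1, 0.3)
  same <- compare_dm_vs_ks(x, x)
  expect_equal(same$direction, "equal")
  expect_gt(same$p, 0.9)
  expect_error(compare_dm_vs_ks(numeric(), numeric()), "empty")

  up <- compare_dm_vs_ks(x * 5, x)
  expect_equal(up$direction, "higher")
  expect_lt(up$p, 0.01)
})

test_that("metaprofiles recover regional levels and respect strand", {
  # uniform full methylation gives a profile of 1 everywhere
  genes <- data.frame(gene_id = "g1", chrom = "c1", start = 3001L,
                      end = 4000L, strand = "+")
  pos <- seq(1001L, 6000L, by = 20L)
  sites <- data.table::data.table(chrom = "c1", pos = pos, context = "CG",
                                  k = 10L, n = 10L)
  mp <- metaprofile(sites, genes)
  expect_true(all(mp$profile$level == 1))
  expect_error(metaprofile(sites, genes[0, ]), "empty annotation")

  # simulated step profile: upstream 0.2 / body 0.8
  cfg <- tiny_config()
  g <- simulate_genome(cfg, 9)
  me <- simulate_methylation(cfg, 9, truth = g$truth)
  cx <- read_cx(me$cx)
  mp2 <- metaprofile(cx, read_gff_genes(g$gff))
  pr <- mp2$profile[mp2$profile$context == "CG", ]
  up <- mean(pr$level[pr$region == "upstream"])
  body <- mean(pr$level[pr$region == "body"])
  expect_lt(abs(up - 0.2), 0.03)
  expect_lt(abs(body - 0.8), 0.03)

  # mirroring the gene and coordinates onto the minus strand leaves the
  # oriented profile unchanged
  L <- 7000L
  genes_m <- data.frame(gene_id = "g1", chrom = "c1",
                        start = L - 4000L + 1L, end = L - 3001L + 1L,
                        strand = "-")
  sites_m <- data.table::data.table(chrom = "c1", pos = L - pos + 1L,
                                    context = "CG", k = rep(c(10L, 5L), length.out = length(pos)),
                                    n = 10L)
  sites_p <- data.table::data.table(chrom = "c1", pos = pos, context = "CG",
                                    k = rep(c(10L, 5L), length.out = length(pos)),
                                    n = 10L)
  mp_p <- metaprofile(sites_p, genes)
  mp_m <- metaprofile(sites_m, genes_m)
  expect_equal(mp_m$profile[order(region, bin), level],
               mp_p$profile[order(region, bin), level], tolerance = 1e-12)
})

test_that("CG dyad strands are merged before calling", {
  tmp <- tempfile()
  tab <- data.frame(chrom = "c1", pos = c(10L, 11L, 50L),
                    strand = c("+", "-", "+"),
                    context = c("CG", "CG", "CHH"),
                    count_methylated = c(3L, 4L, 1L),
                    count_unmethylated = c(2L, 1L, 9L))
  write_tsv_c(tab, tmp)
  cx <- read_cx(tmp)
  cg <- cx[cx$context == "CG", ]
  expect_equal(nrow(cg), 1L)
  expect_equal(cg$pos, 10L)
  expect_equal(cg$k, 7L)
  expect_equal(cg$n, 10L)
})
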