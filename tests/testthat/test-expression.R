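make_expr <- function(pairs, mu_a, mu_b, n_tissues = 2L, n_rep = 3L,
                      noise = function(n, mu) rnorm(n, mu, mu * 0.05)) {
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    for (tt in paste0("t", seq_len(n_tissues))) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene = pairs$gene_A[i], tissue = tt, replicate = seq_len(n_rep),
        value = pmax(0, noise(n_rep, mu_a[i])))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene = pairs$gene_B[i], tissue = tt, replicate = seq_len(n_rep),
        value = pmax(0, noise(n_rep, mu_b[i])))
    }
  }
  data.table::rbindlist(rows)
}

test_that("HEB follows the signed log2 ratio convention", {
  expect_equal(compute_heb(100, 25, eps = 1e-9), 2, tolerance = 1e-6)
  expect_equal(compute_heb(50, 50), 0)
  expect_equal(compute_heb(0, 0), 0)  # pseudocount bounds silent pairs
  expect_error(compute_heb(-1, 5), "negative")
})

test_that("the fold gate blocks significant but sub-twofold pairs", {
  set.seed(61)
  pairs <- data.frame(pair_id = "p1", gene_A = "a1", gene_B = "b1")
  # strong significance (tiny variance) at fold 1.8: must stay unbiased
  expr <- make_expr(pairs, mu_a = 180, mu_b = 100,
                    noise = function(n, mu) rnorm(n, mu, 0.5))
  for (rule in c("paired", "any")) {
    calls <- call_bias(expr, pairs, rule = rule)
    expect_equal(calls$pair_calls$class, "unbiased")
  }
  # the same construction at fold 4 is called, in the right direction
  expr4 <- make_expr(pairs, mu_a = 400, mu_b = 100,
                     noise = function(n, mu) rnorm(n, mu, 0.5))
  for (rule in c("paired", "any")) {
    calls <- call_bias(expr4, pairs, rule = rule)
    expect_equal(calls$pair_calls$class, "A-biased")
  }
})

test_that("bias calls partition pairs and respect direction consistency", {
  cfg <- tiny_config(n_gene_pairs = 60L)
  out <- simulate_expression(cfg, 3)
  calls <- call_bias(read_expression(out$expr), out$truth$homoeolog_pairs)
  pc <- calls$pair_calls
  expect_equal(nrow(pc), 60L)
  expect_equal(sum(pc$class == "A-biased") + sum(pc$class == "B-biased") +
               sum(pc$class == "unbiased"), 60L)
  # tissue-level A-biased calls always have positive HEB in their tissue
  tc <- calls$tissue_calls
  expect_true(all(tc[tc$class == "A-biased", heb] > 0))
  expect_true(all(tc[tc$class == "B-biased", heb] < 0))
  # paired rule: called direction matches the sign of the mean log ratio
  expect_true(all(pc[pc$class == "A-biased", heb_mean] > 0))
  expect_true(all(pc[pc$class == "B-biased", heb_mean] < 0))
})

test_that("replicate and sign requirements raise errors", {
  pairs <- data.frame(pair_id = "p1", gene_A = "a1", gene_B = "b1")
  one_rep <- data.table::data.table(
    gene = c("a1", "b1"), tissue = "t1", replicate = 1L, value = c(5, 10))
  expect_error(call_bias(one_rep, pairs), "replicates")
  neg <- data.table::data.table(
    gene = rep(c("a1", "b1"), each = 2), tissue = "t1", replicate = 1:2,
    value = c(5, 6, -1, 2))
  expect_error(call_bias(neg, pairs), "negative")
})

test_that("the vectorised Welch test agrees with stats::t.test", {
  set.seed(62)
  pairs <- data.frame(pair_id = paste0("p", 1:10),
                      gene_A = paste0("a", 1:10), gene_B = paste0("b", 1:10))
  expr <- make_expr(pairs, mu_a = runif(10, 50, 200), mu_b = runif(10, 50, 200),
                    n_tissues = 3L, n_rep = 4L)
  calls <- call_bias(expr, pairs)$tissue_calls
  for (i in sample(nrow(calls), 10)) {
    va <- expr[gene == pairs$gene_A[match(calls$pair_id[i], pairs$pair_id)] &
               tissue == calls$tissue[i], value]
    vb <- expr[gene == pairs$gene_B[match(calls$pair_id[i], pairs$pair_id)] &
               tissue == calls$tissue[i], value]
    ref <- t.test(va, vb)
    expect_equal(calls$t[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(calls$p[i], ref$p.value, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up oracle and is monotone", {
  set.seed(63)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))^2
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-15)
    adj <- p.adjust(p, "BH")
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("null data keeps the biased fraction within the FDR budget", {
  cfg <- tiny_config(n_gene_pairs = 200L, expression_bias_fraction = 0)
  out <- simulate_expression(cfg, 8)
  calls <- call_bias(read_expression(out$expr), out$truth$homoeolog_pairs)
  frac <- mean(calls$pair_calls$class != "unbiased")
  expect_lte(frac, 0.05)
})

test_that("dominance testing uses the exact binomial sign test", {
  d <- dominance_test(c(338, 470))
  expect_equal(d$dominant, "B")
  expect_equal(d$p, oracle_sign_test(470, 808), tolerance = 1e-12)

  d2 <- dominance_test(c(10, 10))
  expect_equal(d2$dominant, "none")
  expect_equal(d2$p, 1)

  d3 <- dominance_test(c(0, 0))
  expect_equal(d3$dominant, "none")
  expect_equal(d3$p, 1)
})

test_that("selection-pressure comparison behaves on null and empty clusters", {
  pc <- data.table::data.table(pair_id = paste0("p", 1:40),
                               class = rep(c("A-biased", "B-biased"), 20))
  calls <- structure(list(pair_calls = pc), class = "bias_calls")
  set.seed(64)
  om <- runif(40, 0.1, 0.5)
  kaks <- data.table::data.table(pair_id = pc$pair_id, omega_A = om,
                                 omega_B = sample(om))
  res <- biased_set_selection_pressure(calls, kaks)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$p > 0.05))

  empty <- structure(list(pair_calls = pc[class == "A-biased"]),
                     class = "bias_calls")
  expect_error(biased_set_selection_pressure(empty, kaks), "empty cluster")

  # a real downward shift in the dominant copies is detected
  kaks2 <- data.table::data.table(pair_id = pc$pair_id,
                                  omega_A = c(runif(40, 0.05, 0.15)),
                                  omega_B = c(runif(40, 0.25, 0.45)))
  res2 <- biased_set_selection_pressure(calls, kaks2)
  expect_lt(res2[res2$cluster == "I", p], 0.05)
})
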