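# Homoeolog expression bias (HEB), per-pair bias calls and subgenome
# dominance.

#' Read a long-format expression table
#'
#' @param path TSV with columns gene, tissue, replicate, value.
#' @return data.table.
#' @export
read_expression <- function(path) {
  tab <- read_tsv_c(path)
  need <- c("gene", "tissue", "replicate", "value")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stopf("expression table lacks columns: %s",
                             paste(missing, collapse = ", "))
  if (any(tab$value < 0)) stopf("negative expression values")
  tab
}

#' Homoeolog expression bias
#'
#' `HEB = log2((mean_A + eps) / (mean_B + eps))` of replicate means;
#' positive values indicate bias toward subgenome A, negative toward B.
#' The pseudocount bounds HEB for zero expression (two silent copies give
#' HEB = 0).
#'
#' @param mean_A,mean_B replicate-mean expression of the two copies
#'   (vectors over tissues).
#' @param eps pseudocount on FPKM/TPM-like units.
#' @return numeric HEB per tissue.
#' @export
compute_heb <- function(mean_A, mean_B, eps = 1) {
  if (any(mean_A < 0) || any(mean_B < 0)) stopf("negative expression values")
  log2((mean_A + eps) / (mean_B + eps))
}

#' Call homoeolog expression bias per pair and tissue
#'
#' Per pair and tissue, a Welch t-test compares the replicate values of the
#' two copies; p-values are Benjamini-Hochberg adjusted across all
#' pair-x-tissue tests of the run (one family). A tissue-level call is
#' biased only when all three gates pass: raw p < `alpha_p`, adjusted
#' q < `alpha_fdr`, and fold change of replicate means >= `min_fold`
#' (pseudocounted). A pair is globally A-/B-biased when it is biased in
#' that direction in at least one tissue and never in the opposite one
#' (`rule = "any"`), or in every tissue (`rule = "all"`).
#'
#' @param expr expression table ([read_expression()] layout).
#' @param pairs data.frame pair_id, gene_A, gene_B.
#' @param alpha_p raw p-value threshold.
#' @param alpha_fdr BH-adjusted threshold.
#' @param min_fold minimum fold change of replicate means.
#' @param eps pseudocount for HEB and fold computation.
#' @param rule global classification rule: `"paired"` (default) classifies
#'   a pair from one paired t-test of the per-sample log2 ratios across the
#'   entire tissue-by-replicate dataset (BH across pairs), requiring the
#'   fold gate in at least one tissue in the called direction; `"any"` and
#'   `"all"` classify from the per-tissue calls (biased in >= 1 tissue and
#'   never the opposite, or in every tissue). The per-tissue design lacks
#'   power at 2-3 replicates; the whole-dataset paired test is the
#'   recommended default.
#' @param var_equal use the pooled-variance t-test instead of Welch for the
#'   per-tissue tests.
#' @return list of class `bias_calls`: `tissue_calls` (pair_id, tissue,
#'   heb, t, p, q, fold, class) and `pair_calls` (pair_id, class, and for
#'   the paired rule p, q).
#' @export
call_bias <- function(expr, pairs, alpha_p = 0.01, alpha_fdr = 0.05,
                      min_fold = 2, eps = 1, rule = c("paired", "any", "all"),
                      var_equal = FALSE) {
  rule <- match.arg(rule)
  expr <- as.data.table(expr)
  pairs <- as.data.table(pairs)
  if (any(expr$value < 0)) stopf("negative expression values")
  st <- expr[, .(m = mean(value), v = stats::var(value), n = .N),
             by = .(gene, tissue)]
  if (any(st$n < 2L))
    stopf("fewer than 2 replicates for some gene/tissue: the t-test requires >= 2 replicates")
  a <- merge(pairs[, .(pair_id, gene = gene_A)], st, by = "gene",
             allow.cartesian = TRUE)
  b <- merge(pairs[, .(pair_id, gene = gene_B)], st, by = "gene",
             allow.cartesian = TRUE)
  calls <- merge(a[, .(pair_id, tissue, mA = m, vA = v, nA = n)],
                 b[, .(pair_id, tissue, mB = m, vB = v, nB = n)],
                 by = c("pair_id", "tissue"))
  if (var_equal) {
    calls[, sp2 := ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)]
    calls[, `:=`(se = sqrt(sp2 * (1 / nA + 1 / nB)), df = nA + nB - 2)]
  } else {
    calls[, se := sqrt(vA / nA + vB / nB)]
    calls[, df := (vA / nA + vB / nB)^2 /
            ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))]
  }
  calls[, t := (mA - mB) / se]
  calls[, p := 2 * stats::pt(-abs(t), df)]
  calls[!is.finite(t), `:=`(t = NA_real_, p = 1)]
  calls[, heb := compute_heb(mA, mB, eps)]
  calls[, fold := pmax(mA + eps, mB + eps) / pmin(mA + eps, mB + eps)]
  calls <- calls[, .(pair_id, tissue, heb, t, p, fold)]
  setorder(calls, pair_id, tissue)
  calls[, q := p.adjust(p, method = "BH")]
  calls[, class := "unbiased"]
  calls[p < alpha_p & q < alpha_fdr & fold >= min_fold,
        class := ifelse(heb > 0, "A-biased", "B-biased")]

  if (rule == "paired") {
    ja <- merge(pairs[, .(pair_id, gene = gene_A)], expr, by = "gene",
                allow.cartesian = TRUE)
    jb <- merge(pairs[, .(pair_id, gene = gene_B)], expr, by = "gene",
                allow.cartesian = TRUE)
    j <- merge(ja[, .(pair_id, tissue, replicate, a_val = value)],
               jb[, .(pair_id, tissue, replicate, b_val = value)],
               by = c("pair_id", "tissue", "replicate"))
    j[, d := log2(a_val + eps) - log2(b_val + eps)]
    agg <- j[, .(m = mean(d), s = stats::sd(d), n = .N), by = pair_id]
    agg[, t := m / (s / sqrt(n))]
    agg[, p := 2 * stats::pt(-abs(t), n - 1)]
    agg[s == 0, p := ifelse(m == 0, 1, 0)]
    agg[, q := p.adjust(p, "BH")]
    gate <- calls[, .(
      gate_A = any(heb > 0 & fold >= min_fold),
      gate_B = any(heb < 0 & fold >= min_fold)), by = pair_id]
    agg <- merge(agg, gate, by = "pair_id")
    agg[, class := "unbiased"]
    agg[p < alpha_p & q < alpha_fdr & m > 0 & gate_A, class := "A-biased"]
    agg[p < alpha_p & q < alpha_fdr & m < 0 & gate_B, class := "B-biased"]
    pair_calls <- agg[, .(pair_id, class, heb_mean = m, p, q)]
  } else {
    agg <- calls[, .(
      a = sum(class == "A-biased"), b = sum(class == "B-biased"), n = .N),
      by = pair_id]
    agg[, class := "unbiased"]
    if (rule == "any") {
      agg[a > 0 & b == 0, class := "A-biased"]
      agg[b > 0 & a == 0, class := "B-biased"]
    } else {
      agg[a == n, class := "A-biased"]
      agg[b == n, class := "B-biased"]
    }
    pair_calls <- agg[, .(pair_id, class)]
  }
  structure(list(tissue_calls = calls,
                 pair_calls = pair_calls,
                 params = list(alpha_p = alpha_p, alpha_fdr = alpha_fdr,
                               min_fold = min_fold, eps = eps, rule = rule)),
            class = "bias_calls")
}

#' Test subgenome dominance from bias calls
#'
#' Two-sided exact binomial sign test of the A-biased vs B-biased pair
#' counts against 0.5. A subgenome is declared dominant only when p < 0.05;
#' zero biased pairs give "none" with p = 1.
#'
#' @param calls a `bias_calls` object, or a vector of pair-level classes,
#'   or a length-2 numeric `c(n_A, n_B)` of biased-pair counts.
#' @return list of class `dominance_result`: n_A, n_B, p, dominant.
#' @export
dominance_test <- function(calls) {
  if (inherits(calls, "bias_calls")) calls <- calls$pair_calls$class
  if (is.numeric(calls) && length(calls) == 2) {
    nA <- calls[1]; nB <- calls[2]
  } else {
    nA <- sum(calls == "A-biased"); nB <- sum(calls == "B-biased")
  }
  n <- nA + nB
  if (n == 0)
    return(structure(list(n_A = 0, n_B = 0, p = 1, dominant = "none"),
                     class = "dominance_result"))
  p <- binom.test(nB, n, p = 0.5)$p.value
  dominant <- if (p < 0.05) { if (nB > nA) "B" else "A" } else "none"
  structure(list(n_A = nA, n_B = nB, p = p, dominant = dominant),
            class = "dominance_result")
}

#' Compare selection pressure between dominant and suppressed homoeologs
#'
#' For each bias cluster (A-biased pairs: cluster I; B-biased: cluster II),
#' the Ka/Ks of the dominantly transcribed copies is compared with that of
#' their suppressed homoeologs by the Mann-Whitney U test.
#'
#' @param calls a `bias_calls` object.
#' @param kaks data.table from [ng86_pairs()] (needs pair_id, omega for
#'   each copy: columns omega_A and omega_B, or a single omega applying to
#'   the pair is not enough — per-copy estimates, e.g. against an outgroup
#'   copy, are required).
#' @return data.table: cluster, n_pairs, U, p, median_dominant,
#'   median_suppressed.
#' @export
biased_set_selection_pressure <- function(calls, kaks) {
  stopifnot(inherits(calls, "bias_calls"))
  kaks <- as.data.table(kaks)
  need <- c("pair_id", "omega_A", "omega_B")
  missing <- setdiff(need, names(kaks))
  if (length(missing)) stopf("kaks table lacks columns: %s",
                             paste(missing, collapse = ", "))
  pc <- calls$pair_calls
  out <- list()
  for (cl in c("A-biased", "B-biased")) {
    ids <- pc[class == cl, pair_id]
    k <- kaks[pair_id %in% ids]
    if (!nrow(k)) stopf("empty cluster: no %s pairs with Ka/Ks estimates", cl)
    dom <- if (cl == "A-biased") k$omega_A else k$omega_B
    sup <- if (cl == "A-biased") k$omega_B else k$omega_A
    keep <- !is.na(dom) & !is.na(sup)
    mw <- mann_whitney_u(dom[keep], sup[keep])
    out[[cl]] <- data.table(cluster = if (cl == "A-biased") "I" else "II",
                            n_pairs = sum(keep), U = mw$U, p = mw$p,
                            median_dominant = median(dom[keep]),
                            median_suppressed = median(sup[keep]))
  }
  rbindlist(out)
}
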