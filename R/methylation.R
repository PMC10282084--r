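# Per-cytosine binomial methylation calls, gene-body methylation testing,
# CG body-methylated pair selection, metaprofiles and the DmCG/C
# epimutation rate.

#' Read a per-cytosine methylation table
#'
#' CX-report-like layout: chrom, pos (1-based), strand, context (CG, CHG,
#' CHH), count_methylated, count_unmethylated.
#'
#' @param path TSV path (comment lines beginning `#` allowed).
#' @param merge_cg merge the two strands of a CG dyad (counts of the
#'   `-`-strand cytosine at pos p are added to the `+`-strand cytosine at
#'   p - 1) before calling.
#' @return data.table with an added coverage column `n` and `k` methylated
#'   reads.
#' @export
read_cx <- function(path, merge_cg = TRUE) {
  tab <- read_tsv_c(path)
  need <- c("chrom", "pos", "strand", "context", "count_methylated",
            "count_unmethylated")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stopf("cytosine table lacks columns: %s",
                             paste(missing, collapse = ", "))
  tab <- as.data.table(tab)
  if (merge_cg && any(tab$context == "CG" & tab$strand == "-")) {
    cg <- tab[context == "CG"]
    cg[strand == "-", pos := pos - 1L]
    cg <- cg[, .(count_methylated = sum(count_methylated),
                 count_unmethylated = sum(count_unmethylated),
                 strand = "+"),
             by = .(chrom, pos, context)]
    tab <- rbind(tab[context != "CG"], cg, use.names = TRUE, fill = TRUE)
  }
  tab[, `:=`(k = count_methylated, n = count_methylated + count_unmethylated)]
  if (any(tab$k > tab$n)) stopf("methylated count exceeds coverage")
  setorder(tab, chrom, pos, context)
  tab
}

#' Binomial methylation call for cytosine sites
#'
#' The site p-value is the upper-tail binomial probability
#' `P(X >= k | n, p_err)`; a site is called methylated when the p-value is
#' below `alpha`. An optional BH correction across all sites is exposed but
#' off by default (per-site usage).
#'
#' @param sites data.table with columns n (coverage) and k (methylated
#'   reads), e.g. from [read_cx()].
#' @param p_err error rate (bisulfite non-conversion).
#' @param alpha per-site significance threshold.
#' @param adjust apply BH correction across sites before thresholding.
#' @return input with added columns `p_site` and `methylated`.
#' @export
call_sites <- function(sites, p_err = 0.01, alpha = 0.05, adjust = FALSE) {
  s <- data.table::copy(as.data.table(sites))
  if (any(s$k > s$n)) stopf("methylated count exceeds coverage")
  if (any(s$n < 1)) stopf("coverage must be >= 1")
  s[, p_site := pbinom(k - 1, n, p_err, lower.tail = FALSE)]
  if (adjust) s[, methylated := p.adjust(p_site, "BH") < alpha]
  else s[, methylated := p_site < alpha]
  s
}

#' Genome-wide background methylation proportion per context
#'
#' The proportion of covered C residues (coverage > `min_cov`) called
#' methylated, per context — the background `p_c` of the gene-body test.
#'
#' @param called output of [call_sites()].
#' @param min_cov strict coverage floor (sites with n <= min_cov are
#'   excluded).
#' @return named numeric vector per context.
#' @export
methylation_background <- function(called, min_cov = 5L) {
  d <- as.data.table(called)[n > min_cov]
  v <- d[, .(p = mean(methylated)), by = context]
  setNames(v$p, v$context)
}

#' Exact binomial upper tail of the gene-body methylation test
#'
#' `P_c = sum_{i = m_c}^{n_c} C(n_c, i) p_c^i (1 - p_c)^{n_c - i}`:
#' the probability of observing at least `m_c` methylated cytosines among
#' `n_c` covered ones under the genome-wide background proportion `p_c`.
#' Evaluated in log space via the binomial distribution function.
#'
#' @param n_c covered C residues in the gene body (coverage > 5).
#' @param m_c methylated C residues among them.
#' @param p_c genome-wide background proportion, in (0, 1).
#' @return upper-tail probability.
#' @export
gene_body_pvalue <- function(n_c, m_c, p_c) {
  if (any(p_c <= 0 | p_c >= 1)) stopf("background proportion must lie in (0, 1)")
  if (any(n_c < 1)) stopf("n_c must be >= 1")
  if (any(m_c > n_c)) stopf("m_c cannot exceed n_c")
  pbinom(m_c - 1, n_c, p_c, lower.tail = FALSE)
}

#' Per-gene, per-context methylation statistics
#'
#' Counts covered (coverage > `min_cov`) and methylated cytosines per gene
#' body and context, and evaluates the gene-body binomial test against the
#' genome-wide background of the same input.
#'
#' @param called output of [call_sites()].
#' @param genes annotation table (gene_id, chrom, start, end).
#' @param min_cov strict coverage floor.
#' @return data.table: gene_id, context, n_c, m_c, p_c, P_c.
#' @export
gene_methylation_stats <- function(called, genes, min_cov = 5L) {
  d <- as.data.table(called)[n > min_cov]
  genes <- as.data.table(genes)
  bg <- methylation_background(called, min_cov)
  rows <- list()
  data.table::setkey(d, chrom, pos)
  for (i in seq_len(nrow(genes))) {
    s <- d[chrom == genes$chrom[i] & pos >= genes$start[i] & pos <= genes$end[i]]
    if (!nrow(s)) next
    agg <- s[, .(n_c = .N, m_c = sum(methylated)), by = context]
    agg[, `:=`(gene_id = genes$gene_id[i], p_c = bg[context])]
    rows[[length(rows) + 1L]] <- agg
  }
  out <- rbindlist(rows)
  out[, P_c := ifelse(p_c > 0 & p_c < 1,
                      gene_body_pvalue(n_c, m_c, pmin(pmax(p_c, 1e-12), 1 - 1e-12)),
                      NA_real_)]
  out[, .(gene_id, context, n_c, m_c, p_c, P_c)]
}

#' Select CG body-methylated homoeologous pairs
#'
#' A pair is kept iff both members are CG body-methylated (P_CG < `alpha`)
#' and neither member shows CHG or CHH body methylation (P_CHG and P_CHH
#' both >= `alpha`), so that the class isolates CG-only gene-body
#' methylation.
#'
#' @param stats per-gene stats from [gene_methylation_stats()].
#' @param pairs data.frame pair_id, gene_A, gene_B.
#' @param alpha significance threshold on the binomial tail.
#' @return data.table of kept pairs with both members' P-values.
#' @export
select_body_methylated_pairs <- function(stats, pairs, alpha = 0.05) {
  stats <- as.data.table(stats)
  pairs <- as.data.table(pairs)
  wide <- dcast(stats, gene_id ~ context, value.var = "P_c")
  for (ctx in c("CG", "CHG", "CHH"))
    if (!ctx %in% names(wide)) wide[, (ctx) := NA_real_]
  pv <- function(g, ctx) {
    i <- match(g, wide$gene_id)
    wide[[ctx]][i]
  }
  keep <- rep(FALSE, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pa_cg <- pv(pairs$gene_A[i], "CG"); pb_cg <- pv(pairs$gene_B[i], "CG")
    if (is.na(pa_cg) || is.na(pb_cg)) next
    other <- c(pv(pairs$gene_A[i], "CHG"), pv(pairs$gene_B[i], "CHG"),
               pv(pairs$gene_A[i], "CHH"), pv(pairs$gene_B[i], "CHH"))
    other <- other[!is.na(other)]
    keep[i] <- pa_cg < alpha && pb_cg < alpha && all(other >= alpha)
  }
  out <- pairs[keep]
  out[, `:=`(P_CG_A = pv(gene_A, "CG"), P_CG_B = pv(gene_B, "CG"))]
  out
}

#' DmCG/C methylation divergence of one homoeologous pair
#'
#' Comparable sites are aligned positions where both sequences carry a CG
#' dinucleotide and both carry a methylation status call; DmCG/C is the
#' fraction of comparable sites whose methylated/unmethylated status
#' differs between the copies — an epimutation-rate analogue of Ks.
#'
#' @param seq_a,seq_b aligned (equal-length, gap-free here) sequences.
#' @param calls_a,calls_b data.tables (pos, methylated) of site-level
#'   status calls in sequence coordinates.
#' @return list of class `dm_record`: n_comparable, n_discordant, dm
#'   (NA with `defined = FALSE` when no comparable sites exist).
#' @export
dmcg_rate <- function(seq_a, seq_b, calls_a, calls_b) {
  pos <- intersect(cg_positions(as.character(seq_a)),
                   cg_positions(as.character(seq_b)))
  calls_a <- as.data.table(calls_a); calls_b <- as.data.table(calls_b)
  pos <- pos[pos %in% calls_a$pos & pos %in% calls_b$pos]
  if (!length(pos))
    return(structure(list(n_comparable = 0L, n_discordant = 0L,
                          dm = NA_real_, defined = FALSE),
                     class = "dm_record"))
  ma <- calls_a$methylated[match(pos, calls_a$pos)]
  mb <- calls_b$methylated[match(pos, calls_b$pos)]
  disc <- sum(ma != mb)
  structure(list(n_comparable = length(pos), n_discordant = disc,
                 dm = disc / length(pos), defined = TRUE),
            class = "dm_record")
}

#' Compare the DmCG/C epimutation rate with Ks
#'
#' Wilcoxon rank-sum test between the per-pair DmCG/C values and the
#' per-pair synonymous substitution rates; reports the direction of the
#' shift.
#'
#' @param dm numeric DmCG/C values per pair.
#' @param ks numeric Ks values per pair.
#' @return list: direction ("higher"/"lower"/"equal" for Dm vs Ks), U, p,
#'   median_dm, median_ks.
#' @export
compare_dm_vs_ks <- function(dm, ks) {
  dm <- dm[!is.na(dm)]; ks <- ks[!is.na(ks)]
  if (!length(dm) || !length(ks)) stopf("empty input")
  mw <- wilcoxon_rank_sum(dm, ks)
  md <- median(dm); mk <- median(ks)
  list(direction = if (md > mk) "higher" else if (md < mk) "lower" else "equal",
       U = mw$U, p = mw$p, median_dm = md, median_ks = mk)
}

#' Methylation metaprofile over gene bodies and flanks
#'
#' Per gene and context, weighted methylation levels (sum k / sum n) are
#' binned over the 2 kb upstream flank, the length-scaled gene body, and
#' the 2 kb downstream flank; minus-strand genes are flipped so upstream is
#' always 5'. The profile averages per-gene bin levels across genes.
#'
#' @param sites data.table from [read_cx()].
#' @param genes annotation table (gene_id, chrom, start, end, strand).
#' @param flank flank width in bp.
#' @param body_bins,flank_bins bin counts.
#' @return list of class `metaprofile`: data.table (context, region, bin,
#'   level, n_genes), plus counts of skipped genes (shorter than the body
#'   bin count).
#' @export
metaprofile <- function(sites, genes, flank = 2000L, body_bins = 20L,
                        flank_bins = 10L) {
  genes <- as.data.table(genes)
  if (!nrow(genes)) stopf("empty annotation")
  s <- as.data.table(sites)
  acc <- list()
  skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    glen <- genes$end[i] - genes$start[i] + 1L
    if (glen < body_bins) { skipped <- skipped + 1L; next }
    gs <- s[chrom == genes$chrom[i] &
              pos >= genes$start[i] - flank & pos <= genes$end[i] + flank]
    if (!nrow(gs)) next
    rel <- gs$pos - genes$start[i]
    region <- ifelse(rel < 0, "upstream", ifelse(rel >= glen, "downstream", "body"))
    bin <- integer(nrow(gs))
    up <- region == "upstream"
    bin[up] <- pmin(flank_bins - 1L, ((rel[up] + flank) * flank_bins) %/% flank)
    bo <- region == "body"
    bin[bo] <- pmin(body_bins - 1L, (rel[bo] * body_bins) %/% glen)
    dn <- region == "downstream"
    bin[dn] <- pmin(flank_bins - 1L, ((rel[dn] - glen) * flank_bins) %/% flank)
    gd <- data.table(context = gs$context, region = region, bin = bin,
                     k = gs$k, n = gs$n)
    if (identical(genes$strand[i], "-")) {
      up <- gd$region == "upstream"; dn <- gd$region == "downstream"
      bo <- gd$region == "body"
      new_region <- gd$region; new_bin <- gd$bin
      new_region[up] <- "downstream"; new_region[dn] <- "upstream"
      new_bin[up] <- flank_bins - 1L - gd$bin[up]
      new_bin[dn] <- flank_bins - 1L - gd$bin[dn]
      new_bin[bo] <- body_bins - 1L - gd$bin[bo]
      gd[, `:=`(region = new_region, bin = new_bin)]
    }
    acc[[length(acc) + 1L]] <- gd[, .(level = sum(k) / sum(n)),
                                  by = .(context, region, bin)]
  }
  if (!length(acc)) stopf("no genes with methylation sites")
  all <- rbindlist(acc)
  prof <- all[, .(level = mean(level), n_genes = .N),
              by = .(context, region, bin)]
  setorder(prof, context, region, bin)
  structure(list(profile = prof, n_skipped = skipped), class = "metaprofile")
}
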