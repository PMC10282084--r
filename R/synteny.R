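# Syntenic-block chaining over gene-rank coordinates and reciprocal-best-hit
# homoeolog pairing.

#' Derive gene ranks from an annotation
#'
#' Ranks are 0-based ordinal positions of genes along their chromosome,
#' ordered by start coordinate; gaps between syntenic anchors are measured
#' in these gene units.
#'
#' @param genes data.frame with gene_id, chrom, start.
#' @return data.table (gene_id, chrom, rank).
#' @export
gene_ranks <- function(genes) {
  g <- as.data.table(genes)[, .(gene_id, chrom, start)]
  setorder(g, chrom, start)
  g[, rank := seq_len(.N) - 1L, by = chrom]
  g[, .(gene_id, chrom, rank)]
}

#' Read 12-column tabular homology hits
#'
#' Standard blast/LAST tabular layout: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore.
#'
#' @param path TSV path (comment lines beginning `#` allowed).
#' @return data.table (query, subject, identity, score).
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- data.table::fread(text = paste(lines, collapse = "\n"), header = FALSE)
  data.table(query = as.character(f$V1), subject = as.character(f$V2),
             identity = f$V3, score = f$V12)
}

#' Attach gene-rank coordinates to homology hits
#'
#' @param hits data.table (query, subject, score, identity optional).
#' @param genes annotation table accepted by [gene_ranks()].
#' @return hits with qchrom, qrank, schrom, srank columns.
#' @export
rank_hits <- function(hits, genes) {
  rk <- gene_ranks(genes)
  h <- as.data.table(hits)
  iq <- match(h$query, rk$gene_id)
  is <- match(h$subject, rk$gene_id)
  bad <- c(h$query[is.na(iq)], h$subject[is.na(is)])
  if (length(bad)) stopf("hits reference unknown gene(s): %s",
                         paste(unique(bad), collapse = ", "))
  h[, `:=`(qchrom = rk$chrom[iq], qrank = rk$rank[iq],
           schrom = rk$chrom[is], srank = rk$rank[is])]
  h
}

# MCScanX-style preprocessing: hits sharing a query whose subjects are
# adjacent on the same chromosome are tandem-duplicate artefacts; only the
# best-scoring of each adjacent run is kept.
collapse_tandem <- function(hits) {
  h <- data.table::copy(as.data.table(hits))
  setorder(h, query, schrom, srank, -score)
  h[, run := cumsum(c(1L, diff(srank) > 1L)), by = .(query, schrom)]
  h <- h[h[, .I[which.max(score)], by = .(query, schrom, run)]$V1]
  h[, run := NULL]
  h
}

#' Chain homology hits into syntenic blocks
#'
#' Maximal score-weighted chains are found by dynamic programming over gene
#' ranks, separately per chromosome pair and orientation. Consecutive
#' anchors must be strictly monotone on both rank axes (increasing for "+",
#' subject-decreasing for "-") with rank gaps of at most `max_gap` genes on
#' both axes. Chains are extracted greedily by descending chain score (ties
#' broken toward the smaller query start rank), each hit used in at most
#' one block, and chains with fewer than `min_pairs` anchors discarded.
#'
#' @param hits ranked hits from [rank_hits()] (or any table with query,
#'   subject, score, qchrom, qrank, schrom, srank).
#' @param max_gap maximum rank gap between consecutive anchors, in genes.
#' @param min_pairs minimum anchors per retained block.
#' @param collapse_tandems collapse tandem-duplicate hits before chaining.
#' @return list: `blocks` (block_id, qchrom, schrom, orientation,
#'   n_anchors, score), `anchors` (block_id plus the hit columns, in chain
#'   order).
#' @export
chain_syntenic_blocks <- function(hits, max_gap = 20L, min_pairs = 5L,
                                  collapse_tandems = TRUE) {
  h <- as.data.table(hits)
  if (collapse_tandems) h <- collapse_tandem(h)
  blocks <- list(); anchors <- list(); bid <- 0L
  for (grp in split(h, by = c("qchrom", "schrom"))) {
    avail <- data.table::copy(grp)
    repeat {
      best <- NULL
      for (orient in c("+", "-")) {
        ch <- best_chain(avail, orient, max_gap, min_pairs)
        if (is.null(ch)) next
        if (is.null(best) || ch$score > best$score ||
            (ch$score == best$score &&
             min(ch$rows$qrank) < min(best$rows$qrank)))
          best <- ch
      }
      if (is.null(best)) break
      bid <- bid + 1L
      blocks[[bid]] <- data.table(
        block_id = bid, qchrom = best$rows$qchrom[1],
        schrom = best$rows$schrom[1], orientation = best$orient,
        n_anchors = nrow(best$rows), score = best$score)
      anchors[[bid]] <- data.table(block_id = bid, best$rows)
      avail <- avail[!paste(query, subject) %in%
                       paste(best$rows$query, best$rows$subject)]
      if (!nrow(avail)) break
    }
  }
  list(blocks = if (length(blocks)) rbindlist(blocks) else
         data.table(block_id = integer(), qchrom = character(),
                    schrom = character(), orientation = character(),
                    n_anchors = integer(), score = numeric()),
       anchors = if (length(anchors)) rbindlist(anchors) else data.table())
}

# Best score-weighted chain with at least min_pairs anchors for one
# orientation. DP state (hit, capped chain length): f[i, l] is the best
# score of a chain ending at hit i whose length is l (l = min_pairs means
# ">= min_pairs"), which makes the anchor-count constraint exact.
best_chain <- function(hits, orient, max_gap, min_pairs) {
  if (!nrow(hits)) return(NULL)
  h <- data.table::copy(hits)
  if (orient == "+") setorder(h, qrank, srank) else setorder(h, qrank, -srank)
  n <- nrow(h)
  k <- max(1L, as.integer(min_pairs))
  f <- matrix(-Inf, n, k)
  f[, 1] <- h$score
  prevj <- matrix(NA_integer_, n, k)
  prevl <- matrix(NA_integer_, n, k)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      dq <- h$qrank[i] - h$qrank[j]
      ds <- if (orient == "+") h$srank[i] - h$srank[j]
            else h$srank[j] - h$srank[i]
      if (dq < 1L || dq > max_gap || ds < 1L || ds > max_gap) next
      for (l in seq_len(k)) {
        if (!is.finite(f[j, l])) next
        l2 <- min(l + 1L, k)
        cand <- f[j, l] + h$score[i]
        if (cand > f[i, l2]) {
          f[i, l2] <- cand; prevj[i, l2] <- j; prevl[i, l2] <- l
        }
      }
    }
  }
  if (!any(is.finite(f[, k]))) return(NULL)
  top <- max(f[, k])
  end <- which(f[, k] == top)
  backtrack <- function(i, l) {
    path <- integer()
    while (!is.na(i)) {
      path <- c(i, path)
      j <- prevj[i, l]; l <- if (is.na(j)) NA_integer_ else prevl[i, l]
      i <- j
    }
    path
  }
  # tie-break toward the chain with the smallest query start rank
  starts <- vapply(end, function(i) as.numeric(h$qrank[backtrack(i, k)[1]]), 0)
  end <- end[which.min(starts)]
  path <- backtrack(end, k)
  list(rows = h[path], score = top, orient = orient)
}

#' Reciprocal best hit pairs
#'
#' A pair (a, b) is retained iff b is a's unique best-scoring subject and a
#' is b's unique best-scoring query. A tie for best score on either side
#' drops the gene.
#'
#' @param hits data.table (query, subject, score).
#' @return data.table (gene_A = query, gene_B = subject, score,
#'   provenance = "RBH").
#' @export
reciprocal_best_pairs <- function(hits) {
  h <- as.data.table(hits)
  bq <- h[, .(best = max(score), n = sum(score == max(score)),
              subject = subject[which.max(score)]), by = query][n == 1L]
  bs <- h[, .(best = max(score), n = sum(score == max(score)),
              query = query[which.max(score)]), by = subject][n == 1L]
  m <- merge(bq[, .(query, subject, score = best)],
             bs[, .(subject, query)], by = c("query", "subject"))
  out <- m[, .(gene_A = query, gene_B = subject, score, provenance = "RBH")]
  setorder(out, gene_A)
  out
}

#' Derive single-copy homoeologous pairs from blocks and RBH
#'
#' Pairs that are reciprocal best hits; those also anchored in a syntenic
#' block carry provenance "block+RBH", the rest "RBH-only" (dropped when
#' `strict`). Each gene is used at most once: conflicts are resolved toward
#' the higher-scoring pair, deterministically.
#'
#' @param blocks result of [chain_syntenic_blocks()].
#' @param rbh_pairs result of [reciprocal_best_pairs()].
#' @param strict require block anchoring.
#' @return data.table (gene_A, gene_B, score, provenance, single_copy).
#' @export
single_copy_pairs <- function(blocks, rbh_pairs, strict = FALSE) {
  p <- data.table::copy(as.data.table(rbh_pairs))
  anch <- if (nrow(blocks$anchors))
    paste(blocks$anchors$query, blocks$anchors$subject) else character()
  p[, provenance := ifelse(paste(gene_A, gene_B) %in% anch, "block+RBH",
                           "RBH-only")]
  if (strict) p <- p[provenance == "block+RBH"]
  setorder(p, -score, gene_A)
  used_a <- character(); used_b <- character(); keep <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    if (p$gene_A[i] %in% used_a || p$gene_B[i] %in% used_b) next
    keep[i] <- TRUE
    used_a <- c(used_a, p$gene_A[i]); used_b <- c(used_b, p$gene_B[i])
  }
  out <- p[keep]
  out[, single_copy := TRUE]
  setorder(out, gene_A)
  out
}
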