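# Canonical k-mer counting, k-mer-histogram genome size estimation, and
# differential-k-mer subgenome phasing.

NTS <- c("A", "C", "G", "T")

#' Count canonical k-mers per chromosome
#'
#' Every length-L sequence contributes L-k+1 windows; each window is counted
#' under its canonical form (the lexicographic minimum of the window and its
#' reverse complement). Windows containing non-ACGT symbols are skipped.
#' K-mers are held as exact base-4 integer codes (k <= 26 fits a double
#' exactly); [decode_kmer()] maps codes back to strings.
#'
#' @param sequences FASTA path, named character vector, or `DNAStringSet`.
#' @param k k-mer length (odd k recommended so canonicalization is
#'   unambiguous; the phasing default is 13).
#' @return object of class `kmer_counts`: list(table = data.table(code,
#'   chrom, n), k, chroms).
#' @export
count_kmers <- function(sequences, k) {
  stopifnot(k >= 1)
  if (is.character(sequences) && length(sequences) == 1 && file.exists(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  if (inherits(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  if (k > 26) stopf("k > 26 exceeds the exact integer-code range")
  tabs <- list()
  for (ch in names(sequences)) {
    v <- match(strsplit(toupper(sequences[[ch]]), "")[[1]], NTS) - 1L
    L <- length(v)
    if (L < k) next
    nw <- L - k + 1L
    fwd <- numeric(nw); rev <- numeric(nw)
    for (j in seq_len(k)) {
      seg <- v[j:(j + nw - 1L)]
      fwd <- fwd + seg * 4^(k - j)
      rev <- rev + (3 - seg) * 4^(j - 1)
    }
    can <- pmin(fwd, rev)
    can <- can[!is.na(can)]
    if (!length(can)) next
    tabs[[ch]] <- data.table(code = can)[, .(n = .N), by = code][, chrom := ch]
  }
  if (!length(tabs)) {
    if (length(sequences) && k > max(nchar(sequences)))
      warnf("k = %d exceeds the longest sequence; empty counts", k)
    return(structure(list(table = data.table(code = numeric(), chrom = character(),
                                             n = integer()),
                          k = k, chroms = names(sequences)),
                     class = "kmer_counts"))
  }
  structure(list(table = rbindlist(tabs, use.names = TRUE), k = k,
                 chroms = names(sequences)),
            class = "kmer_counts")
}

#' Decode base-4 k-mer codes to strings
#' @param code numeric codes as produced by [count_kmers()].
#' @param k k-mer length.
#' @return character vector.
#' @export
decode_kmer <- function(code, k) {
  vapply(code, function(x) {
    d <- integer(k)
    for (j in k:1) { d[j] <- x %% 4; x <- x %/% 4 }
    paste(NTS[d + 1L], collapse = "")
  }, "")
}

#' Genome-wide canonical k-mer totals
#' @param counts a `kmer_counts` object.
#' @return named integer vector (decoded k-mer -> total count).
#' @export
kmer_totals <- function(counts) {
  stopifnot(inherits(counts, "kmer_counts"))
  tot <- counts$table[, .(n = sum(n)), by = code]
  setNames(tot$n, decode_kmer(tot$code, counts$k))
}

#' k-mer depth histogram
#'
#' @param depth integer depths (>= 1).
#' @param count distinct k-mers observed at each depth.
#' @param k k-mer length used to build the histogram.
#' @return object of class `kmer_histogram` with `total_kmers` (the
#'   depth-weighted sum, i.e. total k-mer instances) precomputed.
#' @export
kmer_histogram <- function(depth, count, k = 17L) {
  stopifnot(length(depth) == length(count), all(depth >= 1), all(count >= 0))
  structure(list(depth = as.integer(depth), count = as.numeric(count), k = k,
                 total_kmers = sum(as.numeric(depth) * as.numeric(count))),
            class = "kmer_histogram")
}

#' Estimate genome size from a k-mer depth histogram
#'
#' Genome size = total k-mer instances / expected k-mer depth, where the
#' expected depth is the modal depth of the histogram after masking depths
#' below the error cutoff (low-depth k-mers are dominated by sequencing
#' errors).
#'
#' @param hist a [kmer_histogram()].
#' @param error_cutoff depths below this are masked when locating the peak.
#' @return list of class `genome_size_estimate`: size_bp, k,
#'   expected_depth, total_kmers.
#' @export
estimate_genome_size <- function(hist, error_cutoff = 4L) {
  stopifnot(inherits(hist, "kmer_histogram"))
  keep <- hist$depth >= error_cutoff
  if (!any(keep)) stopf("no peak: histogram has no depths >= %d", error_cutoff)
  d <- hist$depth[keep]; cnt <- hist$count[keep]
  i <- which.max(cnt)
  if (i == 1L && length(cnt) > 1L && all(diff(cnt) <= 0))
    stopf("no peak: histogram is monotonically decreasing")
  peak <- d[i]
  structure(list(size_bp = hist$total_kmers / peak, k = hist$k,
                 expected_depth = peak, total_kmers = hist$total_kmers),
            class = "genome_size_estimate")
}

#' Phasing parameters
#'
#' @param k k-mer length; odd and >= 5 so canonicalization is unambiguous.
#' @param min_total_count genome-wide occurrence floor, strict `>`.
#' @param min_fold required enrichment ratio between the two members of a
#'   homoeologous chromosome pair (> 1).
#' @param pseudocount added to both counts in the ratio for stability.
#' @return list of class `phasing_params`.
#' @export
phasing_params <- function(k = 13L, min_total_count = 100L, min_fold = 2.0,
                           pseudocount = 1) {
  if (k %% 2 == 0 || k < 5) stopf("k must be odd and >= 5")
  if (min_fold <= 1) stopf("min_fold must be > 1")
  structure(list(k = as.integer(k), min_total_count = min_total_count,
                 min_fold = min_fold, pseudocount = pseudocount),
            class = "phasing_params")
}

#' Select k-mers differentially enriched between homoeologous chromosomes
#'
#' A k-mer is retained iff its genome-wide count is strictly greater than
#' `min_total_count` and, for at least one listed homoeologous chromosome
#' pair, the pseudocounted count ratio in one direction or the other is at
#' least `min_fold`.
#'
#' @param counts a `kmer_counts` object covering all chromosomes in `pairs`.
#' @param pairs data.frame with columns chrom_A, chrom_B (homoeologous
#'   chromosome pairs; the enrichment criterion is pair-relative).
#' @param params a [phasing_params()].
#' @param enforce_floor internal switch used by [phase_subgenomes()]'s
#'   weak-signal fallback; the strict floor is always applied by default.
#' @return object of class `diff_kmer_matrix`: list(counts = k-mer x
#'   chromosome count matrix, z = row-z-scaled view, params).
#' @export
select_differential_kmers <- function(counts, pairs, params = phasing_params(),
                                      enforce_floor = TRUE) {
  stopifnot(inherits(counts, "kmer_counts"))
  pairs <- as.data.frame(pairs)
  if (!nrow(pairs)) stopf("empty homoeologous pair list: the enrichment criterion is pair-relative")
  need <- unique(c(pairs$chrom_A, pairs$chrom_B))
  missing <- setdiff(need, counts$chroms)
  if (length(missing)) stopf("counts lack chromosomes: %s",
                             paste(missing, collapse = ", "))
  tab <- counts$table
  tot <- tab[, .(total = sum(n)), by = code]
  keep_codes <- if (enforce_floor) tot[total > params$min_total_count, code]
                else tot[, code]
  if (!length(keep_codes))
    return(structure(list(counts = matrix(0, 0, length(counts$chroms),
                                          dimnames = list(NULL, counts$chroms)),
                          z = matrix(0, 0, length(counts$chroms)),
                          params = params, totals = numeric()),
                     class = "diff_kmer_matrix"))
  sub <- tab[code %in% keep_codes]
  wide <- dcast(sub, code ~ chrom, value.var = "n", fill = 0)
  for (ch in setdiff(counts$chroms, names(wide)))
    wide[, (ch) := 0]
  m <- as.matrix(wide[, counts$chroms, with = FALSE])
  ps <- params$pseudocount
  fold_ok <- rep(FALSE, nrow(m))
  for (i in seq_len(nrow(pairs))) {
    a <- m[, pairs$chrom_A[i]] + ps
    b <- m[, pairs$chrom_B[i]] + ps
    fold_ok <- fold_ok | (pmax(a / b, b / a) >= params$min_fold)
  }
  m <- m[fold_ok, , drop = FALSE]
  codes <- wide$code[fold_ok]
  rownames(m) <- decode_kmer(codes, counts$k)
  z <- t(apply(m, 1, function(r) {
    s <- sd(r)
    if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  if (nrow(m) == 0) z <- matrix(0, 0, ncol(m), dimnames = dimnames(m))
  dimnames(z) <- dimnames(m)
  kept_tot <- tot$total[match(codes, tot$code)]
  structure(list(counts = m, z = z, params = params,
                 totals = setNames(kept_tot, rownames(m))),
            class = "diff_kmer_matrix")
}

#' Cluster chromosomes into two subgenomes
#'
#' Hierarchical clustering (correlation distance, average linkage) of the
#' z-scaled differential-k-mer columns, cut at two clusters. The group
#' containing the lexicographically smallest chromosome ID is labelled "A"
#' (a pure labelling convention). Chromosome columns with zero variance
#' cannot enter the correlation distance; they are assigned to the nearest
#' group centroid (Euclidean, on the z matrix) and flagged.
#'
#' @param m a `diff_kmer_matrix`.
#' @return object of class `subgenome_assignment`: data.table (chrom,
#'   subgenome, score, flagged) with a `label_note` attribute; `score` is
#'   the silhouette width under the clustering distance.
#' @export
cluster_subgenomes <- function(m) {
  stopifnot(inherits(m, "diff_kmer_matrix"))
  z <- m$z
  if (ncol(z) < 2) stopf("need at least two chromosomes to phase")
  if (nrow(z) < 1) stopf("no differential k-mers to cluster on")
  const <- apply(m$counts, 2, function(col) sd(col) == 0)
  if (sum(!const) < 2) stopf("fewer than two chromosomes with k-mer variance")
  zc <- z[, !const, drop = FALSE]
  cc <- suppressWarnings(cor(zc))
  cc[is.na(cc)] <- 0
  d <- as.dist(1 - cc)
  hc <- hclust(d, method = "average")
  grp <- cutree(hc, k = 2)

  # silhouette on the clustering distance
  dm <- as.matrix(d)
  sil <- vapply(seq_along(grp), function(i) {
    own <- dm[i, grp == grp[i] & seq_along(grp) != i]
    oth <- dm[i, grp != grp[i]]
    if (!length(own) || !length(oth)) return(NA_real_)
    a <- mean(own); b <- mean(oth)
    (b - a) / max(a, b)
  }, 0)

  out <- data.table(chrom = colnames(zc), group = grp, score = sil,
                    flagged = FALSE)
  if (any(const)) {
    cent <- vapply(1:2, function(g)
      rowMeans(z[, colnames(zc)[grp == g], drop = FALSE]), numeric(nrow(z)))
    for (ch in colnames(z)[const]) {
      dd <- colSums((cent - z[, ch])^2)
      out <- rbind(out, data.table(chrom = ch, group = which.min(dd),
                                   score = NA_real_, flagged = TRUE))
    }
  }
  a_group <- out$group[order(out$chrom)[1]]
  out[, subgenome := ifelse(group == a_group, "A", "B")]
  out[, group := NULL]
  setorder(out, chrom)
  structure(out,
            class = c("subgenome_assignment", class(out)),
            label_note = "group containing the lexicographically smallest chromosome is A")
}

#' Phase a genome into two subgenomes from differential k-mers
#'
#' Pipeline wrapper: count canonical k-mers, select those passing the
#' occurrence floor and pair-relative enrichment, and cluster chromosomes.
#' When no k-mer passes the strict selection (weak repeat signal), the
#' floor is dropped and the most enriched k-mers are used instead, with a
#' warning and `weak_signal = TRUE` in the report.
#'
#' @param genome FASTA path (or named sequences).
#' @param pairs homoeologous chromosome pairs (data.frame chrom_A,
#'   chrom_B); when NULL, all chromosome pairs are used as a fallback.
#' @param params a [phasing_params()].
#' @param outdir optional directory for the assignment and z-matrix TSVs.
#' @return list of class `phasing_report`: assignment, matrix, params,
#'   n_kmers, weak_signal, files.
#' @export
phase_subgenomes <- function(genome, pairs = NULL, params = phasing_params(),
                             outdir = NULL) {
  counts <- count_kmers(genome, params$k)
  if (is.null(pairs)) {
    chroms <- counts$chroms
    cmb <- combn(chroms, 2)
    pairs <- data.frame(chrom_A = cmb[1, ], chrom_B = cmb[2, ])
  }
  m <- select_differential_kmers(counts, pairs, params)
  weak <- FALSE
  if (nrow(m$counts) == 0) {
    warnf("no k-mer passed the selection thresholds; falling back to the most enriched k-mers (weak phasing signal)")
    weak <- TRUE
    m <- select_differential_kmers(counts, pairs, params, enforce_floor = FALSE)
    if (nrow(m$counts) > 2000) {
      keep <- order(m$totals, decreasing = TRUE)[seq_len(2000)]
      m$counts <- m$counts[keep, , drop = FALSE]
      m$z <- m$z[keep, , drop = FALSE]
      m$totals <- m$totals[keep]
    }
  }
  asg <- cluster_subgenomes(m)
  files <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    af <- file.path(outdir, "subgenome_assignment.tsv")
    write_tsv_c(as.data.frame(asg), af,
                comments = sprintf("subgenomics phase k=%d min_count=%s min_fold=%g",
                                   params$k, format(params$min_total_count),
                                   params$min_fold))
    zf <- file.path(outdir, "kmer_z_matrix.tsv")
    zdf <- data.frame(kmer = rownames(m$z), m$z, check.names = FALSE)
    write_tsv_c(zdf, zf, comments = "z-scaled differential k-mer matrix")
    files <- list(assignment = af, z_matrix = zf)
  }
  structure(list(assignment = asg, matrix = m, params = params,
                 n_kmers = nrow(m$counts), weak_signal = weak, files = files),
            class = "phasing_report")
}
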