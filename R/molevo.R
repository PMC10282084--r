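# Nei-Gojobori (1986) site and difference counting with Jukes-Cantor
# correction, Ks age distributions and peak-based WGD dating.

ng86_cache <- new.env(parent = emptyenv())

# Per-codon synonymous site fraction: for each of the 3 positions, the 3
# possible single-nucleotide changes are classified; changes producing stop
# codons are excluded from the denominator (NG86 convention).
ng86_codon_sites <- function() {
  if (!is.null(ng86_cache$S_of)) return(ng86_cache$S_of)
  ct <- codon_tables()
  S_of <- numeric(64)
  for (i in 0:63) {
    if (ct$aa_of[i + 1] == "*") { S_of[i + 1] <- NA_real_; next }
    digits <- c(i %/% 16, (i %/% 4) %% 4, i %% 4)
    s <- 0
    for (p in 1:3) {
      syn <- 0L; nonstop <- 0L
      for (alt in setdiff(0:3, digits[p])) {
        d2 <- digits; d2[p] <- alt
        j <- 16L * d2[1] + 4L * d2[2] + d2[3] + 1L
        if (ct$aa_of[j] == "*") next
        nonstop <- nonstop + 1L
        if (ct$aa_of[j] == ct$aa_of[i + 1]) syn <- syn + 1L
      }
      if (nonstop > 0L) s <- s + syn / nonstop
    }
    S_of[i + 1] <- s
  }
  ng86_cache$S_of <- S_of
  S_of
}

# Pathway-averaged synonymous/nonsynonymous difference counts for every
# ordered codon pair. Multi-difference codons average over all orderings of
# the changed positions; pathways passing through stop codons are excluded
# (all-blocked pairs fall back to averaging over every pathway).
ng86_codon_diffs <- function() {
  if (!is.null(ng86_cache$Sd)) return(list(Sd = ng86_cache$Sd, Nd = ng86_cache$Nd))
  ct <- codon_tables()
  Sd <- matrix(0, 64, 64); Nd <- matrix(0, 64, 64)
  dig <- function(i) c(i %/% 16, (i %/% 4) %% 4, i %% 4)
  idx <- function(d) 16L * d[1] + 4L * d[2] + d[3] + 1L
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in 0:63) {
    if (ct$aa_of[i + 1] == "*") next
    di <- dig(i)
    for (j in 0:63) {
      if (ct$aa_of[j + 1] == "*" || i == j) next
      dj <- dig(j)
      pos <- which(di != dj)
      res <- matrix(0, 0, 2)
      res_all <- matrix(0, 0, 2)
      for (ord in perms[[as.character(length(pos))]]) {
        cur <- di; s <- 0; n <- 0; blocked <- FALSE
        for (p in pos[ord]) {
          nxt <- cur; nxt[p] <- dj[p]
          a1 <- ct$aa_of[idx(cur)]; a2 <- ct$aa_of[idx(nxt)]
          if (a2 == "*") blocked <- TRUE
          if (identical(a1, a2)) s <- s + 1 else n <- n + 1
          cur <- nxt
        }
        res_all <- rbind(res_all, c(s, n))
        if (!blocked) res <- rbind(res, c(s, n))
      }
      if (nrow(res) == 0) res <- res_all
      Sd[i + 1, j + 1] <- mean(res[, 1])
      Nd[i + 1, j + 1] <- mean(res[, 2])
    }
  }
  ng86_cache$Sd <- Sd; ng86_cache$Nd <- Nd
  list(Sd = Sd, Nd = Nd)
}

# site counts for an integer-coded CDS (used by the simulator to convert
# target distances into event counts)
ng86_sites <- function(codes) {
  S_of <- ng86_codon_sites()
  ci <- codon_index(codes)
  S <- sum(S_of[ci])
  list(S = S, N = 3 * length(ci) - S)
}

cds_to_codes <- function(x) {
  if (inherits(x, "DNAString")) x <- as.character(x)
  v <- match(strsplit(toupper(x), "")[[1]], c("A", "C", "G", "T")) - 1L
  if (anyNA(v)) stopf("sequence contains non-ACGT symbols")
  if (length(v) %% 3 != 0) stopf("sequence length %d not divisible by 3", length(v))
  v
}

#' Nei-Gojobori (1986) Ka/Ks estimation for one codon alignment
#'
#' Counts synonymous (S) and nonsynonymous (N) sites as pathway fractions
#' per codon (stop-codon outcomes excluded from the denominators), averages
#' site counts over the two sequences, counts observed synonymous (Sd) and
#' nonsynonymous (Nd) differences by equal-weight averaging over all
#' mutational pathways that avoid stop codons, and applies the
#' Jukes-Cantor correction `K = -3/4 log(1 - 4/3 p)`. Proportions at or
#' beyond 3/4 are flagged saturated and the corresponding distance is NA.
#'
#' @param seq_a,seq_b gap-free coding sequences of equal length divisible
#'   by 3, without internal stop codons (character or `DNAString`).
#' @return list of class `ng86` with S, N, Sd, Nd, ps, pn, Ks, Ka, omega,
#'   saturated, codons.
#' @export
ng86 <- function(seq_a, seq_b) {
  a <- cds_to_codes(seq_a); b <- cds_to_codes(seq_b)
  if (length(a) != length(b)) stopf("sequences differ in length (%d vs %d)",
                                    length(a), length(b))
  ct <- codon_tables()
  ca <- codon_index(a); cb <- codon_index(b)
  n_codons <- length(ca)
  intern_a <- ct$aa_of[ca] == "*"; intern_b <- ct$aa_of[cb] == "*"
  # a terminal stop in both sequences is tolerated and trimmed
  if (n_codons > 1 && intern_a[n_codons] && intern_b[n_codons]) {
    ca <- ca[-n_codons]; cb <- cb[-n_codons]
    intern_a <- intern_a[-n_codons]; intern_b <- intern_b[-n_codons]
    n_codons <- n_codons - 1L
  }
  if (any(intern_a) || any(intern_b)) stopf("internal stop codon in input")
  S_of <- ng86_codon_sites()
  diffs <- ng86_codon_diffs()
  S <- (sum(S_of[ca]) + sum(S_of[cb])) / 2
  N <- 3 * n_codons - S
  Sd <- sum(diffs$Sd[cbind(ca, cb)])
  Nd <- sum(diffs$Nd[cbind(ca, cb)])
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p < 0.75) -3 / 4 * log(1 - 4 / 3 * p) else NA_real_
  Ks <- jc(ps); Ka <- jc(pn)
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 Ks = Ks, Ka = Ka,
                 omega = if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_,
                 saturated = ps >= 0.75 || pn >= 0.75,
                 codons = n_codons),
            class = "ng86")
}

#' NG86 estimates for a table of homoeologous CDS pairs
#'
#' @param fasta_A,fasta_B CDS FASTA paths; sequences are matched by the
#'   pair table.
#' @param pairs data.frame with columns pair_id, gene_A, gene_B; defaults
#'   to positional pairing of the two files.
#' @return data.table: pair_id, S, N, Sd, Nd, ps, pn, Ks, Ka, omega,
#'   saturated.
#' @export
ng86_pairs <- function(fasta_A, fasta_B, pairs = NULL) {
  sa <- Biostrings::readDNAStringSet(fasta_A)
  sb <- Biostrings::readDNAStringSet(fasta_B)
  if (is.null(pairs)) {
    if (length(sa) != length(sb)) stopf("files carry different sequence counts")
    pairs <- data.frame(pair_id = paste0("pair_", seq_along(sa)),
                        gene_A = names(sa), gene_B = names(sb))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    e <- ng86(as.character(sa[[pairs$gene_A[i]]]),
              as.character(sb[[pairs$gene_B[i]]]))
    data.table(pair_id = pairs$pair_id[i], gene_A = pairs$gene_A[i],
               gene_B = pairs$gene_B[i], S = e$S, N = e$N, Sd = e$Sd,
               Nd = e$Nd, ps = e$ps, pn = e$pn, Ks = e$Ks, Ka = e$Ka,
               omega = e$omega, saturated = e$saturated)
  })
  rbindlist(rows)
}

#' Build a Ks age distribution
#'
#' @param ks numeric Ks values, or a data.table from [ng86_pairs()] (its
#'   unsaturated `Ks` column is used and saturated pairs are counted).
#' @param bin_width histogram bin width (default 0.01).
#' @param max_ks upper histogram bound; values beyond are counted as
#'   saturated.
#' @return list of class `ks_distribution`: values, bin_width, mids,
#'   counts, n_saturated.
#' @export
build_ks_distribution <- function(ks, bin_width = 0.01, max_ks = 5) {
  n_sat <- 0L
  if (is.data.frame(ks)) {
    n_sat <- sum(ks$saturated | is.na(ks$Ks))
    ks <- ks$Ks[!ks$saturated & !is.na(ks$Ks)]
  } else {
    n_sat <- sum(is.na(ks))
    ks <- ks[!is.na(ks)]
  }
  over <- ks > max_ks
  n_sat <- n_sat + sum(over)
  ks <- ks[!over]
  if (!length(ks)) stopf("no unsaturated Ks values to bin")
  breaks <- seq(0, max_ks, by = bin_width)
  h <- hist(ks, breaks = breaks, plot = FALSE)
  structure(list(values = ks, bin_width = bin_width, mids = h$mids,
                 counts = h$counts, n_saturated = n_sat),
            class = "ks_distribution")
}

#' Find local peaks of a Ks distribution
#'
#' A bin is a peak iff its count is strictly greater than every bin within
#' `window` bins on either side and at least `min_count`; peaks are
#' returned as bin centers, descending by height.
#'
#' @param dist a `ks_distribution`.
#' @param window half-width of the local-maximum window in bins.
#' @param min_count minimum bin count for a peak.
#' @return data.table (ks, count), possibly empty.
#' @export
find_ks_peaks <- function(dist, window = 3L, min_count = 5L) {
  stopifnot(inherits(dist, "ks_distribution"))
  counts <- dist$counts
  nb <- length(counts)
  if (nb < 2L * window + 1L) stopf("need at least %d bins", 2L * window + 1L)
  is_peak <- vapply(seq_len(nb), function(i) {
    lo <- max(1L, i - window); hi <- min(nb, i + window)
    nb_others <- counts[setdiff(lo:hi, i)]
    counts[i] >= min_count && all(counts[i] > nb_others)
  }, TRUE)
  out <- data.table(ks = dist$mids[is_peak], count = counts[is_peak])
  setorder(out, -count)
  out
}

#' Date a whole-genome duplication from a Ks peak
#'
#' `T = Ks / (2 r)` with `r` the synonymous substitution rate per site per
#' year (for the lineage studied here, 5.26e-9).
#'
#' @param ks_peak Ks value of the duplication peak (>= 0).
#' @param r substitution rate, substitutions/site/year (> 0).
#' @return list of class `wgd_date`: T_years, ks_peak, rate.
#' @export
date_wgd <- function(ks_peak, r = 5.26e-9) {
  if (r <= 0) stopf("substitution rate must be > 0")
  if (ks_peak < 0) stopf("ks_peak must be >= 0")
  structure(list(T_years = ks_peak / (2 * r), ks_peak = ks_peak, rate = r),
            class = "wgd_date")
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from midrank sums. The p-value is exact — by complete
#' enumeration of all rank splits — whenever the number of splits
#' `choose(n+m, n)` is at most `exact_limit`; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_limit largest number of rank splits enumerated exactly.
#' @return list: U (for `x`), p, method ("exact" or "normal").
#' @export
mann_whitney_u <- function(x, y, exact_limit = 1e4) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  if (choose(N, n) <= exact_limit) {
    splits <- combn(N, n)
    us <- colSums(matrix(r[splits], nrow = n)) - n * (n + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    method <- "exact"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) { p <- 1 } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(0, z)))
    }
    method <- "normal"
  }
  list(U = u, p = p, method = method)
}

#' Wilcoxon rank-sum test (alias of [mann_whitney_u()])
#'
#' The Wilcoxon rank-sum and Mann-Whitney U tests are the same test up to
#' the linear shift `W = U + n(n+1)/2`; this alias exists because both
#' names are conventional in the literature this workflow follows.
#'
#' @inheritParams mann_whitney_u
#' @return see [mann_whitney_u()].
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 1e4) {
  mann_whitney_u(x, y, exact_limit = exact_limit)
}
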