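# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

.oracle_gc <- Biostrings::GENETIC_CODE
.oracle_nts <- c("A", "C", "G", "T")

oracle_translate <- function(codon) unname(.oracle_gc[codon])

# NG86 oracle: explicit string-based enumeration of site fractions and of
# all pathway permutations per codon. Results are memoized per codon (pair)
# purely for speed; the computation itself stays independent of the package.
.oracle_memo <- new.env(parent = emptyenv())

oracle_ng86_counts <- function(seq_a, seq_b) {
  codons_a <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  codons_b <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  syn_sites <- function(codon) {
    key <- paste0("s_", codon)
    if (!is.null(.oracle_memo[[key]])) return(.oracle_memo[[key]])
    aa <- oracle_translate(codon)
    total <- 0
    for (pos in 1:3) {
      syn <- 0; valid <- 0
      for (nt in setdiff(.oracle_nts, substr(codon, pos, pos))) {
        mut <- codon
        substr(mut, pos, pos) <- nt
        if (oracle_translate(mut) == "*") next
        valid <- valid + 1
        if (oracle_translate(mut) == aa) syn <- syn + 1
      }
      if (valid > 0) total <- total + syn / valid
    }
    .oracle_memo[[key]] <- total
    total
  }
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms_of(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  path_counts <- function(ca, cb) {
    key <- paste0("p_", ca, cb)
    if (!is.null(.oracle_memo[[key]])) return(.oracle_memo[[key]])
    pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    ok <- list(); all_paths <- list()
    for (ord in perms_of(pos)) {
      cur <- ca; s <- 0; n <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        if (oracle_translate(nxt) == "*") blocked <- TRUE
        if (oracle_translate(nxt) == oracle_translate(cur)) s <- s + 1
        else n <- n + 1
        cur <- nxt
      }
      all_paths <- c(all_paths, list(c(s, n)))
      if (!blocked) ok <- c(ok, list(c(s, n)))
    }
    use <- if (length(ok)) ok else all_paths
    res <- colMeans(do.call(rbind, use))
    .oracle_memo[[key]] <- res
    res
  }
  S <- (sum(vapply(codons_a, syn_sites, 0)) +
        sum(vapply(codons_b, syn_sites, 0))) / 2
  sd_nd <- rowSums(vapply(seq_along(codons_a), function(i)
    path_counts(codons_a[i], codons_b[i]), c(0, 0)))
  list(S = S, N = 3 * length(codons_a) - S, Sd = sd_nd[1], Nd = sd_nd[2])
}

# exhaustive chain enumeration: best score-weighted admissible chain over
# <= 12 hits, one chromosome pair, both orientations
oracle_best_chain_score <- function(qrank, srank, score, max_gap, min_pairs) {
  n <- length(qrank)
  best <- 0
  admissible <- function(idx, orient) {
    if (length(idx) < 2) return(TRUE)
    q <- qrank[idx]; s <- srank[idx]
    o <- order(q)
    q <- q[o]; s <- s[o]
    dq <- diff(q); ds <- diff(s)
    if (orient == "+") all(dq >= 1 & dq <= max_gap & ds >= 1 & ds <= max_gap)
    else all(dq >= 1 & dq <= max_gap & -ds >= 1 & -ds <= max_gap)
  }
  for (m in seq_len(n)) {
    if (m < min_pairs) next
    for (idx in utils::combn(n, m, simplify = FALSE)) {
      for (orient in c("+", "-")) {
        if (admissible(idx, orient)) best <- max(best, sum(score[idx]))
      }
    }
  }
  best
}

# binomial upper tail by direct term-wise summation
oracle_binom_tail <- function(n, m, p) {
  if (m <= 0) return(1)
  sum(exp(lchoose(n, m:n) + (m:n) * log(p) + (n - (m:n)) * log(1 - p)))
}

# exact two-sided binomial sign test against 0.5 by tail summation
oracle_sign_test <- function(k, n) {
  d <- abs(k - n / 2)
  sum(dbinom(0:n, n, 0.5)[abs(0:n - n / 2) >= d - 1e-12])
}

# BH step-up by literal definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o] * n / seq_len(n)
  running <- rev(cummin(rev(sorted)))
  adj[o] <- pmin(1, running)
  adj
}

# exact Mann-Whitney by full enumeration of rank splits
oracle_mwu <- function(x, y) {
  n <- length(x); N <- n + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * length(y) / 2
  us <- apply(utils::combn(N, n), 2, function(idx)
    sum(r[idx]) - n * (n + 1) / 2)
  list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12))
}

# adjusted Rand index between two labelings (used where mclust is not
# guaranteed; mclust::adjustedRandIndex is the cross-check when available)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- si * sj / nn
  (sij - expected) / ((si + sj) / 2 - expected)
}

# random stop-free CDS string, independent of the package generator
oracle_random_cds <- function(n_codons) {
  ok <- names(.oracle_gc)[.oracle_gc != "*"]
  paste(sample(ok, n_codons, replace = TRUE), collapse = "")
}

# mutate a CDS string at random positions (may create multi-hit codons),
# avoiding stop codons
oracle_mutate_cds <- function(seq, n_mut) {
  v <- strsplit(seq, "")[[1]]
  for (i in seq_len(n_mut)) {
    repeat {
      p <- sample(length(v), 1)
      old <- v[p]
      v[p] <- sample(setdiff(.oracle_nts, old), 1)
      cod <- (p - 1) %/% 3
      codon <- paste(v[(3 * cod + 1):(3 * cod + 3)], collapse = "")
      if (oracle_translate(codon) != "*") break
      v[p] <- old
    }
  }
  paste(v, collapse = "")
}
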