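#' Simulation configuration for a synthetic allotetraploid
#'
#' Builds and validates the configuration object consumed by the
#' `simulate_*` generators. Defaults describe a small allotetraploid with
#' two subgenomes of 10 and 12 chromosomes, subgenome-private repeat
#' families dense enough to phase (copy number above the 100-occurrence
#' k-mer selection floor), homoeologous gene pairs with a bimodal Ks
#' mixture (a recent divergence component and an older duplication
#' component), a two-component TE divergence landscape with a known
#' segregation window, replicated expression with a configurable fraction
#' of two-fold biased pairs, and per-cytosine methylation counts.
#'
#' @param n_chromosomes_A,n_chromosomes_B chromosomes per subgenome.
#' @param chromosome_length chromosome length in bp.
#' @param n_repeat_families_specific subgenome-private repeat families per
#'   subgenome.
#' @param n_repeat_families_shared repeat families shared by both subgenomes.
#' @param repeat_copy_number copies per repeat family across the genome;
#'   must exceed 100 for the k-mer phasing signal to pass the selection
#'   floor, lower values are emitted with a weak-signal flag.
#' @param repeat_length repeat unit length in bp.
#' @param n_gene_pairs number of homoeologous gene pairs.
#' @param gene_length gene span in bp (one CDS of `gene_length/3` codons).
#' @param ks_mixture list of `c(mean, sd, weight)` components on the Ks
#'   scale; weights must sum to 1.
#' @param ka_omega Ka/Ks ratio used to derive per-pair target Ka from Ks.
#' @param ks_saturation Ks beyond which a pair is flagged saturated.
#' @param expression_bias_fraction proportion of pairs simulated with
#'   expression bias.
#' @param fold_change multiplicative expression bias (> 0).
#' @param n_tissues,n_replicates expression design.
#' @param expr_meanlog,expr_sdlog log-normal baseline expression means.
#' @param dispersion negative-binomial dispersion of expression counts.
#' @param te_shared_range,te_specific_range percent-divergence intervals of
#'   the shared and subgenome-private TE components.
#' @param te_shared_copies shared TE copies per subgenome.
#' @param te_specific_copies named vector `c(A=, B=)` of private TE copies.
#' @param te_rate TE substitution rate (substitutions/site/year) used when
#'   converting divergence to time.
#' @param methylation_levels nested list `context -> c(upstream, body,
#'   downstream)` of true per-site methylation probabilities.
#' @param meth_site_density named vector of cytosine sites per bp by context.
#' @param meth_coverage mean read coverage per cytosine.
#' @param p_err methylation error rate (non-conversion); unmethylated sites
#'   draw methylated reads at this rate.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes_A = 10L,
                       n_chromosomes_B = 12L,
                       chromosome_length = 100000L,
                       n_repeat_families_specific = 5L,
                       n_repeat_families_shared = 5L,
                       repeat_copy_number = 150L,
                       repeat_length = 200L,
                       n_gene_pairs = 200L,
                       gene_length = 900L,
                       ks_mixture = list(c(mean = 0.055, sd = 0.01, weight = 0.5),
                                         c(mean = 0.46,  sd = 0.05, weight = 0.5)),
                       ka_omega = 0.2,
                       ks_saturation = 2.0,
                       expression_bias_fraction = 0.3,
                       fold_change = 2.0,
                       n_tissues = 7L,
                       n_replicates = 3L,
                       expr_meanlog = log(100),
                       expr_sdlog = 0.7,
                       dispersion = 0.1,
                       te_shared_range = c(8, 30),
                       te_specific_range = c(1, 5),
                       te_shared_copies = 5000L,
                       te_specific_copies = c(A = 3000L, B = 600L),
                       te_rate = 1.0e-8,
                       methylation_levels = list(
                         CG  = c(upstream = 0.2,  body = 0.8,  downstream = 0.2),
                         CHG = c(upstream = 0.1,  body = 0.05, downstream = 0.1),
                         CHH = c(upstream = 0.05, body = 0.02, downstream = 0.05)),
                       meth_site_density = c(CG = 0.04, CHG = 0.03, CHH = 0.06),
                       meth_coverage = 20,
                       p_err = 0.01) {
  cfg <- as.list(environment())
  counts <- c(n_chromosomes_A, n_chromosomes_B, chromosome_length,
              n_repeat_families_specific, n_repeat_families_shared,
              repeat_copy_number, repeat_length, n_gene_pairs, gene_length,
              n_tissues, n_replicates)
  if (any(counts < 1)) stopf("all counts must be >= 1")
  w <- sum(vapply(ks_mixture, function(m) m[["weight"]], 0))
  if (abs(w - 1) > 1e-8) stopf("ks_mixture weights must sum to 1 (got %g)", w)
  if (gene_length %% 3 != 0) stopf("gene_length must be a multiple of 3")
  if (expression_bias_fraction < 0 || expression_bias_fraction > 1)
    stopf("expression_bias_fraction must be in [0,1]")
  if (fold_change <= 0) stopf("fold_change must be > 0")
  for (rg in list(te_shared_range, te_specific_range))
    if (length(rg) != 2 || rg[1] >= rg[2] || rg[1] < 0 || rg[2] > 100)
      stopf("TE divergence ranges must satisfy 0 <= low < high <= 100")
  lv <- unlist(methylation_levels)
  if (any(lv < 0 | lv > 1)) stopf("methylation levels must be in [0,1]")
  if (p_err < 0 || p_err > 1) stopf("p_err must be in [0,1]")
  if (p_err >= min(lv[lv > 0], 1))
    warnf("p_err >= smallest true methylation level; tests will lose power")
  structure(cfg, class = "sim_config")
}

chrom_ids <- function(config) {
  list(A = sprintf("A%02d", seq_len(config$n_chromosomes_A)),
       B = sprintf("B%02d", seq_len(config$n_chromosomes_B)))
}

# Collinear gene layout shared by a homoeologous chromosome pair. Genes are
# distributed over the first min(nA, nB) chromosome pairs; throws a capacity
# error when the chromosome cannot host its share.
gene_layout <- function(config) {
  ids <- chrom_ids(config)
  n_pairs_chrom <- min(config$n_chromosomes_A, config$n_chromosomes_B)
  per_chrom <- diff(round(seq(0, config$n_gene_pairs, length.out = n_pairs_chrom + 1)))
  flank <- 2500L
  rows <- list()
  for (i in seq_len(n_pairs_chrom)) {
    ng <- per_chrom[i]
    if (ng == 0) next
    usable <- config$chromosome_length - 2L * flank
    spacing <- floor(usable / ng)
    if (spacing < config$gene_length + 200L)
      stopf("chromosome_length %d too small for %d genes of %d bp",
            config$chromosome_length, ng, config$gene_length)
    starts <- flank + (seq_len(ng) - 1L) * spacing + 1L
    for (j in seq_len(ng)) {
      gid <- sprintf("g%02d_%04d", i, j)
      rows[[length(rows) + 1L]] <- data.table(
        pair_id = paste0("pair_", gid),
        gene_A = paste0("A", gid), gene_B = paste0("B", gid),
        chrom_A = ids$A[i], chrom_B = ids$B[i],
        start = starts[j], end = starts[j] + config$gene_length - 1L)
    }
  }
  rbindlist(rows)
}

random_dna <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

#' Simulate an allotetraploid genome with phaseable subgenomes
#'
#' Each chromosome is i.i.d. uniform ACGT background with inserted copies of
#' repeat families shared by both subgenomes and of families private to its
#' own subgenome; the private families carry the differential k-mer signal
#' used for phasing. Gene loci are placed collinearly so homoeologous
#' chromosomes share gene order. A machine-readable truth record accompanies
#' the FASTA/GFF3 output.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param outdir output directory (created if missing).
#' @return list with `fasta`, `gff` paths and the `truth` record.
#' @export
simulate_genome <- function(config, seed, outdir = tempfile("simgenome")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(substream(seed, 0L))
  ids <- chrom_ids(config)
  all_chroms <- c(ids$A, ids$B)

  rep_seq <- function(n_fam, prefix)
    setNames(lapply(seq_len(n_fam), function(i) random_dna(config$repeat_length)),
             paste0(prefix, seq_len(n_fam)))
  fam_shared <- rep_seq(config$n_repeat_families_shared, "shared_")
  fam_A <- rep_seq(config$n_repeat_families_specific, "privA_")
  fam_B <- rep_seq(config$n_repeat_families_specific, "privB_")

  # copies of each family are spread uniformly over its eligible chromosomes
  assign_copies <- function(fams, chroms) {
    out <- data.table(family = character(), chrom = character())
    for (f in names(fams)) {
      ch <- sample(chroms, config$repeat_copy_number, replace = TRUE)
      out <- rbind(out, data.table(family = f, chrom = ch))
    }
    out
  }
  placements <- rbind(assign_copies(fam_shared, all_chroms),
                      assign_copies(fam_A, ids$A),
                      assign_copies(fam_B, ids$B))
  fam_seqs <- c(fam_shared, fam_A, fam_B)

  slot <- config$repeat_length + 50L
  n_slots <- floor(config$chromosome_length / slot)
  per_chrom_n <- placements[, .N, by = chrom]
  if (any(per_chrom_n$N > n_slots))
    stopf("chromosome_length %d too small to host %d repeat copies",
          config$chromosome_length, max(per_chrom_n$N))

  seqs <- vector("list", length(all_chroms))
  names(seqs) <- all_chroms
  for (ch in all_chroms) {
    s <- random_dna(config$chromosome_length)
    fams <- placements[chrom == ch, family]
    if (length(fams)) {
      slots <- sample.int(n_slots, length(fams))
      starts <- (slots - 1L) * slot + 1L
      for (i in seq_along(fams)) {
        idx <- starts[i]:(starts[i] + config$repeat_length - 1L)
        s[idx] <- fam_seqs[[fams[i]]]
      }
    }
    seqs[[ch]] <- paste(s, collapse = "")
  }

  layout <- gene_layout(config)
  fasta <- file.path(outdir, "genome.fa")
  sset <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(sset, fasta, width = 60L)

  genes <- rbind(
    layout[, .(gene_id = gene_A, chrom = chrom_A, start, end, strand = "+",
               subgenome = "A")],
    layout[, .(gene_id = gene_B, chrom = chrom_B, start, end, strand = "+",
               subgenome = "B")])
  setorder(genes, chrom, start)
  gff <- file.path(outdir, "genes.gff3")
  write_gff3(genes, gff)

  truth <- list(
    seed = as.integer(seed),
    subgenome_of_chromosome = setNames(
      c(rep("A", length(ids$A)), rep("B", length(ids$B))), all_chroms),
    homoeolog_chromosome_pairs = data.frame(
      chrom_A = ids$A[seq_len(min(length(ids$A), length(ids$B)))],
      chrom_B = ids$B[seq_len(min(length(ids$A), length(ids$B)))]),
    homoeolog_pairs = as.data.frame(layout[, .(pair_id, gene_A, gene_B)]),
    genes = as.data.frame(genes),
    te_window = unname(config$te_specific_range),
    phasing_signal = if (config$repeat_copy_number > 100L) "strong" else "weak",
    methylation_levels = config$methylation_levels)
  class(truth) <- "sim_truth"
  list(fasta = fasta, gff = gff, truth = truth)
}

#' Write gene annotations as GFF3 (1-based, fully closed)
#'
#' @param genes data.frame with gene_id, chrom, start, end, strand.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tsubgenomics\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene spans from a GFF3 file
#'
#' Minimal reader for `gene`-type records with `ID=` attributes, as written
#' by [write_gff3()].
#'
#' @param path GFF3 path.
#' @return data.table with gene_id, chrom, start, end, strand.
#' @export
read_gff_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- data.table::fread(text = paste(lines, collapse = "\n"), sep = "\t",
                         header = FALSE)
  f <- f[f$V3 == "gene", ]
  data.table(gene_id = sub("^.*ID=([^;]+).*$", "\\1", f$V9),
             chrom = f$V1, start = f$V4, end = f$V5, strand = f$V7)
}

# ---- codon machinery shared with the molevo module ------------------------

codon_tables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    nts <- c("A", "C", "G", "T")
    codons <- as.vector(outer(outer(nts, nts, paste0), nts, paste0))
    codons <- sort(codons)
    gc <- Biostrings::GENETIC_CODE
    aa <- unname(gc[codons])
    idx <- function(c1, c2, c3) 16L * c1 + 4L * c2 + c3 + 1L
    # aa_of[i]: amino acid of codon with base-4 index i-1 ("*" for stops)
    aa_of <- character(64)
    for (i in 0:63) {
      n1 <- i %/% 16; n2 <- (i %/% 4) %% 4; n3 <- i %% 4
      aa_of[i + 1] <- unname(gc[paste0(nts[n1 + 1], nts[n2 + 1], nts[n3 + 1])])
    }
    cache <<- list(nts = nts, aa_of = aa_of, idx = idx)
    cache
  }
})

codon_index <- function(nt_codes) {
  # nt_codes: integer vector (0..3), length divisible by 3
  m <- matrix(nt_codes, nrow = 3)
  16L * m[1, ] + 4L * m[2, ] + m[3, ] + 1L
}

random_cds <- function(n_codons) {
  ct <- codon_tables()
  repeat {
    codes <- sample(0:3, 3L * n_codons, replace = TRUE)
    ci <- codon_index(codes)
    bad <- which(ct$aa_of[ci] == "*")
    if (!length(bad)) return(codes)
    for (b in bad) {
      repeat {
        codes[(3 * b - 2):(3 * b)] <- sample(0:3, 3L, replace = TRUE)
        if (ct$aa_of[codon_index(codes[(3 * b - 2):(3 * b)])] != "*") break
      }
    }
    return(codes)
  }
}

# Apply one substitution of the requested class (synonymous / nonsynonymous)
# to an integer-coded CDS; proposals hitting stop codons are rejected and
# resampled.
apply_substitution <- function(codes, synonymous) {
  ct <- codon_tables()
  len <- length(codes)
  repeat {
    p <- sample.int(len, 1L)
    old <- codes[p]
    new <- sample((0:3)[-(old + 1L)], 1L)
    cod <- (p - 1L) %/% 3L
    span <- (3L * cod + 1L):(3L * cod + 3L)
    oldc <- codes[span]
    newc <- oldc
    newc[p - 3L * cod] <- new
    aa_old <- ct$aa_of[codon_index(oldc)]
    aa_new <- ct$aa_of[codon_index(newc)]
    if (aa_new == "*") next
    if (synonymous == (aa_new == aa_old)) {
      codes[span] <- newc
      return(codes)
    }
  }
}

codes_to_string <- function(codes) {
  paste(c("A", "C", "G", "T")[codes + 1L], collapse = "")
}

#' Simulate homoeologous CDS pairs with controlled Ka and Ks
#'
#' For each pair an ancestral stop-free coding sequence is evolved along two
#' branches. Per-pair target Ks is drawn from the configured normal mixture
#' (truncated at 0) and target Ka is `ka_omega * Ks`; the number of
#' synonymous / nonsynonymous substitution events realised on the tree is
#' `round(target * sites)` with sites counted by the Nei-Gojobori
#' site-fraction convention on the ancestral sequence. Pairs whose drawn Ks
#' exceeds the saturation bound are flagged (not silently dropped).
#'
#' @inheritParams simulate_genome
#' @param truth optional truth record from [simulate_genome()]; its
#'   homoeolog pair IDs are reused, otherwise free-standing IDs are created.
#' @return list with `fasta_A`, `fasta_B` paths and the updated `truth`
#'   (fields `true_ks`, `true_ka`, `saturated` per pair).
#' @export
simulate_cds_pairs <- function(config, seed, outdir = tempfile("simcds"),
                               truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(substream(seed, 1L))
  if (is.null(truth)) {
    n <- config$n_gene_pairs
    truth <- list(homoeolog_pairs = data.frame(
      pair_id = sprintf("pair_%04d", seq_len(n)),
      gene_A = sprintf("A_%04d", seq_len(n)),
      gene_B = sprintf("B_%04d", seq_len(n))))
    class(truth) <- "sim_truth"
  }
  pairs <- truth$homoeolog_pairs
  n <- nrow(pairs)
  n_codons <- config$gene_length %/% 3L

  comp <- sample.int(length(config$ks_mixture), n, replace = TRUE,
                     prob = vapply(config$ks_mixture, function(m) m[["weight"]], 0))
  ks <- vapply(seq_len(n), function(i) {
    m <- config$ks_mixture[[comp[i]]]
    max(0, rnorm(1, m[["mean"]], m[["sd"]]))
  }, 0)
  ka <- ks * config$ka_omega
  saturated <- ks > config$ks_saturation

  seq_a <- seq_b <- character(n)
  for (i in seq_len(n)) {
    anc <- random_cds(n_codons)
    sites <- ng86_sites(anc)
    n_syn <- round(ks[i] * sites$S)
    n_non <- round(ka[i] * sites$N)
    evolve <- function(codes, ns, nn) {
      ev <- sample(c(rep(TRUE, ns), rep(FALSE, nn)))
      for (syn in ev) codes <- apply_substitution(codes, syn)
      codes
    }
    # events split binomially between the two branches
    sa <- rbinom(1, n_syn, 0.5); na <- rbinom(1, n_non, 0.5)
    seq_a[i] <- codes_to_string(evolve(anc, sa, na))
    seq_b[i] <- codes_to_string(evolve(anc, n_syn - sa, n_non - na))
  }

  fa <- file.path(outdir, "cds_A.fa")
  fb <- file.path(outdir, "cds_B.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seq_a, pairs$gene_A)), fa, width = 60L)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seq_b, pairs$gene_B)), fb, width = 60L)

  truth$true_ks <- setNames(ks, pairs$pair_id)
  truth$true_ka <- setNames(ka, pairs$pair_id)
  truth$saturated <- setNames(saturated, pairs$pair_id)
  list(fasta_A = fa, fasta_B = fb, truth = truth)
}

#' Simulate a transposable-element copy table
#'
#' Emits one row per TE copy (copy ID, subgenome, family, percent divergence
#' to consensus, length). The shared component is drawn identically for both
#' subgenomes over `te_shared_range`; private components are drawn only for
#' their own subgenome over `te_specific_range`, which becomes the truth
#' segregation window. Copy counts of the private component may differ
#' between subgenomes (the amplitude asymmetry the segregation detector
#' keys on).
#'
#' @inheritParams simulate_cds_pairs
#' @return list with `te` (TSV path), `sizes` (named subgenome sizes in bp)
#'   and updated `truth` (field `te_window`).
#' @export
simulate_te_table <- function(config, seed, outdir = tempfile("simte"),
                              truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(substream(seed, 2L))
  if (is.null(truth)) { truth <- list(); class(truth) <- "sim_truth" }

  draw <- function(n, rng, sub, fam_prefix) {
    if (n == 0) return(NULL)
    data.table(subgenome = sub,
               family = paste0(fam_prefix, sample.int(5L, n, replace = TRUE)),
               perc_div = runif(n, rng[1], rng[2]),
               length = pmax(50L, round(stats::rlnorm(n, log(300), 0.5))))
  }
  tab <- rbindlist(list(
    draw(config$te_shared_copies, config$te_shared_range, "A", "shared"),
    draw(config$te_shared_copies, config$te_shared_range, "B", "shared"),
    draw(config$te_specific_copies[["A"]], config$te_specific_range, "A", "privA"),
    draw(config$te_specific_copies[["B"]], config$te_specific_range, "B", "privB")))
  tab[, copy_id := sprintf("te%06d", seq_len(.N))]
  data.table::setcolorder(tab, c("copy_id", "subgenome", "family", "perc_div", "length"))

  path <- file.path(outdir, "te_copies.tsv")
  write_tsv_c(tab, path,
              comments = c("subgenomics simulate_te_table",
                           sprintf("seed=%d", as.integer(seed))))
  sizes <- c(A = config$n_chromosomes_A * config$chromosome_length,
             B = config$n_chromosomes_B * config$chromosome_length)
  truth$te_window <- unname(config$te_specific_range)
  list(te = path, sizes = sizes, truth = truth)
}

#' Simulate a replicated homoeolog expression table
#'
#' Negative-binomial counts per gene copy, tissue and replicate. Baseline
#' means are log-normal per pair and tissue and shared between the two
#' copies; for pairs drawn into the biased set, one copy's mean is
#' multiplied by `fold_change` in every tissue (direction recorded in the
#' truth record).
#'
#' @inheritParams simulate_cds_pairs
#' @return list with `expr` (long TSV path: gene, tissue, replicate, value)
#'   and updated `truth` (data frame `biased_pairs`: pair_id, direction).
#' @export
simulate_expression <- function(config, seed, outdir = tempfile("simexpr"),
                                truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_replicates < 2L)
    stopf("n_replicates must be >= 2 (downstream t-test impossible with 1)")
  if (config$fold_change <= 0) stopf("fold_change must be > 0")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(substream(seed, 3L))
  if (is.null(truth)) {
    n <- config$n_gene_pairs
    truth <- list(homoeolog_pairs = data.frame(
      pair_id = sprintf("pair_%04d", seq_len(n)),
      gene_A = sprintf("A_%04d", seq_len(n)),
      gene_B = sprintf("B_%04d", seq_len(n))))
    class(truth) <- "sim_truth"
  }
  pairs <- truth$homoeolog_pairs
  n <- nrow(pairs)
  tissues <- paste0("tissue", seq_len(config$n_tissues))

  n_biased <- round(config$expression_bias_fraction * n)
  biased_idx <- if (n_biased > 0) sort(sample.int(n, n_biased)) else integer()
  direction <- sample(c("A", "B"), length(biased_idx), replace = TRUE)

  rows <- vector("list", n)
  size <- 1 / config$dispersion
  for (i in seq_len(n)) {
    mu <- stats::rlnorm(config$n_tissues, config$expr_meanlog, config$expr_sdlog)
    mu_a <- mu; mu_b <- mu
    bi <- match(i, biased_idx)
    if (!is.na(bi)) {
      if (direction[bi] == "A") mu_a <- mu * config$fold_change
      else mu_b <- mu * config$fold_change
    }
    ka <- rnbinom(config$n_tissues * config$n_replicates,
                  mu = rep(mu_a, each = config$n_replicates), size = size)
    kb <- rnbinom(config$n_tissues * config$n_replicates,
                  mu = rep(mu_b, each = config$n_replicates), size = size)
    rows[[i]] <- data.table(
      gene = rep(c(pairs$gene_A[i], pairs$gene_B[i]),
                 each = config$n_tissues * config$n_replicates),
      tissue = rep(rep(tissues, each = config$n_replicates), 2L),
      replicate = rep(seq_len(config$n_replicates), 2L * config$n_tissues),
      value = c(ka, kb))
  }
  tab <- rbindlist(rows)
  path <- file.path(outdir, "expression.tsv")
  write_tsv_c(tab, path,
              comments = c("subgenomics simulate_expression",
                           sprintf("seed=%d", as.integer(seed))))
  truth$biased_pairs <- data.frame(
    pair_id = pairs$pair_id[biased_idx],
    direction = direction, stringsAsFactors = FALSE)
  list(expr = path, truth = truth)
}

#' Simulate per-cytosine methylation counts
#'
#' For every gene, cytosine sites are placed in the 2 kb upstream flank, the
#' gene body and the 2 kb downstream flank at context-specific densities.
#' A site is truly methylated with the configured regional probability;
#' truly methylated sites draw methylated read counts as
#' `Binomial(n, 1 - p_err)` and unmethylated sites as `Binomial(n, p_err)`,
#' with coverage `n ~ 1 + Poisson(meth_coverage)`.
#'
#' @inheritParams simulate_cds_pairs
#' @param genes optional gene table (gene_id, chrom, start, end, strand,
#'   subgenome); taken from `truth$genes` when omitted, or synthesised.
#' @return list with `cx` (TSV path: chrom, pos, strand, context,
#'   count_methylated, count_unmethylated) and updated `truth`.
#' @export
simulate_methylation <- function(config, seed, outdir = tempfile("simmeth"),
                                 truth = NULL, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(substream(seed, 4L))
  if (is.null(genes)) {
    if (!is.null(truth$genes)) genes <- as.data.table(truth$genes)
    else {
      layout <- gene_layout(config)
      genes <- rbind(
        layout[, .(gene_id = gene_A, chrom = chrom_A, start, end,
                   strand = "+", subgenome = "A")],
        layout[, .(gene_id = gene_B, chrom = chrom_B, start, end,
                   strand = "+", subgenome = "B")])
    }
  }
  genes <- as.data.table(genes)
  if (is.null(truth)) { truth <- list(); class(truth) <- "sim_truth" }
  flank <- 2000L
  contexts <- names(config$methylation_levels)
  rows <- vector("list", nrow(genes) * length(contexts) * 3L)
  ri <- 1L
  for (g in seq_len(nrow(genes))) {
    span <- list(
      upstream   = c(max(1L, genes$start[g] - flank), genes$start[g] - 1L),
      body       = c(genes$start[g], genes$end[g]),
      downstream = c(genes$end[g] + 1L, genes$end[g] + flank))
    for (ctx in contexts) {
      dens <- config$meth_site_density[[ctx]]
      for (rg in names(span)) {
        lo <- span[[rg]][1]; hi <- span[[rg]][2]
        if (hi <= lo) next
        ns <- max(1L, round((hi - lo + 1L) * dens))
        pos <- sort(sample(lo:hi, min(ns, hi - lo + 1L)))
        level <- config$methylation_levels[[ctx]][[rg]]
        truly <- runif(length(pos)) < level
        n <- 1L + rpois(length(pos), config$meth_coverage)
        k <- rbinom(length(pos), n, ifelse(truly, 1 - config$p_err, config$p_err))
        rows[[ri]] <- data.table(chrom = genes$chrom[g], pos = pos,
                                 strand = "+", context = ctx,
                                 count_methylated = k,
                                 count_unmethylated = n - k)
        ri <- ri + 1L
      }
    }
  }
  tab <- rbindlist(rows)
  setorder(tab, chrom, pos, context)
  path <- file.path(outdir, "cytosines.tsv")
  write_tsv_c(tab, path,
              comments = c("subgenomics simulate_methylation",
                           sprintf("seed=%d p_err=%g", as.integer(seed), config$p_err)))
  truth$methylation_levels <- config$methylation_levels
  list(cx = path, truth = truth)
}

#' Simulate per-pair CG methylation status calls with an elevated
#' epimutation rate
#'
#' Given the CDS FASTA files of homoeologous pairs, finds positions where
#' both copies carry a CG dinucleotide, assigns a methylation status to copy
#' A, and flips it in copy B with probability
#' `min(0.75, epi_factor * true_ks)` — an epimutation process running at a
#' controlled multiple of the substitution rate.
#'
#' @param fasta_A,fasta_B CDS FASTA paths from [simulate_cds_pairs()].
#' @param truth truth record carrying `true_ks` and `homoeolog_pairs`.
#' @param epi_factor epimutation rate as a multiple of Ks.
#' @param level marginal probability a CG site is methylated in copy A.
#' @param seed integer seed.
#' @return data.table (gene, pos, methylated) covering both copies.
#' @export
simulate_pair_cg_calls <- function(fasta_A, fasta_B, truth, epi_factor = 5,
                                   level = 0.7, seed = 1L) {
  set.seed(substream(seed, 5L))
  sa <- Biostrings::readDNAStringSet(fasta_A)
  sb <- Biostrings::readDNAStringSet(fasta_B)
  pairs <- truth$homoeolog_pairs
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- as.character(sa[[pairs$gene_A[i]]])
    b <- as.character(sb[[pairs$gene_B[i]]])
    pos <- intersect(cg_positions(a), cg_positions(b))
    if (!length(pos)) { out[[i]] <- NULL; next }
    ma <- runif(length(pos)) < level
    flip <- runif(length(pos)) < min(0.75, epi_factor * truth$true_ks[[pairs$pair_id[i]]])
    mb <- ifelse(flip, !ma, ma)
    out[[i]] <- data.table(
      gene = rep(c(pairs$gene_A[i], pairs$gene_B[i]), each = length(pos)),
      pos = rep(pos, 2L), methylated = c(ma, mb))
  }
  rbindlist(out)
}

cg_positions <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  which(v[-length(v)] == "C" & v[-1] == "G")
}

#' Simulate tabular homology hits for the synthetic gene set
#'
#' Writes a 12-column blast-tab-style TSV: one high-scoring hit per true
#' homoeologous pair (collinear by construction) plus uniformly drawn
#' spurious low-scoring hits between random genes, so that chaining and
#' reciprocal-best-hit filtering have realistic negatives to reject.
#'
#' @param truth truth record from [simulate_genome()] (needs
#'   `homoeolog_pairs` and `genes`).
#' @param seed integer seed.
#' @param outdir output directory.
#' @param n_spurious number of random background hits.
#' @return list with `hits` (TSV path).
#' @export
simulate_homology_hits <- function(truth, seed, outdir = tempfile("simhits"),
                                   n_spurious = 200L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(substream(seed, 7L))
  pairs <- truth$homoeolog_pairs
  genes <- as.data.table(truth$genes)
  n <- nrow(pairs)
  true_hits <- data.table(
    query = pairs$gene_A, subject = pairs$gene_B,
    identity = round(runif(n, 85, 99), 1), length = 900L, mismatch = 0L,
    gapopen = 0L, qstart = 1L, qend = 900L, sstart = 1L, send = 900L,
    evalue = 1e-100, score = round(runif(n, 800, 1200), 1))
  ga <- genes[subgenome == "A", gene_id]; gb <- genes[subgenome == "B", gene_id]
  sp <- data.table(
    query = sample(ga, n_spurious, replace = TRUE),
    subject = sample(gb, n_spurious, replace = TRUE),
    identity = round(runif(n_spurious, 30, 60), 1), length = 300L,
    mismatch = 100L, gapopen = 5L, qstart = 1L, qend = 300L, sstart = 1L,
    send = 300L, evalue = 1e-5,
    score = round(runif(n_spurious, 50, 200), 1))
  sp <- sp[!paste(query, subject) %in% paste(true_hits$query, true_hits$subject)]
  tab <- rbind(true_hits, sp)
  path <- file.path(outdir, "homology_hits.tsv")
  lines <- c(sprintf("# subgenomics simulate_homology_hits seed=%d", as.integer(seed)),
             do.call(paste, c(tab, sep = "\t")))
  writeLines(lines, path)
  list(hits = path)
}

#' Simulate a k-mer depth histogram from a genome of known size
#'
#' Emulates a shotgun k-mer counting run at uniform coverage: each of the
#' `genome_size - k + 1` genomic k-mers (assumed distinct, as in random
#' sequence) is observed `Poisson(depth)` times; an optional error component
#' adds singleton k-mers.
#'
#' @param genome_size true genome size in bp.
#' @param depth mean sequencing depth.
#' @param k k-mer length (depth-histogram convention, default 17).
#' @param error_kmers number of error k-mers added at depth 1.
#' @param seed integer seed.
#' @return a [kmer_histogram()] object.
#' @export
simulate_kmer_histogram <- function(genome_size, depth, k = 17L,
                                    error_kmers = 0L, seed = 1L) {
  set.seed(substream(seed, 6L))
  n_kmers <- genome_size - k + 1L
  counts <- rpois(n_kmers, depth)
  counts <- counts[counts > 0]
  tab <- table(counts)
  depths <- as.integer(names(tab))
  cnt <- as.integer(tab)
  if (error_kmers > 0) {
    if (1L %in% depths) cnt[depths == 1L] <- cnt[depths == 1L] + error_kmers
    else { depths <- c(1L, depths); cnt <- c(error_kmers, cnt) }
  }
  o <- order(depths)
  kmer_histogram(depths[o], cnt[o], k = k)
}

#' Write a truth record as JSON
#' @param truth a `sim_truth` record.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  # named atomic vectors must go out as JSON objects, not arrays
  for (f in c("subgenome_of_chromosome", "true_ks", "true_ka", "saturated"))
    if (!is.null(x[[f]])) x[[f]] <- as.list(x[[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a truth record written by [write_truth()]
#' @param path JSON path.
#' @return `sim_truth` list.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("homoeolog_pairs", "homoeolog_chromosome_pairs", "genes",
              "biased_pairs"))
    if (!is.null(x[[f]])) x[[f]] <- as.data.frame(x[[f]])
  for (f in c("subgenome_of_chromosome", "true_ks", "true_ka", "saturated"))
    if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]])
  class(x) <- "sim_truth"
  x
}

#' Generate the full synthetic dataset in one call
#'
#' Runs every generator with sub-seeds derived from one master seed and
#' writes the combined truth record alongside.
#'
#' @inheritParams simulate_genome
#' @return list of output paths plus `truth` and `sizes`.
#' @export
simulate_all <- function(config, seed, outdir = tempfile("simall")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g <- simulate_genome(config, seed, outdir)
  cds <- simulate_cds_pairs(config, seed, outdir, truth = g$truth)
  te <- simulate_te_table(config, seed, outdir, truth = cds$truth)
  ex <- simulate_expression(config, seed, outdir, truth = te$truth)
  me <- simulate_methylation(config, seed, outdir, truth = ex$truth)
  hits <- simulate_homology_hits(me$truth, seed, outdir)
  truth <- me$truth
  tp <- file.path(outdir, "truth.json")
  write_truth(truth, tp)
  list(fasta = g$fasta, gff = g$gff, cds_A = cds$fasta_A, cds_B = cds$fasta_B,
       te = te$te, sizes = te$sizes, expr = ex$expr, cx = me$cx,
       hits = hits$hits, truth_json = tp, truth = truth)
}
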