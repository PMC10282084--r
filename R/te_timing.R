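# TE divergence landscapes per subgenome and the allopolyploidy window
# bounded by their segregation region.

#' Read a TE copy table
#'
#' Expects columns copy_id, subgenome, family, perc_div, length (the
#' RepeatMasker "PercDiv" convention: percent substitutions of each copy
#' against its family consensus).
#'
#' @param path TSV path (comment lines beginning `#` allowed).
#' @return data.table.
#' @export
read_te_table <- function(path) {
  tab <- read_tsv_c(path)
  need <- c("copy_id", "subgenome", "family", "perc_div", "length")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stopf("TE table lacks columns: %s",
                             paste(missing, collapse = ", "))
  if (any(tab$perc_div < 0 | tab$perc_div > 100))
    stopf("perc_div must lie in [0, 100]")
  if (any(tab$length <= 0)) stopf("copy length must be > 0")
  tab
}

#' Build per-subgenome TE divergence profiles
#'
#' Length-weighted histograms of percent divergence on a shared bin grid,
#' normalised to percent of subgenome size, so each bin holds the fraction
#' of the subgenome occupied by TE copies of that age class.
#'
#' @param copies TE copy table ([read_te_table()] layout).
#' @param subgenome_sizes named vector of subgenome sizes in bp.
#' @param bin_width histogram bin width in percent divergence.
#' @return object of class `te_profiles`: list(bins = bin left edges,
#'   profiles = named list of per-bin percent-of-subgenome values,
#'   bin_width).
#' @export
build_te_profiles <- function(copies, subgenome_sizes, bin_width = 0.5) {
  copies <- as.data.table(copies)
  subs <- sort(unique(copies$subgenome))
  unknown <- setdiff(subs, names(subgenome_sizes))
  if (length(unknown)) stopf("unknown subgenome label(s): %s",
                             paste(unknown, collapse = ", "))
  breaks <- seq(0, 100, by = bin_width)
  profiles <- lapply(subs, function(s) {
    d <- copies[subgenome == s]
    bin <- pmin(findInterval(d$perc_div, breaks, rightmost.closed = TRUE),
                length(breaks) - 1L)
    mass <- tapply(d$length, factor(bin, levels = seq_len(length(breaks) - 1L)),
                   sum, default = 0)
    100 * as.numeric(mass) / subgenome_sizes[[s]]
  })
  names(profiles) <- subs
  structure(list(bins = breaks[-length(breaks)], profiles = profiles,
                 bin_width = bin_width),
            class = "te_profiles")
}

#' Locate the segregation region of two TE divergence profiles
#'
#' Formalises the "non-overlapping" region of two TE landscapes: per bin,
#' the relative difference `D(b) = |pA(b) - pB(b)| / max(pA(b), pB(b),
#' floor)` is computed, and the window is the maximal contiguous run of at
#' least `min_run` bins with `D(b) > delta`, anchored at the bin of
#' largest relative difference (runs are ranked by their strongest bin, so
#' shrinking `delta` can only extend the window, never relocate it to a
#' longer but weaker run). An empty window (no qualifying run) is allowed.
#'
#' @param profiles a `te_profiles` object with exactly two subgenomes.
#' @param delta relative-difference threshold in (0 corresponds to "any
#'   difference"); default 0.5.
#' @param min_run minimum run length in bins.
#' @param floor denominators below this are clamped (guards empty bins).
#' @return list of class `te_window`: d_low, d_high (percent divergence;
#'   NA when empty), n_bins, D (per-bin relative difference).
#' @export
segregation_region <- function(profiles, delta = 0.5, min_run = 2L,
                               floor = 1e-9) {
  stopifnot(inherits(profiles, "te_profiles"))
  if (length(profiles$profiles) != 2)
    stopf("segregation region is defined for exactly two subgenomes")
  pA <- profiles$profiles[[1]]; pB <- profiles$profiles[[2]]
  D <- abs(pA - pB) / pmax(pA, pB, floor)
  over <- D > delta
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_run)
  if (!length(runs))
    return(structure(list(d_low = NA_real_, d_high = NA_real_, n_bins = 0L,
                          D = D), class = "te_window"))
  peak_D <- vapply(runs, function(k) max(D[starts[k]:ends[k]]), 0)
  best <- runs[which.max(peak_D)]
  lo_bin <- starts[best]; hi_bin <- ends[best]
  structure(list(d_low = profiles$bins[lo_bin],
                 d_high = profiles$bins[hi_bin] + profiles$bin_width,
                 n_bins = hi_bin - lo_bin + 1L, D = D),
            class = "te_window")
}

#' Convert TE percent divergence to time
#'
#' Under a symmetric molecular clock each of the two diverging copies
#' accumulates half the observed divergence, so
#' `t = (d / 100) / (2 * rate)` years.
#'
#' @param d percent divergence (0-100).
#' @param rate substitution rate, substitutions/site/year (> 0).
#' @return time in years.
#' @export
divergence_to_time <- function(d, rate) {
  if (rate <= 0) stopf("rate must be > 0")
  (d / 100) / (2 * rate)
}

#' Estimate the allopolyploidy window from a TE copy table
#'
#' Pipeline wrapper: build profiles, locate the segregation region, and
#' convert its bounds to the genome-merger time (lower bound, the youngest
#' subgenome-specific insertions) and the progenitor-divergence time (upper
#' bound).
#'
#' @inheritParams build_te_profiles
#' @inheritParams segregation_region
#' @param rate TE substitution rate (substitutions/site/year).
#' @return list of class `te_timing`: window, t_merge, t_divergence, rate,
#'   delta, profiles.
#' @export
te_timing <- function(copies, subgenome_sizes, rate, bin_width = 0.5,
                      delta = 0.5, min_run = 2L) {
  prof <- build_te_profiles(copies, subgenome_sizes, bin_width)
  win <- segregation_region(prof, delta = delta, min_run = min_run)
  structure(list(window = c(d_low = win$d_low, d_high = win$d_high),
                 t_merge = if (is.na(win$d_low)) NA_real_
                           else divergence_to_time(win$d_low, rate),
                 t_divergence = if (is.na(win$d_high)) NA_real_
                                else divergence_to_time(win$d_high, rate),
                 rate = rate, delta = delta, profiles = prof),
            class = "te_timing")
}
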