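---
title: "Methods: subgenome phasing and comparative analysis of an allotetraploid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgenome phasing and comparative analysis of an allotetraploid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the choices made where the design
was genuinely open, and what the synthetic-data tests do and do not show
about real data. Every empirical number referred to here is computed by the
test suite (`tests/testthat/`) or by `scripts/acceptance.R`; the vignette
states no result of its own.

## The scientific setting

An allotetraploid genome carries two chromosome sets — subgenomes —
inherited from two diverged diploid progenitors. Reconstructing that
history from a modern assembly requires answering, in order: which
chromosomes belong to which subgenome; which gene copies are homoeologs
(descendants of orthologs in the two progenitors); how old is the shared
whole-genome duplication (WGD) and how old is the hybridization; and how
asymmetrically have the two subgenomes evolved since the merger, in
expression and in DNA methylation. The package implements one tested
pipeline for each question, plus a generator of synthetic allotetraploid
data with a machine-readable ground truth, so that every step is verifiable
end to end without any external dataset.

## Subgenome phasing from differential k-mers

Subgenome-specific transposable-element insertions accumulated while the
progenitors evolved separately; their sequences survive as k-mers that are
abundant on one subgenome's chromosomes and rare on the other's. Phasing
therefore (i) counts canonical 13-mers per chromosome, (ii) keeps 13-mers
with genome-wide count strictly greater than 100 that are at least two-fold
enriched (pseudocount 1) in one member of at least one homoeologous
chromosome pair, and (iii) clusters the chromosomes on the z-scaled
count matrix — hierarchical clustering with correlation distance and
average linkage, cut at two groups. Labelling is a pure convention: the
group containing the lexicographically smallest chromosome ID is "A".

Choices worth stating:

* **Canonical form** is the lexicographic minimum of a window and its
  reverse complement; odd k makes this unambiguous. Windows containing
  non-ACGT symbols are skipped.
* **The enrichment criterion is pair-relative**, so homoeologous
  chromosome pairs are an explicit input (from the synteny step, or from
  truth in simulations). With no pairs supplied, all chromosome pairs are
  tried — a weaker but well-defined fallback.
* **The clustering algorithm is not dictated by the phasing idea**;
  correlation/average-linkage was chosen because the signal is a profile
  shape, not an absolute magnitude, and is cross-checked in tests by
  perfect recovery (adjusted Rand index 1.0) across replicate simulations.
* **Weak signal**: if no k-mer passes the strict floor (e.g. repeat
  families with fewer than ~100 copies), the floor is dropped, the most
  enriched k-mers are used, a warning is raised and the report carries
  `weak_signal = TRUE`. Assignments in that regime are emitted, with
  silhouette scores as the confidence measure, rather than silently
  failing.

Genome size estimation from a k-mer depth histogram uses
`size = total k-mer instances / modal depth`, with depths below 4 masked
as sequencing error before the mode is taken (standard k-mer histogram
practice). A histogram that only decreases has no peak and is an error.

## Synteny and homoeolog pairing

Homology hits (12-column blast-tab layout) are chained in **gene-rank
coordinates** — the cut-offs are "20 genes" and "5 pairs", so ordinal gene
positions, not base pairs, are the right axis. Chains are score-weighted
and found by dynamic programming with a state per (hit, capped chain
length), which makes the minimum-anchor constraint exact; tests verify
equality with exhaustive enumeration over all admissible chains on
randomized instances of up to 12 hits. Tandem-duplicate hits (same query,
adjacent subjects) collapse to their best-scoring representative before
chaining, as MCScanX-style preprocessing does. Homoeolog pairs are
reciprocal best hits (score ties on either side drop the gene); pairs also
anchored in a block are marked `block+RBH`, and a strict mode keeps only
those. Conflicts (one gene in two candidate pairs) resolve to the
higher-scoring pair, deterministically.

## Ka/Ks, Ks distributions and WGD dating

The Nei–Gojobori (1986) estimator is implemented in full: synonymous site
fractions per codon with stop-codon outcomes excluded from the
denominators; site counts averaged over the two sequences; observed
differences averaged with equal weight over all mutational pathways that
avoid stop codons (with a fallback to all pathways for the rare fully
blocked codon pair); Jukes–Cantor correction `K = -3/4 ln(1 - 4/3 p)`;
proportions at or above 3/4 flagged saturated. The implementation is
table-driven (64 x 64 precomputed pathway averages); its independence is
guarded by a test-side oracle that enumerates pathway permutations
directly from strings.

Ks age distributions are binned at 0.01 by default over [0, 5], with
saturated pairs counted separately. A peak is a bin strictly greater than
every bin within a +/-3-bin window and above a minimum count — the
local-maximum definition used by common `findPeaks`-style helpers. WGD
dating is the molecular-clock identity `T = Ks / (2r)`; the default rate
is 5.26e-9 substitutions/site/year, the value appropriate for the lineage
this workflow was built around, and is always an explicit parameter.

The Mann–Whitney U test used for group comparisons computes U from
midranks and is exact — complete enumeration of rank splits — whenever
`choose(n + m, n) <= 1e4`; beyond that it uses the normal approximation
with tie-corrected variance and continuity correction. The exact branch
handles ties correctly, which `wilcox.test` does not attempt; tests verify
both branches against enumeration and against `wilcox.test` where each is
applicable.

## TE divergence landscapes and the allopolyploidy window

Per-copy percent divergences to family consensus (RepeatMasker's PercDiv
convention) are binned at 0.5% and **length-weighted**, normalised to
percent of subgenome size, so the two profiles are comparable between
subgenomes of different sizes. "Non-overlapping segregation region" is not
an operational definition, so the package formalises it: per bin, the
relative difference `D(b) = |pA - pB| / max(pA, pB, floor)`; the window is
the maximal run of at least 2 bins with `D > 0.5`, anchored at the bin of
largest `D`. Anchoring (rather than taking the longest run) guarantees
that lowering the threshold extends the window instead of relocating it to
a long but weak run of sampling noise. Both `delta` and `min_run` are
prominent parameters because this formalisation is the module's central
modelling decision. Conversion to time assumes a symmetric clock,
`t = (d/100) / (2 rate)`; the TE rate (default 1e-8/site/year in the
simulations) is a declared input, never inferred.

## Homoeolog expression bias and dominance

Per pair and tissue, HEB is `log2((mean_A + 1) / (mean_B + 1))` of
replicate means; the pseudocount bounds silent pairs at 0. Tissue-level
calls apply a Welch t-test with three gates: raw p < 0.01, BH-adjusted
q < 0.05 (one family across all pair x tissue tests of the run), and fold
change >= 2 of replicate means. The Welch form was chosen over the pooled
test for robustness to unequal variances; a flag restores the pooled test.

Pair-level classification has three selectable rules. The default,
`"paired"`, runs one paired t-test per pair on the per-sample log2 ratios
across the entire tissue x replicate dataset, BH-adjusts across pairs, and
additionally requires the two-fold gate in at least one tissue in the
called direction. The alternatives classify from the per-tissue calls
(biased in >= 1 tissue and never the opposite; or in every tissue). The
paired rule is the default because per-tissue two-sample tests at two or
three replicates have very low power against a two-fold shift under
realistic overdispersion (negative-binomial dispersion 0.1), whereas the
whole-dataset paired test reaches high recall at the same false-discovery
budget — the power simulations in the acceptance suite quantify both.

Dominance is a two-sided exact binomial sign test of the A-biased versus
B-biased pair counts against 0.5, with a subgenome declared dominant only
below p = 0.05. The selection-pressure comparison between dominant and
suppressed copies of extreme-bias clusters uses the Mann–Whitney test
above and requires per-copy Ka/Ks estimates (e.g. against an outgroup
copy).

## Methylation

Site calls are upper-tail binomial tests `P(X >= k | n, p_err)` at 0.05,
with `p_err = 0.01` as the default bisulfite non-conversion rate (the
error rate is a parameter; no value is canonical). Both strands of a CG
dyad are merged before calling. Sites need coverage strictly greater
than 5 to enter gene-level statistics. The gene-body test is the exact
binomial tail `sum_{i=m}^{n} C(n,i) p^i (1-p)^{n-i}` with the background
`p` computed per context from the input itself (genome-wide proportion of
covered cytosines called methylated). CG body-methylated homoeologous
pairs require both members significant in CG and neither significant in
CHG or CHH — the class isolates CG-only gene-body methylation.

DmCG/C compares methylation status at aligned positions where both copies
carry a CG dinucleotide; the rate is discordant/comparable sites, an
epimutation analogue of Ks, flagged undefined when no comparable site
exists. Site matching uses alignment columns (positional orthology would
be an alternative; the column rule is declared and symmetric in pair
order). Metaprofiles average per-gene weighted levels over 2 kb flanks
(10 bins) and length-scaled gene bodies (20 bins), strand-flipped so
upstream is always 5'.

## The synthetic-data generator

The generator is first-class, tested code: one master seed, fixed
per-output sub-streams (so adding an output never perturbs another), and
byte-identical outputs for identical seeds. The default scenario mirrors
the study conditions the pipeline was designed for: 10 + 12 chromosomes of
100 kb; 5 shared and 5 subgenome-private repeat families of 200 bp at 150
copies (above the 100-count selection floor — a 60-copy variant exercises
the weak-signal path); 200 collinear homoeologous gene pairs of 300
codons; a Ks mixture with components at 0.055 (sd 0.01) and 0.46 (sd
0.05), equal weights — the recent progenitor split and the older WGD;
Ka = 0.2 Ks; a TE landscape with a shared uniform component on 8–30%
divergence and private components on 1–5% with asymmetric copy numbers
(3000 vs 600), the asymmetry giving the segregation detector its contrast;
7 tissues x 3 replicates of negative-binomial expression (dispersion 0.1,
log-normal baselines) with 30% of pairs two-fold biased; methylation
levels 0.2/0.8/0.2 (CG upstream/body/downstream) against low CHG/CHH,
coverage 1 + Poisson(20), error rate 0.01.

Codon evolution realises `round(Ks * S)` synonymous and `round(Ka * N)`
nonsynonymous substitution events (sites counted on the ancestral
sequence), split binomially between the two branches, with proposals that
hit stop codons rejected. Multiple hits arise naturally, so the
Jukes–Cantor correction is genuinely exercised; recovery tests bound the
median estimation error rather than assuming it away. A methylation state
is simulated per cytosine (methylated with the regional probability; reads
then Binomial(n, 1 - p_err) or Binomial(n, p_err)), so the configured
level is also the expected read-level methylation — the convention the
metaprofile tests rely on.

What the generator does **not** emulate: read-level sequencing noise,
assembly errors, homoeologous exchanges, gene loss and fractionation,
tandem arrays, TE families with age-structured divergence within the
window, tissue-specific bias directions, or spatially correlated
methylation. Passing tests therefore demonstrate correctness of the
algorithms under their stated models and adequate power at study-scale
signal strengths — not robustness to every artefact of real data.

## Numerical and degenerate-input conventions

Binomial tails are evaluated in log space via `pbinom`; tests pin them to
term-wise summation oracles at 1e-12. Fold ratios and HEB use pseudocount
1; k-mer fold ratios use pseudocount 1. Zero-variance t-tests return
p = 1 (identical means) or 0. Zero-variance chromosome columns cannot
enter the correlation distance and are assigned by nearest centroid with a
flag. Empty inputs error early with named messages (no peak, empty
cluster, unknown subgenome label, unknown gene ID). Problem sizes
throughout the tests — 20-seed phasing replicates, 200 x 100-codon oracle
alignments, 2000-value Ks mixtures, 500-pair expression and epimutation
simulations — were chosen as the smallest sizes at which the stochastic
properties under test are stable.

## Known limitations

* Branch-specific Ka/Ks (free-ratio style, against an outgroup on a fixed
  tree) is approximated by pairwise NG86 against the outgroup copy;
  maximum-likelihood branch models are out of scope.
* The two-cluster cut encodes the tetraploid assumption; higher ploidies
  would need a generalised cut and a different labelling convention.
* The segregation-window formalisation is one defensible reading of
  "non-overlapping"; its `delta` default (0.5) suppresses single-bin noise
  but has no external calibration.
* The pipeline consumes homology hits and TE tables; it does not compute
  alignments or annotate repeats.
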