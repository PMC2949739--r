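---
title: "Short-range linkage disequilibrium from phased haplotype alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-range linkage disequilibrium from phased haplotype alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapld)
```

## The problem

Association mapping in the malaria vector *Anopheles gambiae s.l.* depends on
how far linkage disequilibrium (LD) extends around a causative variant. In
these mosquitoes LD within genes is strikingly weak: between SNPs only tens
to hundreds of base pairs apart, most pairwise r² values fall below 0.3. That
regime determines marker density for candidate-gene and genome-wide studies,
so it needs to be quantified carefully from phased data.

`hapld` analyses phased, gap-aligned haplotype alignments — one multi-FASTA
per gene and species, one record per cloned haplotype, so each individual
contributes up to two records — and carries the analysis from raw alignment
to cross-gene/cross-species comparison:

1. site classification and polymorphism summaries (`extract_sites`,
   `polymorphism_summary`),
2. all pairwise two-locus LD with exact-test significance
   (`pairwise_ld_scan`),
3. LD-decay curves against distance (`fit_parametric_decay`,
   `fit_nonparametric_decay`),
4. haploblock grids (`build_grid`),
5. segment-based Wilcoxon group comparisons (`segment_means`,
   `compare_groups`),
6. a coalescent-with-recombination generator (`simulate_haplotypes`,
   `simulate_study`) so that every stage is testable with no external data.

## Site filtering

A column enters LD analysis only if it is biallelic over `A,C,G,T` with no
gap or `N` in any haplotype. The polymorphic-site count S is more liberal: it
counts every column with at least two nucleotide states, whether or not a gap
is also present. The usable count k is therefore at most S, and the published
pair counts for these genes are consistent with `choose(k, 2)` for a k
strictly below S — i.e. with exactly this kind of exclusion rule. Which
specific sites the original software excluded is not documented anywhere we
could check, so the gap/multiallelic rule used here is the standard
convention rather than a verified reconstruction; `run_full_analysis` logs
every excluded site count so the filter is auditable.

Two optional knobs tighten the filter: `drop_singletons` and its
generalisation `min_minor_count`. Frequency conditioning matters for decay
fitting (below); the default keeps every biallelic site.

Coordinates are 0-based aligned columns, and distances are differences of
aligned-column indices, so insertions count toward distance. An `N` excludes
a site exactly like a gap; no imputation is attempted.

## Diversity

Nucleotide diversity π is the mean, over all haplotype pairs, of the
proportion of differing sites among pairwise-comparable columns (both states
in `A,C,G,T`). No multiple-hit correction is applied. The synonymous /
non-synonymous partition follows Nei & Gojobori (1986): per-codon counts of
potential synonymous sites (the fraction of single-nucleotide changes that
preserve the amino acid, changes to stop codons counted as non-synonymous),
and observed differences averaged over all mutational pathways between the
two codons with equal weights, excluding pathways that pass through a stop
codon. Codons containing a gap or `N` in either sequence of a pair are
skipped entirely. Because πs divides by synonymous sites only, πs can exceed
the total π computed over all sites — different denominators, not an error.
Coding intervals are supplied as 0-based half-open column ranges with a
reading-frame offset; the frame of the first interval shifts the codon start
and any trailing partial codon is dropped.

## Pairwise LD

For each usable site pair the 2×2 haplotype table is built with the
alphabetically first allele as reference (deterministic labelling), and

* `D = p_AB − p_A p_B`,
* `D' = |D| / D_max`,
* `r = D / sqrt(p_A p_a p_B p_b)`, `r² = r²`.

Significance uses the Fisher exact test with both margins fixed. The default
two-tailed convention is the probability-mass method — sum the probabilities
of all tables whose point probability does not exceed the observed table's —
which matches `stats::fisher.test` and the software classically used for
such scans; tail-doubling is available behind `method = "doubling"`. The two
conventions do not order consistently, so published significant-pair counts
computed under an unknown convention may differ slightly from recomputed
ones. The Bonferroni family is all pairwise tests within one gene × species
dataset.

Haploblocks are defined as maximal runs of consecutive usable sites whose
within-run pairwise r² all reach a threshold (default 0.8). This is a
deliberate simplification of the D′-confidence-interval block rule used by
Haploview: with phased haplotypes and the r² grid already in hand, a
threshold rule is transparent and directly tied to the plotted quantity.
Blocks are reported with their bp span; in both the real data this emulates
and the simulations, strong blocks rarely span more than ~50 bp.

```{r quick-example}
aln <- simulate_haplotypes(sim_params(n = 16, L = 600, theta = 0.02,
                                      rho = 0.01, seed = 42,
                                      gene_id = "demo"))
scan <- pairwise_ld_scan(aln)
scan
build_grid(scan)$blocks
```

## Decay modelling

The parametric decay curve is the Hill & Weir (1988) drift–recombination
expectation with sample-size adjustment,

$$E[r^2] = \frac{10 + C}{(2 + C)(11 + C)}
  \left[1 + \frac{(3 + C)(12 + 12C + C^2)}{n(2 + C)(11 + C)}\right],
  \qquad C = \rho\, d,$$

fitted by bounded nonlinear least squares for the per-bp recombination
parameter ρ, started from the best point of a 40-point log grid over
`[1e-6, 1]` to avoid local minima. Two properties of this expectation drive
the design:

* its ceiling at `C = 0` is about 0.45–0.48 for realistic n, so datasets
  whose observed r² exceed the ceiling cannot be fitted — the estimate runs
  to the boundary or the optimiser fails, and both outcomes are *returned*
  (`converged`, `boundary`, `failure_reason`) rather than raised, because
  they are informative: high-LD datasets genuinely defeat this model;
* for finite n it tends to the 1/n sampling floor at large C, not to zero
  (the zero limit holds only as n → ∞).

The simpler Sved (1971) form `1/(1+C)` is available via
`model = "sved"`. The attribution of the published decay model to Hill–Weir
is an assumption — the cited page gives no formula — adopted because this
expectation's ceiling explains the reported pattern of failed nonlinear fits
for high-LD datasets.

The nonparametric curve is a penalized cubic regression spline of r² on
distance with smoothing chosen by generalized cross-validation — `mgcv::gam`
with `s(d, bs = "cr")`, the same smoother habitually used to draw LD decay
lines. The basis dimension is capped at `min(10, distinct distances − 1)`,
ties in distance are kept as separate observations, and the fitted curve is
reported only within the observed distance range (no extrapolation).
`distance_at_threshold` reads off where a fitted curve first drops below a
given r² (e.g. 0.3), with an explicit not-reached status for curves that
never do.

### Estimating ρ from r² and frequency conditioning

Fitting this expectation to *all* pairwise r² overestimates ρ severely. The
reason is classical (McVean 2002): the expectation is a ratio-of-expectations
(σ_d²-type) quantity, while observed mean r² is an expectation-of-ratio, and
the two agree only for intermediate-frequency alleles; rare alleles drag
observed r² far below the curve. In our simulations (n = 32, θ = 0.01/bp,
L = 1000) mean r² for completely linked sites is ≈ 0.21 with singletons
included, against a model ceiling of 0.478; conditioning on minor-allele
count ≥ 4 (MAF ≥ 0.125) brings it to ≈ 0.45, and with that conditioning the
median ρ̂ over 20 replicates recovers true ρ within ~10% at ρ = 0.01 and
stays monotone across a 0.002/0.01/0.05 ladder. The recovery experiments in
the test-suite therefore condition on MAF ≥ 0.125 via
`pairwise_ld_scan(..., min_minor_count = 4)`; descriptive scans keep all
sites.

## Segment comparison

To compare LD levels between genes or species, each alignment is cut into 4
consecutive segments of near-equal length (remainder columns go to the
leftmost segments) and mean r² is computed per segment from the pairs whose
*both* sites fall in that segment; straddling pairs are discarded. Pooling
the segment means by gene (up to 4 segments × 7 species = 28 values) or by
species (up to 16 values) gives the lists compared by two-sided Wilcoxon
rank-sum tests — unpaired, because the pooled lists are not matched; the
exact distribution is used for combined sizes ≤ 20 without ties, otherwise
the tie-corrected normal approximation, and the method used is reported.
Segments with no pairs are dropped, and no correction across the group-pair
tests is applied by default (a `p_adjust_method` argument exists). Treating
the 4 segment means as independent is itself an approximation — neighbouring
segments share genealogical history — so these tests are implemented as
specified but should be read as descriptive.

## The synthetic-data generator

`simulate_haplotypes` samples the standard neutral coalescent with
recombination: lineages carry ancestral-material segments on [0, L); going
back in time, each lineage pair coalesces at rate 1 (time in units of 2N
generations), each lineage recombines at rate ρ/2 per bp of breakable span,
and mutations fall at θ/2 per bp per lineage on live segments. Segments
whose descendant set reaches the full sample have found their MRCA and are
dropped. Mutations follow the infinite-sites model on continuous positions,
realised as biallelic columns (ancestral `A`, derived `C`); in the rare event
that two mutations floor to the same integer column the later one is dropped
and counted. θ and ρ are per-bp population-scaled rates (4Nμ, 4Nc), so the
decay-fit estimate ρ̂ is directly comparable to the simulation input.

The generator was cross-checked against an independent coalescent simulator:
mean-of-means r² at ρ = 0 (n = 32, θ = 0.01, 200 replicates) agreed within
one standard error, as do the site-frequency spectrum and the Watterson
segregating-site expectation.

What it deliberately does not model: selection, gene conversion, population
structure or migration, and chromosomal inversions. Two switches exercise
the data-quality filters rather than add realism: `gap_rate` injects random
alignment gaps, and `finite_sites` lets recurrent mutations stack into
multiallelic columns. An optional backward exponential-growth rate supports
the qualitative property that rapid population growth lowers LD. Passing
tests on simulated data therefore demonstrate the statistical machinery, not
robustness to selection, structure, or alignment error in real data.

`default_study_design()` mirrors the study layout this package is built
around: 4 genes × 7 taxa, per-gene lengths 1108/1238/834/735 bp and per-bp
diversities 0.0253/0.0247/0.0099/0.0159 (the reported M-form values, used as
θ for all taxa since diversities are comparable across the complex),
haplotype counts twice the reported individual counts (32 for the M form,
10–28 elsewhere), one dataset (REL2 × *An. bwambae*) monomorphic as
observed, and ρ = 0.01/bp — chosen once so that the expected decay crosses
r² = 0.3 within ~200 bp, the regime reported for these populations.

## Pipeline and numerical conventions

`run_full_analysis` writes plain tab-separated outputs with a fixed column
order and literal `NA` for undefined cells (a monomorphic dataset reports 0
pairs and `NA` mean r² rather than failing). Headline tables print at 4
significant digits; the per-pair, per-curve and grid files keep full double
precision. Every excluded site count, failed dataset and non-converged or
boundary decay fit is written to `run_log.txt`, because these are exactly
the silent choices that make LD analyses hard to reproduce. Reruns with the
same design and seed are byte-identical.

Problem sizes used in the shipped tests and in `scripts/acceptance.R` —
e.g. 200 replicates for the diversity calibration, 20 replicates per ρ level
for recovery, the full 4 × 7 study for the end-to-end and regime checks —
were chosen as the smallest designs at which the targeted 3-standard-error
and median-based checks are stable.

## Known limitations

* The haploblock rule is a threshold simplification, not the
  confidence-interval algorithm of Haploview; block counts are comparable
  only qualitatively.
* ρ̂ from the drift–recombination fit is a method-of-moments style estimate
  with the frequency-conditioning caveat above; it is not a
  composite-likelihood recombination estimator.
* πs/πn use equal pathway weighting (unweighted Nei–Gojobori); transition /
  transversion weighting is not implemented.
* The segment-based Wilcoxon design inherits the independence approximation
  discussed above.
* Real curated alignments can differ from what an automatic aligner produces
  from the deposited sequences; exact reproduction of published tables
  depends on using the original alignments.
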