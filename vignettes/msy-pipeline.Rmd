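---
title: "From sex-stratified coverage to a dated Y-chromosome phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sex-stratified coverage to a dated Y-chromosome phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msytools)
```

# Overview

msytools implements the computational chain used to study paternal lineages
in non-model mammals from short-read whole-genome sequencing, developed here
around the reindeer/caribou (*Rangifer tarandus*) Y chromosome:

1. **Molecular sexing** of samples with unknown sex from SRY-matching read
   counts and fold coverage.
2. **MSY discovery**: identifying Y-candidate contigs in a de novo assembly
   from sex-stratified coverage, then classifying 50-bp windows into
   single-copy Y (scY), multi-copy Y (mcY) and non-Y (nonY) states with a
   probabilistic depth model.
3. A **haploid variant filter cascade** with per-depth-group coverage rules
   and allele-conflict limits, plus the stringent variant ascertainment used
   for outgroup-private (moose) SNPs.
4. A **maximum-parsimony haplotype tree** built by perfect-phylogeny
   construction, with branch placement of every variant, detection of
   curation categories (recurrent, single-sample heterozygous, externally
   flagged), tree-guided imputation of missing calls, haplotype collapsing
   and hierarchical haplogroup naming.
5. **Calibration-point strict-clock dating** of tree nodes with parametric
   bootstrap intervals.
6. **Watterson's theta** per sample group.
7. A **synthetic-data module** that generates every input with known ground
   truth, so the whole chain is testable without any sequencing data.

# The models

## Window classification

Sequencing depth is normalized per sample by the mode of its window mean
depths over autosomal contigs, so 1.0 means diploid. On that scale the
expected (male, female) depth signatures are: autosomal (1, 1), X-like
(0.5, 1), scY (0.5, *b*), mcY with *c* copies (*c*/2, *b*), and unmapped
(0, 0), where *b* is the female Y-background level (the mode of female
normalized depths on Y-candidate contigs). For a window with cross-sample
mean male depth $\bar m$ and female depth $\bar f$, the two hypotheses are
scored as Gaussian mixtures,

$$
L_\mathrm{MSY} = \Big[\tfrac1{C}\sum_{c=1}^{C}
  N(\bar m;\, c/2,\, \sigma_m)\Big]\, N(\bar f;\, b,\, \sigma_f),
\qquad
L_\mathrm{nonY} = \tfrac13 \sum_{(e_m, e_f)} N(\bar m; e_m, \sigma_m)\,
  N(\bar f; e_f, \sigma_f),
$$

with nonY components $(e_m,e_f) \in \{(1,1), (0.5,1), (0,0)\}$, and
$p_\mathrm{MSY} = L_\mathrm{MSY} / (L_\mathrm{MSY} + L_\mathrm{nonY})$.
Windows with $p_\mathrm{MSY} > 0.5$ are MSY; within MSY, windows with
$\bar m < 0.75$ (the midpoint of the haploid and diploid male expectations)
are scY, the rest mcY with copy number $\mathrm{round}(2\bar m)$. Defaults:
$\sigma_m = \sigma_f = 0.15$, $C = 10$, uniform component priors. All
constants sit in `pipeline_config()`. A `per_sample = TRUE` switch evaluates
the likelihood per sample instead of on cross-sample means; the published
descriptions of this model family do not pin down which variant was used, so
both are available and the cross-sample mean is the default.

Likelihoods are evaluated in log space with log-sum-exp, so windows far
from every component (e.g. very deep repeats) still get a finite, ordered
probability instead of 0/0.

## Y-candidate contigs

Per contig, the percent covered is averaged over males and over females and
an ordinary least squares regression of female on male percent is fitted over
all contigs. Y contigs have high male but near-zero female coverage, so they
fall far below the line: a contig is flagged when its raw residual is below
-35 (percent scale) and its internally studentized residual is negative.
The response/predictor orientation is configurable because the published
description names neither; regressing female on male is the orientation under
which Y contigs produce large *negative* residuals consistent with the -35
cutoff. For the autosomal normalization set, contigs must be covered at
least 75% in both sexes with a male:female mean relative-depth ratio within
0.01 of 1; each sample's per-contig depths are first scaled by their median
across contigs (autosomes dominate any assembly, so the median is the
diploid level), which makes the ratio criterion meaningful when male and
female cohorts differ in depth. We read the published "difference of no more
than 0.01 male-to-female mean coverage ratio" as $|r - 1| \le 0.01$.

## Variant filters

Only biallelic SNPs are kept (indels, MNP/complex and multiallelic records
removed). Variants must lie in scY windows more than 50 bp from contig ends.
A sample is *conflicted* at a site when both its reference and alternative
alleles have read support. The stringent ascertainment filter (used for the
outgroup-private SNP list) removes sites with more than 2 conflicted samples,
any missing call, or any sample depth outside its depth group's range
(vLowDP 1.5-2.5, LowDP 3-7, ModDP 10-30). The genotyped-set filter removes
sites with more than 5 conflicted samples or per-group mean depth outside
vLowDP 2-8, LowDP 3-10, ModDP 8-30, and masks surviving conflicted calls to
missing so the tree never sees contradictory support. The depth semantics
differ deliberately: the ascertainment rule is applied per sample, the
genotyping rule to the per-group mean at each site (a `depth_scope` switch
exposes both readings). Filters only remove or mask, are idempotent, and
log one reason per removed site; the attrition log lets callers assert
input = survivors + removals after every stage.

For mtDNA, `consensus_from_counts()` emits the most frequent base per
position when total depth is at least 3 and N otherwise, with ties also
giving N (the upstream consensus tools do not document their tie behavior,
so the conservative choice is made explicit here). `excise_region()` removes
the D-loop columns before tree building; its coordinates are an input
because only the excised length (926 bp) is fixed by the study design, not
its span on a given reference.

## Parsimony tree

The curated haploid matrix is nearly homoplasy-free, which makes a general
tree search unnecessary: after polarizing alleles against the outgroup
(ancestral = outgroup allele; majority vote, flagged, where the outgroup
call is missing), each site defines the set of samples carrying the derived
allele. Sets that are pairwise nested-or-disjoint form a laminar family and
*are* the rooted tree; sites are processed best-supported-first and a site
whose observed carriers fit inside an accepted clade (with all observed
ancestral carriers outside it) is placed on that clade's branch, so missing
calls act as wildcards rather than spawning conflicting clades. Sites
incompatible with the accepted family are flagged recurrent and scored by
exact minimum-change (Sankoff) placement on the finished tree; the total
parsimony score is the number of placed sites plus those Sankoff costs. For
six or fewer taxa the tests verify the score against exhaustive Fitch
scoring over all topologies.

Tree-guided imputation sets a missing call to derived exactly when the
sample descends from the branch its site is placed on. Placement uses the
*smallest* explaining clade. This is conservative: when every carrier of a
small clade is missing at a site, the site is indistinguishable from a
pendant-branch site of the remaining carrier, and the smallest-clade rule
then imputes ancestral. Such sites are inherently ambiguous under parsimony
(both placements cost one change); the test suite therefore asserts exact
imputation on the identifiable subset and >=95% accuracy overall.

Haplogroup names alternate letter and number levels below the two basal
clades (named per scheme, e.g. EB and NA), children ordered by clade size
then smallest member id: `Y-EB`, `Y-EB-A`, `Y-EB-A2`, `Y-EB-A2.B`,
`Y-EB-A2.B1`, and so on. The ordering rule makes names deterministic given
the tree.

## Clock dating

A calibration node of known age $T$ (here 11,000 years, the last land
connection across the Bering strait) converts mutation counts to time. With
$\bar m$ the mean mutation count per path from the node to its descendant
tips and $L$ the scanned length (1,234,870 bp of trimmed scY),

$$
\mu_\mathrm{year} = \frac{\bar m}{L\,T}, \qquad
\mu_\mathrm{gen} = \mu_\mathrm{year}\, g,
$$

with generation time $g = 6$ years (bounds 4 and 8, which give the upper and
lower per-year rates when the per-generation rate is held fixed). The
generation count is reported both as $\lfloor T/g \rfloor = 1833$ (matching
the printed value) and as the exact ratio. Every internal node is then dated
as $\bar m_\mathrm{node} / (\mu_\mathrm{year} L)$. Intervals come from a
parametric bootstrap: each branch count is resampled Poisson around its
observed value, the rate is re-estimated from the resampled calibration
node, ages recomputed, and the percentile interval reported (1,000
replicates by default, seed fixed). By construction the calibration node is
dated at exactly $T$ in every replicate. Children dated older than their
parents - possible with noisy counts - are flagged, never clamped. This
replaces the Bayesian machinery used in the original analysis (HKY
substitution model, coalescent prior, MCMC) with the same strict-clock point
arithmetic that produced the published rate; the printed rate numbers are
reproduced exactly by `estimate_rate(14.01, 1234870, 11000, 6)`.

## Diversity

Watterson's estimator per site over a group of $n$ samples with $S$
segregating sites in $L$ bp: $\theta_W = S / (a_n L)$ with
$a_n = \sum_{i=1}^{n-1} 1/i$. Missing calls are ignored; a site needs at
least two non-missing calls within the group to count. $L$ defaults to the
total scY length (1,360,096 bp) and is decoupled from window accounting so
the estimator works on any region set.

# The synthetic-data module

`simulate_coverage_dataset()` draws per-window mean depths over a labeled
contig plan for a cohort with lognormal diploid depths. Window base counts
are Poisson with a lognormal-scaled mean (mean-preserving overdispersion,
the kind seen in real WGS depth); dispersion 0 returns exact expectations.
The defaults (11 males, 5 females, ~12x median depth, 2% female Y
background, dispersion 0.1) mirror the cohort structure used for window
classification in the study. `simulate_tree_snps()` runs an infinite-sites
process on a dated tree: per-branch Poisson mutation counts at a per-site
per-year rate, each mutation at a fresh site, so derived alleles map
uniquely to branches; missing calls, allele-support conflicts and recurrent
sites are injected afterwards with truth recorded. Injected recurrent sites
are constrained to fail the unrooted four-gamete test against the generating
topology, so they are detectable in principle; without that constraint a
homoplasy can mimic a legal clade and no method could flag it.
`simulate_sry_counts()` draws SRY-matching read counts proportional to
coverage for males and at a contamination level (default 0) for females.

What the generators deliberately do **not** model: read-level artifacts
(mapping errors, duplicates, base-quality structure), reference bias,
paralogous collapse in mcY regions, and recombination (absent from both MSY
and mtDNA). Passing tests therefore demonstrate that the *computational
chain* is correct under its stated statistical assumptions, not that those
assumptions capture every failure mode of real sequencing data.

`example_dated_tree()` provides the fixed dating substrate: a 40,000-year
two-clade topology with a 25,000-year island split, an expansion polytomy,
a four-tip calibration clade at 11,000 years and a 6,000-year young clade -
the shape of the published time tree.

# Numerical choices and degenerate inputs

* Mode estimation: histogram with fixed bin width (1 depth unit raw, 0.02
  normalized), argmax, bin midpoint - deterministic and robust to the long
  right tail of depth distributions.
* All-zero windows are classified nonY (unmapped) with their model
  probability still reported.
* Consensus ties emit N; depth below 3 emits N.
* `excise_region()` of the whole alignment returns empty sequences with a
  warning; an empty region is the identity.
* Contigs with more than 50% nonY window bp are discarded; the published
  account says only "mostly nonY", so the threshold is explicit
  configuration.
* Sex calls are strict: more than 13 SRY reads AND at least 4x coverage.
  The three-way call keeps "not-male at good coverage" distinct from
  "insufficient coverage", since the study's treatment of the former is not
  recoverable from the text.
* Haplogroup naming ties break on the lexicographically smallest member id.
* The bootstrap seed, like every other seed, lives in the configuration and
  derives from one base seed in `run_pipeline()`.

# Problem sizes in the test suite

The suite simulates ~20,000 coverage windows for classification accuracy,
perfect-phylogeny recovery up to 64 tips (~3,000 sites), exhaustive
parsimony oracles up to 6 ingroup taxa (945 topologies), 100 dating
replicates with 300 bootstrap resamples each, and 500-replicate
Monte-Carlo checks of the generators' Poisson structure. These sizes give
Monte-Carlo standard errors comfortably below the asserted tolerances while
keeping the full suite around a minute on one core.

# Known limitations

* The greedy perfect-phylogeny construction is exact for compatible
  matrices and verified against exhaustive search on small instances, but
  under heavy homoplasy with weakly supported clades (single-site support
  against single-site homoplasy) the tie is arbitrary, as it is for any
  parsimony method.
* Strict-clock point dating inherits the calibration's assumptions: a
  single rate across branches and a correct calibration age. The bootstrap
  intervals capture counting noise, not rate variation among lineages.
* External curation categories (assembly errors, repetitive regions,
  normalization failures) require raw alignments and enter as annotation
  flags rather than being computed.
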