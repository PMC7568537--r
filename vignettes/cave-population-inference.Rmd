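---
title: "Population-genomic inference for island-like cave populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genomic inference for island-like cave populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavepop)
```

## The problem

Obligate cave dwellers (troglobionts) live in habitat patches that behave
like oceanic islands: caves a few kilometers apart can be completely
isolated for gene flow. `cavepop` implements the analysis chain used to
quantify that isolation from reduced-representation (RAD-style) SNP data:
delineating populations without supervision, measuring pairwise
differentiation, estimating within-cave diversity and effective size, and
inverting an equilibrium migration model. Because the interesting claims
are about *how little* migration is compatible with the data, every stage
is exercised against a forward simulator with known truth.

Two parallel tracks run through the package, mirroring common practice:

* a **hard-call track**, where each genotype is either called (dosage 0,
  1, 2) or missing, and
* a **genotype-likelihood (GL) track**, where each individual contributes
  the likelihood of its three possible genotypes and downstream
  quantities are estimated by EM without ever calling genotypes.

## The island-model simulator

`simulate_island_model()` runs `n_demes` Wright–Fisher demes of constant
diploid size $N$. Each generation, deme frequencies are first mixed
deterministically toward the mean of the other demes,
$p' = (1-m)\,p + m\,\bar p_{\text{others}}$, then resampled binomially
($2N$ draws). Loci are unlinked and there is no mutation by default:
variation enters through ancestral frequencies drawn uniformly from
$[0.05, 0.95]$. These choices keep the equilibrium theory exact enough to
test against:

* the fixation index for two lineages sampled anywhere in the
  metapopulation approaches $1/\bigl(1 + 4Nm\,(d/(d-1))^2\bigr)$
  (`global_fst()` measures this), while
* the mean *pairwise* index approaches $1/\bigl(1 + 4Nm\,d/(d-1)\bigr)$ —
  the two differ by the chance that two random lineages start in the same
  deme, and conflating them is a classic source of "F_ST doesn't match
  theory" confusion.

Default study conditions (4 demes, $N = 500$, 5000 sites, 2000
generations, 10 diploids sampled per deme) reproduce the scale of the
motivating field system: four caves, 6–16 individuals per cave, thousands
of biallelic RAD SNPs, pairwise weighted F_ST in the 0.1–0.55 range and
per-site diversity of order $10^{-4}$–$10^{-3}$. An optional symmetric
`mutation_rate` enables mutation–drift equilibrium runs; the expectation
of heterozygosity then follows a linear recursion that the test suite
uses as an exact oracle.

`simulate_reads()` adds the observation layer: depth is Poisson per
genotype, reads report the alternate base with probability $e$, $1/2$, or
$1-e$ for dosages 0, 1, 2, and the three genotype likelihoods are the
corresponding binomial probabilities. Zero-depth entries are missing.
What the generator deliberately does *not* emulate: linkage between RAD
tags on a locus, mapping and strand artifacts, batch effects in coverage,
and allele-specific error — so a green test suite says the *estimators*
are correct, not that real libraries are free of those artifacts.

## Filtering

The hard-call track masks genotypes below a depth floor (default 2), then
removes sites in a fixed order: non-biallelic/indel/non-diploid records,
call rate below 75%, singletons (minor-allele count exactly 1), and
heterozygote excess. The excess test is the exact conditional
(Wigginton-style) Hardy–Weinberg distribution, one-sided toward excess
only (p < 0.1 removes the site): a RAD locus where everything is
heterozygous is almost always two collapsed paralogs, while heterozygote
*deficits* are expected under population structure and are never
filtered. The rule order cannot change the retained set, only how the
report attributes removals; the report always satisfies
input = retained + sum(removed).

The GL track removes sites seen in fewer than 80% of samples, sites that
fail a SNP likelihood-ratio test at p ≥ 0.05, and sites whose mean
posterior heterozygote fraction (uniform genotype prior) exceeds 50%
(the paralog screen again, likelihood-flavored). The LRT compares the ML
allele frequency against the *better* of the two monomorphic hypotheses
($p=0$ or $p=1$): testing against $p=0$ alone would declare a site fixed
for the alternate allele "polymorphic", which is not what the screen
means.

## Structure

`ibs_distance_matrix()` samples one allele per individual per site
(emulating single-read identity-by-state sampling when no read data are
at hand) and counts mismatches over the $M$ jointly observed sites:
$d_{ij} = \sum_m (1 - I(b_i = b_j)) / M$. Sampling, not averaging,
keeps the distance an unbiased mismatch probability even for
heterozygotes. The matrix feeds average-linkage hierarchical clustering
(linkage is a flag; nothing in the theory prefers one), classical
Torgerson MDS (negative eigenvalues dropped), and BIC selection of the
number of Gaussian mixture components on the 3-axis embedding via
mclust's shared-diagonal ("EEI") family. BIC is reported in the
minimizing convention $-2\log L + k\log n$ (the negative of mclust's);
the selected K is identical either way. Fixing the embedding (3 axes)
and one covariance family keeps selection deterministic and cheap; the
full mclust family search adds nothing for well-separated, roughly
spherical cave clusters.

`admixture_em()` maximizes the standard admixture likelihood — dosage
$g_{ij} \sim \mathrm{Binomial}(2, \sum_k q_{ik} f_{kj})$ — by EM, from
hard calls (missing entries marginalized out) or genotype likelihoods
(genotypes posterior-weighted each iteration, NGSadmix-style). Defaults:
relative log-likelihood tolerance $10^{-6}$, 2000 iterations, 5 restarts
from Dirichlet(1) ancestry rows. Label switching is resolved only at
reporting time (`own_deme_ancestry()` greedily matches components to
populations); the likelihood itself is invariant.

## Differentiation and migration

Three estimators are reported per population pair:

* **Weir–Cockerham θ** from genotype counts, including the
  observed-heterozygosity term, with both the per-site-mean summary
  (matching common VCFtools usage) and the ratio-of-sums summary. The
  two differ systematically — mean-of-ratios is noisier and lower —
  which is why reported "weighted" and "unweighted" F_ST columns in
  surveys of strongly structured taxa disagree so visibly.
* **Reynolds-style A/B components** from sample frequencies:
  $A = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{2n_1-1} - \frac{p_2(1-p_2)}{2n_2-1}$,
  $B = p_1(1-p_2) + p_2(1-p_1)$, with weighted $=\sum A/\sum B$ and
  unweighted $=\overline{A/B}$. This is the Bhatia–Hudson moment form of
  the two-population between/total decomposition; it is unbiased under
  binomial allele sampling, which is what makes the brute-force oracle
  comparison in the tests meaningful.
* **d_XY** $= x(1-y) + (1-x)y$, averaged over SNPs.

`migration_from_fst()` inverts the equilibrium island-model expectation
$E(F_{ST}) = 1/(1+4N_em)$ to $M = 4N_em = 1/F_{ST}-1$ and, given an
effective size, $m = M/(4N_e)$. `migration_report()` uses the mean of the
two populations' $N_e$ for each pair — the model gives no reason to
prefer either end of the pair, and the choice moves $m$ by far less than
the uncertainty in $N_e$ itself.

## Diversity and effective size

Hard-call π sums the small-sample-corrected expected heterozygosity
$h = \frac{n}{n-1}(1-\sum p_i^2)$ over segregating sites and divides by
the number of *interrogated* positions — the denominator is explicit
because it, not the numerator, is where likelihood-based and hard-call π
estimates of the same data diverge by large factors (stricter hard-call
filtering interrogates fewer sites). The per-site $n$ is that site's
non-missing allele count.

The GL track computes, per site, the likelihood of every total
minor-allele count $0..2N$ by dynamic programming over individuals with
hypergeometric composition weights $\prod C(2,g_i)/C(2N,c)$ (missing
individuals enter with flat likelihoods so all sites share one count
axis), folds counts by minor allele (the self-conjugate class $c = N$ is
kept unhalved), estimates the folded SFS by EM across sites (tolerance
$10^{-8}$ on the proportions, 1000 iterations), and reads π off the
count posteriors: the per-site term $c(2N-c)/\binom{2N}{2}$ is exactly
the unbiased $h$ at count $c$, so at high depth the two tracks agree to
numerical precision — a property the acceptance tests exercise at depth
100.

$N_e = \pi/(4\mu)$ uses $\mu = 2.8\times10^{-9}$ by default, a
*Drosophila* estimate borrowed for arthropods whose own rates are
unknown; every output that carries an $N_e$ says so. These values are
order-of-magnitude statements, and the migration bounds inherit that
uncertainty.

## Pipeline, regression and reproducibility

`run_all()` chains the stages and writes one TSV per table plus a Newick
tree and a log with the seeds; identical configurations produce
byte-identical outputs. The diversity–cave-length relationship is fit as
$\pi \sim \log_{10}(\text{length})$ with an optional additive species
term. A model that also includes cave identity alongside cave length is
rank-deficient (cave determines length), so it is not offered.

Problem sizes in the test suite are chosen to keep the full run in
minutes on one core: estimator-vs-oracle checks use exhaustive
enumeration at $N \le 8$ diploids, equilibrium checks use 4 demes ×
5000 sites × 2000 generations with 20 replicates, and the
mutation–drift check uses $\theta = 10^{-3}$ at reduced deme size with
the exact expectation recursion as oracle rather than a larger
simulation.

## Known limitations

* The island model is a stand-in: the real demographic history of cave
  populations (colonization order, bottlenecks, watershed-structured
  connectivity) is unknown, and $m$ from $F_{ST}$ is an equilibrium
  statement, not an inference of recent migration events.
* No linkage: RAD tags are treated as independent; confidence intervals
  that would need block resampling are out of scope.
* The GL track assumes a shared, known error model across individuals;
  real base-quality variation enters only through the likelihoods the
  caller provides.
* Reported $N_e$ scales inversely with an assumed mutation rate.
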