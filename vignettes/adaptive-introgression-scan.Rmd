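---
title: "Detecting adaptive introgression from local ancestry: model and methods"
author: "aiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting adaptive introgression from local ancestry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aiscan)
```

## The problem

After a pulse of admixture, donor-population haplotypes are progressively
broken up by recombination.  Under neutrality the frequency of donor
ancestry stays near the admixture fraction $m$ and ancestry tracts shorten
at a predictable rate; an adaptively introgressed allele instead rises in
frequency and drags long flanking donor tracts with it.  `aiscan` detects
such loci in samples from an admixed population and estimates the
selection coefficient $s$ acting on them, given only a site-by-site table
of allele counts in two unadmixed reference panels plus low-coverage reads
(or genotypes) for the admixed samples, and three demographic inputs
estimated upstream: the effective size $N_e$ of the admixed population,
the admixture fraction $m$, and the time since the pulse $t$ in
generations.

The method is a hidden Markov model along the chromosome.  The hidden
state of a sample of ploidy $n$ at a site is its donor-ancestry dosage
$\{0,\dots,n\}$.  Emissions are the standard local-ancestry-inference
read (or genotype) models and are unaffected by selection; selection
enters only through the transition rates.  For each candidate site and
candidate $s$, the likelihood of the data in a window around the site is
compared with the neutral model, and the resulting log-likelihood-ratio
surface over sites is the scan.

## Ancestry-transition rates

Under the neutral one-pulse model the donor$\to$recipient switching rate
per Morgan is

$$L_{10} = 2 N_e (1-m)\left(1 - e^{-t/2N_e}\right),$$

and detailed balance at stationary frequency $m$ gives
$L_{01} = L_{10}\, m/(1-m)$.  The package exposes these in
`neutral_rates()`.

Selection at a focal site distorts the rates as a function of genetic
distance $r$ from that site.  Two ingredients build the distorted curves:

1. **Allele trajectory.** The selected-allele frequency $x_g$ follows the
   logistic approximation $x_g = m e^{sg} / (1 - m + m e^{sg})$, where
   $s$ is the per-generation, per-copy coefficient: genotype fitnesses
   are $1$, $1+s$, $1+2s$, so a heterozygote experiences half the
   homozygote's advantage.  For very small pulses
   (`stochastic_trajectory()`), the trajectory is instead averaged over
   binomial Wright–Fisher replicates conditioned on the allele surviving
   to sampling, which lifts the early trajectory above the deterministic
   curve.  Frequencies are clipped to $[10^{-9}, 1-10^{-9}]$ before use,
   so near-fixation inputs return finite rates (with a `fixation` flag:
   past fixation $\hat s$ is biased downward, because post-fixation
   generations erode the very tract signal the model reads).

2. **Hitchhiking recursion.** A two-locus recursion tracks
   $a_g(r) = P(\text{marker donor} \mid \text{focal donor})$ and
   $b_g(r) = P(\text{marker donor} \mid \text{focal recipient})$ with
   per-generation Haldane recombination probability
   $c(r) = \tfrac12(1-e^{-2r})$ and mixing toward the marginal
   $q_g = x_g a + (1-x_g) b$.

The donor$\to$recipient hazard is extracted by finite differences of
$-\log a_t(r)$ and folded additively into the neutral rate,
$f_{10}(r) = L_{10} + h_s(r) - h_0(r)$, where $h_0$ is the identical
computation at $s = 0$.  The recursion is driftless, so this fold restores
the $2N_e$ coalescent saturation exactly at $s=0$ and at large $r$, where
both raw hazards vanish; for $s>0$ the curve is clamped into
$[0, L_{10}]$, matching its theoretical monotone approach to the neutral
limit from below.  The recipient$\to$donor hazard is set by *local
detailed balance with the hitchhiked marginal*,
$f_{01}(r) = f_{10}(r)\, q_t(r) / (1 - q_t(r))$: the chain's local
equilibrium at distance $r$ is the selection-elevated donor frequency
$q_t(r)$.  Near a strong sweep $q_t \to x_t \approx 1$ and $f_{01}$ is
very large — a recipient tract almost surely switches to donor within a
short distance — while at $s=0$ it reduces exactly to $L_{01}$.  We
validated the marginal profile $q_t(r)$ against tract simulations (the
package's own forward simulator): with the realized trajectory plugged
in, the maximum absolute deviation of the marginal donor-frequency
profile is a few percent (`tests/testthat/test-transitions.R`).  We chose
this construction over global detailed balance with $m$, which would
wrongly *depress* recipient$\to$donor switching near the sweep.

**Four-point approximation.**  The scan's default backend fits the
parametric form $\hat f(r) = L - k e^{-\alpha r^p}$ per direction, with
$k = L - \hat f(0)$, anchors at $r_2 = 2/L_{10}$ (the neutral tract-length
scale) and $r_1 = r_2/10$, and exponents
$p = \log(y_1/y_2)/\log(r_1/r_2)$, $\alpha = -y_1/r_1^p$ with
$y_i = \log[(L-\hat f(r_i))/k]$.  The three anchor hazards come from the
forward recursion, so the parametric curve interpolates them exactly and
has limit $L$.  Degenerate anchors ($k \approx 0$, no measurable
distortion) return the constant neutral curve.  The alternative
`backend = "forward"` tabulates the folded hazards on a log-spaced grid
(64 points per decade — hazards vary fastest near $r = 0$) and
interpolates; beyond the tabulated range both backends sit at the neutral
limits.  The two backends disagree mid-range (between $r_2$ and
$\sim 3 r_2$) by up to $\sim$10% of $L_{10}$ in near-fixation regimes —
the stretched-exponential family approaches its limit more slowly than
the folded recursion saturates — but the scans they produce give matching
$\hat s$ (tested), which is the operational contract; the four-point
backend is also $\sim$30-fold cheaper.

**Transition matrices.**  For each adjacent site pair at distance $d$ and
midpoint distance $r$ from the focal site, the exact two-state kernel
with rates $(f_{10}(r), f_{01}(r))$ gives single-chromosome switch
probabilities, which are lifted to the dosage chain by assuming
independent chromosomes (binomial convolution).  Rows are stochastic by
construction, so no renormalization is ever required.  The curves are
functions of $|r|$ only; the model is symmetric about the focal site.

## Emissions

In pileup mode the observation at a site is a read pair $(n_A, n_a)$;
each read samples one of the individual's chromosomes uniformly and
reports its allele with error $\varepsilon$ (default 0.01).  Given dosage
$k$, the genotype mixes $\mathrm{Bin}(k, p_1)$ and
$\mathrm{Bin}(n-k, p_0)$ draws from the panel allele frequencies, which
are estimated with a $+1/+2$ pseudocount, $(c_A+1)/(c_A+c_a+2)$ — finite
panels otherwise produce zero-probability emissions (a flag restores raw
frequencies).  Genotype mode conditions on the called dosage directly.
Sites where either panel has no sampled alleles are dropped on input with
a logged count: the mixture is undefined for a missing panel.  Zero-depth
sites have emission 1 in every state, so they never change the
likelihood.  Per-sample chains are independent; the total log-likelihood
sums over samples, which is also how pooled data (one column of ploidy
$n_\text{pool}$) are handled.

The forward pass uses per-site scaling (exact, testable against brute
force path enumeration at small sizes; agreement to $10^{-10}$), with the
dosage-transition construction and the forward kernel implemented in
C++.  Posteriors (`posterior_dosage()`) use the scaled forward–backward
recursion in R; at sequencing depth 2 with moderately divergent panels
the posterior donor frequency at a swept site tracks the *sampled* tract
frequency closely (within $\sim$0.01 in our calibration runs), but can
sit a few percent below 1 when occasional donor haplotypes happen to look
recipient-like over a stretch of sites — an emission-information limit,
not a bias of the chain.

## The scan

For each evaluated site, both the selection and neutral likelihoods are
computed on the same window extending 10% of the chromosome's genetic
length on each side (configurable, or fixed in Morgans).  In `gss` mode,
$s$ is optimized per site by golden-section search on $\log s$ within
[0.001, 0.15] (the explored range of the validation study) to a relative
tolerance of $10^{-2}$; `grid` mode evaluates a user grid of $s$ values.
Windows with fewer than 10 informative sites are flagged and skipped;
window truncation at chromosome ends and boundary maxima of the search
are flagged rather than hidden.  Ties in peak calling go to the leftmost
site (determinism).  Negative selection on donor ancestry is detected by
the label flip (`flip_labels()`): swap the panels and replace $m$ by
$1-m$, then scan for positive selection.

Significance is calibrated exclusively by neutral simulation
(`null_threshold()`): linkage makes per-site analytic cutoffs unreliable,
so the threshold is the smallest LR at which neutral replicate scans
yield at most the targeted number of proximity-filtered false discoveries
per genome (greedy peaks separated by at least 2 cM by default, matching
the separability of adjacent selected sites).

## The simulator

`simulate_admixture()` is a discrete-generation Wright–Fisher simulator
of $N$ diploids (default 10,000) with exact ancestry-tract recording:
meiosis places Poisson($L$) crossovers uniformly (no interference,
sex-averaged map), parents are sampled proportional to fitness, and
selected-locus alleles travel with the segment that covers them, so a
donor allele segregating at 50% at the pulse is supported.  Fitness is
multiplicative across loci with per-locus factors $1, 1+2sh, 1+2s$
($h = 0.5$ additive, 0 recessive, 1 dominant), times a penalty $1+s$
($s<0$) for carriers of incompatible two-locus allele combinations in the
Dobzhansky–Muller scenarios (either any cross-population combination —
dominant sign epistasis — or one specific combination).  Continuous gene
flow after the pulse and conditioning on non-loss (restart up to a retry
cap) are available.  The simulator runs the full $t$ generations by
default and only *flags* replicates whose focal allele crossed 0.99
(early stopping at 0.99 is available via `stop_freq`): sampling at a
stated $t$ is what the validation design requires, and the flag marks the
regime where $\hat s$ is expected to be underestimated.

`synthesize_panels()` stands in for a coalescent simulation of the two
source populations: per site, an ancestral frequency is drawn from a
neutral-SFS-like density ($\propto 1/x$ on [0.05, 0.95]), the two
population frequencies disperse around it by a Balding–Nichols model with
a single divergence parameter (default 0.2, a typical between-population
$F_{ST}$ for recently diverged populations such as African and
cosmopolitan *D. melanogaster*), panels of 100 haplotypes are drawn
binomially, and each sampled chromosome's alleles follow its local
ancestry.  What this emulates is the *marginal ancestry informativeness
per site*; what it does not emulate is linkage disequilibrium within the
reference panels, background selection, or mutation-model detail — so
passing tests show the inference machinery is correct and calibrated
against its own generative assumptions, not that real panels carry the
same information content.  `simulate_reads()` draws Poisson read depth
(mean 2) and per-allele errors (0.01), matching the validation protocol;
pooling merges all chromosomes into one observation column.

## Study conditions and numerical choices

The acceptance experiments (`scripts/acceptance.R` and
`tests/testthat/test-acceptance.R`) rerun the validation study at desk
scale, chosen once: $N = 10{,}000$ diploids (scaled from 100,000), one
1-Morgan chromosome at $10^7$ bp/Morgan, 2,000 sites (10,000 at 1 kb
spacing for the incompatibility scenario, where localization in kb is the
endpoint), 25 diploids at depth 2, error 0.01, 10 replicates per
experiment, 20 neutral replicates for threshold calibration, and
golden-section scans with stride 10 (every 100th site for pooled data,
as in the original protocol).  The incompatibility scenario samples at
$t = 200$: mid-range of the validated sampling times, late enough for
the incompatibility to have swept one ancestry to high frequency at the
interacting loci.  At a 50% pulse the direction of that sweep is decided
by drift per replicate, so the analysis scans both label orientations
and keeps the higher-likelihood one — a data-driven choice that uses no
simulator truth.

Numerical details worth knowing: golden-section search assumes a
unimodal LR in $s$ (non-finite evaluations shrink the bracket); the
finite-difference step for anchor hazards is $r_1/20$ (grid hazards use
$\max(0.05 r, 10^{-4} r_2)$); four-point fits guard degenerate or
non-monotone anchors by falling back to $p = 1$ or the constant curve;
dosage lifts assume exchangeable, independent chromosomes within a
sample.  Known limitations: one admixture pulse only (no multi-pulse
theory), no background-selection model, $\hat s$ is biased downward once
the allele fixes well before sampling, localization precision at
$N = 10{,}000$ is drift-limited (tract boundaries wander tens of kb
around weakly selected loci, an order of magnitude more than at the
original study's $N = 100{,}000$), and $m$-misspecification moves
$\hat s$ more than $t$- or $N_e$-misspecification.
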