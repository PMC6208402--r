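---
title: "Methods: Pool-seq landscape genomics of adaptation to metalliferous soils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Pool-seq landscape genomics of adaptation to metalliferous soils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis in one paragraph

`poolscape` goes from pooled whole-genome variant calls of plant populations
on metalliferous (M) and non-metalliferous (NM) soils to a ranked list of
candidate adaptation genes. Pools of individuals are sequenced together, so
the observable per population is a pair of read counts (reference,
alternate) per SNP rather than genotypes. The pipeline filters variant
records, estimates pooled allele frequencies, finds the soil variables that
discriminate M from NM sites, tests every SNP for association with each of
those variables under a latent-factor model that absorbs neutral population
structure, cross-validates the hits with a covariance-corrected rank
statistic, computes per-gene diversity statistics (segregating sites S,
nucleotide diversity &pi;, Watterson's &theta;~W~, Tajima's D), tests gene
sets for a polygenic enrichment of association evidence, and finally reports
genes that are (i) associated, (ii) members of an enriched pathway and
(iii) carry a selective-sweep signature (strongly negative Tajima's D) in at
least one metallicolous population.

## Pooled data model

For pool $j$ with $N$ chromosomes (default $N = 60$: 30 diploids) and true
alternate-allele frequency $p_{ij}$ at SNP $i$, the generator and all
variance reasoning use the double-binomial Pool-seq model: read depth
$d_{ij} \sim \mathrm{Poisson}(\bar d)$ (at least 1), chromosome sample
$k \sim \mathrm{Binomial}(N, p_{ij})$, alternate reads
$a_{ij} \sim \mathrm{Binomial}(d_{ij}, k/N)$. The frequency estimator is
$\hat p_{ij} = a_{ij}/d_{ij}$ with variance
$p(1-p)\,(1/N + (1-1/N)/\bar d)$ — the extra $1/N$ term is the
pool-sampling stage that distinguishes Pool-seq from simple read binomials,
and the generator is tested against this closed form.

## Variant filtering

The canonical post-calling cascade retains a record only if it passes every
rule, testing rules in a fixed order so each removed record is attributed to
its first failing rule: site quality > 30 (PHRED), mapping quality > 40,
total depth < 1200, per-pool depth > 60 (one read per chromosome), site
quality / total depth > 0.25, no missing pool data, total alternate
observation count within [4, 236], bi-allelic records only, and no
non-variant sites. The quality/depth/ratio bounds are strict inequalities,
following the usual phrasing of such filter sets; the alternate-count bounds
are inclusive. For designs other than 4 pools at ~150x, `scaled_thresholds()`
rescales the depth-dependent bounds (total depth below twice the expected
total; alternate bounds 4 and mirror) while keeping the quality rules fixed.
Multi-allelic records are read and flagged rather than rejected at parse
time, and are removed here, not in the parser.

## Environmental association with latent factors

Per environmental variable $x$ (standardized; the binary Site-type is used
as its 0/1 coding), the model per SNP is

$$ y = \mu + x\beta + U V^\top + \varepsilon $$

with $U$ an $n \times K$ latent-factor matrix absorbing neutral structure.
Estimation alternates a rank-$K$ truncated SVD of the residual matrix with
per-SNP ridge regression of the latent-adjusted frequencies on $x$, to
convergence of $\max|\Delta\beta| < 10^{-6}$ (cap 100 sweeps), repeated from
12 random initializations; per-SNP statistics are combined as the median
over restarts, mirroring the multi-run median-z protocol of Bayesian LFMM
implementations while remaining deterministic given the seed.

**Why ridge/ALS rather than MCMC.** The MCMC sampler behind the original
LFMM protocol (12 runs, 5,000 burn-in + 10,000 cycles) is replaced by this
deterministic alternating solver with random restarts: the protocol shape
(multiple runs, median combination, genomic-control correction) is
preserved at a fraction of the cost, and results are exactly reproducible.

**z-score calibration.** The per-SNP t ratio ($\hat\beta$ over its standard
error at $n - K - 2$ residual degrees of freedom) is not t-distributed in
pooled data: binomial sampling noise is bounded and, at rare alleles,
nearly discrete, so its shape varies strongly with allele frequency and no
single inflation factor or fixed-df reference calibrates it. The package
therefore uses a stratified semi-parametric empirical null, in the spirit
of Efron's empirical-null estimation: SNPs are stratified by folded mean
frequency (8 strata); within a stratum the bulk of the |t| distribution
(to its 95th percentile) is mapped onto the standard-normal scale by
mid-ranks — the overwhelming majority of SNPs are null, so the genome-wide
distribution estimates the null itself — while beyond the body a scaled-t
reference extrapolates the extreme quantiles, its scale and degrees of
freedom fitted to the stratum's 75th/90th percentiles (robust to a few
percent of genuine signals) and its df bounded below by the nominal
$n-K-2$ (the tail is never assumed heavier than the regression model
implies). The pre-calibration t statistics are kept in the output, and
`calibrate = FALSE` restores the plain $t_{n-K-2}$ map.

Downstream, the genomic inflation factor
$\lambda = \mathrm{median}(z^2)/0.4549$, the correction
$P = \Pr(\chi^2_1 > z^2/\lambda)$, Benjamini–Hochberg q-values and the 1%
FDR threshold follow the standard genomic-control protocol exactly. With
the empirical-null z-scores, $\lambda$ sits at 1 under the null by
construction and the correction is a no-op there; it remains in the
pipeline both as a guard (it corrects any residual scale error, e.g. under
model misspecification) and because the K-selection rule reads it.

**Choosing K.** Candidate latent dimensions K = 2–4 are each fitted and
`choose_latent_count()` picks the K whose λ is closest to 1 from above
(reducing to "smallest λ" when all exceed 1, the usual situation for
uncalibrated z-scores). With 4 pools and K = 3 the model has no residual
degrees of freedom; the association stage refuses K > n − 3, which is why
association analyses in this package run on designs with 12 or more pools.

## Cross-validation with a covariance-corrected statistic

As an independent check of the association hits, a pool-by-pool covariance
matrix $\Omega$ of standardized frequencies
$x_i = (p_i - \bar p_i)/\sqrt{\bar p_i(1-\bar p_i)}$ is estimated from a
random 20% SNP subset (moment estimator; fixed SNPs excluded). Both the
standardized frequencies and the standardized environmental vector are
whitened with the inverse Cholesky factor of $\Omega + 10^{-8}I$, and the
per-SNP statistic is $Z = 0.5\,|\rho_s|$ with $\rho_s$ the Spearman rank
correlation of the whitened vectors, so $Z \in [0, 0.5]$ and 0.5 indicates
a perfect monotone environmental relationship after removing shared
structure. Association-significant SNPs are compared with a random
non-significant SNP set (the desk-scale analogue of a 12,000-SNP control)
by KS statistic, median difference, and a 20-bin histogram overlap
coefficient.

## Per-gene diversity

Pooled frequencies are mapped to chromosome counts
$k = \mathrm{round}(\hat p N)$ (round-half-even; sub-resolution variants
become invariant and leave S). Per gene and pool: S counts sites with
$0 < k < N$; $\pi = \sum_\mathrm{sites} 2k(N-k)/(N(N-1))$;
$\theta_W = S/a_1$; $D = (\pi - \theta_W)/\sqrt{e_1 S + e_2 S(S-1)}$ with
the classical constants, undefined at S = 0. All quantities are invariant
under swapping derived/ancestral labels. Genome-wide mid-rank percentiles
of D are computed per pool over genes with defined D. A read-depth-aware
&pi; estimator (factors $N/(N-1)\cdot d/(d-1)$ on $2\hat p(1-\hat p)$) is
available behind `estimator = "read_counts"`, default off: plain rounded
counts match the way per-gene Tajima's D is conventionally reported.

## Polygenic enrichment

Each gene is scored by the maximum |z| over its SNPs (all SNPs, not only
significant ones). Because a maximum grows with the number of draws, raw
scores are standardized within SNP-count decile bins — a bias adjustment
verified by simulation (adjusted scores are uncorrelated with SNP count
under the null). A gene set's SUMSTAT is the sum of its members' adjusted
scores; its empirical P value compares it with `n_perm` random same-size
sets drawn from all scored genes, with the $(1+\#\{ \text{null} \ge
\text{obs}\})/(n_\mathrm{perm}+1)$ convention, and Q values are
Benjamini–Hochberg. Pruning then iteratively accepts the lowest-P set with
Q ≤ 10%, removes its genes from the remaining sets and re-tests, so a
pathway cannot appear enriched merely through genes it shares with an
already-accepted pathway.

## Candidate cascade

Genes with at least one significant SNP form one list per variable. The
soil-variable lists (the five designated discriminators) are intersected;
the union of that overlap with the Site-type list, restricted to members of
accepted pathways, is the candidate set, each gene tagged with its pathway
and source. A candidate is a *strong* candidate when its Tajima's D is
negative in at least one metallicolous pool with a genome-wide percentile
at or below 0.01 — the cutoff is inferred from the reference analysis,
where all reported sweep percentiles are ≤ 0.0016, and is configurable.
Variant effects for candidate SNPs are classified SnpEff-style by codon
translation on either strand (synonymous/low, missense/moderate with an
amino-acid change string such as I138L, stop gained/lost/high, UTR, intron,
intergenic as modifier), and verified in tests against an independent
full-CDS-translation oracle.

## The synthetic-data generator

The generator is first-class, tested code that produces data with the
statistical structure the analysis assumes, plus a ground-truth table for
recovery tests.

* **Design.** Default desk scale: 12 pools of 60 chromosomes in three
  genetic clusters, each cluster holding 2 M and 2 NM pools; 10,000
  bi-allelic SNPs over 500 genes on 10 scaffolds; 20 disjoint pathways of
  10 genes. The 4-pool field layout (two M pools forming one cluster, each
  NM pool its own) is available via `sim_params_paper()` and is used for
  structure and diversity checks; association tests need the residual
  degrees of freedom of the larger design. The balanced cluster/site-type
  layout at desk scale deliberately separates environmental signal from
  neutral structure, so recovery statistics measure association power
  rather than confounding.
* **Environment.** 16 soil and 15 bioclimatic variables; the five
  designated soil variables (total Cd; extractable K, Mg, Pb, Zn) are
  shifted six within-type standard deviations between site types (K
  downward, the others upward), reflecting the orders-of-magnitude
  M/NM contrasts measured on real metalliferous soils. Replicate topsoil
  measurements (3 per site, SD 0.5) feed the ANOVA-based discrimination
  test.
* **Frequencies.** Ancestral frequencies follow a rare-enriched spectrum
  with density ∝ $p^{-2}$ on $[1/N, 1-1/N]$. The idealized neutral
  spectrum (∝ $1/p$) would be correct for directly observed counts, but
  drift, pool sampling, finite depth and rounding absorb much of the rare
  class into the invariant class; the exponent was calibrated once so that
  the *observed* drift-only spectrum is neutral-like (gene-level Tajima's D
  centred near zero, matching the slightly positive genome-wide medians of
  natural populations) and is also what recent population expansion
  produces. Pool frequencies then arise by two Balding–Nichols stages
  (between clusters, F = 0.1; within, F = 0.05).
* **Adaptive loci.** 1% of SNPs (default), 70% of them inside the first
  ("adaptive") pathway's genes, draw ancestral frequencies from
  Uniform(0.05, 0.95) — selection acts on standing variation at usable
  frequencies — and shift each pool's frequency on the logit scale by
  $\beta$ × the standardized driving variable (Site-type or one designated
  soil variable). The default $\beta = 2$ reproduces the near-fixed
  contrast reported for real adaptive variants (alternate allele > 0.9 in
  M pools, absent or rare in NM pools).
* **Sweeps.** Five genes among the adaptive pathway's genes receive a
  selective-sweep signature in the M pools: with probability 0.8 per site
  and pool, the minor-allele count is redrawn to at most 2 chromosomes.
  The swept haplotype is shared across the affected pools, so the
  near-fixed side is common to them: the beneficial allele at adaptive
  sites, a random side at hitchhiking sites (hitchhiking direction is
  haplotype-determined, not frequency-determined).
* **What it does not emulate.** No coalescent or forward simulation, no
  recombination or linkage beyond the gene-level sweep skew, no indels, no
  reference bias or mapping artefacts. Passing recovery tests therefore
  demonstrates the statistical machinery under the stated noise model, not
  performance on any particular real dataset.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; conversion
  happens only in readers/writers (GFF3 and VCF are 1-based on disk).
* All randomness flows from one integer seed through a deterministic
  splitting scheme (`stage -> sub-seed`), so each stage is independently
  reproducible.
* The ridge penalty on the per-SNP regression is $10^{-8}$ — numerically
  stabilizing, statistically negligible (the K = 0 path agrees with
  ordinary least squares to $10^{-8}$ on the t scale).
* PCA component signs are fixed by making each component's
  largest-magnitude loading positive.
* Box–Cox exponents maximize the profile log-likelihood on the grid
  [−5, 5] step 0.01; assumption checks (Shapiro–Wilk, Breusch–Pagan) use
  α = 0.05.
* The soil-variable selection rule adds a consistent-direction condition
  (every M site mean on the same side of every NM site mean) to the ANOVA
  P < 0.001 rule, since a 4-level site ANOVA alone does not encode the
  M-vs-NM contrast.
* Empirical P values never return 0 (+1 smoothing); BH is used wherever an
  FDR is unspecified.
* Genes with S = 0 are excluded from percentile denominators; SNPs in two
  overlapping genes count for both.
* Test problem sizes: unit tests run 2,000–6,000 SNP scenarios; the
  calibration and end-to-end acceptance checks use the full 10,000-SNP
  default design.

## Known limitations

* With 4 pools the association model is unusable at K ≥ 2 (no residual
  df); the 4-pool layout is supported for structure and diversity only.
* The empirical-null calibration needs a few hundred SNPs per stratum;
  below ~500 SNPs it falls back to a single stratum, below 50 to the
  nominal t map.
* The cross-validation Z statistic is a rank correlation over n pools, so
  its null mean depends on n (about 0.23 at 4 pools, 0.12 at 12); the
  comparison of significant vs random sets is calibrated against the same
  design and is not comparable across designs.
* The depth-aware diversity estimator corrects the mean of &pi; but not
  the variance of D; for small S both estimators are noisy.
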