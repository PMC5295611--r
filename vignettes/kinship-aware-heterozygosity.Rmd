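---
title: "Kinship-aware estimation of gene diversity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship-aware estimation of gene diversity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinhet)
```

## The problem

Gene diversity, or expected heterozygosity, of a locus with allele
frequencies $p_1, \dots, p_I$ is

$$H = 1 - \sum_{i=1}^I p_i^2,$$

the probability that two allele copies drawn at random from the population
differ.  The classical estimator
$\hat H = \frac{n}{n-1}\bigl(1 - \sum_i \hat p_i^2\bigr)$ (with $n$ the
number of allele copies and $\hat p_i$ the sample proportions) is unbiased
only when all sampled allele copies are independent.  Samples from natural
populations, breeding programs, or small isolated groups routinely contain
relatives and inbred individuals; every identical-by-descent (IBD) allele
pair inflates the apparent homozygosity, and $\hat H$ underestimates $H$ by
an amount that grows with both the relatedness of the sample and the
diversity of the locus.

kinhet implements a family of estimators that remain unbiased for samples
of **any** ploidy, relatedness and inbreeding, given pedigree-derived
kinship coefficients.

## The estimator family

Let $X_k^{(i)}$ be the fraction of individual $k$'s $m_k$ allele copies
that are of type $i$.  Any weight vector $w$ with $\sum_k w_k = 1$ yields
an unbiased linear frequency estimator
$\breve p_i = \sum_k w_k X_k^{(i)}$, and

$$\breve H = \frac{1 - \sum_i \breve p_i^2}{1 - \rho_2}, \qquad
  \rho_2 = \sum_{j}\sum_{k} w_j w_k \Phi_{jk},$$

is an unbiased estimator of $H$, where $\Phi_{jk}$ is the kinship
coefficient (the probability that one allele drawn from $j$ and one from
$k$ are IBD; $\Phi_{kk}$ is the with-replacement self-kinship).  Two
specializations matter in practice:

* `h_tilde()` — allele-copy weights $w_k = m_k/\sum_j m_j$, so
  $\breve p = \hat p$ and $\rho_2 = \bar\Phi_2$, the allele-copy-weighted
  mean kinship of the sample.
* `h_blue()` — weights from the best linear unbiased estimator (BLUE) of
  allele frequency, $w_k \propto \sum_j (K^{-1})_{jk}$ for the sample
  kinship matrix $K$.  These weights minimise the frequency-estimate
  variance among linear unbiased estimators, and the gain propagates to the
  heterozygosity estimate; the matching correction uses
  $\kappa_2 = w' K w$.

On unrelated, outbred samples of any ploidy mix both reduce exactly to
$\hat H$ (then $\bar\Phi_2 = 1/\sum_k m_k$).  On samples containing a
single relative-pair type the two are identical by exchangeability; they
diverge — in favour of the BLUE version — as the mixture of pair types, and
hence the asymmetry of the optimal weights, grows.  BLUE weights can be
negative for some kinship configurations; frequency estimates are then
reported as computed (possibly outside $[0,1]$) with a flag rather than
clipped, which is what keeps the estimator unbiased.

The bias of the classical estimator on a related sample is available in
closed form (`bias_h_hat()`):

$$\mathrm{Bias}[\hat H] = \frac{1 - n\rho_2}{n-1}\,H,$$

vanishing exactly at $\rho_2 = 1/n$.  We read $n$ here as the number of
**allele copies**, not individuals: with that reading the bias is zero for
unrelated outbred samples of arbitrary ploidy mix, and the general
correction collapses to the classical one, which is not true under the
individuals reading for diploids.

## Variance theory

The exact variance of any member of the family is a polynomial in
$\sum_i p_i^2$ and $\sum_i p_i^3$ whose coefficients are the weighted mean
kinship coefficients of sample *pairs*, *trios*, *quartets* and
*pairs-of-pairs* ($\rho_2, \rho_3, \rho_4, \rho_{2,2}$); see
`variance_exact()`.  For samples in which no individual is related to more
than one other, the higher-order coefficients are $O(\rho_2^2)$ and

$$\mathrm{Var}[\breve H] \approx
  \frac{4\rho_2}{(1-\rho_2)^2}\Bigl[\sum_i p_i^3 -
  \bigl(\sum_i p_i^2\bigr)^2\Bigr]$$

(`variance_approx()`).  Two numerical remarks.  First, the bracket
vanishes identically for any *uniform* spectrum (e.g. ten alleles at 0.1
each), where $\sum p^3 = (\sum p^2)^2$; the approximation is uninformative
there while the exact polynomial is not, so comparisons between the two are
made at non-uniform spectra.  Second, on a design of 30 same-type pairs the
relative disagreement between the exact and approximate forms is about 3%;
the package's own check uses a 5% band.

Higher-order coefficients for arbitrary pedigrees are obtained by
gene-dropping Monte Carlo rather than condensed-identity-state algebra: the
founders' allele copies receive unique labels, labels are transmitted by
Mendelian (or X-linked) rules, and IBD probabilities are read off the
realized label fractions.  The estimates are Rao-Blackwellized — per
replicate we compute the *exact* conditional matching probability of
independent draws, i.e. the power sums $\sum_\ell v_\ell^r$ of the weighted
label frequencies — which shrinks the Monte Carlo error dramatically at no
extra cost.  Repeated indices in tuple coefficients (e.g. $\Phi_{jkj}$) are
resolved as independent draws with replacement from the same individual;
that convention is what makes $\rho_2 = w'Kw$ with the self-kinship
diagonal, and it is applied consistently everywhere.

For multi-family designs the sums decompose: alleles in different families
are never IBD, so $\rho_3$ and $\rho_4$ are sums of within-family moments
and $\rho_{2,2}$ couples families only through products of their exact
pairwise terms (`design_mean_kinship()`).  This makes the exact variance of
a 60-individual design computable from per-template drops of at most six
individuals.

## Kinship machinery

`kinship_pair()` implements the standard pedigree recursion, with founders
mutually unrelated and non-inbred: for $j$ not an ancestor of $k$,
$\Phi_{jk} = \tfrac12(\Phi_{f(j),k} + \Phi_{m(j),k})$ and
$\Phi_{jj} = \tfrac12(1 + F_j)$, $F_j$ the kinship of $j$'s parents.  At an
X-linked locus males are hemizygous: they carry one allele ($m = 1$),
transmit their single X to daughters only, and have self-kinship 1; a
non-founder male's kinship recursion passes through his mother alone.  This
yields the textbook X-linked full-sibling values $1/2$ (brother–brother),
$1/4$ (brother–sister) and $3/8$ (sister–sister).

The kinship-matrix diagonal uses the ploidy-general self-kinship
$(1 + (m_k - 1) f_k)/m_k$ — the probability that two draws *with
replacement* from individual $k$ are IBD.  It reduces to $(1+f)/2$ for
diploids and to 1 for haploids, and it is the convention under which BLUE
weights reproduce allele-copy weighting for unrelated samples of mixed
ploidy.  Relatedness among founders can only be injected through a
user-supplied kinship matrix; the package never estimates kinship from
genotypes (pedigrees, or a kinship TSV, are taken as known).

## Population differentiation

With between-population heterozygosity
$\breve H_{12} = 1 - \sum_i \breve p_i \breve q_i$, the differentiation
statistic is

$$\breve F_{ST} = \frac{\breve H_{12} - \tfrac12(\breve H_1 + \breve H_2)}
 {\breve H_{12}},$$

computable from any of the estimator families (`fst_from_het()`).  Because
the classical components are biased *downward* by relatedness, the ratio is
biased *upward*; the corrected families remove this.  The delta-method
variance (`fst_variance_approx()`) uses the theoretical within-population
variances and estimates $\mathrm{Var}[\breve H_{12}]$ and the
$\mathrm{Cov}[\breve H_{12}, \breve H_\cdot]$ terms by seeded gene-drop
Monte Carlo: their closed forms are long, gain no accuracy, and the Monte
Carlo estimates are exact in expectation under the same model.  Sampling is
independent across populations, so cross-population covariances are zero by
construction.  Locus-specific branch lengths (`lsbl()`) place three
populations on an unrooted tree with $L_1 = (f_{12}+f_{13}-f_{23})/2$ and
cyclic permutations, so $L_i + L_j = f_{ij}$ exactly; negative branch
lengths are reported as computed.

Multi-locus aggregation, when wanted, is ratio-of-averages (mean numerator
over mean denominator across loci), with per-locus values always exposed;
this is a documented package choice, as reasonable alternatives (e.g.
averaging per-locus ratios) exist.

## The range-normalized diversity B

Given the allele count $I$ and the largest allele frequency $M$, the
attainable heterozygosity range follows from majorization: the maximum
spreads the residual mass $1 - M$ evenly over the other $I-1$ alleles; the
minimum concentrates it into as few alleles as possible subject to each
frequency being at most $M$ (`het_bounds()`, validated against brute-force
search over discretized simplices for $I \le 4$).  `normalized_het_B()`
returns $B = (H_{obs} - H_{min})/(H_{max} - H_{min}) \in [0,1]$.  For
biallelic loci $M$ fixes the whole spectrum, the range degenerates to a
point and the statistic is undefined; this is signalled as an error rather
than returned as 0/0.

## The synthetic-data generator

Every catalogued relative-pair type is realized by a small template
pedigree (grandparents → brother–sister parents → two offspring for inbred
full siblings, and so on).  `gene_drop_sample()` draws founder alleles
i.i.d. from a parametric spectrum and transmits them through the template,
so the simulated genotypes carry *exactly* the IBD structure of the
pedigree — including within-individual IBD for inbred designs and
hemizygosity for X-linked ones.  The lighter allele-copying generator
(`simulate_relative()`) reproduces the classical two-gene sharing
distributions — $(0,1,0)$ parent–offspring, $(\tfrac14,\tfrac12,\tfrac14)$
full siblings, $(\tfrac12,\tfrac12,0)$ avuncular — and is provably
equivalent to gene-dropping for outbred autosomal pairs, but it cannot
express inbred or X-linked identity-state structure, so those types always
route through the pedigree drop.

The two mechanisms differ in one consequential way.  Under allele copying
every individual is marginally in Hardy–Weinberg proportions; under a
sib-mating pedigree drop the offspring are genuinely inbred ($f = 1/4$).
Removing one member of each pair (`h_hat_reduced()`) then cures
relatedness but *not* inbreeding: the reduced sample of a design with
inbred pairs retains a small downward bias,
$(1 - n\rho_2^{red})(n-1)^{-1} H$ with $\rho_2^{red}$ the mean kinship of
the retained (unrelated but partly inbred) set — about $-0.0014\,H$ for
the 60-individual mixed design used throughout.  The corrected estimators
are immune because their kinship matrices carry the inbreeding on the
diagonal.  Passing unbiasedness checks under this generator therefore says
more than the copy-method equivalent would; conversely the reduced-sample
estimator is only asserted unbiased on outbred designs.

What the generator does **not** emulate: mutation, genotyping error,
null alleles, missing-data patterns, linkage between loci, relatedness
among founders, or uncertainty in the pedigree itself (all kinship
matrices are taken as exactly known — misreported pedigrees degrade the
BLUE weights first, since they sharpen the inverse-kinship contrast).
Conclusions from simulations here are about estimator properties under a
correct kinship model, not about robustness to kinship misspecification.

## Experiment sizes, seeds and numerical choices

* Default experiment sizes: $10^4$ replicates for replicate-mean (bias)
  checks, $10^5$ for variance checks, $2\times10^5$ gene-drop replicates
  for higher-order coefficients, $10^3$ for paired-population FST
  experiments.  These give Monte Carlo standard errors one to two orders
  of magnitude below the effects being measured while keeping any single
  check within seconds.
* All randomness flows through explicit integer seeds; composite
  experiments derive per-component sub-seeds with `derive_seeds()`
  (`set.seed` + `sample.int`), so a master seed reproduces everything
  bit-for-bit.  R's built-in generator is used deliberately: it is the
  idiom of R simulation code and offers the same reproducibility a
  counter-based generator would.
* Kinship matrices are rejected (not pseudo-inverted) when the reciprocal
  condition number falls below $10^{-12}$: BLUE weights are defined only
  for invertible $K$, and silently regularizing would trade an error
  message for a silently biased estimate.
* Weight vectors must sum to 1 within $10^{-12}$; $\rho_2 \ge 1$ (e.g. a
  sample of one haploid) is rejected rather than returning an infinite
  correction.
* Estimates are never clipped to $[0,1]$; an unbiased estimator must be
  allowed to leave the parametric range on individual replicates, and a
  flag marks such values.
* Individuals with any missing allele call at a locus are dropped from
  that locus, and all weights (including BLUE weights, via the matching
  principal submatrix of $K$) are recomputed on the retained set.

## Known limitations

* Autosomal kinship recursion assumes diploid meiosis; polyploid
  individuals are supported in the estimators (via $m_k$ and a supplied
  kinship matrix) but pedigree-derived kinship for polyploid transmission
  is not implemented.
* Exact condensed-identity-state coefficients for arbitrary pedigrees are
  not computed analytically; gene-dropping Monte Carlo (with
  Rao-Blackwellization) stands in, with the two-generation enumeration
  oracle in the test suite guarding its correctness.
* Kinship is never inferred from genotype data; relative-pair
  misclassification is out of scope.
* The FST variance is a first-order delta approximation around the
  parametric components; for weakly differentiated pairs its linearization
  error is visible (the package's own self-consistency check allows 15%),
  and it should be read as a scale, not a confidence interval.
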