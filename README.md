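# kinhet

Unbiased estimation of gene diversity (expected heterozygosity) for samples
that contain **related and inbred individuals of any ploidy**, with a
lower-variance variant built on the best linear unbiased estimator (BLUE) of
allele frequencies — plus the pedigree-kinship, variance-theory, FST/LSBL
and simulation machinery around it.

## Who this is for

Population geneticists estimating diversity or differentiation from samples
where relatives are unavoidable: small or isolated populations, pedigreed
breeding material, social insects and other mixed-ploidy systems, X-linked
loci (hemizygous males), or any dataset where relative pairs have been
identified and would otherwise have to be discarded.

## The statistics

For a locus with allele frequencies $p_i$, gene diversity is
$H = 1 - \sum_i p_i^2$.  The classical estimator
$\hat H = \frac{n}{n-1}(1 - \sum_i \hat p_i^2)$ ($n$ allele copies) is
downward-biased when sampled allele copies are identical by descent (IBD).
With per-individual weights $w$ summing to 1, the general corrected
estimator is

$$\breve H = \frac{1 - \sum_i \breve p_i^2}{1 - \rho_2},
\qquad \breve p_i = \sum_k w_k X_k^{(i)},
\qquad \rho_2 = \sum_{j,k} w_j w_k \Phi_{jk},$$

where $\Phi_{jk}$ is the kinship coefficient and $X_k^{(i)}$ the fraction
of individual $k$'s alleles of type $i$.  Allele-copy weights give the
kinship-corrected estimator $\tilde H$ (`h_tilde()`); inverse-kinship
(BLUE) weights $w_k \propto \sum_j (K^{-1})_{jk}$ give $\tilde H_{BLUE}$
(`h_blue()`), which has the smallest frequency-estimate variance among
linear unbiased estimators and hence typically the smallest MSE of the
family.  The package also provides the reduced-sample estimator
(`h_hat_reduced()`), the closed-form bias of $\hat H$ (`bias_h_hat()`),
exact and approximate estimator variances (`variance_exact()`,
`variance_approx()`),
$F_{ST} = [H_{12} - \tfrac12(H_1 + H_2)]/H_{12}$ under any estimator
family with a delta-method variance (`fst_from_het()`,
`fst_variance_approx()`), and locus-specific branch lengths (`lsbl()`).

Kinship comes from pedigrees by the standard recursion — autosomal and
X-linked (`kinship_pair()`, `kinship_matrix()`) — and higher-order IBD
coefficients by Rao-Blackwellized gene-dropping Monte Carlo
(`gene_drop_identity_coeffs()`, `design_mean_kinship()`).

## Worked example

```r
library(kinhet)

ped  <- read_ped(system.file("extdata", "toy.ped", package = "kinhet"))
loci <- read_genotypes(system.file("extdata", "toy_genotypes.tsv",
                                   package = "kinhet"))
K <- kinship_matrix(ped, loci$locA$ids)

h_hat(loci$locA)    # classical, biased here (full sibs C1, C2 in sample)
#> Expected heterozygosity (h_hat_full): 0.530303  [correction 1.09091]
h_tilde(loci$locA, K)
#> Expected heterozygosity (h_tilde): 0.57377  [correction 1.18033]
h_blue(loci$locA, K)
#> Expected heterozygosity (h_blue): 0.571429  [correction 1.14286]
```

The corrected estimators raise the estimate because four of the twelve
allele copies come from one sib pair and the parents of that pair: the
sample carries fewer independent copies than its size suggests, so the
observed homozygosity overstates the population's.  The two corrections
differ because the BLUE reweights the unrelated individuals upward.

A bias/variance/MSE experiment on the 60-individual design (10 inbred
full-sib, 10 outbred full-sib, 10 avuncular pairs) at a 10-allele locus
with $H = 0.8452$:

```r
sp <- locus_spectrum(c(.25, .20, .15, .12, .08, .06, .05, .04, .03, .02))
design <- list(pair_spec("full_sib_inbred_sibmating", 10),
               pair_spec("full_sib_outbred", 10),
               pair_spec("avuncular", 10))
run_experiment(design, sp, reps = 10000, seed = 1)
#> Estimator experiment: 10000 replicates, true H = 0.8452
#>   estimator     mean       bias  variance       mse  se_mean   se_var   se_mse
#>  h_hat_full 0.840998 -4.202e-03 0.0003482 0.0003658 0.000187 5.95e-06 6.71e-06
#>   h_hat_red 0.844097 -1.103e-03 0.0004994 0.0005007 0.000223 8.73e-06 8.95e-06
#>     h_tilde 0.845141 -5.894e-05 0.0003516 0.0003516 0.000188 6.01e-06 6.02e-06
#>      h_blue 0.845148 -5.245e-05 0.0003376 0.0003376 0.000184 5.61e-06 5.61e-06
```

The classical estimator is biased by almost exactly its predicted
$(1 - n\rho_2)H/(n-1) = -0.0041$; the kinship-corrected estimators are
unbiased, and the BLUE variant has the smallest MSE.

## Command line

A thin CLI over the same functions ships in `inst/cli/kinhet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "kinhet.R", package = "kinhet"))')" \
  het --genotypes geno.tsv --kinship kin.tsv --estimator blue
```

Subcommands: `kinship`, `het`, `fst`, `lsbl`, `simulate`.  Output is TSV
with a commented `# key=value` metadata header; all stochastic commands
take `--seed`.

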