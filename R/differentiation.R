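# Population differentiation: FST from heterozygosities, its delta-method
# variance with Monte Carlo covariance terms, and locus-specific branch
# lengths.

#' Between-population heterozygosity
#'
#' \eqn{\breve H_{12} = 1 - \sum_i \breve p_i \breve q_i}, the probability
#' that one allele drawn from each of two populations differ.  Frequency
#' estimates are harmonized to the union of the two allele sets (absent
#' alleles at frequency 0); unnamed estimates of unequal length cannot be
#' harmonized and raise an error.
#'
#' @param freq1,freq2 [linear_estimate()] results (or plain named frequency
#'   vectors) for populations 1 and 2.
#' @return Numeric value.
#' @examples
#' between_heterozygosity(c(A = 0.9, B = 0.1), c(A = 0.5, B = 0.5))  # 0.5
#' @export
between_heterozygosity <- function(freq1, freq2) {
  p <- if (inherits(freq1, "frequency_estimate")) freq1$freq else freq1
  q <- if (inherits(freq2, "frequency_estimate")) freq2$freq else freq2
  if (is.null(names(p)) || is.null(names(q))) {
    if (length(p) != length(q)) {
      stop("allele sets are not harmonized: unnamed frequency vectors of unequal length")
    }
  } else {
    universe <- union(names(p), names(q))
    fill <- function(x) { y <- stats::setNames(numeric(length(universe)), universe)
                          y[names(x)] <- x; y }
    p <- fill(p); q <- fill(q)
  }
  1 - sum(p * q)
}

#' FST from within- and between-population heterozygosities
#'
#' \deqn{F_{ST} = \frac{H_{12} - \frac{1}{2}(H_1 + H_2)}{H_{12}}.}
#' With classical full-sample components this is the Hudson-style estimator;
#' substituting the kinship-corrected or BLUE-based heterozygosities yields
#' the corresponding corrected FST.  Negative estimates are reported as
#' computed, not truncated.
#'
#' @param H1,H2 Within-population expected heterozygosities (values or
#'   `diversity_estimate` objects).
#' @param H12 Between-population heterozygosity (> 0).
#' @param estimator Tag recorded in the result (e.g. `"fst_blue"`).
#' @return An object of class `pairwise_fst`: list with `value`, the three
#'   components, and the tag.
#' @examples
#' fst_from_het(0.18, 0.5, 0.5)$value  # 0.32
#' @export
fst_from_het <- function(H1, H2, H12, estimator = "fst") {
  g <- function(h) if (inherits(h, "diversity_estimate")) h$value else h
  H1 <- g(H1); H2 <- g(H2); H12 <- g(H12)
  if (H12 <= 0) stop("H12 must be positive")
  structure(list(value = (H12 - (H1 + H2) / 2) / H12,
                 H1 = H1, H2 = H2, H12 = H12, estimator = estimator),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, ...) {
  cat(sprintf("FST (%s): %.6g  [H1 = %.4g, H2 = %.4g, H12 = %.4g]\n",
              x$estimator, x$value, x$H1, x$H2, x$H12))
  invisible(x)
}

#' Locus-specific branch lengths from three pairwise FST values
#'
#' Places three populations on an unrooted star tree with branch lengths
#' \eqn{L_1 = (f_{12} + f_{13} - f_{23})/2} and cyclic permutations, so that
#' \eqn{L_i + L_j = f_{ij}} exactly.  Negative branch lengths are reported
#' as computed.
#'
#' @param f12,f13,f23 Pairwise FST values among populations 1, 2, 3.
#' @return Named numeric vector `c(L1, L2, L3)`.
#' @examples
#' lsbl(0.5, 0.5, 0)  # 0.5, 0, 0
#' @export
lsbl <- function(f12, f13, f23) {
  c(L1 = (f12 + f13 - f23) / 2,
    L2 = (f12 + f23 - f13) / 2,
    L3 = (f13 + f23 - f12) / 2)
}

#' Delta-method variance of an FST estimator
#'
#' Approximates \eqn{Var[\breve F_{ST}]} by the variance-of-a-ratio
#' expansion around the parametric components, with
#' \deqn{Var[\breve H_{12} - \tfrac12(\breve H_1+\breve H_2)] =
#'  Var[\breve H_{12}] + \tfrac14 Var[\breve H_1] + \tfrac14 Var[\breve H_2]
#'  - Cov[\breve H_{12}, \breve H_1] - Cov[\breve H_{12}, \breve H_2].}
#' The within-population variances come from the theory
#' ([variance_exact()] when higher-order coefficients are available,
#' otherwise [variance_approx()]); \eqn{Var[\breve H_{12}]} and the
#' covariance terms are estimated by seeded gene-drop Monte Carlo over
#' `mc_reps` replicates of both sampling designs (their closed forms are
#' long and gain nothing here).  Cross-population sampling is independent.
#'
#' @param spectrum1,spectrum2 Parametric [locus_spectrum()] objects for the
#'   two populations, over a shared allele universe.
#' @param pair_specs1,pair_specs2 Sampling designs ([pair_spec()] lists) for
#'   the two populations.
#' @param estimator `"fst_hat_full"`, `"fst_tilde"` or `"fst_blue"`: which
#'   heterozygosity family the FST is built from.
#' @param mc_reps Monte Carlo replicates (>= 1000).
#' @param seed Integer seed.
#' @param mode `"autosomal"` or `"x_linked"`.
#' @return Non-negative numeric variance, with the Monte Carlo component
#'   estimates in attribute `"components"`.
#' @export
fst_variance_approx <- function(spectrum1, spectrum2, pair_specs1, pair_specs2,
                                estimator = c("fst_tilde", "fst_blue",
                                              "fst_hat_full"),
                                mc_reps = 2000, seed = NULL,
                                mode = c("autosomal", "x_linked")) {
  estimator <- match.arg(estimator)
  mode <- match.arg(mode)
  if (mc_reps < 1000) stop("mc_reps must be at least 1000")
  if (!inherits(spectrum1, "locus_spectrum")) spectrum1 <- locus_spectrum(spectrum1)
  if (!inherits(spectrum2, "locus_spectrum")) spectrum2 <- locus_spectrum(spectrum2)
  H1 <- spectrum1$H; H2 <- spectrum2$H
  H12 <- 1 - sum(spectrum1$p * spectrum2$p)
  if (H12 <= 0) stop("H12 must be positive")

  fam <- c(fst_hat_full = "h_hat_full", fst_tilde = "h_tilde",
           fst_blue = "h_blue")[[estimator]]
  seeds <- if (is.null(seed)) rep(NA_integer_, 3L) else derive_seeds(seed, 3L)
  sim <- fst_experiment(pair_specs1, pair_specs2, spectrum1, spectrum2,
                        estimators = fam, reps = mc_reps,
                        seed = if (is.na(seeds[1L])) NULL else seeds[1L],
                        mode = mode)
  h1 <- sim$components[[fam]][, "H1"]
  h2 <- sim$components[[fam]][, "H2"]
  h12 <- sim$components[[fam]][, "H12"]

  # theory for the within-population variances, MC for the rest
  v1 <- .family_variance(spectrum1, sim$design1, fam, seeds[2L])
  v2 <- .family_variance(spectrum2, sim$design2, fam, seeds[3L])
  v12 <- stats::var(h12)
  c121 <- stats::cov(h12, h1)
  c122 <- stats::cov(h12, h2)

  ex <- H12 - (H1 + H2) / 2
  ey <- H12
  var_x <- v12 + v1 / 4 + v2 / 4 - (c121 + c122)
  cov_xy <- v12 - (c121 + c122) / 2
  v <- var_x / ey^2 + ex^2 * v12 / ey^4 - 2 * ex * cov_xy / ey^3
  v <- max(v, 0)
  attr(v, "components") <- c(var_H1 = v1, var_H2 = v2, var_H12 = v12,
                             cov_H12_H1 = c121, cov_H12_H2 = c122)
  v
}

# Theoretical variance of one heterozygosity family on a sampling design.
# variance_exact() returns Var[(1 - sum p^2)]/(1 - rho2)^2; the classical
# estimator rescales the raw variance by (n/(n-1))^2 instead.
.family_variance <- function(spectrum, design, fam, seed = NA_integer_) {
  coeffs <- design_mean_kinship(
    design, weights = if (fam == "h_blue") "blue" else "copy",
    reps = 20000, seed = if (is.na(seed)) NULL else seed)
  v_corrected <- variance_exact(spectrum, coeffs)
  if (fam == "h_hat_full") {
    n <- design$n_copies
    v_corrected * (1 - coeffs$rho2)^2 * (n / (n - 1))^2
  } else {
    v_corrected
  }
}
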