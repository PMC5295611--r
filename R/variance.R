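# Theoretical variance of the kinship-corrected heterozygosity estimators,
# and the range-normalized diversity statistic B = D/R.

#' Exact theoretical variance of a kinship-corrected estimator
#'
#' For an estimator \eqn{\breve H = (1-\sum_i \breve p_i^2)/(1-\rho_2)},
#' the exact variance is \eqn{Var[1-\sum_i \breve p_i^2]/(1-\rho_2)^2} with
#' \deqn{Var[1-\textstyle\sum_i \breve p_i^2] =
#'   (\rho_{2,2}-\rho_2^2) + 2(\rho_2^2-\rho_4)\sum_i p_i^2 +
#'   4(2\rho_4+\rho_2-2\rho_3-\rho_{2,2})\sum_i p_i^3 +
#'   (3\rho_{2,2}+8\rho_3-6\rho_4-4\rho_2-\rho_2^2)(\sum_i p_i^2)^2,}
#' evaluated at the parametric allele frequencies.  The weighted mean
#' kinship coefficients for pairs, trios, quartets and pairs-of-pairs come
#' from [mean_kinship()] (analytic tuple arrays), [gene_drop_mean_kinship()]
#' or [design_mean_kinship()].
#'
#' @param spectrum A [locus_spectrum()] (or frequency vector).
#' @param coeffs A [mean_kinship_coeffs()] with all four coefficients.
#' @return Non-negative numeric variance.
#' @export
variance_exact <- function(spectrum, coeffs) {
  if (!inherits(spectrum, "locus_spectrum")) spectrum <- locus_spectrum(spectrum)
  stopifnot(inherits(coeffs, "mean_kinship_coeffs"))
  if (anyNA(c(coeffs$rho3, coeffs$rho4, coeffs$rho2_2))) {
    stop("variance_exact needs rho3, rho4 and rho2_2; ",
         "estimate them with gene_drop_mean_kinship() or design_mean_kinship()")
  }
  r2 <- coeffs$rho2; r3 <- coeffs$rho3; r4 <- coeffs$rho4; r22 <- coeffs$rho2_2
  s2 <- sum(spectrum$p^2); s3 <- sum(spectrum$p^3)
  raw <- (r22 - r2^2) +
    2 * (r2^2 - r4) * s2 +
    4 * (2 * r4 + r2 - 2 * r3 - r22) * s3 +
    (3 * r22 + 8 * r3 - 6 * r4 - 4 * r2 - r2^2) * s2^2
  v <- raw / (1 - r2)^2
  # guard tiny negative round-off on degenerate (e.g. monomorphic) input
  if (v < 0 && v > -1e-12) v <- 0
  v
}

#' Approximate theoretical variance for sparse relatedness
#'
#' When no sampled individual is related to more than one other, the
#' higher-order coefficients are negligible and
#' \deqn{Var[\breve H] \approx \frac{4\rho_2}{(1-\rho_2)^2}
#'   \left[\sum_i p_i^3 - \left(\sum_i p_i^2\right)^2\right].}
#' Always non-negative, since \eqn{\sum p^3 \ge (\sum p^2)^2} for
#' probability vectors.
#'
#' @inheritParams variance_exact
#' @param rho2 Weighted mean kinship coefficient in \eqn{[0, 1)}.
#' @return Non-negative numeric variance.
#' @examples
#' variance_approx(locus_spectrum(c(0.95, 0.05)), rho2 = 3 / 8)  # 0.1477
#' @export
variance_approx <- function(spectrum, rho2) {
  if (!inherits(spectrum, "locus_spectrum")) spectrum <- locus_spectrum(spectrum)
  stopifnot(rho2 >= 0, rho2 < 1)
  s2 <- sum(spectrum$p^2); s3 <- sum(spectrum$p^3)
  4 * rho2 * (s3 - s2^2) / (1 - rho2)^2
}

#' Range of expected heterozygosity given allele count and maximum frequency
#'
#' For a locus with exactly `I` alleles whose most frequent allele has
#' frequency `M` (`1/I <= M <= 1`), the heterozygosity maximum is attained
#' by spreading the residual mass evenly over the remaining `I - 1` alleles;
#' the minimum by concentrating it into as few alleles as possible subject
#' to each frequency being at most `M` (majorization bounds).
#'
#' @param I Number of distinct alleles (>= 1).
#' @param M Frequency of the most frequent allele.
#' @return Named numeric vector `c(min = , max = )`.
#' @export
het_bounds <- function(I, M) {
  stopifnot(I >= 1, M >= 1 / I - 1e-12, M <= 1 + 1e-12)
  M <- min(M, 1)
  h_max <- 1 - M^2 - (1 - M)^2 / max(I - 1, 1)
  if (I == 1L) return(c(min = 0, max = 0))
  # most concentrated spectrum: k alleles at M, remainder on one allele,
  # remaining alleles vanishingly small (supremum of sum p^2)
  k <- floor(1 / M + 1e-12)
  rem <- 1 - k * M
  if (rem < 1e-12) rem <- 0
  h_min <- 1 - (k * M^2 + rem^2)
  c(min = h_min, max = h_max)
}

#' Range-normalized expected heterozygosity B = D/R
#'
#' Normalizes an observed heterozygosity to the range attainable given the
#' locus's allele count `I` and maximum allele frequency `M`:
#' `B = (H_obs - H_min) / (H_max - H_min)`, in \[0, 1\].  When the bounds
#' coincide (e.g. any biallelic locus, where `M` fixes the spectrum), the
#' statistic is undefined and an error is raised.
#'
#' @param H_obs Observed expected heterozygosity, within the attainable
#'   bounds (tolerance 1e-8).
#' @inheritParams het_bounds
#' @return Numeric value in \[0, 1\].
#' @export
normalized_het_B <- function(H_obs, I, M) {
  b <- het_bounds(I, M)
  R <- b["max"] - b["min"]
  if (R < 1e-12) {
    stop("heterozygosity range is zero for I = ", I, ", M = ", M,
         "; B = D/R is undefined")
  }
  if (H_obs < b["min"] - 1e-8 || H_obs > b["max"] + 1e-8) {
    stop("H_obs = ", format(H_obs), " lies outside the attainable range [",
         format(b["min"]), ", ", format(b["max"]), "]")
  }
  unname(min(1, max(0, (H_obs - b["min"]) / R)))
}
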