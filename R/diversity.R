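# Gene-diversity (expected heterozygosity) estimators.
#
# H = 1 - sum_i p_i^2 is the probability that two allele copies randomly
# sampled from the population differ.  On samples of unrelated outbred
# individuals the classical estimator H_hat = n/(n-1) (1 - sum p_hat_i^2)
# (n allele copies) is unbiased; with related or inbred individuals it is
# downward-biased, and the general correction 1/(1 - rho2) with a weighted
# mean kinship coefficient rho2 restores unbiasedness for any linear
# unbiased frequency estimator.

#' Parametric locus spectrum
#'
#' Holds the true allele frequencies of a locus together with the derived
#' summaries used throughout: allele count `I`, maximum frequency `M`, and
#' parametric heterozygosity `H`.
#'
#' @param p Numeric vector of allele frequencies summing to 1 within 1e-12;
#'   names are allele labels (defaults `a1..aI`).
#' @return An object of class `locus_spectrum`.
#' @examples
#' locus_spectrum(c(0.15, 0.85))$H  # 0.255
#' @export
locus_spectrum <- function(p) {
  labs <- names(p)
  p <- as.numeric(p)
  if (any(p < 0)) stop("allele frequencies must be non-negative")
  if (abs(sum(p) - 1) > 1e-12) stop("allele frequencies must sum to 1 (within 1e-12)")
  if (is.null(labs)) labs <- paste0("a", seq_along(p))
  names(p) <- labs
  structure(list(p = p, I = length(p), M = max(p), H = 1 - sum(p^2)),
            class = "locus_spectrum")
}

#' @export
print.locus_spectrum <- function(x, ...) {
  cat(sprintf("Locus spectrum: I = %d alleles, M = %.4g, H = %.4g\n",
              x$I, x$M, x$H))
  invisible(x)
}

#' Parametric expected heterozygosity
#'
#' \eqn{H = 1 - \sum_i p_i^2}, the probability that two randomly sampled
#' allele copies differ; lies in \eqn{[0, 1 - 1/I]}.
#'
#' @param spectrum A [locus_spectrum()] or plain frequency vector.
#' @return Numeric value.
#' @export
true_heterozygosity <- function(spectrum) {
  if (!inherits(spectrum, "locus_spectrum")) spectrum <- locus_spectrum(spectrum)
  spectrum$H
}

.diversity_estimate <- function(value, estimator, correction, weights,
                                n_copies = NA_integer_, variance = NULL,
                                bias = NULL) {
  structure(list(value = value, estimator = estimator,
                 correction = correction, weights = weights,
                 n_copies = n_copies, variance = variance, bias = bias,
                 out_of_range = (value < 0 || value > 1)),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("Expected heterozygosity (%s): %.6g  [correction %.6g]\n",
              x$estimator, x$value, x$correction))
  if (!is.null(x$variance)) cat(sprintf("  theoretical variance: %.6g\n", x$variance))
  invisible(x)
}

#' Classical heterozygosity estimator
#'
#' \eqn{\hat H = \frac{n}{n-1}(1 - \sum_i \hat p_i^2)} with `n` the number
#' of allele copies and \eqn{\hat p} the sample proportions.  Unbiased only
#' for samples of unrelated, outbred individuals.
#'
#' @param sample A [genotype_sample()] (individuals with missing calls are
#'   dropped first).
#' @return A `diversity_estimate` tagged `"h_hat_full"`.
#' @examples
#' h_hat(genotype_sample("a", list(c("A", "B"))))$value  # 1
#' @export
h_hat <- function(sample) {
  sample <- drop_missing(sample)
  n <- n_allele_copies(sample)
  if (n < 2L) stop("h_hat needs at least 2 allele copies")
  p <- sample_proportion(sample)
  corr <- n / (n - 1)
  .diversity_estimate(corr * (1 - sum(p$freq^2)), "h_hat_full", corr,
                      p$weights, n)
}

#' Reduced-sample heterozygosity estimator
#'
#' Removes one member of each listed relative pair -- a seeded random choice
#' for same-ploidy pairs, deterministically the lower-ploidy member for
#' mixed-ploidy (e.g. male-female X-linked) pairs -- then applies [h_hat()]
#' to the retained individuals.
#'
#' @inheritParams h_hat
#' @param relative_pairs List of length-2 character vectors of ids; pairs
#'   must be disjoint and their members present in the sample.
#' @param seed Optional integer seed for the random member choices.
#' @return A `diversity_estimate` tagged `"h_hat_red"`, with the retained
#'   ids in attribute `"retained"`.
#' @export
h_hat_reduced <- function(sample, relative_pairs = list(), seed = NULL) {
  stopifnot(inherits(sample, "genotype_sample"))
  members <- unlist(relative_pairs, use.names = FALSE)
  if (anyDuplicated(members)) stop("relative pairs overlap")
  if (!all(members %in% sample$ids)) {
    stop("pair member(s) absent from sample: ",
         paste(setdiff(members, sample$ids), collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  remove <- character(0)
  for (pair in relative_pairs) {
    m <- sample$ploidies[match(pair, sample$ids)]
    drop_id <- if (m[1L] != m[2L]) pair[which.min(m)]
               else pair[sample.int(2L, 1L)]
    remove <- c(remove, drop_id)
  }
  retained <- setdiff(sample$ids, remove)
  est <- h_hat(subset_sample(sample, retained))
  est$estimator <- "h_hat_red"
  attr(est, "retained") <- retained
  est
}

#' General kinship-corrected heterozygosity estimator
#'
#' \eqn{\breve H = (1 - \sum_i \breve p_i^2) / (1 - \rho_2)} for any
#' unbiased linear frequency estimator with weights `w` and matching
#' weighted mean kinship \eqn{\rho_2 = \sum_{jk} w_j w_k \Phi_{jk}}.
#' Unbiased for samples of any ploidy, relatedness and inbreeding.
#'
#' @inheritParams h_hat
#' @param weights Per-individual weights summing to 1.
#' @param rho2 Weighted mean kinship coefficient in \eqn{[0, 1)}; values
#'   \eqn{\ge 1} (no independent allele information) are rejected.
#' @param estimator Tag recorded in the result.
#' @return A `diversity_estimate`.
#' @export
h_general <- function(sample, weights, rho2, estimator = "h_general") {
  sample <- drop_missing(sample)
  if (rho2 < 0 || rho2 >= 1) {
    stop("rho2 must lie in [0, 1): rho2 >= 1 leaves no independent allele information")
  }
  p <- linear_estimate(sample, weights)
  corr <- 1 / (1 - rho2)
  .diversity_estimate(corr * (1 - sum(p$freq^2)), estimator, corr, weights,
                      n_allele_copies(sample))
}

#' Kinship-corrected heterozygosity with sample-proportion frequencies
#'
#' \eqn{\tilde H = (1 - \sum_i \hat p_i^2)/(1 - \bar\Phi_2)}, where
#' \eqn{\bar\Phi_2} is the allele-copy-weighted mean kinship of the sample.
#' On unrelated outbred samples of any ploidy mix it coincides with
#' [h_hat()] exactly, since then \eqn{\bar\Phi_2 = 1/\sum_k m_k}.
#'
#' @inheritParams h_hat
#' @param K A [kinship_spec()] covering the sample (same order); individuals
#'   dropped for missingness are removed from `K` as well.
#' @return A `diversity_estimate` tagged `"h_tilde"`.
#' @export
h_tilde <- function(sample, K) {
  res <- .with_kinship(sample, K)
  w <- res$sample$ploidies / sum(res$sample$ploidies)
  phibar2 <- drop(crossprod(w, res$K$K %*% w))
  est <- h_general(res$sample, w, phibar2, estimator = "h_tilde")
  est
}

#' BLUE-based kinship-corrected heterozygosity
#'
#' \eqn{\tilde H_{BLUE} = (1 - \sum_i \tilde p_i^2)/(1 - \kappa_2)}, using
#' the best linear unbiased estimator of allele frequencies and the matching
#' BLUE-weighted mean kinship \eqn{\kappa_2}.  Requires an invertible
#' kinship matrix.
#'
#' @inheritParams h_tilde
#' @return A `diversity_estimate` tagged `"h_blue"`.
#' @export
h_blue <- function(sample, K) {
  res <- .with_kinship(sample, K)
  w <- blue_weights(res$K)
  kappa2 <- drop(crossprod(w, res$K$K %*% w))
  h_general(res$sample, w, kappa2, estimator = "h_blue")
}

# Align a kinship spec with a (possibly missing-data-reduced) sample.
.with_kinship <- function(sample, K) {
  stopifnot(inherits(sample, "genotype_sample"))
  if (!inherits(K, "kinship_spec")) K <- kinship_spec(as.matrix(K), ids = sample$ids)
  sample <- drop_missing(sample)
  idx <- match(sample$ids, K$ids)
  if (anyNA(idx)) {
    stop("kinship matrix does not cover sample id(s): ",
         paste(sample$ids[is.na(idx)], collapse = ", "))
  }
  list(sample = sample,
       K = kinship_spec(K$K[idx, idx, drop = FALSE], ids = sample$ids))
}

#' Bias of the classical estimator on related samples
#'
#' \eqn{Bias[\hat H] = \frac{1 - n\rho_2}{n - 1} H}, with `n` the number of
#' allele copies in the sample.  Vanishes when \eqn{\rho_2 = 1/n}, the
#' unrelated outbred case.
#'
#' @param H Parametric expected heterozygosity.
#' @param n_copies Number of allele copies (>= 2).
#' @param rho2 Weighted mean kinship coefficient in \eqn{[0, 1)}.
#' @return Numeric bias (negative for related samples).
#' @export
bias_h_hat <- function(H, n_copies, rho2) {
  stopifnot(n_copies >= 2, rho2 >= 0, rho2 < 1)
  (1 - n_copies * rho2) / (n_copies - 1) * H
}

#' Mean squared error from bias and variance
#'
#' @param bias Numeric bias.
#' @param variance Non-negative variance.
#' @return `bias^2 + variance`.
#' @export
mse <- function(bias, variance) {
  stopifnot(variance >= 0)
  bias^2 + variance
}
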