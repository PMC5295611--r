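# Unbiased linear estimators of allele frequency: the general weighted
# estimator, the sample proportion, and the BLUE built on the inverse
# kinship matrix.

#' Generic weighted allele-frequency estimate
#'
#' The general unbiased linear estimator
#' \eqn{\breve p_i = \sum_k w_k X_k^{(i)}} with per-individual weights
#' summing to 1.  Both [sample_proportion()] and [blue_frequencies()] are
#' specializations.
#'
#' @param X Allele-fraction matrix from [allele_fractions()] (or a
#'   [genotype_sample()], which is converted).
#' @param weights Numeric vector, one weight per individual, summing to 1
#'   within 1e-12.
#' @param estimator Tag recorded in the result.
#' @return An object of class `frequency_estimate`: list with `alleles`,
#'   `freq` (named numeric), `weights`, `estimator`, and `out_of_range`
#'   (`TRUE` when any estimate falls outside \[0, 1\], possible for negative
#'   weights; estimates are reported as computed, not clipped).
#' @export
linear_estimate <- function(X, weights, estimator = "custom") {
  if (inherits(X, "genotype_sample")) X <- allele_fractions(X)
  if (length(weights) != nrow(X)) {
    stop("weights length (", length(weights), ") does not match sample size (",
         nrow(X), ")")
  }
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1 (within 1e-12)")
  p <- drop(crossprod(X, weights))
  names(p) <- colnames(X)
  oor <- any(p < -1e-12 | p > 1 + 1e-12)
  if (oor) warning("frequency estimate outside [0, 1] (negative weights); reported as computed")
  structure(list(alleles = colnames(X), freq = p, weights = weights,
                 estimator = estimator, out_of_range = oor),
            class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("Allele frequency estimate (%s):\n", x$estimator))
  print(round(x$freq, 6))
  invisible(x)
}

#' Sample-proportion allele frequencies
#'
#' Weights each individual by its share of allele copies,
#' \eqn{w_k = m_k / \sum_j m_j}, so the estimate equals pooled allele counts
#' over total copies.
#'
#' @param sample A [genotype_sample()], or an allele-fraction matrix if
#'   `ploidies` is given.
#' @param ploidies Per-individual ploidies (taken from `sample` when it is a
#'   [genotype_sample()]).
#' @return A [linear_estimate()] result tagged `"sample_proportion"`.
#' @examples
#' g <- genotype_sample(c("a", "b"), list(c("A", "B"), c("A", "A")))
#' sample_proportion(g)$freq  # A: 3/4
#' @export
sample_proportion <- function(sample, ploidies = NULL) {
  if (inherits(sample, "genotype_sample")) {
    ploidies <- sample$ploidies
    sample <- allele_fractions(sample)
  }
  if (is.null(ploidies)) stop("ploidies required when passing a plain matrix")
  if (nrow(sample) == 0L) stop("empty sample")
  w <- ploidies / sum(ploidies)
  linear_estimate(sample, w, estimator = "sample_proportion")
}

#' BLUE weights from a kinship matrix
#'
#' The best linear unbiased estimator of allele frequency weights individual
#' `k` by the normalized column sums of the inverse kinship matrix,
#' \eqn{w_k = \sum_j (K^{-1})_{jk} / (1' K^{-1} 1)}.  `K` must be
#' invertible; a reciprocal condition number below `tol` is rejected rather
#' than silently pseudo-inverted.  Weights can be negative for some kinship
#' configurations; they always sum to 1.
#'
#' @param K A [kinship_spec()] or plain symmetric matrix.
#' @param tol Reciprocal condition number threshold (default 1e-12).
#' @return Named numeric weight vector.
#' @examples
#' K <- matrix(c(.5, .25, 0, .25, .5, 0, 0, 0, .5), 3)
#' blue_weights(K)  # 2/7, 2/7, 3/7
#' @export
blue_weights <- function(K, tol = 1e-12) {
  if (inherits(K, "kinship_spec")) { ids <- K$ids; K <- K$K } else {
    ids <- rownames(K); K <- as.matrix(K)
  }
  rc <- 1 / kappa(K, exact = TRUE)
  if (!is.finite(rc) || rc < tol) {
    stop("kinship matrix is singular or numerically non-invertible ",
         "(reciprocal condition number ", format(rc), "); BLUE weights are ",
         "defined only for invertible K")
  }
  cs <- colSums(solve(K))
  w <- cs / sum(cs)
  names(w) <- ids
  w
}

#' BLUE allele frequencies
#'
#' Applies [linear_estimate()] with [blue_weights()] computed from the
#' kinship matrix of the sampled individuals.
#'
#' @param X Allele-fraction matrix or [genotype_sample()].
#' @param K A [kinship_spec()] (or matrix) covering the sample, in the same
#'   individual order.
#' @return A [linear_estimate()] result tagged `"blue"`.
#' @export
blue_frequencies <- function(X, K) {
  if (inherits(X, "genotype_sample")) X <- allele_fractions(X)
  w <- blue_weights(K)
  if (length(w) != nrow(X)) stop("dimensions of X and K disagree")
  linear_estimate(X, w, estimator = "blue")
}
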