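# Gene-dropping Monte Carlo on pedigrees.
#
# Founder alleles receive unique integer labels which are transmitted through
# the pedigree by Mendelian segregation (or the X-linked hemizygous rules).
# Identity-by-descent probabilities are then estimated as Rao-Blackwellized
# Monte Carlo means: conditional on a realized drop, the probability that
# independently drawn alleles match is computed exactly from the label
# fractions, so the per-replicate values have far lower variance than raw
# 0/1 indicators.

# Simulate founder-label transmission.  Returns a list with one reps x m_k
# integer matrix of labels per individual, ordered as ped$id.
.gene_drop_labels <- function(ped, reps, mode = c("autosomal", "x_linked")) {
  mode <- match.arg(mode)
  fi <- attr(ped, "father_idx")
  mi <- attr(ped, "mother_idx")
  ord <- attr(ped, "topo_order")
  sex <- ped$sex
  n <- nrow(ped)
  if (mode == "x_linked" && any(sex == "U")) {
    stop("x_linked gene dropping requires a specified sex for every individual")
  }
  m <- if (mode == "x_linked") ifelse(sex == "M", 1L, 2L) else rep(2L, n)
  labels <- vector("list", n)
  next_label <- 1L
  pick <- function(mat) {
    # one uniformly chosen allele copy per replicate
    if (ncol(mat) == 1L) mat[, 1L]
    else mat[cbind(seq_len(nrow(mat)), sample.int(ncol(mat), nrow(mat), replace = TRUE))]
  }
  for (i in ord) {
    founder <- fi[i] == 0L && mi[i] == 0L
    if (founder) {
      lab <- matrix(rep(next_label:(next_label + m[i] - 1L), each = reps),
                    nrow = reps)
      next_label <- next_label + m[i]
      labels[[i]] <- lab
    } else {
      # validated pedigrees have both parents or none
      if (mode == "x_linked") {
        maternal <- pick(labels[[mi[i]]])
        labels[[i]] <- if (sex[i] == "M") matrix(maternal, ncol = 1L)
                       else cbind(labels[[fi[i]]][, 1L], maternal)
      } else {
        labels[[i]] <- cbind(pick(labels[[fi[i]]]), pick(labels[[mi[i]]]))
      }
    }
  }
  names(labels) <- ped$id
  list(labels = labels, ploidy = m, n_labels = next_label - 1L)
}

# Per-replicate weighted label-frequency moments for a set of individuals:
# v_l = sum_k w_k * (count of label l in k) / m_k.  Returns a reps x 4 matrix
# with columns sum(v^2), sum(v^3), sum(v^4), (sum(v^2))^2.
.u_moments <- function(drop, ids_idx, weights, reps) {
  cw <- unlist(lapply(seq_along(ids_idx), function(a) {
    i <- ids_idx[a]
    rep(weights[a] / ncol(drop$labels[[i]]), ncol(drop$labels[[i]]))
  }))
  M <- do.call(cbind, drop$labels[ids_idx])
  present <- sort(unique(as.vector(M)))
  s2 <- s3 <- s4 <- numeric(reps)
  for (l in present) {
    u <- as.numeric((M == l) %*% cw)
    s2 <- s2 + u * u
    s3 <- s3 + u * u * u
    s4 <- s4 + u * u * u * u
  }
  cbind(s2 = s2, s3 = s3, s4 = s4, s22 = s2 * s2)
}

#' Gene-drop estimates of identity-by-descent tuple coefficients
#'
#' Estimates, for a tuple of 2-4 (not necessarily distinct) individuals, the
#' probability that alleles sampled independently one from each listed
#' individual are identical by descent: \eqn{\Phi_{jk}} for the first two
#' ids, \eqn{\Phi_{jkl}} for three, and for four both \eqn{\Phi_{jklm}}
#' (all four IBD) and the pair-of-pairs coefficient \eqn{\Phi_{jk,lm}}
#' (first pair IBD and, jointly, second pair IBD, following argument order).
#' A repeated id means an independent draw with replacement from the same
#' individual.  Conditional matching probabilities are computed exactly per
#' replicate, so the returned Monte Carlo standard errors are small even for
#' moderate `reps`.
#'
#' @param ped A [build_pedigree()] object.
#' @param ids Character vector of 2-4 ids (repeats allowed).
#' @param reps Number of gene-drop replicates (>= 1).
#' @param seed Optional integer seed.
#' @param mode `"autosomal"` or `"x_linked"`.
#' @return A list with elements `phi2`, and when applicable `phi3`, `phi4`,
#'   `phi22`, each a named vector `c(estimate, se)`; plus `reps` and `ids`.
#' @examples
#' fs <- build_pedigree(data.frame(id = c("F", "M", "S1", "S2"),
#'   father = c(NA, NA, "F", "F"), mother = c(NA, NA, "M", "M"),
#'   sex = c("M", "F", "M", "F")))
#' gene_drop_identity_coeffs(fs, c("S1", "S2"), reps = 2000, seed = 1)$phi2
#' @export
gene_drop_identity_coeffs <- function(ped, ids, reps = 10000, seed = NULL,
                                      mode = c("autosomal", "x_linked")) {
  mode <- match.arg(mode)
  if (reps < 1) stop("reps must be >= 1")
  if (length(ids) < 2L || length(ids) > 4L) {
    stop("ids must name 2 to 4 individuals (repeats allowed)")
  }
  idx <- .ped_index(ped, ids)
  if (!is.null(seed)) set.seed(seed)
  drop <- .gene_drop_labels(ped, reps, mode)
  L <- lapply(idx, function(i) drop$labels[[i]])

  pair_cond <- function(A, B) {
    acc <- numeric(reps)
    for (s in seq_len(ncol(A))) for (t in seq_len(ncol(B))) {
      acc <- acc + (A[, s] == B[, t])
    }
    acc / (ncol(A) * ncol(B))
  }
  est <- function(x) c(estimate = mean(x), se = stats::sd(x) / sqrt(reps))

  out <- list(ids = ids, reps = reps)
  p12 <- pair_cond(L[[1L]], L[[2L]])
  out$phi2 <- est(p12)
  if (length(L) >= 3L) {
    acc <- numeric(reps)
    for (s in seq_len(ncol(L[[1L]]))) for (t in seq_len(ncol(L[[2L]])))
      for (u in seq_len(ncol(L[[3L]]))) {
        acc <- acc + (L[[1L]][, s] == L[[2L]][, t] & L[[2L]][, t] == L[[3L]][, u])
      }
    out$phi3 <- est(acc / prod(vapply(L[1:3], ncol, 1L)))
  }
  if (length(L) == 4L) {
    acc <- numeric(reps)
    for (s in seq_len(ncol(L[[1L]]))) for (t in seq_len(ncol(L[[2L]])))
      for (u in seq_len(ncol(L[[3L]])))  for (v in seq_len(ncol(L[[4L]]))) {
        acc <- acc + (L[[1L]][, s] == L[[2L]][, t] &
                      L[[2L]][, t] == L[[3L]][, u] &
                      L[[3L]][, u] == L[[4L]][, v])
      }
    out$phi4 <- est(acc / prod(vapply(L, ncol, 1L)))
    out$phi22 <- est(p12 * pair_cond(L[[3L]], L[[4L]]))
  }
  out
}

#' Gene-drop estimates of weighted mean kinship coefficients
#'
#' Estimates the weighted mean kinship coefficients of a sample for all
#' pairs, trios, quartets and pairs-of-pairs of individuals (indices ranging
#' over all individuals including repeats):
#' \deqn{\rho_2 = \sum_{jk} w_j w_k \Phi_{jk}, \quad
#'       \rho_3 = \sum_{jkl} w_j w_k w_l \Phi_{jkl},}
#' and analogously \eqn{\rho_4} and \eqn{\rho_{2,2}}.  Per replicate the
#' conditional values are the power sums \eqn{\sum_l v_l^r} of the weighted
#' founder-label frequencies \eqn{v_l = \sum_k w_k X_{kl}}, which makes the
#' estimator exact in conditional expectation.
#'
#' @inheritParams gene_drop_identity_coeffs
#' @param ids Sampled individual ids (the weight vector refers to these).
#' @param weights Numeric weights summing to 1 (within 1e-12).
#' @return A `mean_kinship_coeffs` object: list with `rho2`, `rho3`, `rho4`,
#'   `rho2_2`, their standard errors in `se`, the `weights`, and `reps`.
#' @export
gene_drop_mean_kinship <- function(ped, ids, weights = NULL, reps = 10000,
                                   seed = NULL,
                                   mode = c("autosomal", "x_linked")) {
  mode <- match.arg(mode)
  if (reps < 1) stop("reps must be >= 1")
  idx <- .ped_index(ped, ids)
  if (is.null(weights)) weights <- rep(1 / length(ids), length(ids))
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  if (length(weights) != length(ids)) stop("weights length must match ids")
  if (!is.null(seed)) set.seed(seed)
  drop <- .gene_drop_labels(ped, reps, mode)
  mom <- .u_moments(drop, idx, weights, reps)
  mean_kinship_coeffs(
    rho2 = mean(mom[, "s2"]), rho3 = mean(mom[, "s3"]),
    rho4 = mean(mom[, "s4"]), rho2_2 = mean(mom[, "s22"]),
    weights = weights,
    se = apply(mom, 2, stats::sd) / sqrt(reps), reps = reps)
}

#' Mean kinship coefficient container
#'
#' @param rho2,rho3,rho4,rho2_2 Weighted mean kinship coefficients for
#'   pairs, trios, quartets and pairs-of-pairs; probabilities in \[0, 1\].
#' @param weights The weight vector that produced them.
#' @param se Optional Monte Carlo standard errors.
#' @param reps Optional replicate count behind Monte Carlo estimates.
#' @return An object of class `mean_kinship_coeffs`.
#' @export
mean_kinship_coeffs <- function(rho2, rho3 = NA_real_, rho4 = NA_real_,
                                rho2_2 = NA_real_, weights = NULL,
                                se = NULL, reps = NULL) {
  for (v in c(rho2, rho3, rho4, rho2_2)) {
    if (!is.na(v) && (v < -1e-12 || v > 1 + 1e-12)) {
      stop("mean kinship coefficients must lie in [0, 1]")
    }
  }
  structure(list(rho2 = rho2, rho3 = rho3, rho4 = rho4, rho2_2 = rho2_2,
                 weights = weights, se = se, reps = reps),
            class = "mean_kinship_coeffs")
}

#' @export
print.mean_kinship_coeffs <- function(x, ...) {
  cat("Weighted mean kinship coefficients:\n")
  cat(sprintf("  rho2 = %.6g  rho3 = %.6g  rho4 = %.6g  rho2,2 = %.6g\n",
              x$rho2, x$rho3, x$rho4, x$rho2_2))
  invisible(x)
}

#' Weighted mean kinship coefficients from a kinship specification
#'
#' Computes \eqn{\rho_2 = w' K w} (sums include the diagonal, i.e. repeated
#' indices use self-kinship), and, when the higher-order coefficient arrays
#' `phi3`, `phi4`, `phi22` are present in `K` (or supplied via
#' `tuple_coeffs`), the corresponding weighted sums \eqn{\rho_3},
#' \eqn{\rho_4} and \eqn{\rho_{2,2}}.
#'
#' @param K A [kinship_spec()].
#' @param weights Numeric weights summing to 1 (within 1e-12).
#' @param tuple_coeffs Optional list with arrays `phi3` (n^3), `phi4`,
#'   `phi22` (n^4), overriding those stored in `K`.
#' @param require_higher If `TRUE`, error when the tuple coefficient arrays
#'   are unavailable instead of returning `NA` higher-order sums.
#' @return A [mean_kinship_coeffs()] object.
#' @examples
#' K <- kinship_spec(matrix(c(.5, .25, .25, .5), 2))
#' mean_kinship(K, c(.5, .5))$rho2  # 3/8 for an outbred full-sib pair
#' @export
mean_kinship <- function(K, weights, tuple_coeffs = NULL,
                         require_higher = FALSE) {
  stopifnot(inherits(K, "kinship_spec"))
  n <- length(K$ids)
  if (length(weights) != n) stop("weights length must equal sample size")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1 (within 1e-12)")
  phi3 <- if (!is.null(tuple_coeffs)) tuple_coeffs$phi3 else K$phi3
  phi4 <- if (!is.null(tuple_coeffs)) tuple_coeffs$phi4 else K$phi4
  phi22 <- if (!is.null(tuple_coeffs)) tuple_coeffs$phi22 else K$phi22
  rho2 <- drop(crossprod(weights, K$K %*% weights))
  rho3 <- rho4 <- rho2_2 <- NA_real_
  if (!is.null(phi3)) {
    w3 <- outer(outer(weights, weights), weights)
    rho3 <- sum(phi3 * w3)
  }
  w4 <- NULL
  if (!is.null(phi4) || !is.null(phi22)) {
    w4 <- outer(outer(outer(weights, weights), weights), weights)
  }
  if (!is.null(phi4)) rho4 <- sum(phi4 * w4)
  if (!is.null(phi22)) rho2_2 <- sum(phi22 * w4)
  if (require_higher && (is.na(rho3) || is.na(rho4) || is.na(rho2_2))) {
    stop("higher-order tuple coefficients requested but not available; ",
         "supply phi3/phi4/phi22 arrays or use gene_drop_mean_kinship()")
  }
  mean_kinship_coeffs(rho2, rho3, rho4, rho2_2, weights = weights)
}
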