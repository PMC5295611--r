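# Recursive pedigree kinship (autosomal and X-linked), kinship matrices and
# the KinshipSpec container.
#
# The kinship coefficient Phi_jk is the probability that one allele sampled
# at random from individual j and one from k are identical by descent.  On a
# pedigree with mutually unrelated, non-inbred founders it satisfies the
# classical recursion: for j not an ancestor of k,
#   Phi_jk = 1/2 (Phi_{father(j),k} + Phi_{mother(j),k}),
# with Phi_jj = 1/2 (1 + F_j) for diploids, F_j the kinship of j's parents.
# At an X-linked locus males are hemizygous: a male transmits his single X,
# male self-kinship is 1, and a non-founder male j has Phi_jk =
# Phi_{mother(j),k}.

.kin_engine <- function(ped, mode = c("autosomal", "x_linked")) {
  mode <- match.arg(mode)
  fi <- attr(ped, "father_idx")
  mi <- attr(ped, "mother_idx")
  rank <- attr(ped, "topo_rank")
  sex <- ped$sex
  if (mode == "x_linked" && any(sex == "U")) {
    stop("x_linked kinship requires a specified sex for every individual")
  }
  memo <- new.env(parent = emptyenv(), size = 4L * nrow(ped))

  phi <- function(a, b) {
    if (a == 0L || b == 0L) return(0)
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    key <- paste0(a, ":", b)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    if (a == b) {
      val <- if (mode == "x_linked" && sex[a] == "M") 1
             else 0.5 * (1 + phi(fi[a], mi[a]))
    } else {
      # recurse through the individual later in topological order: it cannot
      # be an ancestor of the other
      u <- if (rank[a] >= rank[b]) a else b
      v <- if (u == a) b else a
      val <- if (fi[u] == 0L && mi[u] == 0L) {
        0  # founder, unrelated to everyone else
      } else if (mode == "x_linked" && sex[u] == "M") {
        phi(mi[u], v)
      } else {
        0.5 * (phi(fi[u], v) + phi(mi[u], v))
      }
    }
    memo[[key]] <- val
    val
  }
  phi
}

.ped_index <- function(ped, ids) {
  idx <- match(ids, ped$id)
  if (anyNA(idx)) {
    stop("unknown id(s) in pedigree: ", paste(ids[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Pairwise kinship coefficient from a pedigree
#'
#' Computes \eqn{\Phi_{jk}}, the probability that one allele sampled from
#' individual `j` and one from `k` are identical by descent, by the standard
#' recursion on the pedigree.  Founders are assumed mutually unrelated and
#' non-inbred.  `kinship_pair(ped, j, j)` returns the diploid self-kinship
#' \eqn{(1 + F_j)/2} (autosomal), or 1 for a male at an X-linked locus.
#'
#' @param ped A [build_pedigree()] object.
#' @param j,k Individual ids.
#' @param mode `"autosomal"` (default) or `"x_linked"` (hemizygous males).
#' @return A probability in \[0, 1\].
#' @examples
#' fs <- build_pedigree(data.frame(
#'   id = c("F", "M", "S1", "S2"), father = c(NA, NA, "F", "F"),
#'   mother = c(NA, NA, "M", "M"), sex = c("M", "F", "M", "F")))
#' kinship_pair(fs, "S1", "S2")              # 1/4
#' kinship_pair(fs, "S1", "S2", "x_linked")  # brother-sister: 1/4
#' @export
kinship_pair <- function(ped, j, k, mode = c("autosomal", "x_linked")) {
  mode <- match.arg(mode)
  idx <- .ped_index(ped, c(j, k))
  phi <- .kin_engine(ped, mode)
  phi(idx[1L], idx[2L])
}

#' Inbreeding coefficient of a pedigree member
#'
#' The probability that an individual's two alleles at a locus are identical
#' by descent; equals the kinship coefficient of its parents (0 for a
#' founder).
#'
#' @inheritParams kinship_pair
#' @param id Individual id.
#' @return A probability in \[0, 1\].
#' @export
inbreeding <- function(ped, id, mode = c("autosomal", "x_linked")) {
  mode <- match.arg(mode)
  i <- .ped_index(ped, id)
  fi <- attr(ped, "father_idx")[i]
  mi <- attr(ped, "mother_idx")[i]
  if (fi == 0L || mi == 0L) return(0)
  phi <- .kin_engine(ped, mode)
  phi(fi, mi)
}

#' Self-kinship for arbitrary ploidy
#'
#' Probability that two alleles drawn with replacement from one individual
#' are identical by descent: \eqn{(1 + (m-1) f)/m} for ploidy `m` and
#' inbreeding coefficient `f`.  Reduces to \eqn{(1+f)/2} for diploids and to
#' 1 for haploids.
#'
#' @param ploidy Integer number of allele copies carried.
#' @param f Inbreeding coefficient in \[0, 1\].
#' @return A probability in \[0, 1\].
#' @export
self_kinship <- function(ploidy, f = 0) {
  stopifnot(ploidy >= 1, f >= 0, f <= 1)
  (1 + (ploidy - 1) * f) / ploidy
}

#' Kinship matrix for a set of pedigree members
#'
#' Assembles the symmetric matrix `K` with off-diagonal entries
#' \eqn{\Phi_{jk}} from [kinship_pair()] and diagonal entries given by the
#' ploidy-general self-kinship \eqn{(1 + (m_k - 1) f_k)/m_k}.  At an
#' X-linked locus males default to ploidy 1 (so their diagonal is 1) and
#' females to ploidy 2.
#'
#' @inheritParams kinship_pair
#' @param sample_ids Ids of the sampled individuals (rows/columns of `K`).
#' @param ploidies Integer vector of per-individual ploidies, recycled;
#'   default 2 for autosomal mode, sex-based (`M` = 1, `F` = 2) for
#'   X-linked mode.
#' @return A [kinship_spec()] object.
#' @examples
#' po <- build_pedigree(data.frame(id = c("P", "Q", "A"),
#'   father = c(NA, NA, "P"), mother = c(NA, NA, "Q"), sex = c("M", "F", "U")))
#' kinship_matrix(po, c("P", "A"))$K  # [[1/2, 1/4], [1/4, 1/2]]
#' @export
kinship_matrix <- function(ped, sample_ids, mode = c("autosomal", "x_linked"),
                           ploidies = NULL) {
  mode <- match.arg(mode)
  idx <- .ped_index(ped, sample_ids)
  n <- length(idx)
  if (is.null(ploidies)) {
    ploidies <- if (mode == "x_linked") ifelse(ped$sex[idx] == "M", 1L, 2L)
                else rep(2L, n)
  } else {
    ploidies <- rep_len(as.integer(ploidies), n)
  }
  phi <- .kin_engine(ped, mode)
  fi <- attr(ped, "father_idx")
  mi <- attr(ped, "mother_idx")
  K <- matrix(0, n, n, dimnames = list(sample_ids, sample_ids))
  for (a in seq_len(n)) {
    inb <- 0
    if (fi[idx[a]] > 0L && mi[idx[a]] > 0L) inb <- phi(fi[idx[a]], mi[idx[a]])
    K[a, a] <- if (mode == "x_linked" && ped$sex[idx[a]] == "M") 1
               else self_kinship(ploidies[a], inb)
    if (a < n) for (b in (a + 1L):n) {
      K[a, b] <- K[b, a] <- phi(idx[a], idx[b])
    }
  }
  kinship_spec(K, ploidies = ploidies)
}

#' Kinship specification container
#'
#' Holds a labeled symmetric kinship matrix and, optionally, the
#' higher-order identity-by-descent coefficient arrays needed by
#' [mean_kinship()]: `phi3[j,k,l]` (three alleles, one drawn from each listed
#' individual, all IBD), `phi4[j,k,l,m]` (four alleles all IBD) and
#' `phi22[j,k,l,m]` (alleles from `j`,`k` IBD and, jointly, alleles from
#' `l`,`m` IBD).  Indices may repeat; repeated indices mean independent
#' draws with replacement from the same individual.
#'
#' @param K Symmetric numeric matrix with entries in \[0, 1\]; dimnames are
#'   the sample ids.
#' @param ids Sample ids; defaults to `rownames(K)` or `V1..Vn`.
#' @param ploidies Optional per-individual ploidies (stored, used as the
#'   default by estimators that need allele-copy counts).
#' @param phi3,phi4,phi22 Optional coefficient arrays (dimensions `n^3`,
#'   `n^4`, `n^4`).
#' @return An object of class `kinship_spec`.
#' @export
kinship_spec <- function(K, ids = NULL, ploidies = NULL,
                         phi3 = NULL, phi4 = NULL, phi22 = NULL) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("kinship matrix must be square")
  if (is.null(ids)) ids <- rownames(K)
  if (is.null(ids)) ids <- paste0("V", seq_len(nrow(K)))
  if (length(ids) != nrow(K)) stop("ids length does not match kinship matrix")
  asym <- max(abs(K - t(K)))
  if (asym > 1e-9) stop("kinship matrix is asymmetric beyond tolerance (max |K - t(K)| = ",
                        format(asym), ")")
  K <- (K + t(K)) / 2
  if (any(K < -1e-12) || any(K > 1 + 1e-12)) {
    stop("kinship coefficients must lie in [0, 1]")
  }
  dimnames(K) <- list(ids, ids)
  structure(list(ids = ids, K = K, ploidies = ploidies,
                 phi3 = phi3, phi4 = phi4, phi22 = phi22),
            class = "kinship_spec")
}

#' @export
print.kinship_spec <- function(x, ...) {
  cat(sprintf("Kinship matrix for %d individuals%s\n", length(x$ids),
              if (!is.null(x$phi3)) " (with higher-order coefficients)" else ""))
  print(round(x$K, 6))
  invisible(x)
}

#' Read / write a labeled kinship matrix TSV
#'
#' The format is a square tab-separated matrix whose first row and first
#' column carry the sample ids.  Written at full double precision so that
#' `read_kinship(write_kinship(K, f))` round-trips exactly; on reading,
#' asymmetry beyond 1e-9 is an error and smaller asymmetry is symmetrized.
#'
#' @param path File path.
#' @return `read_kinship` returns a [kinship_spec()]; `write_kinship`
#'   returns `path` invisibly.
#' @export
read_kinship <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(tab)
  if (nrow(K) != ncol(K)) stop("kinship TSV is not square")
  if (!identical(rownames(K), colnames(K))) {
    stop("kinship TSV row and column labels mismatch")
  }
  kinship_spec(K)
}

#' @param K A [kinship_spec()] or a plain labeled symmetric matrix.
#' @rdname read_kinship
#' @export
write_kinship <- function(K, path) {
  if (inherits(K, "kinship_spec")) K <- K$K
  df <- as.data.frame(K)
  out <- cbind(id = rownames(K), df)
  # full precision: format doubles with 17 significant digits
  for (j in seq_along(out)[-1L]) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
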