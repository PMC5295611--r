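# Genotype container for one locus and the allele-fraction matrix X.

#' Genotype sample at one locus
#'
#' Stores, for each individual, its ploidy \eqn{m_k} and its list of allele
#' labels at a single locus.  Allele labels are arbitrary strings
#' (microsatellite repeat counts, SNP bases, ...); `NA` marks a missing
#' allele call.  The allele universe is the union of observed alleles and
#' any additionally declared alleles (needed e.g. to harmonize allele sets
#' across populations), in a stable order.
#'
#' @param ids Character vector of individual ids.
#' @param alleles List with one character vector per individual; each of
#'   length equal to that individual's ploidy.
#' @param ploidies Integer vector of ploidies; default is the allele vector
#'   lengths.
#' @param locus Locus identifier.
#' @param allele_universe Optional character vector of allele labels to
#'   include even if unobserved.
#' @return An object of class `genotype_sample`.
#' @examples
#' g <- genotype_sample(c("a", "b"), list(c("A", "B"), c("A", "A")))
#' allele_fractions(g)
#' @export
genotype_sample <- function(ids, alleles, ploidies = NULL, locus = "locus1",
                            allele_universe = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated individual ids in genotype sample")
  if (length(alleles) != length(ids)) stop("one allele vector per individual required")
  alleles <- lapply(alleles, as.character)
  if (is.null(ploidies)) ploidies <- lengths(alleles)
  ploidies <- as.integer(ploidies)
  if (any(ploidies < 1L)) stop("ploidies must be positive integers")
  bad <- lengths(alleles) != ploidies
  if (any(bad)) {
    stop("allele list length does not equal ploidy for: ",
         paste(ids[bad], collapse = ", "))
  }
  observed <- unique(unlist(alleles, use.names = FALSE))
  observed <- observed[!is.na(observed)]
  universe <- unique(c(observed, as.character(allele_universe)))
  structure(list(ids = ids, ploidies = ploidies, alleles = alleles,
                 locus = locus, allele_universe = universe),
            class = "genotype_sample")
}

#' @export
print.genotype_sample <- function(x, ...) {
  cat(sprintf("Genotype sample at %s: %d individuals, %d alleles\n",
              x$locus, length(x$ids), length(x$allele_universe)))
  geno <- vapply(x$alleles, function(a) paste(ifelse(is.na(a), ".", a),
                                              collapse = "/"), "")
  print(data.frame(id = x$ids, ploidy = x$ploidies, genotype = geno),
        row.names = FALSE)
  invisible(x)
}

#' Number of individuals in a genotype sample
#' @param sample A [genotype_sample()].
#' @return Integer count.
#' @export
n_individuals <- function(sample) length(sample$ids)

#' Total allele copies in a genotype sample
#' @param sample A [genotype_sample()].
#' @return Integer sum of ploidies.
#' @export
n_allele_copies <- function(sample) sum(sample$ploidies)

#' Drop individuals with missing allele calls
#'
#' The missing-data policy: an individual with any missing allele at the
#' locus is removed from that locus's sample; downstream weights (including
#' BLUE weights via the matching principal submatrix of K) are then
#' recomputed on the retained set.
#'
#' @param sample A [genotype_sample()].
#' @return A complete [genotype_sample()] (allele universe preserved).
#' @export
drop_missing <- function(sample) {
  stopifnot(inherits(sample, "genotype_sample"))
  keep <- !vapply(sample$alleles, anyNA, TRUE)
  if (all(keep)) return(sample)
  genotype_sample(sample$ids[keep], sample$alleles[keep],
                  sample$ploidies[keep], sample$locus,
                  allele_universe = sample$allele_universe)
}

#' Subset a genotype sample by individual ids
#' @param sample A [genotype_sample()].
#' @param ids Ids to retain (order preserved as given).
#' @return A [genotype_sample()].
#' @export
subset_sample <- function(sample, ids) {
  idx <- match(ids, sample$ids)
  if (anyNA(idx)) stop("unknown id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  genotype_sample(sample$ids[idx], sample$alleles[idx], sample$ploidies[idx],
                  sample$locus, allele_universe = sample$allele_universe)
}

#' Allele-fraction matrix X
#'
#' Row `k` holds \eqn{X_k^{(i)}}, the fraction of individual `k`'s allele
#' copies that are of type `i`; rows sum to 1 and entries are multiples of
#' \eqn{1/m_k}.  Genotypes must be complete (apply [drop_missing()] first).
#'
#' @param sample A [genotype_sample()].
#' @return Numeric matrix, individuals x alleles, with dimnames.
#' @export
allele_fractions <- function(sample) {
  stopifnot(inherits(sample, "genotype_sample"))
  if (any(vapply(sample$alleles, anyNA, TRUE))) {
    stop("missing allele calls present; apply drop_missing() first")
  }
  alleles <- sample$allele_universe
  X <- matrix(0, length(sample$ids), length(alleles),
              dimnames = list(sample$ids, alleles))
  for (k in seq_along(sample$ids)) {
    tab <- table(factor(sample$alleles[[k]], levels = alleles))
    X[k, ] <- as.numeric(tab) / sample$ploidies[k]
  }
  X
}
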