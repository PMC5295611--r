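# Synthetic genotype samples with specified relatedness structure, and the
# Monte Carlo bias/variance/MSE experiment machinery.
#
# Each catalogued relative-pair type is realized by a small template
# pedigree.  Founder alleles are drawn i.i.d. from a parametric locus
# spectrum and dropped through the template, so the sampled pair carries
# exactly the identity-by-descent structure of the pedigree -- including
# inbred and X-linked configurations that simple allele-copying cannot
# capture.

#' Deterministic seed splitting
#'
#' Derives `n` independent sub-seeds from a master seed, so that composite
#' simulations (multiple loci, two populations) are reproducible from a
#' single integer.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`, each below 2^31.
#' @export
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Relative-pair specification
#'
#' One homogeneous group of a sampling design: `count` pairs (or
#' singletons) of the given type.  Catalogued types and their pairwise
#' kinship coefficients: `parent_offspring` (1/4), `full_sib_outbred`
#' (1/4), `full_sib_inbred_sibmating` (3/8, full siblings whose parents are
#' brother and sister), `avuncular` (1/8), and at an X-linked locus
#' `mm_xlinked` (1/2), `mf_xlinked` (1/4), `ff_xlinked` (3/8);
#' `unrelated_singleton` adds lone individuals.
#'
#' @param type One of the catalogued pair types.
#' @param count Non-negative number of pairs (or singletons) of this type.
#' @return An object of class `pair_spec`.
#' @export
pair_spec <- function(type = c("parent_offspring", "full_sib_outbred",
                               "full_sib_inbred_sibmating", "avuncular",
                               "mm_xlinked", "mf_xlinked", "ff_xlinked",
                               "unrelated_singleton"),
                      count = 1L) {
  type <- match.arg(type)
  count <- as.integer(count)
  if (count < 0L) stop("count must be non-negative")
  structure(list(type = type, count = count), class = "pair_spec")
}

.x_types <- c("mm_xlinked", "mf_xlinked", "ff_xlinked")

.template_defs <- list(
  unrelated_singleton = list(
    rows = data.frame(id = "X1", father = NA, mother = NA, sex = "F"),
    members = "X1"),
  parent_offspring = list(
    rows = data.frame(id = c("P", "Q", "C"), father = c(NA, NA, "P"),
                      mother = c(NA, NA, "Q"), sex = c("M", "F", "F")),
    members = c("P", "C")),
  full_sib_outbred = list(
    rows = data.frame(id = c("F", "M", "S1", "S2"),
                      father = c(NA, NA, "F", "F"),
                      mother = c(NA, NA, "M", "M"), sex = c("M", "F", "F", "F")),
    members = c("S1", "S2")),
  full_sib_inbred_sibmating = list(
    rows = data.frame(id = c("GF", "GM", "PB", "PS", "C1", "C2"),
                      father = c(NA, NA, "GF", "GF", "PB", "PB"),
                      mother = c(NA, NA, "GM", "GM", "PS", "PS"),
                      sex = c("M", "F", "M", "F", "F", "F")),
    members = c("C1", "C2")),
  avuncular = list(
    rows = data.frame(id = c("GF", "GM", "A1", "A2", "SP", "N"),
                      father = c(NA, NA, "GF", "GF", NA, "SP"),
                      mother = c(NA, NA, "GM", "GM", NA, "A2"),
                      sex = c("M", "F", "F", "F", "M", "F")),
    members = c("A1", "N")),
  mm_xlinked = list(
    rows = data.frame(id = c("F", "M", "S1", "S2"),
                      father = c(NA, NA, "F", "F"),
                      mother = c(NA, NA, "M", "M"), sex = c("M", "F", "M", "M")),
    members = c("S1", "S2")),
  mf_xlinked = list(
    rows = data.frame(id = c("F", "M", "S1", "S2"),
                      father = c(NA, NA, "F", "F"),
                      mother = c(NA, NA, "M", "M"), sex = c("M", "F", "M", "F")),
    members = c("S1", "S2")),
  ff_xlinked = list(
    rows = data.frame(id = c("F", "M", "S1", "S2"),
                      father = c(NA, NA, "F", "F"),
                      mother = c(NA, NA, "M", "M"), sex = c("M", "F", "F", "F")),
    members = c("S1", "S2"))
)

.pair_template <- function(type) {
  def <- .template_defs[[type]]
  if (is.null(def)) stop("uncatalogued pair type: ", type)
  list(ped = build_pedigree(def$rows), members = def$members,
       pair = length(def$members) == 2L)
}

#' Assemble a sampling design from pair specifications
#'
#' Expands a list of [pair_spec()]s into the concrete design: individual
#' ids, ploidies, the analytic block-diagonal kinship matrix (assembled
#' from the template-pair kinship coefficients, not re-estimated per
#' replicate), the relative-pair list, and the allele-copy and BLUE weight
#' vectors.
#'
#' @param pair_specs A list of [pair_spec()]s (a single one is accepted).
#' @param mode `"autosomal"` or `"x_linked"`; X-linked pair types are only
#'   valid in `x_linked` mode and vice versa.
#' @return An object of class `relative_design`.
#' @examples
#' d <- relative_design(list(pair_spec("full_sib_outbred", 2)))
#' d$K$K
#' @export
relative_design <- function(pair_specs, mode = c("autosomal", "x_linked")) {
  mode <- match.arg(mode)
  if (inherits(pair_specs, "pair_spec")) pair_specs <- list(pair_specs)
  types <- vapply(pair_specs, function(s) s$type, "")
  if (mode == "autosomal" && any(types %in% .x_types)) {
    stop("X-linked pair types require mode = \"x_linked\"")
  }
  if (mode == "x_linked" &&
      any(!types %in% c(.x_types, "unrelated_singleton"))) {
    stop("autosomal pair types are not catalogued for mode = \"x_linked\"")
  }
  blocks <- list()
  b <- 0L
  for (s in pair_specs) {
    if (s$count == 0L) next
    tmpl <- .pair_template(s$type)
    km <- kinship_matrix(tmpl$ped, tmpl$members, mode = mode)
    for (i in seq_len(s$count)) {
      b <- b + 1L
      gids <- paste0(s$type, b, "_", tmpl$members)
      blocks[[b]] <- list(type = s$type, ped = tmpl$ped,
                          members = tmpl$members, ids = gids,
                          ploidies = km$ploidies, Kb = km$K,
                          pair = tmpl$pair)
    }
  }
  if (!length(blocks)) stop("design is empty")
  ids <- unlist(lapply(blocks, `[[`, "ids"))
  ploidies <- unlist(lapply(blocks, `[[`, "ploidies"))
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  at <- 1L
  for (blk in blocks) {
    span <- at:(at + length(blk$ids) - 1L)
    K[span, span] <- blk$Kb
    at <- at + length(blk$ids)
  }
  Kspec <- kinship_spec(K, ploidies = ploidies)
  pairs <- lapply(Filter(function(blk) blk$pair, blocks), `[[`, "ids")
  cw <- ploidies / sum(ploidies)
  structure(list(blocks = blocks, ids = ids, ploidies = ploidies, K = Kspec,
                 pairs = pairs, copy_weights = stats::setNames(cw, ids),
                 blue_weights = blue_weights(Kspec),
                 n_copies = sum(ploidies), mode = mode,
                 moments = NULL),
            class = "relative_design")
}

#' @export
print.relative_design <- function(x, ...) {
  tab <- table(vapply(x$blocks, `[[`, "", "type"))
  cat(sprintf("Relative-pair design (%s): %d individuals, %d allele copies\n",
              x$mode, length(x$ids), x$n_copies))
  for (t in names(tab)) cat(sprintf("  %s x %d\n", t, tab[[t]]))
  invisible(x)
}

#' Higher-order mean kinship coefficients of a design
#'
#' Computes the weighted mean kinship coefficients \eqn{\rho_2, \rho_3,
#' \rho_4, \rho_{2,2}} for a relative-pair design.  \eqn{\rho_2} is exact
#' (from the analytic kinship matrix).  The higher-order sums decompose over
#' blocks because alleles in different template pedigrees can never be IBD:
#' trio and quartet sums are sums of within-block gene-drop moments, and the
#' pair-of-pairs sum couples blocks only through the product of their exact
#' pairwise terms.  Within-block moments are estimated by Rao-Blackwellized
#' gene-dropping, cached across identical blocks.
#'
#' @param design A [relative_design()] (or a list of [pair_spec()]s).
#' @param weights `"copy"` (allele-copy proportions), `"blue"`, or a numeric
#'   vector over the design's individuals summing to 1.
#' @param reps Gene-drop replicates per unique block type.
#' @param seed Optional integer seed.
#' @param mode Locus mode, used when `design` is a list of specs.
#' @return A [mean_kinship_coeffs()] object.
#' @export
design_mean_kinship <- function(design, weights = "copy", reps = 20000,
                                seed = NULL,
                                mode = c("autosomal", "x_linked")) {
  if (!inherits(design, "relative_design")) {
    design <- relative_design(design, match.arg(mode))
  }
  w <- if (is.character(weights)) {
    switch(match.arg(weights, c("copy", "blue")),
           copy = design$copy_weights, blue = design$blue_weights)
  } else weights
  if (abs(sum(w) - 1) > 1e-12) stop("weights must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  rho2 <- drop(crossprod(w, design$K$K %*% w))
  rho3 <- rho4 <- 0
  sum_s22 <- 0        # sum over blocks of E[(sum_l v_l^2)^2]
  sum_s2sq <- 0       # sum over blocks of (exact within-block s2)^2
  cache <- new.env(parent = emptyenv())
  at <- 1L
  for (blk in design$blocks) {
    span <- at:(at + length(blk$ids) - 1L)
    at <- at + length(blk$ids)
    wb <- unname(w[span])
    s2_exact <- drop(crossprod(wb, blk$Kb %*% wb))
    key <- paste(blk$type, paste(signif(wb, 12), collapse = ","))
    mom <- cache[[key]]
    if (is.null(mom)) {
      idx <- match(blk$members, blk$ped$id)
      drop_ <- .gene_drop_labels(blk$ped, reps, design$mode)
      mm <- .u_moments(drop_, idx, wb, reps)
      mom <- colMeans(mm)
      cache[[key]] <- mom
    }
    rho3 <- rho3 + mom[["s3"]]
    rho4 <- rho4 + mom[["s4"]]
    sum_s22 <- sum_s22 + mom[["s22"]]
    sum_s2sq <- sum_s2sq + s2_exact^2
  }
  rho2_2 <- sum_s22 - sum_s2sq + rho2^2
  mean_kinship_coeffs(rho2, rho3, rho4, min(max(rho2_2, 0), 1),
                      weights = w, reps = reps)
}

#' Sample independent genotypes from a locus spectrum
#'
#' Every allele copy is drawn i.i.d. from the parametric allele frequency
#' distribution; individuals are mutually unrelated and outbred.
#'
#' @param spectrum A [locus_spectrum()] (or frequency vector).
#' @param n Number of individuals.
#' @param ploidies Per-individual ploidies (recycled; default diploid).
#' @param seed Optional integer seed.
#' @return A [genotype_sample()].
#' @export
sample_independent_genotypes <- function(spectrum, n, ploidies = 2L,
                                         seed = NULL) {
  if (!inherits(spectrum, "locus_spectrum")) spectrum <- locus_spectrum(spectrum)
  if (!is.null(seed)) set.seed(seed)
  ploidies <- rep_len(as.integer(ploidies), n)
  labs <- names(spectrum$p)
  draws <- sample(labs, sum(ploidies), replace = TRUE, prob = spectrum$p)
  alleles <- split(draws, rep(seq_len(n), ploidies))
  genotype_sample(paste0("ind", seq_len(n)), unname(alleles), ploidies,
                  allele_universe = labs)
}

#' Simulate a relative of a diploid genotype by allele copying
#'
#' Draws the number of alleles shared identical by descent (0, 1, or 2)
#' from the pair type's sharing distribution -- parent-offspring `(0, 1, 0)`,
#' outbred full siblings `(1/4, 1/2, 1/4)`, avuncular `(1/2, 1/2, 0)` --
#' copies that many alleles from the proband, and fills the rest i.i.d.
#' from the spectrum.  Inbred and X-linked pair types are not expressible
#' through two-gene sharing probabilities and must be generated with
#' [gene_drop_sample()] instead.
#'
#' @param proband Character vector of 2 allele labels.
#' @param pair_type `"parent_offspring"`, `"full_sib_outbred"` or
#'   `"avuncular"`.
#' @param spectrum A [locus_spectrum()] (or frequency vector).
#' @param seed Optional integer seed.
#' @return Character vector of 2 allele labels for the relative.
#' @export
simulate_relative <- function(proband,
                              pair_type = c("parent_offspring",
                                            "full_sib_outbred", "avuncular"),
                              spectrum, seed = NULL) {
  pair_type <- tryCatch(match.arg(pair_type), error = function(e) {
    stop("pair type not catalogued for allele copying (inbred and X-linked ",
         "types require gene_drop_sample())")
  })
  if (length(proband) != 2L) stop("proband must be a diploid genotype (2 alleles)")
  if (!inherits(spectrum, "locus_spectrum")) spectrum <- locus_spectrum(spectrum)
  if (!is.null(seed)) set.seed(seed)
  probs <- switch(pair_type,
                  parent_offspring = c(0, 1, 0),
                  full_sib_outbred = c(1 / 4, 1 / 2, 1 / 4),
                  avuncular = c(1 / 2, 1 / 2, 0))
  shared <- sample(0:2, 1L, prob = probs)
  copied <- if (shared == 0L) character(0) else
    proband[sample.int(2L, shared)]
  fresh <- sample(names(spectrum$p), 2L - shared, replace = TRUE,
                  prob = spectrum$p)
  c(copied, fresh)
}

# Gene-drop genotype states for a whole design, vectorized across reps.
# Returns A: reps x n_copies matrix of allele indices into spectrum$p, plus
# the copy -> individual map.
.simulate_design_states <- function(design, spectrum, reps) {
  I <- length(spectrum$p)
  copy_ind <- rep(seq_along(design$ids), design$ploidies)
  A <- matrix(0L, reps, design$n_copies)
  col <- 1L
  for (blk in design$blocks) {
    drop_ <- .gene_drop_labels(blk$ped, reps, design$mode)
    L <- drop_$n_labels
    # i.i.d. founder allele states per replicate and founder label
    S <- matrix(sample.int(I, reps * L, replace = TRUE, prob = spectrum$p),
                reps, L)
    midx <- match(blk$members, blk$ped$id)
    for (a in midx) {
      lab <- drop_$labels[[a]]
      for (cpy in seq_len(ncol(lab))) {
        A[, col] <- S[cbind(seq_len(reps), lab[, cpy])]
        col <- col + 1L
      }
    }
  }
  list(A = A, copy_ind = copy_ind)
}

#' Gene-drop a genotype sample with a specified relatedness structure
#'
#' Draws founder alleles i.i.d. from the spectrum and transmits them through
#' each pair's template pedigree, so the returned genotypes carry exactly
#' the identity-by-descent structure of the design (including inbred and
#' X-linked pair types; X-linked males receive a single allele).
#'
#' @param pair_specs A list of [pair_spec()]s, or a [relative_design()].
#' @param spectrum A [locus_spectrum()] (or frequency vector).
#' @param seed Optional integer seed.
#' @param mode `"autosomal"` or `"x_linked"` (when specs are given).
#' @return A [genotype_sample()] whose ids match the design's.
#' @export
gene_drop_sample <- function(pair_specs, spectrum, seed = NULL,
                             mode = c("autosomal", "x_linked")) {
  design <- if (inherits(pair_specs, "relative_design")) pair_specs
            else relative_design(pair_specs, match.arg(mode))
  if (!inherits(spectrum, "locus_spectrum")) spectrum <- locus_spectrum(spectrum)
  if (!is.null(seed)) set.seed(seed)
  sim <- .simulate_design_states(design, spectrum, reps = 1L)
  labs <- names(spectrum$p)
  alleles <- split(labs[sim$A[1L, ]], sim$copy_ind)
  genotype_sample(design$ids, unname(alleles), design$ploidies,
                  allele_universe = labs)
}

# Per-replicate frequency matrices for the design: sample-proportion, BLUE
# and (optionally) reduced-sample frequencies.  A is reps x copies.
.replicate_frequencies <- function(design, A, reps, want_red = TRUE) {
  I <- max(1L, max(A))
  copy_ind <- rep(seq_along(design$ids), design$ploidies)
  N <- design$n_copies
  cw_hat <- rep(1 / N, N)
  cw_blue <- (design$blue_weights / design$ploidies)[copy_ind]
  P_hat <- P_blue <- matrix(0, reps, I)
  keep <- NULL
  P_red <- NULL
  N_red <- NULL
  if (want_red) {
    keep <- matrix(TRUE, reps, N)
    for (pair in design$pairs) {
      pi_ <- match(pair, design$ids)
      m <- design$ploidies[pi_]
      cols1 <- which(copy_ind == pi_[1L])
      cols2 <- which(copy_ind == pi_[2L])
      if (m[1L] != m[2L]) {
        drop_cols <- if (m[1L] < m[2L]) cols1 else cols2
        keep[, drop_cols] <- FALSE
      } else {
        r <- stats::runif(reps) < 0.5
        keep[, cols1] <- r
        keep[, cols2] <- !r
      }
    }
    N_red <- rowSums(keep)[1L]  # constant across replicates by construction
    P_red <- matrix(0, reps, I)
  }
  for (i in seq_len(I)) {
    hit <- A == i
    P_hat[, i] <- hit %*% cw_hat
    P_blue[, i] <- hit %*% cw_blue
    if (want_red) P_red[, i] <- (hit & keep) %*% rep(1 / N_red, N)
  }
  list(P_hat = P_hat, P_blue = P_blue, P_red = P_red, N = N, N_red = N_red)
}

.estimator_tags <- c("h_hat_full", "h_hat_red", "h_tilde", "h_blue")

# Replicate estimator values from the frequency matrices.
.replicate_heterozygosities <- function(design, fr, estimators) {
  out <- list()
  if ("h_hat_full" %in% estimators) {
    out$h_hat_full <- fr$N / (fr$N - 1) * (1 - rowSums(fr$P_hat^2))
  }
  if ("h_hat_red" %in% estimators) {
    out$h_hat_red <- fr$N_red / (fr$N_red - 1) * (1 - rowSums(fr$P_red^2))
  }
  if ("h_tilde" %in% estimators) {
    w <- design$copy_weights
    phibar2 <- drop(crossprod(w, design$K$K %*% w))
    out$h_tilde <- (1 - rowSums(fr$P_hat^2)) / (1 - phibar2)
  }
  if ("h_blue" %in% estimators) {
    w <- design$blue_weights
    kappa2 <- drop(crossprod(w, design$K$K %*% w))
    out$h_blue <- (1 - rowSums(fr$P_blue^2)) / (1 - kappa2)
  }
  out
}

#' Monte Carlo bias/variance/MSE experiment over heterozygosity estimators
#'
#' Repeatedly gene-drops a sampling design at a locus with known parametric
#' frequencies and evaluates the selected estimators on every replicate.
#' The reduced-sample estimator removes a fresh random member of each
#' same-ploidy pair per replicate (the haploid member, deterministically,
#' for mixed-ploidy pairs).  Identical seeds give identical output.
#'
#' @param pair_specs A list of [pair_spec()]s, or a [relative_design()].
#' @param spectrum A [locus_spectrum()] (or frequency vector).
#' @param estimators Subset of `"h_hat_full"`, `"h_hat_red"`, `"h_tilde"`,
#'   `"h_blue"`.
#' @param reps Number of replicates (>= 2).
#' @param seed Optional integer seed.
#' @param mode `"autosomal"` or `"x_linked"` (when specs are given).
#' @param keep_values Keep the reps x estimator matrix of raw values.
#' @return An object of class `experiment_result`: a summary data frame
#'   (replicate mean, empirical bias, population variance, MSE = bias^2 +
#'   variance, and Monte Carlo standard errors of mean/variance/MSE), the
#'   frequency-estimate mean squared errors for the sample-proportion and
#'   BLUE estimators, the true `H`, `reps`, `seed` and the design.
#' @examples
#' r <- run_experiment(list(pair_spec("full_sib_outbred", 5)),
#'                     locus_spectrum(c(0.5, 0.5)), reps = 200, seed = 7)
#' r$summary
#' @export
run_experiment <- function(pair_specs, spectrum,
                           estimators = .estimator_tags,
                           reps = 1000, seed = NULL,
                           mode = c("autosomal", "x_linked"),
                           keep_values = FALSE) {
  estimators <- match.arg(estimators, .estimator_tags, several.ok = TRUE)
  design <- if (inherits(pair_specs, "relative_design")) pair_specs
            else relative_design(pair_specs, match.arg(mode))
  if (!inherits(spectrum, "locus_spectrum")) spectrum <- locus_spectrum(spectrum)
  if (reps < 2) stop("reps must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  sim <- .simulate_design_states(design, spectrum, reps)
  fr <- .replicate_frequencies(design, sim$A, reps,
                               want_red = "h_hat_red" %in% estimators)
  vals <- .replicate_heterozygosities(design, fr, estimators)
  H <- spectrum$H

  summarize <- function(x) {
    mu <- mean(x)
    v <- mean((x - mu)^2)             # population variance: MSE identity exact
    m4 <- mean((x - mu)^4)
    err2 <- (x - H)^2
    c(mean = mu, bias = mu - H, variance = v, mse = (mu - H)^2 + v,
      se_mean = stats::sd(x) / sqrt(reps),
      se_var = sqrt(max(m4 - v^2, 0) / reps),
      se_mse = stats::sd(err2) / sqrt(reps))
  }
  summary <- as.data.frame(t(vapply(vals, summarize, numeric(7))))
  summary <- cbind(estimator = rownames(summary), summary)
  rownames(summary) <- NULL

  ptrue <- spectrum$p
  pad <- function(P) { # frequency matrices may lack trailing unobserved alleles
    if (ncol(P) < length(ptrue))
      P <- cbind(P, matrix(0, nrow(P), length(ptrue) - ncol(P)))
    P
  }
  freq_mse <- c(
    sample_proportion = mean(rowSums(sweep(pad(fr$P_hat), 2, ptrue)^2)),
    blue = mean(rowSums(sweep(pad(fr$P_blue), 2, ptrue)^2)))

  structure(list(summary = summary, freq_mse = freq_mse, true_H = H,
                 reps = reps, seed = seed, design = design,
                 values = if (keep_values) do.call(cbind, vals) else NULL),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Estimator experiment: %d replicates, true H = %.6g\n",
              x$reps, x$true_H))
  print(transform(x$summary,
                  mean = signif(mean, 6), bias = signif(bias, 4),
                  variance = signif(variance, 4), mse = signif(mse, 4),
                  se_mean = signif(se_mean, 3), se_var = signif(se_var, 3),
                  se_mse = signif(se_mse, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Grid of biallelic SNP spectra over a minor-allele-frequency range
#'
#' @param maf_min,maf_max Minor allele frequency range, `0 < maf_min <=
#'   maf_max <= 0.5`.
#' @param step Grid increment.
#' @return List of biallelic [locus_spectrum()]s `(m, 1 - m)` on the
#'   inclusive grid.
#' @examples
#' length(snp_locus_grid(0.01, 0.5, 0.01))  # 50
#' @export
snp_locus_grid <- function(maf_min, maf_max, step = 0.01) {
  if (!(maf_min > 0 && maf_min <= maf_max && maf_max <= 0.5)) {
    stop("need 0 < maf_min <= maf_max <= 0.5")
  }
  mafs <- seq(maf_min, maf_max + 1e-12, by = step)
  mafs <- mafs[mafs <= 0.5 + 1e-12]
  lapply(mafs, function(m) locus_spectrum(c(minor = m, major = 1 - m)))
}

#' Paired-population FST simulation experiment
#'
#' Gene-drops two independent sampling designs at a shared locus (allele
#' universes harmonized by position) and computes, per replicate and per
#' estimator family, the within-population heterozygosities, the
#' between-population heterozygosity built from the same family's frequency
#' estimates, and the resulting FST.
#'
#' @param pair_specs1,pair_specs2 Designs for the two populations.
#' @param spectrum1,spectrum2 Parametric spectra over the same allele list.
#' @param estimators Families, a subset of `"h_hat_full"`, `"h_hat_red"`,
#'   `"h_tilde"`, `"h_blue"`.
#' @param reps Replicates.
#' @param seed Optional integer seed (split deterministically between the
#'   two populations).
#' @param mode Locus mode.
#' @return An object of class `fst_experiment`: per-family replicate FST
#'   matrix `fst`, per-family component matrices (`H1`, `H2`, `H12`), the
#'   true FST and components, and both designs.
#' @export
fst_experiment <- function(pair_specs1, pair_specs2, spectrum1, spectrum2,
                           estimators = .estimator_tags, reps = 1000,
                           seed = NULL, mode = c("autosomal", "x_linked")) {
  mode <- match.arg(mode)
  estimators <- match.arg(estimators, .estimator_tags, several.ok = TRUE)
  if (!inherits(spectrum1, "locus_spectrum")) spectrum1 <- locus_spectrum(spectrum1)
  if (!inherits(spectrum2, "locus_spectrum")) spectrum2 <- locus_spectrum(spectrum2)
  if (length(spectrum1$p) != length(spectrum2$p)) {
    stop("spectra must share one allele universe (pad absent alleles with 0)")
  }
  d1 <- if (inherits(pair_specs1, "relative_design")) pair_specs1
        else relative_design(pair_specs1, mode)
  d2 <- if (inherits(pair_specs2, "relative_design")) pair_specs2
        else relative_design(pair_specs2, mode)
  if (!is.null(seed)) {
    seeds <- derive_seeds(seed, 2L)
  } else seeds <- c(NA, NA)

  one_pop <- function(design, spectrum, s) {
    if (!is.na(s)) set.seed(s)
    sim <- .simulate_design_states(design, spectrum, reps)
    fr <- .replicate_frequencies(design, sim$A, reps,
                                 want_red = "h_hat_red" %in% estimators)
    vals <- .replicate_heterozygosities(design, fr, estimators)
    I <- length(spectrum$p)
    pad <- function(P) if (is.null(P) || ncol(P) >= I) P else
      cbind(P, matrix(0, nrow(P), I - ncol(P)))
    list(vals = vals, P_hat = pad(fr$P_hat), P_blue = pad(fr$P_blue),
         P_red = pad(fr$P_red))
  }
  pop1 <- one_pop(d1, spectrum1, seeds[1L])
  pop2 <- one_pop(d2, spectrum2, seeds[2L])

  freq_of <- function(pop, fam) switch(fam,
    h_hat_full = , h_tilde = pop$P_hat,
    h_hat_red = pop$P_red, h_blue = pop$P_blue)
  fst <- components <- list()
  for (fam in estimators) {
    H12 <- 1 - rowSums(freq_of(pop1, fam) * freq_of(pop2, fam))
    H1 <- pop1$vals[[fam]]
    H2 <- pop2$vals[[fam]]
    components[[fam]] <- cbind(H1 = H1, H2 = H2, H12 = H12)
    fst[[fam]] <- (H12 - (H1 + H2) / 2) / H12
  }
  H1t <- spectrum1$H; H2t <- spectrum2$H
  H12t <- 1 - sum(spectrum1$p * spectrum2$p)
  structure(list(fst = fst, components = components,
                 true = list(H1 = H1t, H2 = H2t, H12 = H12t,
                             fst = (H12t - (H1t + H2t) / 2) / H12t),
                 design1 = d1, design2 = d2, reps = reps, seed = seed),
            class = "fst_experiment")
}

#' @export
print.fst_experiment <- function(x, ...) {
  cat(sprintf("FST experiment: %d replicates, true FST = %.6g\n",
              x$reps, x$true$fst))
  for (fam in names(x$fst)) {
    v <- x$fst[[fam]]
    cat(sprintf("  %-11s mean = %.6g  var = %.3g  mse = %.3g\n", fam,
                mean(v), stats::var(v), mean((v - x$true$fst)^2)))
  }
  invisible(x)
}
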