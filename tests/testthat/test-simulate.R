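test_that("independent genotype sampling honors the spectrum and the seed", {
  mono <- sample_independent_genotypes(1, 20, seed = 1)
  expect_true(all(unlist(mono$alleles) == "a1"))

  g <- sample_independent_genotypes(c(a = .5, b = .5), 10000, seed = 2)
  phat <- sample_proportion(g)$freq[["a"]]
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / 20000))

  g1 <- sample_independent_genotypes(c(a = .3, b = .7), 50, ploidies = c(1, 2),
                                     seed = 7)
  expect_identical(g1$ploidies, rep(c(1L, 2L), 25))
  g2 <- sample_independent_genotypes(c(a = .3, b = .7), 50, ploidies = c(1, 2),
                                     seed = 7)
  expect_identical(g1$alleles, g2$alleles)
})

test_that("allele copying realizes the catalogued IBD-sharing distributions", {
  # proband labels disjoint from the spectrum, so copies are identifiable
  sp <- locus_spectrum(c(a = .5, b = .3, c = .2))
  proband <- c("X", "Y")
  shared <- function(type, reps, seed) {
    set.seed(seed)
    vapply(seq_len(reps), function(i) {
      sum(simulate_relative(proband, type, sp) %in% proband)
    }, 0)
  }
  s_po <- shared("parent_offspring", 400, 61)
  expect_true(all(s_po == 1))  # exactly one allele always copied

  s_fs <- shared("full_sib_outbred", 4000, 62)
  kin_fs <- mean(s_fs) / 4   # empirical kinship = E[shared]/4
  expect_lt(abs(kin_fs - 1 / 4), 3 * sd(s_fs / 4) / sqrt(4000))

  s_av <- shared("avuncular", 4000, 63)
  expect_true(all(s_av <= 1))  # sharing two alleles impossible
  expect_lt(abs(mean(s_av) / 4 - 1 / 8), 3 * sd(s_av / 4) / sqrt(4000))

  expect_error(simulate_relative(proband, "full_sib_inbred_sibmating", sp),
               "gene_drop_sample")
  expect_error(simulate_relative("X", "avuncular", sp), "diploid")
})

test_that("copy method and pedigree gene drop give the same pair-genotype distribution", {
  sp <- locus_spectrum(c(a = .5, b = .3, c = .2))
  reps <- 4000
  design <- relative_design(list(pair_spec("full_sib_outbred", 1)))
  cat_gd <- character(reps)
  set.seed(71)
  for (r in seq_len(reps)) {
    g <- gene_drop_sample(design, sp)
    cat_gd[r] <- paste(sort(g$alleles[[1]]), collapse = "") |>
      paste(paste(sort(g$alleles[[2]]), collapse = ""), sep = "|")
  }
  cat_cp <- character(reps)
  set.seed(72)
  for (r in seq_len(reps)) {
    pro <- sample(names(sp$p), 2, replace = TRUE, prob = sp$p)
    rel <- simulate_relative(pro, "full_sib_outbred", sp)
    cat_cp[r] <- paste(sort(pro), collapse = "") |>
      paste(paste(sort(rel), collapse = ""), sep = "|")
  }
  lev <- union(unique(cat_gd), unique(cat_cp))
  tab <- rbind(table(factor(cat_gd, lev)), table(factor(cat_cp, lev)))
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 1e-3)
})

test_that("gene-dropped designs are reproducible and respect the mode", {
  specs <- list(pair_spec("full_sib_outbred", 2),
                pair_spec("unrelated_singleton", 1))
  sp <- locus_spectrum(c(a = .6, b = .4))
  g1 <- gene_drop_sample(specs, sp, seed = 5)
  g2 <- gene_drop_sample(specs, sp, seed = 5)
  expect_identical(g1$alleles, g2$alleles)
  expect_equal(n_individuals(g1), 5L)

  gx <- gene_drop_sample(list(pair_spec("mf_xlinked", 3)), sp, seed = 6,
                         mode = "x_linked")
  expect_identical(gx$ploidies, rep(c(1L, 2L), 3))
  expect_error(relative_design(list(pair_spec("mm_xlinked", 1))),
               "x_linked")
  expect_error(relative_design(list(pair_spec("avuncular", 1)),
                               mode = "x_linked"), "not catalogued")
})

test_that("the analytic design kinship matrix has the template block structure", {
  specs <- list(pair_spec("full_sib_inbred_sibmating", 10),
                pair_spec("full_sib_outbred", 10),
                pair_spec("avuncular", 10))
  d <- relative_design(specs)
  expect_equal(length(d$ids), 60L)
  expect_equal(length(d$pairs), 30L)
  expect_equal(sum(d$blue_weights), 1)
  w <- d$copy_weights
  phibar2 <- drop(crossprod(w, d$K$K %*% w))
  # hand-assembled: (10*(2*5/8 + 2*3/8) + 10*(2*.5 + 2*.25) + 10*(2*.5 + 2*.125))/3600
  expect_equal(phibar2, 47.5 / 3600)
})

test_that("experiments are deterministic and coherent", {
  sp <- locus_spectrum(rep(0.1, 10))
  specs <- list(pair_spec("avuncular", 5))
  r1 <- run_experiment(specs, sp, reps = 200, seed = 9, keep_values = TRUE)
  r2 <- run_experiment(specs, sp, reps = 200, seed = 9, keep_values = TRUE)
  expect_identical(r1$values, r2$values)
  expect_equal(r1$summary$mse,
               r1$summary$bias^2 + r1$summary$variance, tolerance = 1e-12)
  expect_true(all(r1$summary$se_mean > 0))

  # one relative-pair type: the two corrected estimators coincide replicate
  # by replicate (exchangeable weights)
  expect_equal(r1$values[, "h_tilde"], r1$values[, "h_blue"],
               tolerance = 1e-12)
  expect_error(run_experiment(specs, sp, reps = 1), "reps")
})

test_that("MSE falls with sample size and is lower for second-degree pairs", {
  sp <- locus_spectrum(rep(0.1, 10))
  ests <- c("h_hat_full", "h_tilde", "h_blue")
  get_mse <- function(specs, seed) {
    r <- run_experiment(specs, sp, estimators = ests, reps = 4000, seed = seed)
    stats::setNames(r$summary$mse, r$summary$estimator)
  }
  small_fs <- get_mse(list(pair_spec("full_sib_outbred", 5)), 81)
  large_fs <- get_mse(list(pair_spec("full_sib_outbred", 25)), 82)
  small_av <- get_mse(list(pair_spec("avuncular", 5)), 83)
  for (e in ests) {
    expect_lt(large_fs[[e]], small_fs[[e]])      # more pairs, lower MSE
    expect_lt(small_av[[e]], small_fs[[e]])      # second degree beats first
  }
})

test_that("the SNP locus grid spans the documented heterozygosity range", {
  grid <- snp_locus_grid(0.01, 0.5, 0.01)
  expect_length(grid, 50L)
  H <- vapply(grid, `[[`, 0, "H")
  expect_equal(H[1], 0.0198)
  expect_equal(H[50], 0.5)
  expect_true(all(diff(H) > 0))
  expect_length(snp_locus_grid(0.5, 0.5), 1L)
  expect_error(snp_locus_grid(0, 0.5), "maf")
  expect_error(snp_locus_grid(0.2, 0.1), "maf")
})
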