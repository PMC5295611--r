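test_that("parametric heterozygosity matches the closed form", {
  expect_equal(true_heterozygosity(c(0.15, 0.85)), 0.255)
  expect_equal(true_heterozygosity(c(0.05, 0.95)), 0.095)
  expect_equal(true_heterozygosity(c(0.01, 0.99)), 0.0198)
  expect_equal(true_heterozygosity(1), 0)
  expect_error(locus_spectrum(c(0.5, 0.6)), "sum to 1")
  sp <- locus_spectrum(rep(0.1, 10))
  expect_lte(sp$H, 1 - 1 / sp$I)
})

test_that("the classical estimator follows its closed form", {
  expect_equal(h_hat(genotype_sample("a", list(c("A", "B"))))$value, 1)
  expect_equal(h_hat(genotype_sample(c("a", "b"),
                                     list(c("A", "A"), c("A", "A"))))$value, 0)
  expect_equal(h_hat(genotype_sample(c("a", "b"),
                                     list(c("A", "B"), c("A", "B"))))$value,
               2 / 3)
  expect_error(h_hat(genotype_sample("a", list("A"), ploidies = 1)),
               "2 allele copies")
})

test_that("kinship-corrected estimators reproduce hand-computed values", {
  fsK <- kinship_spec(matrix(c(.5, .25, .25, .5), 2,
                             dimnames = list(c("a", "b"), c("a", "b"))))
  fs <- genotype_sample(c("a", "b"), list(c("A", "B"), c("A", "B")))
  expect_equal(h_tilde(fs, fsK)$value, 0.8)     # (1 - 1/2)/(1 - 3/8)
  expect_equal(h_blue(fs, fsK)$value, 0.8)      # kappa2 = 3/8 by symmetry

  solo <- genotype_sample("a", list(c("A", "B")))
  expect_equal(h_tilde(solo, kinship_spec(matrix(.5, 1, 1,
                                                 dimnames = list("a", "a"))))$value, 1)

  # specializations of the general estimator
  w <- fs$ploidies / sum(fs$ploidies)
  expect_equal(h_general(fs, w, 3 / 8)$value, h_tilde(fs, fsK)$value)
  expect_equal(h_general(fs, blue_weights(fsK), 3 / 8)$value,
               h_blue(fs, fsK)$value)
  mono <- genotype_sample(c("a", "b"), list(c("A", "A"), c("A", "A")))
  expect_equal(h_general(mono, c(.5, .5), 3 / 8)$value, 0)
  expect_error(h_general(solo, 1, 1), "rho2")

  expect_error(h_blue(fs, matrix(c(.5, .5, .5, .5), 2)),
               "singular|non-invertible")
})

test_that("corrected and classical estimators coincide on unrelated samples", {
  # any ploidy mix: Phi-bar-2 = 1/(total copies), so the corrections agree
  g <- genotype_sample(c("h1", "d1", "d2", "t1"),
                       list("A", c("A", "B"), c("B", "B"), c("A", "A", "B", "B")),
                       ploidies = c(1, 2, 2, 4))
  K <- kinship_spec(diag(1 / g$ploidies),
                    ids = g$ids, ploidies = g$ploidies)
  expect_equal(h_tilde(g, K)$value, h_hat(g)$value, tolerance = 1e-12)
  expect_equal(h_blue(g, K)$value, h_hat(g)$value, tolerance = 1e-12)
})

test_that("estimators are invariant to allele relabeling and individual order", {
  K <- kinship_spec(matrix(c(.5, .25, 0, .25, .5, 0, 0, 0, .5), 3,
                           dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))
  g1 <- genotype_sample(c("a", "b", "c"),
                        list(c("A", "B"), c("B", "B"), c("A", "C")))
  relabel <- c(A = "z9", B = "q1", C = "m5")
  g2 <- genotype_sample(c("c", "a", "b"),
                        list(relabel[c("A", "C")], relabel[c("A", "B")],
                             relabel[c("B", "B")]))
  for (f in list(h_hat, function(g) h_tilde(g, K), function(g) h_blue(g, K))) {
    expect_equal(f(g1)$value, f(g2)$value, tolerance = 1e-12)
  }
})

test_that("the reduced-sample estimator removes one member per pair", {
  g <- genotype_sample(paste0("i", 1:4),
                       list(c("A", "B"), c("A", "B"), c("A", "A"), c("B", "B")))
  expect_equal(h_hat_reduced(g)$value, h_hat(g)$value)  # no pairs

  # mixed-ploidy pair at an X-linked locus: the haploid male is removed
  x <- genotype_sample(c("son", "daughter"), list("A", c("A", "B")),
                       ploidies = c(1, 2))
  red <- h_hat_reduced(x, list(c("son", "daughter")))
  expect_identical(attr(red, "retained"), "daughter")
  expect_equal(red$value, 1)  # h_hat on the daughter's 2 copies

  pairs <- list(c("i1", "i2"), c("i3", "i4"))
  r1 <- h_hat_reduced(g, pairs, seed = 5)
  r2 <- h_hat_reduced(g, pairs, seed = 5)
  expect_identical(attr(r1, "retained"), attr(r2, "retained"))
  expect_equal(length(attr(r1, "retained")), 2L)  # n - #pairs

  expect_error(h_hat_reduced(g, list(c("i1", "i2"), c("i2", "i3"))),
               "overlap")
  expect_error(h_hat_reduced(g, list(c("i1", "zz"))), "absent")
})

test_that("the bias formula for the classical estimator behaves", {
  expect_equal(bias_h_hat(0.5, 10, 1 / 10), 0)   # unrelated outbred
  expect_equal(bias_h_hat(0.6, 4, 3 / 8), -0.6 / 6)  # full-sib pair
  expect_equal(bias_h_hat(0, 8, 0.3), 0)
  expect_error(bias_h_hat(0.5, 1, 0.1))
})

test_that("mse composes squared bias and variance", {
  expect_equal(mse(0, 0.3), 0.3)
  expect_equal(mse(-0.2, 0), 0.04)
  expect_equal(mse(-0.5 / 6, 0.01), 0.25 / 36 + 0.01)
  expect_error(mse(0.1, -1))
})
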