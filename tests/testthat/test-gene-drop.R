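se3 <- function(x) max(3 * x[["se"]], 1e-3)  # 3 MC standard errors, floored

test_that("gene-drop pair coefficients agree with the recursion", {
  cases <- list(
    list(ped = ped_full_sib(), ids = c("S1", "S2"), mode = "autosomal",
         phi = 1 / 4),
    list(ped = ped_avuncular(), ids = c("A1", "N"), mode = "autosomal",
         phi = 1 / 8),
    list(ped = ped_inbred_full_sib(), ids = c("C1", "C2"), mode = "autosomal",
         phi = 3 / 8),
    list(ped = ped_parent_offspring(), ids = c("P", "C"), mode = "autosomal",
         phi = 1 / 4),
    list(ped = ped_full_sib(c("M", "M")), ids = c("S1", "S2"),
         mode = "x_linked", phi = 1 / 2),
    list(ped = ped_full_sib(c("M", "F")), ids = c("S1", "S2"),
         mode = "x_linked", phi = 1 / 4),
    list(ped = ped_full_sib(c("F", "F")), ids = c("S1", "S2"),
         mode = "x_linked", phi = 3 / 8))
  for (cs in cases) {
    gd <- gene_drop_identity_coeffs(cs$ped, cs$ids, reps = 20000,
                                    seed = 101, mode = cs$mode)
    expect_lt(abs(gd$phi2[["estimate"]] - cs$phi), se3(gd$phi2))
    expect_equal(gd$phi2[["estimate"]],
                 gene_drop_identity_coeffs(cs$ped, cs$ids, reps = 20000,
                                           seed = 101, mode = cs$mode)$phi2[["estimate"]])
  }
  # founders carry distinct labels: exactly zero
  gd0 <- gene_drop_identity_coeffs(ped_full_sib(), c("F", "M"), reps = 500,
                                   seed = 1)
  expect_identical(gd0$phi2[["estimate"]], 0)
})

test_that("gene-drop tuple coefficients match exhaustive meiosis enumeration", {
  arr <- enum_fullsib_arrays()
  # exact values for the sib pair, derived from the 16 meiosis outcomes
  expect_equal(arr$phi2, matrix(c(.5, .25, .25, .5), 2))
  expect_equal(arr$phi3[1, 2, 1], 1 / 8)
  expect_equal(arr$phi4[1, 2, 1, 2], 1 / 16)
  expect_equal(arr$phi22[1, 2, 1, 2], 3 / 32)

  gd <- gene_drop_identity_coeffs(ped_full_sib(), c("S1", "S2", "S1", "S2"),
                                  reps = 30000, seed = 7)
  expect_lt(abs(gd$phi2[["estimate"]] - arr$phi2[1, 2]), se3(gd$phi2))
  expect_lt(abs(gd$phi3[["estimate"]] - arr$phi3[1, 2, 1]), se3(gd$phi3))
  expect_lt(abs(gd$phi4[["estimate"]] - arr$phi4[1, 2, 1, 2]), se3(gd$phi4))
  expect_lt(abs(gd$phi22[["estimate"]] - arr$phi22[1, 2, 1, 2]), se3(gd$phi22))

  expect_error(gene_drop_identity_coeffs(ped_full_sib(), "S1"), "2 to 4")
  expect_error(gene_drop_identity_coeffs(ped_full_sib(), c("S1", "S2"),
                                         reps = 0), "reps")
})

test_that("mean kinship weighted sums match hand computation", {
  # n unrelated outbred diploids, equal weights: rho2 = 1/(2n)
  n <- 5
  Ku <- kinship_spec(diag(n) / 2)
  expect_equal(mean_kinship(Ku, rep(1 / n, n))$rho2, 1 / (2 * n))

  # one outbred full-sib pair: (1/4)(1/2 + 1/4 + 1/4 + 1/2) = 3/8
  Kfs <- kinship_spec(matrix(c(.5, .25, .25, .5), 2))
  expect_equal(mean_kinship(Kfs, c(.5, .5))$rho2, 3 / 8)

  # all weight on one outbred diploid: self-kinship only
  expect_equal(mean_kinship(Kfs, c(1, 0))$rho2, 1 / 2)

  expect_error(mean_kinship(Kfs, c(.6, .6)), "sum to 1")
  expect_error(mean_kinship(Kfs, c(.5, .5), require_higher = TRUE),
               "higher-order")
})

test_that("exact enumeration, direct gene drop and block assembly agree on rho sums", {
  arr <- enum_fullsib_arrays()
  Kfs <- kinship_spec(arr$phi2, phi3 = arr$phi3, phi4 = arr$phi4,
                      phi22 = arr$phi22)
  exact <- mean_kinship(Kfs, c(.5, .5), require_higher = TRUE)
  expect_equal(exact$rho2, 3 / 8)
  expect_equal(exact$rho3, 5 / 32)
  expect_equal(exact$rho4, 9 / 128)
  expect_equal(exact$rho2_2, 19 / 128)

  mc <- gene_drop_mean_kinship(ped_full_sib(), c("S1", "S2"), c(.5, .5),
                               reps = 30000, seed = 11)
  for (f in c("rho2", "rho3", "rho4", "rho2_2")) {
    expect_lt(abs(mc[[f]] - exact[[f]]), max(3 * mc$se[[
      c(rho2 = "s2", rho3 = "s3", rho4 = "s4", rho2_2 = "s22")[[f]]]], 1e-3))
  }

  dk <- design_mean_kinship(list(pair_spec("full_sib_outbred", 1)),
                            weights = "copy", reps = 30000, seed = 12)
  expect_equal(dk$rho2, exact$rho2)  # rho2 comes from the analytic K
  expect_lt(abs(dk$rho3 - exact$rho3), 2e-3)
  expect_lt(abs(dk$rho4 - exact$rho4), 2e-3)
  expect_lt(abs(dk$rho2_2 - exact$rho2_2), 2e-3)
})

test_that("block-assembled design coefficients match a direct multi-family gene drop", {
  specs <- list(pair_spec("full_sib_outbred", 2), pair_spec("avuncular", 1))
  design <- relative_design(specs)
  dk <- design_mean_kinship(design, weights = "copy", reps = 60000, seed = 21)

  big <- combine_pedigrees(
    list(ped_full_sib(), ped_full_sib(), ped_avuncular()),
    c("fam1_", "fam2_", "fam3_"))
  ids <- c("fam1_S1", "fam1_S2", "fam2_S1", "fam2_S2", "fam3_A1", "fam3_N")
  direct <- gene_drop_mean_kinship(big, ids, rep(1 / 6, 6), reps = 60000,
                                   seed = 22)
  expect_lt(abs(dk$rho2 - direct$rho2), max(3 * direct$se[["s2"]], 1e-3))
  expect_lt(abs(dk$rho3 - direct$rho3), max(3 * direct$se[["s3"]], 1e-3))
  expect_lt(abs(dk$rho4 - direct$rho4), max(3 * direct$se[["s4"]], 1e-3))
  expect_lt(abs(dk$rho2_2 - direct$rho2_2), max(3 * direct$se[["s22"]], 1e-3))
})
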