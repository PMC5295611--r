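test_that("pedigree construction validates its input", {
  trio <- build_pedigree(data.frame(id = c("A", "B", "C"),
                                    father = c(NA, NA, "A"),
                                    mother = c(NA, NA, "B"),
                                    sex = c("M", "F", "M")))
  expect_s3_class(trio, "pedigree")
  expect_setequal(founders(trio), c("A", "B"))

  expect_error(build_pedigree(data.frame(id = c("A", "B", "C"),
                                         father = c(NA, NA, "C"),
                                         mother = c(NA, NA, "B"),
                                         sex = c("M", "F", "M"))),
               "cycle")
  expect_error(build_pedigree(data.frame(id = c("A", "B"),
                                         father = c(NA, "Z"),
                                         mother = c(NA, "A"),
                                         sex = c("F", "M"))),
               "dangling")
  expect_error(build_pedigree(data.frame(id = c("A", "A"),
                                         father = c(NA, NA),
                                         mother = c(NA, NA),
                                         sex = c("M", "M"))),
               "duplicated")
  expect_error(build_pedigree(data.frame(id = c("A", "B", "C"),
                                         father = c(NA, NA, "A"),
                                         mother = c(NA, NA, "B"),
                                         sex = c("F", "F", "M"))),
               "father")
})

test_that("recursive kinship reproduces the catalogued relative-pair values", {
  fs <- ped_full_sib()
  expect_equal(kinship_pair(fs, "S1", "S2"), 1 / 4)
  expect_equal(kinship_pair(ped_parent_offspring(), "P", "C"), 1 / 4)
  expect_equal(kinship_pair(ped_avuncular(), "A1", "N"), 1 / 8)
  inb <- ped_inbred_full_sib()
  expect_equal(kinship_pair(inb, "C1", "C2"), 3 / 8)
  expect_equal(kinship_pair(fs, "F", "M"), 0)  # founders unrelated

  # X-linked full siblings by sex combination
  expect_equal(kinship_pair(ped_full_sib(c("M", "M")), "S1", "S2", "x_linked"),
               1 / 2)
  expect_equal(kinship_pair(ped_full_sib(c("M", "F")), "S1", "S2", "x_linked"),
               1 / 4)
  expect_equal(kinship_pair(ped_full_sib(c("F", "F")), "S1", "S2", "x_linked"),
               3 / 8)

  expect_error(kinship_pair(fs, "S1", "nope"), "unknown id")
  u <- build_pedigree(data.frame(id = "A", father = NA, mother = NA, sex = "U"))
  expect_error(kinship_pair(u, "A", "A", "x_linked"), "sex")
})

test_that("kinship is symmetric, bounded, and consistent with inbreeding", {
  for (ped in list(ped_full_sib(), ped_avuncular(), ped_inbred_full_sib())) {
    ids <- ped$id
    for (j in ids) for (k in ids) {
      phi <- kinship_pair(ped, j, k)
      expect_identical(phi, kinship_pair(ped, k, j))
      expect_gte(phi, 0); expect_lte(phi, 1)
    }
  }
  inb <- ped_inbred_full_sib()
  # inbreeding equals parental kinship; outbred diploid self-kinship is 1/2
  expect_equal(inbreeding(inb, "C1"), kinship_pair(inb, "PB", "PS"))
  expect_equal(inbreeding(inb, "C1"), 1 / 4)
  expect_equal(kinship_pair(inb, "C1", "C1"), 5 / 8)
  expect_equal(kinship_pair(inb, "PB", "PB"), 1 / 2)
  # male X-linked self-kinship is 1
  mm <- ped_full_sib(c("M", "M"))
  expect_equal(kinship_pair(mm, "S1", "S1", "x_linked"), 1)
})

test_that("kinship_matrix assembles the ploidy-general diagonal", {
  po <- ped_parent_offspring()
  K <- kinship_matrix(po, c("P", "C"))
  expect_equal(unname(K$K), matrix(c(.5, .25, .25, .5), 2))

  unrel <- build_pedigree(data.frame(id = paste0("u", 1:4), father = NA,
                                     mother = NA, sex = "U"))
  expect_equal(unname(kinship_matrix(unrel, paste0("u", 1:4))$K),
               diag(4) / 2)

  inb <- ped_inbred_full_sib()
  Ki <- kinship_matrix(inb, c("C1", "C2"))
  expect_equal(unname(Ki$K), matrix(c(5 / 8, 3 / 8, 3 / 8, 5 / 8), 2))

  # X-linked: male diagonal 1 (haploid), female 1/2
  mf <- ped_full_sib(c("M", "F"))
  Kx <- kinship_matrix(mf, c("S1", "S2"), mode = "x_linked")
  expect_equal(unname(diag(Kx$K)), c(1, 0.5))
  expect_equal(Kx$ploidies, c(1L, 2L))

  # haploid self-kinship via the general formula
  expect_equal(self_kinship(1), 1)
  expect_equal(self_kinship(2, 0.25), 5 / 8)
  expect_equal(self_kinship(4, 0), 1 / 4)
})

test_that("PED files round into validated pedigrees", {
  ped <- read_ped(system.file("extdata", "toy.ped", package = "kinhet"))
  expect_setequal(founders(ped), c("P1", "P2", "U1", "U2"))
  expect_equal(kinship_pair(ped, "C1", "C2"), 1 / 4)
  expect_equal(kinship_pair(ped, "U1", "U2"), 0)

  # headerless variant
  tmp <- tempfile()
  writeLines(c("A 0 0 1", "B 0 0 2", "C A B 1"), tmp)
  ped2 <- read_ped(tmp)
  expect_equal(kinship_pair(ped2, "A", "C"), 1 / 4)
})
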