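# Shared fixture builders and independent oracles.

ped_full_sib <- function(sexes = c("M", "F")) {
  build_pedigree(data.frame(
    id = c("F", "M", "S1", "S2"), father = c(NA, NA, "F", "F"),
    mother = c(NA, NA, "M", "M"), sex = c("M", "F", sexes)))
}

ped_parent_offspring <- function() {
  build_pedigree(data.frame(
    id = c("P", "Q", "C"), father = c(NA, NA, "P"),
    mother = c(NA, NA, "Q"), sex = c("M", "F", "F")))
}

ped_avuncular <- function() {
  build_pedigree(data.frame(
    id = c("GF", "GM", "A1", "A2", "SP", "N"),
    father = c(NA, NA, "GF", "GF", NA, "SP"),
    mother = c(NA, NA, "GM", "GM", NA, "A2"),
    sex = c("M", "F", "F", "F", "M", "F")))
}

ped_inbred_full_sib <- function() {
  build_pedigree(data.frame(
    id = c("GF", "GM", "PB", "PS", "C1", "C2"),
    father = c(NA, NA, "GF", "GF", "PB", "PB"),
    mother = c(NA, NA, "GM", "GM", "PS", "PS"),
    sex = c("M", "F", "M", "F", "F", "F")))
}

# Exhaustive enumeration oracle for the two-generation full-sib template:
# father carries founder labels {1,2}, mother {3,4}; each child's genotype is
# one independent paternal and one maternal pick, giving 2^4 equally likely
# meiosis outcomes.  Returns the exact identity coefficient arrays for the
# sib pair (indices 1 = S1, 2 = S2), with repeated indices meaning
# independent draws with replacement.
enum_fullsib_arrays <- function() {
  out <- expand.grid(p1 = 1:2, m1 = 3:4, p2 = 1:2, m2 = 3:4)
  n <- 2L
  phi2 <- matrix(0, n, n)
  phi3 <- array(0, c(n, n, n))
  phi4 <- array(0, c(n, n, n, n))
  phi22 <- array(0, c(n, n, n, n))
  for (r in seq_len(nrow(out))) {
    x <- rbind(tabulate(c(out$p1[r], out$m1[r]), 4) / 2,
               tabulate(c(out$p2[r], out$m2[r]), 4) / 2)
    pc <- x %*% t(x)  # conditional pairwise match probabilities
    for (j in 1:n) for (k in 1:n) {
      phi2[j, k] <- phi2[j, k] + pc[j, k]
      for (l in 1:n) {
        phi3[j, k, l] <- phi3[j, k, l] + sum(x[j, ] * x[k, ] * x[l, ])
        for (m in 1:n) {
          phi4[j, k, l, m] <- phi4[j, k, l, m] +
            sum(x[j, ] * x[k, ] * x[l, ] * x[m, ])
          phi22[j, k, l, m] <- phi22[j, k, l, m] + pc[j, k] * pc[l, m]
        }
      }
    }
  }
  lapply(list(phi2 = phi2, phi3 = phi3, phi4 = phi4, phi22 = phi22),
         function(a) a / nrow(out))
}

# Brute-force heterozygosity bounds over a discretized simplex with I alleles,
# largest frequency fixed at M and every frequency at most M.
brute_force_het_bounds <- function(I, M, step = 0.01) {
  if (I == 1L) return(c(min = 0, max = 0))
  grid <- seq(0, M, by = step)
  rest <- if (I > 2L) {
    do.call(expand.grid, rep(list(grid), I - 2L))
  } else data.frame(matrix(numeric(0), nrow = 1, ncol = 0))
  s2 <- numeric(0)
  for (r in seq_len(nrow(rest))) {
    mid <- as.numeric(rest[r, , drop = TRUE])
    last <- 1 - M - sum(mid)
    if (last < -1e-9 || last > M + 1e-9) next
    s2 <- c(s2, M^2 + sum(mid^2) + last^2)
  }
  c(min = 1 - max(s2), max = 1 - min(s2))
}

# Combine several template-style pedigrees into one disjoint pedigree with
# prefixed ids (for cross-checking design-level machinery against a direct
# single-pedigree gene drop).
combine_pedigrees <- function(peds, prefixes) {
  rows <- Map(function(p, pre) {
    data.frame(id = paste0(pre, p$id),
               father = ifelse(is.na(p$father), NA, paste0(pre, p$father)),
               mother = ifelse(is.na(p$mother), NA, paste0(pre, p$mother)),
               sex = p$sex)
  }, peds, prefixes)
  build_pedigree(do.call(rbind, rows))
}

# Run the bundled command-line script; returns list(output lines, status).
run_cli <- function(args) {
  script <- system.file("cli", "kinhet.R", package = "kinhet")
  out <- suppressWarnings(system2(
    "Rscript", c(shQuote(script), args), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  status <- attr(out, "status")
  list(out = out, status = if (is.null(status)) 0L else status)
}

read_cli_tsv <- function(lines) {
  keep <- lines[!startsWith(lines, "#")]
  utils::read.delim(text = paste(keep, collapse = "\n"),
                    stringsAsFactors = FALSE)
}
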