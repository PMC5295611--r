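# Readers for the genotype table format (canonical; allele labels are
# arbitrary strings) and, as a convenience for SNP data, VCF.

#' Read per-locus genotype samples
#'
#' The canonical table format is tab- or whitespace-delimited with a header:
#' column 1 `id`, column 2 `ploidy`, then one column per locus holding
#' comma-separated allele labels (`.` for a missing call), with as many
#' labels as the individual's ploidy.  The VCF reader (requires the vcfR
#' package) takes alleles from the GT field, inferring ploidy per genotype
#' (`0` haploid, `0/1` diploid, ...), and labels them by REF/ALT sequence.
#'
#' @param path Input file.
#' @param format `"table"` or `"vcf"`.
#' @return Named list with one [genotype_sample()] per locus.
#' @export
read_genotypes <- function(path, format = c("table", "vcf")) {
  format <- match.arg(format)
  switch(format, table = .read_genotype_table(path), vcf = .read_vcf(path))
}

.read_genotype_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 3L) stop("genotype table needs id, ploidy and >= 1 locus column")
  if (!identical(tolower(names(tab)[1:2]), c("id", "ploidy"))) {
    stop("genotype table must start with columns 'id' and 'ploidy'")
  }
  ids <- tab[[1L]]
  ploidies <- suppressWarnings(as.integer(tab[[2L]]))
  if (anyNA(ploidies) || any(ploidies < 1L)) stop("malformed ploidy column")
  loci <- names(tab)[-(1:2)]
  out <- lapply(loci, function(loc) {
    cells <- strsplit(tab[[loc]], ",", fixed = TRUE)
    bad <- lengths(cells) != ploidies
    if (any(bad)) {
      stop("locus ", loc, ": allele count does not match ploidy for ",
           paste(ids[bad], collapse = ", "))
    }
    alleles <- lapply(cells, function(a) { a[a == "."] <- NA_character_; a })
    genotype_sample(ids, alleles, ploidies, locus = loc)
  })
  stats::setNames(out, loci)
}

.read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF reading requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  ids <- colnames(gt)
  out <- list()
  for (r in seq_len(nrow(gt))) {
    labels <- c(fix[r, "REF"], strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1L]])
    calls <- strsplit(gt[r, ], "[/|]")
    alleles <- lapply(calls, function(a) {
      if (length(a) == 0L || all(is.na(a))) return(NA_character_)
      ifelse(a == ".", NA_character_, labels[as.integer(a) + 1L])
    })
    loc <- if (!is.na(fix[r, "ID"]) && fix[r, "ID"] != ".") fix[r, "ID"]
           else paste0(fix[r, "CHROM"], ":", fix[r, "POS"])
    out[[loc]] <- genotype_sample(ids, alleles, lengths(alleles), locus = loc,
                                  allele_universe = labels)
  }
  out
}

#' Write per-locus heterozygosity estimates as annotated TSV
#'
#' Plain TSV with a commented `# key=value` metadata header recording the
#' estimator tag, seed and package version; one row per locus.
#'
#' @param results Data frame of results (one row per locus).
#' @param path Output file, or `""` for standard output.
#' @param meta Named character vector/list of metadata to record.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path = "", meta = list()) {
  meta <- c(list(package = paste0("kinhet ",
                                  utils::packageVersion("kinhet"))), meta)
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("# %s=%s", k, meta[[k]]), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
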