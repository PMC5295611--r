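#' Build a validated pedigree
#'
#' Constructs a `pedigree` object from a table of individuals with parent
#' links.  Founders are individuals with both parents missing.  The pedigree
#' is validated: ids must be unique, every named parent must itself be a row,
#' the parent graph must be acyclic, and a named father (mother) may not be
#' recorded as female (male).
#'
#' @param records A data frame (or coercible) with columns `id`, `father`,
#'   `mother`, `sex`.  Missing parents are `NA`, `""` or `"0"`.  Sex codes
#'   accepted: `"M"`/`"male"`/`1`, `"F"`/`"female"`/`2`, anything else (or
#'   `NA`, `0`) is treated as unspecified.
#' @return An object of class `pedigree`: a data frame with character `id`,
#'   `father`, `mother` (NA for missing), factor-free character `sex` in
#'   `c("M","F","U")`, plus attributes giving a founders-first topological
#'   order.
#' @examples
#' trio <- build_pedigree(data.frame(
#'   id = c("A", "B", "C"), father = c(NA, NA, "A"),
#'   mother = c(NA, NA, "B"), sex = c("M", "F", "M")))
#' founders(trio)
#' @seealso [kinship_pair()], [kinship_matrix()], [read_ped()]
#' @export
build_pedigree <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("id", "father", "mother", "sex")
  if (!all(need %in% names(records))) {
    # positional fallback for headerless four-column input
    if (ncol(records) >= 4) names(records)[1:4] <- need
    else stop("pedigree records need columns id, father, mother, sex")
  }
  id <- as.character(records$id)
  fa <- .norm_parent(records$father)
  mo <- .norm_parent(records$mother)
  sex <- .norm_sex(records$sex)

  if (anyDuplicated(id)) {
    stop("duplicated id in pedigree: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  dangling <- setdiff(c(fa, mo), c(id, NA))
  if (length(dangling)) {
    stop("dangling parent reference in pedigree: ",
         paste(dangling, collapse = ", "))
  }
  fi <- match(fa, id, nomatch = 0L)
  mi <- match(mo, id, nomatch = 0L)

  # sex consistency of named parents
  if (any(sex[fi[fi > 0L]] == "F")) stop("a named father is recorded as female")
  if (any(sex[mi[mi > 0L]] == "M")) stop("a named mother is recorded as male")

  ord <- .topo_order(fi, mi)
  if (is.null(ord)) stop("cycle detected in pedigree: an individual is its own ancestor")

  ped <- data.frame(id = id, father = fa, mother = mo, sex = sex,
                    stringsAsFactors = FALSE)
  attr(ped, "father_idx") <- fi
  attr(ped, "mother_idx") <- mi
  attr(ped, "topo_rank") <- order(ord)          # rank[i]: position of i in order
  attr(ped, "topo_order") <- ord                # founders-first ordering of indices
  class(ped) <- c("pedigree", "data.frame")
  ped
}

.norm_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x %in% c("", "0", "-", ".")] <- NA_character_
  x
}

.norm_sex <- function(x) {
  x <- toupper(as.character(x))
  out <- rep("U", length(x))
  out[x %in% c("M", "MALE", "1")] <- "M"
  out[x %in% c("F", "FEMALE", "2")] <- "F"
  out
}

# Kahn's algorithm; returns founders-first order of indices or NULL on a cycle
.topo_order <- function(fi, mi) {
  n <- length(fi)
  nkids <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fi[i], mi[i])) if (p > 0L) {
      kids[[p]] <- c(kids[[p]], i)
    }
  }
  indeg <- (fi > 0L) + (mi > 0L)
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) NULL else ord
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(is.na(x$father) & is.na(x$mother))
  cat(sprintf("Pedigree with %d individuals (%d founders)\n", nrow(x), nf))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Founder ids of a pedigree
#'
#' @param ped A [build_pedigree()] object.
#' @return Character vector of ids whose parents are both missing.
#' @export
founders <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ped$id[is.na(ped$father) & is.na(ped$mother)]
}

#' Read a PED-style pedigree file
#'
#' Whitespace-delimited columns `id father mother sex`, with `0` marking a
#' missing parent and sex coded `1` (male), `2` (female), `0`/other
#' (unspecified).  A header line naming the columns is optional.
#'
#' @param path Path to the text file.
#' @return A [build_pedigree()] object.
#' @export
read_ped <- function(path) {
  first <- scan(path, what = character(), nlines = 1L, quiet = TRUE)
  header <- any(tolower(first) %in% c("id", "father", "mother", "sex"))
  tab <- utils::read.table(path, header = header, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!header) names(tab)[1:4] <- c("id", "father", "mother", "sex")
  build_pedigree(tab)
}
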