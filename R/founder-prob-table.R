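#' Founder diplotype state labels
#'
#' The 36 unordered diplotype states for an eight-founder panel, in the fixed
#' order used throughout the package: the 8 homozygous states `AA`..`HH`
#' first, then the 28 heterozygous pairs `AB`, `AC`, ..., `GH` in
#' lexicographic founder order.  All probability arrays and incidence
#' matrices index their state dimension in this order.
#'
#' @return Character vector of length 36.
#' @export
#' @examples
#' diplotype_states()[1:10]
diplotype_states <- function() {
  founders <- founder_labels()
  hom <- paste0(founders, founders)
  het <- character(0)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      het <- c(het, paste0(founders[i], founders[j]))
    }
  }
  c(hom, het)
}

#' Founder labels
#'
#' Single-letter labels for the eight founder haplotypes (`A`..`H`), matching
#' the conventional lettering of the Collaborative Cross founders.
#'
#' @return Character vector of length 8.
#' @export
founder_labels <- function() LETTERS[1:8]

#' Additive model matrix
#'
#' The fixed 36 x 8 matrix `A` that maps a diplotype state to founder
#' haplotype dosages: the homozygous state `kk` carries 2 doses of founder
#' `k`, a heterozygous state `jk` carries one dose each of `j` and `k`.
#' Every row sums to 2.
#'
#' @return Numeric 36 x 8 matrix with rownames [diplotype_states()] and
#'   colnames [founder_labels()].
#' @export
#' @examples
#' A <- additive_model_matrix()
#' A["AA", ]  # 2 doses of founder A
#' A["AB", ]  # 1 dose each of A and B
additive_model_matrix <- function() {
  states <- diplotype_states()
  founders <- founder_labels()
  A <- matrix(0, nrow = 36, ncol = 8, dimnames = list(states, founders))
  for (s in seq_along(states)) {
    pair <- strsplit(states[s], "")[[1]]
    A[s, pair[1]] <- A[s, pair[1]] + 1
    A[s, pair[2]] <- A[s, pair[2]] + 1
  }
  A
}

#' Construct a founder probability table
#'
#' The central genome container: per-strain, per-locus probability vectors
#' over the 36 founder diplotype states, together with a marker map.  This
#' is the probabilistic haplotype mosaic representation produced by HMM
#' founder inference in multiparental panels (`P` in the Haley-Knott mapping
#' model), consumed here rather than inferred.
#'
#' @param probs Numeric array, strains x loci x 36, each 36-vector
#'   nonnegative and summing to 1 within `tol`.
#' @param map Data frame with columns `locus_id` (unique character),
#'   `chromosome` (character, e.g. `"1"`..`"19"`, `"X"`), `position_Mb`
#'   (numeric, strictly increasing within chromosome).
#' @param strains Character vector of strain labels (length `dim(probs)[1]`).
#' @param tol Tolerance for the sum-to-1 check.
#'
#' @return An object of class `founder_prob_table`: a list with elements
#'   `strains`, `map` (with an `index` column of interval order), `probs`.
#' @export
founder_prob_table <- function(probs, map, strains, tol = 1e-6) {
  stopifnot(is.array(probs), length(dim(probs)) == 3L)
  if (dim(probs)[3] != 36L) {
    stop("`probs` must have 36 diplotype states in its third dimension")
  }
  if (length(strains) != dim(probs)[1]) {
    stop("`strains` length does not match the first dimension of `probs`")
  }
  if (length(strains) < 2L) {
    stop("a founder probability table needs at least 2 strains")
  }
  map <- as.data.frame(map)
  required <- c("locus_id", "chromosome", "position_Mb")
  if (!all(required %in% names(map))) {
    stop("`map` must have columns locus_id, chromosome, position_Mb")
  }
  if (nrow(map) != dim(probs)[2]) {
    stop("`map` rows do not match the locus dimension of `probs`")
  }
  map$locus_id <- as.character(map$locus_id)
  map$chromosome <- as.character(map$chromosome)
  map$index <- seq_len(nrow(map))
  if (anyDuplicated(map$locus_id)) {
    stop("duplicated locus_id in marker map")
  }
  for (chr in unique(map$chromosome)) {
    pos <- map$position_Mb[map$chromosome == chr]
    if (any(diff(pos) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", chr)
    }
  }
  dimnames(probs) <- list(strains, map$locus_id, diplotype_states())
  obj <- structure(
    list(strains = as.character(strains), map = map, probs = probs),
    class = "founder_prob_table"
  )
  validate_prob_table(obj, tol = tol)
  obj
}

#' Validate the probability invariants of a table
#'
#' Checks that every strain x locus probability vector is nonnegative and
#' sums to 1 within `tol`.
#'
#' @param table A [founder_prob_table()].
#' @param tol Tolerance on the row sums.
#' @return The table, invisibly; errors on violation.
#' @export
validate_prob_table <- function(table, tol = 1e-6) {
  p <- table$probs
  if (any(p < -tol)) stop("negative diplotype probabilities")
  sums <- rowSums(p, dims = 2L)   # strains x loci
  bad <- abs(sums - 1) > tol
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "diplotype probabilities for strain '%s' at locus '%s' sum to %.6f, not 1",
      table$strains[idx[1]], table$map$locus_id[idx[2]], sums[idx[1], idx[2]]
    ))
  }
  invisible(table)
}

#' @export
print.founder_prob_table <- function(x, ...) {
  cat(sprintf(
    "founder_prob_table: %d strains x %d loci on %d chromosome(s)\n",
    length(x$strains), nrow(x$map), length(unique(x$map$chromosome))
  ))
  invisible(x)
}

#' @export
dim.founder_prob_table <- function(x) dim(x$probs)

#' Number of strains / loci of a table
#'
#' @param table A [founder_prob_table()].
#' @return Integer count.
#' @export
n_strains <- function(table) length(table$strains)

#' @rdname n_strains
#' @export
n_loci <- function(table) nrow(table$map)

#' Subset a founder probability table by strain
#'
#' @param table A [founder_prob_table()].
#' @param strains Character vector of strain labels (subset of
#'   `table$strains`).
#' @return A `founder_prob_table` restricted to those strains.
#' @export
subset_strains <- function(table, strains) {
  if (!all(strains %in% table$strains)) {
    stop("unknown strain(s): ",
         paste(setdiff(strains, table$strains), collapse = ", "))
  }
  founder_prob_table(
    probs = table$probs[strains, , , drop = FALSE],
    map = table$map[, c("locus_id", "chromosome", "position_Mb")],
    strains = strains
  )
}

locus_index <- function(table, locus) {
  if (is.character(locus)) {
    idx <- match(locus, table$map$locus_id)
    if (is.na(idx)) stop("unknown locus: ", locus)
    return(idx)
  }
  idx <- as.integer(locus)
  if (idx < 1L || idx > n_loci(table)) stop("locus index out of range: ", locus)
  idx
}
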