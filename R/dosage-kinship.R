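#' Founder haplotype dosages at a locus
#'
#' The expected founder haplotype dosages `P A` used as predictors in
#' Haley-Knott regression: row `i` is the strain's 36-state probability
#' vector at the locus multiplied by the additive model matrix.  For exact
#' probability vectors every row sums to 2.
#'
#' @param table A [founder_prob_table()].
#' @param locus Locus id (character) or index.
#' @return Numeric strains x 8 matrix.
#' @export
haplotype_dosage <- function(table, locus) {
  l <- locus_index(table, locus)
  d <- table$probs[, l, , drop = TRUE]
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  out <- d %*% additive_model_matrix()
  rownames(out) <- table$strains
  out
}

#' Full dosage array for a table
#'
#' Computes founder haplotype dosages at every locus in one pass, returning
#' a strains x loci x 8 array.  Used internally by the scan machinery.
#'
#' @param table A [founder_prob_table()].
#' @return Numeric array strains x loci x 8.
#' @export
dosage_array <- function(table) {
  n <- n_strains(table); L <- n_loci(table)
  flat <- matrix(table$probs, nrow = n * L, ncol = 36)
  dos <- flat %*% additive_model_matrix()
  array(dos, dim = c(n, L, 8),
        dimnames = list(table$strains, table$map$locus_id, founder_labels()))
}

#' Hard-call diplotype states
#'
#' Collapses each probability vector to its most probable diplotype state
#' (the incidence matrix `D` used to define simulation truth).  Ties are
#' broken toward the lowest state index.
#'
#' @param table A [founder_prob_table()].
#' @return Integer strains x loci matrix of state indices in
#'   [diplotype_states()] order.
#' @export
hard_call_diplotypes <- function(table) {
  n <- n_strains(table); L <- n_loci(table)
  calls <- matrix(0L, n, L, dimnames = list(table$strains, table$map$locus_id))
  for (l in seq_len(L)) {
    m <- table$probs[, l, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    calls[, l] <- max.col(m, ties.method = "first")
  }
  calls
}

#' Realized kinship from founder mosaic probabilities
#'
#' Strain-by-strain genetic similarity computed from the haplotype
#' probability shares: with `f_il` the 8-vector of founder shares
#' (dosage / 2) for strain `i` at locus `l`,
#' `K_ij = (1/L) * sum_l <f_il, f_jl>`.  Two fully inbred strains with
#' identical mosaics have `K_ij = 1`; strains never sharing a founder have
#' `K_ij = 0`.
#'
#' @param table A [founder_prob_table()].
#' @return Symmetric strains x strains matrix of class `matrix`, with a
#'   `"normalization"` attribute describing the share convention.
#' @export
compute_kinship <- function(table) {
  if (n_strains(table) < 2L) stop("kinship needs at least 2 strains")
  dos <- dosage_array(table)
  n <- n_strains(table); L <- n_loci(table)
  shares <- matrix(dos / 2, nrow = n)   # n x (L*8)
  K <- tcrossprod(shares) / L
  K <- (K + t(K)) / 2
  dimnames(K) <- list(table$strains, table$strains)
  attr(K, "normalization") <- "mean inner product of haplotype-probability shares (dosage/2)"
  K
}

#' Balanced (idealized) kinship
#'
#' Replaces every off-diagonal element of a kinship matrix by the mean
#' realized off-diagonal value, keeping the diagonal.  This is the
#' equal-relatedness idealization against which population structure is
#' diagnosed.
#'
#' @param K Symmetric kinship matrix.
#' @return Matrix of the same dimension.
#' @export
balanced_kinship <- function(K) {
  K <- as.matrix(K)
  off <- K[upper.tri(K) | lower.tri(K)]
  B <- matrix(mean(off), nrow(K), ncol(K), dimnames = dimnames(K))
  diag(B) <- diag(K)
  attr(B, "normalization") <- attr(K, "normalization")
  B
}

#' Principal components needed to explain a variance fraction
#'
#' The smallest number `k` of eigenvalues of `K` (negative eigenvalues
#' clipped at zero) whose sum reaches at least `fraction` of the total.
#' Comparing this count between a realized and a balanced kinship matrix
#' diagnoses population structure: structure concentrates variance in fewer
#' components.
#'
#' @param K Symmetric kinship matrix.
#' @param fraction Target fraction in (0, 1]; default 0.95.
#' @return Integer count of components.
#' @export
pcs_for_variance <- function(K, fraction = 0.95) {
  stopifnot(fraction > 0, fraction <= 1)
  ev <- pmax(eigen(as.matrix(K), symmetric = TRUE, only.values = TRUE)$values, 0)
  cum <- cumsum(ev) / sum(ev)
  as.integer(which(cum >= fraction - 1e-12)[1])
}
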