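#' Reduce adjacent, nearly identical loci
#'
#' Adjacent genomic intervals whose diplotype probability vectors are highly
#' similar across all strains are averaged into a single interval, shrinking
#' the scan grid without losing mapping information.  Similarity is judged
#' by the L2 norm between 36-state probability vectors; two intervals are
#' mergeable when, for every strain, that distance is below
#' `threshold * max_norm`.  The maximum norm is taken as 2 by convention
#' (the value used when this reduction was applied to the realized
#' Collaborative Cross cache), so the default `threshold = 0.10` corresponds
#' to an absolute distance of 0.2.  Note the geometric maximum distance
#' between unit-sum probability vectors is sqrt(2); the absolute threshold
#' is kept at 0.2 regardless, matching established practice.
#'
#' Merging is greedy left-to-right within each chromosome.  Under the
#' default `policy = "run_mean"` a locus joins the current run if its
#' distance to the run's running average is below the threshold for every
#' strain; under `policy = "adjacent"` it joins if its distance to the
#' previous original locus is below the threshold.  Chromosome boundaries
#' are never merged across.  A merged interval takes the mean probability
#' vector and mean position of its members, and the locus id of its first
#' member.
#'
#' @param table A [founder_prob_table()].
#' @param threshold Fraction of the maximum norm, in (0, 1); default 0.10.
#' @param max_norm Maximum-norm convention; default 2.
#' @param policy `"run_mean"` (default) or `"adjacent"`.
#' @return A reduced [founder_prob_table()]; the attribute `"provenance"`
#'   is a data frame mapping each merged `locus_id` to its source locus ids.
#' @export
reduce_adjacent_loci <- function(table, threshold = 0.10, max_norm = 2,
                                 policy = c("run_mean", "adjacent")) {
  policy <- match.arg(policy)
  if (n_loci(table) == 0L) stop("empty table")
  stopifnot(threshold > 0, threshold < 1)
  abs_thr <- threshold * max_norm

  runs <- list()      # each: integer vector of source locus indices
  for (chr in unique(table$map$chromosome)) {
    idx <- which(table$map$chromosome == chr)
    current <- idx[1]
    run_sum <- table$probs[, idx[1], , drop = TRUE]   # strains x 36
    if (is.null(dim(run_sum))) run_sum <- matrix(run_sum, nrow = 1)
    for (l in idx[-1]) {
      p <- table$probs[, l, , drop = TRUE]
      if (is.null(dim(p))) p <- matrix(p, nrow = 1)
      ref <- switch(policy,
        run_mean = run_sum / length(current),
        adjacent = {
          prev <- table$probs[, current[length(current)], , drop = TRUE]
          if (is.null(dim(prev))) prev <- matrix(prev, nrow = 1)
          prev
        })
      d <- sqrt(rowSums((p - ref)^2))
      if (all(d < abs_thr)) {
        current <- c(current, l)
        run_sum <- run_sum + p
      } else {
        runs[[length(runs) + 1L]] <- current
        current <- l
        run_sum <- p
      }
    }
    runs[[length(runs) + 1L]] <- current
  }

  n <- n_strains(table)
  L_out <- length(runs)
  probs <- array(0, dim = c(n, L_out, 36))
  map <- data.frame(locus_id = character(L_out), chromosome = character(L_out),
                    position_Mb = numeric(L_out), stringsAsFactors = FALSE)
  prov <- vector("list", L_out)
  for (k in seq_len(L_out)) {
    members <- runs[[k]]
    block <- table$probs[, members, , drop = FALSE]
    probs[, k, ] <- rowMeans(aperm(block, c(1, 3, 2)), dims = 2)
    map$locus_id[k] <- table$map$locus_id[members[1]]
    map$chromosome[k] <- table$map$chromosome[members[1]]
    map$position_Mb[k] <- mean(table$map$position_Mb[members])
    prov[[k]] <- data.frame(merged_locus_id = map$locus_id[k],
                            source_locus_id = table$map$locus_id[members],
                            stringsAsFactors = FALSE)
  }
  out <- founder_prob_table(probs, map, table$strains)
  attr(out, "provenance") <- do.call(rbind, prov)
  out
}
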