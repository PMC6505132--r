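test_that("cache round-trips and validates on load", {
  tab <- random_prob_table(n_strains = 3, loci_per_chr = c(5, 5), seed = 11)
  dir <- withr::local_tempdir()
  save_genome_cache(tab, dir)
  back <- load_genome_cache(dir)
  expect_equal(back$strains, tab$strains)
  expect_equal(n_loci(back), 10)
  expect_equal(back$probs, tab$probs, tolerance = 1e-12)
  expect_equal(back$map$position_Mb, tab$map$position_Mb)

  # missing chromosome file
  file.remove(file.path(dir, "chr2.csv"))
  expect_error(load_genome_cache(dir), "missing chromosome file")
})

test_that("probability invariants are enforced", {
  tab <- random_prob_table(n_strains = 3, loci_per_chr = 4, seed = 2)
  bad <- tab$probs
  bad[2, 3, ] <- bad[2, 3, ] * 0.8   # sums to 0.8
  expect_error(
    founder_prob_table(bad, tab$map[, 1:3], tab$strains),
    "sum to 0.8")
  expect_error(
    founder_prob_table(tab$probs, within(tab$map[, 1:3], locus_id[2] <- locus_id[1]),
                       tab$strains),
    "duplicated locus_id")
  expect_error(
    founder_prob_table(tab$probs, within(tab$map[, 1:3], position_Mb[2] <- position_Mb[1]),
                       tab$strains),
    "strictly increasing")
})

test_that("adjacent-locus reduction merges runs and keeps invariants", {
  # two identical adjacent loci collapse to one, probabilities unchanged
  states <- matrix(rep(c(1L, 2L, 3L), 4), nrow = 3)   # 3 strains x 4 loci
  tab <- one_hot_table(states, loci_per_chr = 4)
  red <- reduce_adjacent_loci(tab)
  expect_equal(n_loci(red), 1)
  expect_equal(as.numeric(red$probs[1, 1, ]), as.numeric(tab$probs[1, 1, ]))
  expect_equal(red$map$position_Mb, mean(tab$map$position_Mb))
  prov <- attr(red, "provenance")
  expect_setequal(prov$source_locus_id, tab$map$locus_id)

  # distances above threshold: nothing merges, chromosome boundaries hold
  states2 <- rbind(c(1L, 2L, 1L, 2L), c(3L, 4L, 3L, 4L), c(5L, 6L, 5L, 6L))
  tab2 <- one_hot_table(states2, loci_per_chr = c(2, 2))
  red2 <- reduce_adjacent_loci(tab2)
  expect_equal(n_loci(red2), 4)
  expect_equal(red2$probs, tab2$probs, ignore_attr = TRUE)
})

test_that("reduction matches a brute-force greedy oracle on random tables", {
  # independent re-implementation: explicit run accumulation with loops
  oracle_runs <- function(tab, abs_thr) {
    runs <- list()
    for (chr in unique(tab$map$chromosome)) {
      idx <- which(tab$map$chromosome == chr)
      cur <- idx[1]
      for (l in idx[-1]) {
        ref <- apply(tab$probs[, cur, , drop = FALSE], c(1, 3), mean)
        ok <- TRUE
        for (i in seq_along(tab$strains)) {
          if (sqrt(sum((tab$probs[i, l, ] - ref[i, ])^2)) >= abs_thr) ok <- FALSE
        }
        if (ok) cur <- c(cur, l) else { runs[[length(runs) + 1]] <- cur; cur <- l }
      }
      runs[[length(runs) + 1]] <- cur
    }
    runs
  }
  for (seed in 1:4) {
    # concentrated rows make merge decisions borderline rather than trivial
    tab <- random_prob_table(n_strains = 4, loci_per_chr = c(6, 4),
                             seed = seed, concentration = 40)
    red <- reduce_adjacent_loci(tab, threshold = 0.25)
    runs <- oracle_runs(tab, abs_thr = 0.25 * 2)
    expect_equal(n_loci(red), length(runs))
    for (k in seq_along(runs)) {
      expect_equal(red$probs[, k, ],
                   apply(tab$probs[, runs[[k]], , drop = FALSE], c(1, 3), mean),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("reduction is idempotent on mosaic genomes", {
  tab <- mosaic_table(n_strains = 6, n_chr = 3, softening = 0.05, seed = 3)
  red <- reduce_adjacent_loci(tab)
  expect_lte(n_loci(red), n_loci(tab))
  red2 <- reduce_adjacent_loci(red)
  expect_equal(n_loci(red2), n_loci(red))
  expect_equal(red2$probs, red$probs, tolerance = 1e-12)
  validate_prob_table(red)
})

test_that("haplotype dosages follow P %*% A", {
  states <- cbind(rep(state_of("AA"), 3),
                  rep(state_of("AB"), 3),
                  rep(state_of("CC"), 3))
  tab <- one_hot_table(states, loci_per_chr = 3)
  expect_equal(as.numeric(haplotype_dosage(tab, 1)[1, ]), c(2, rep(0, 7)))
  expect_equal(as.numeric(haplotype_dosage(tab, 2)[1, ]), c(1, 1, rep(0, 6)))

  # mixture 0.5 AA + 0.5 BB -> (1,1,0,...) by linearity
  probs <- tab$probs
  probs[1, 1, ] <- 0
  probs[1, 1, state_of("AA")] <- 0.5
  probs[1, 1, state_of("BB")] <- 0.5
  tab2 <- founder_prob_table(probs, tab$map[, 1:3], tab$strains)
  expect_equal(as.numeric(haplotype_dosage(tab2, 1)[1, ]), c(1, 1, rep(0, 6)))

  # rows always sum to 2 for exact probabilities
  rnd <- random_prob_table(n_strains = 5, loci_per_chr = 4, seed = 9)
  for (l in 1:4) expect_equal(rowSums(haplotype_dosage(rnd, l)),
                              rep(2, 5), ignore_attr = TRUE)
  expect_error(haplotype_dosage(rnd, "nope"), "unknown locus")
})

test_that("hard calls take the argmax with lowest-index tie-break", {
  tab <- random_prob_table(n_strains = 3, loci_per_chr = 2, seed = 5)
  probs <- tab$probs
  probs[1, 1, ] <- 0; probs[1, 1, state_of("AA")] <- 0.9; probs[1, 1, state_of("BB")] <- 0.1
  probs[2, 1, ] <- 0; probs[2, 1, state_of("AA")] <- 0.5; probs[2, 1, state_of("BB")] <- 0.5
  tab2 <- founder_prob_table(probs, tab$map[, 1:3], tab$strains)
  calls <- hard_call_diplotypes(tab2)
  expect_equal(calls[1, 1], state_of("AA"))
  expect_equal(calls[2, 1], state_of("AA"))   # tie broken to lowest index

  # idempotent on one-hot input
  oh <- one_hot_table(matrix(c(3L, 17L, 36L, 9L), 2, 2), loci_per_chr = 2)
  expect_equal(unname(hard_call_diplotypes(oh)), matrix(c(3L, 17L, 36L, 9L), 2, 2))
})

test_that("kinship matches its brute-force definition and limits", {
  # identical genomes: K12 equals K11
  states <- matrix(rep(c(1L, 9L, 5L, 2L, 30L), each = 2), nrow = 2)
  tab <- one_hot_table(states, loci_per_chr = 5)
  K <- compute_kinship(tab)
  expect_equal(K[1, 2], K[1, 1])

  # disjoint founders at every locus: K12 = 0
  states2 <- rbind(c(1L, 1L, 2L), c(3L, 4L, 5L))
  tab2 <- one_hot_table(states2, loci_per_chr = 3)
  expect_equal(compute_kinship(tab2)[1, 2], 0)

  # brute-force double loop over loci, all small tables
  for (seed in 1:3) {
    tab3 <- random_prob_table(n_strains = 3, loci_per_chr = 5, seed = seed)
    K3 <- compute_kinship(tab3)
    A <- additive_model_matrix()
    for (i in 1:3) for (j in 1:3) {
      acc <- 0
      for (l in 1:5) {
        fi <- as.numeric(tab3$probs[i, l, ] %*% A) / 2
        fj <- as.numeric(tab3$probs[j, l, ] %*% A) / 2
        acc <- acc + sum(fi * fj)
      }
      expect_equal(K3[i, j], acc / 5, tolerance = 1e-12)
    }
    expect_equal(K3, t(K3))
    expect_gte(min(eigen(K3, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("balanced kinship flattens off-diagonals", {
  K <- matrix(c(1, 0.1, 0.2, 0.1, 1, 0.3, 0.2, 0.3, 1), 3, 3)
  B <- balanced_kinship(K)
  expect_equal(diag(B), diag(K))
  expect_equal(unique(B[upper.tri(B)]), 0.2)
  expect_equal(stats::var(B[upper.tri(B) | lower.tri(B)]), 0)
  expect_equal(balanced_kinship(B), B, ignore_attr = TRUE)   # fixed point
})

test_that("pcs_for_variance counts components as defined", {
  expect_equal(pcs_for_variance(diag(20), 0.95), 19)
  r1 <- tcrossprod(c(1, 2, 3)) # rank 1
  expect_equal(pcs_for_variance(r1, 0.95), 1)

  # non-increasing as off-diagonals approach the diagonal
  counts <- vapply(seq(0, 0.9, by = 0.15), function(rho) {
    K <- matrix(rho, 12, 12); diag(K) <- 1
    pcs_for_variance(K, 0.95)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})
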