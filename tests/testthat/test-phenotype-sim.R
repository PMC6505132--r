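test_that("QTL design X = D A M follows the merge-matrix semantics", {
  # strain 1 homozygous AA; series groups A alone vs the rest
  states <- cbind(c(state_of("AA"), state_of("BB"), state_of("AB"),
                    rep(state_of("CC"), 9)))
  tab <- one_hot_table(states, loci_per_chr = 1)
  ser <- parse_series("12222222")
  X <- build_design(tab, 1, ser)
  expect_equal(as.numeric(X[1, ]), c(2, 0))   # 2 doses of allele 1
  expect_equal(as.numeric(X[2, ]), c(0, 2))
  expect_equal(as.numeric(X[3, ]), c(1, 1))   # AB: one dose each
  expect_equal(rowSums(X), rep(2, 12), ignore_attr = TRUE)

  # identity series: X equals the hard-call haplotype dosage
  id <- allelic_series(1:8)
  Xid <- build_design(tab, 1, id)
  expect_equal(Xid, additive_model_matrix()[states[, 1], ] %*% diag(8),
               ignore_attr = TRUE)

  # random D, A, M triple product oracle
  set.seed(3)
  st <- matrix(sample.int(36, 10 * 2, replace = TRUE), 10, 2)
  tab2 <- one_hot_table(st, loci_per_chr = 2)
  ser3 <- sample_series(3, seed = 7)
  D <- matrix(0, 10, 36); D[cbind(1:10, st[, 2])] <- 1
  expect_equal(build_design(tab2, 2, ser3),
               D %*% additive_model_matrix() %*% ser3$M, ignore_attr = TRUE)
})

test_that("allele-effect scaling hits the target variance exactly", {
  # Definition B: popvar(2 beta) = h2_qtl
  beta <- scale_allele_effects(c(-1, 1), "B", h2_qtl = 0.5)
  expect_equal(pop_var(2 * beta), 0.5, tolerance = 1e-14)
  expect_equal(beta, c(-1, 1) * sqrt(0.125), tolerance = 1e-12)

  # null QTL: zero effects under every definition
  expect_equal(scale_allele_effects(c(-1, 1), "B", 0), c(0, 0))
  expect_equal(scale_allele_effects(rnorm(3), "DAMB", 0,
                                    X = matrix(1, 4, 3)), rep(0, 3))

  # Definition MB: popvar(2 M beta) = h2_qtl
  ser <- parse_series("11122222")
  raw <- c(0.4, -1.2)
  betaMB <- scale_allele_effects(raw, "MB", 0.3, M = ser$M)
  expect_equal(pop_var(2 * as.numeric(ser$M %*% betaMB)), 0.3, tolerance = 1e-14)

  # Definition DAMB: popvar(X beta) = h2_qtl on the sampled strains
  set.seed(8)
  st <- matrix(sample.int(8, 12, replace = TRUE), 12, 1)
  tab <- one_hot_table(st, loci_per_chr = 1)
  X <- build_design(tab, 1, ser)
  betaD <- scale_allele_effects(raw, "DAMB", 0.4, X = X)
  expect_equal(pop_var(as.numeric(X %*% betaD)), 0.4, tolerance = 1e-14)

  # monomorphic locus: explicit degenerate condition
  mono <- one_hot_table(matrix(state_of("BB"), 12, 1), loci_per_chr = 1)
  Xm <- build_design(mono, 1, ser)
  expect_error(scale_allele_effects(raw, "DAMB", 0.4, X = Xm),
               class = "ccpower_degenerate_locus")
})

test_that("simulated phenotypes decompose exactly per draw", {
  tab <- mosaic_table(n_strains = 15, n_chr = 3, seed = 21)
  ser <- sample_series(3, seed = 2)
  locus <- tab$map$locus_id[7]

  # noiseless limit: ybar is exactly X beta
  spec <- qtl_sim_spec(locus, ser, variance_config(1, 0, 0), "DAMB", seed = 5)
  phe <- simulate_phenotypes(spec, tab)
  X <- build_design(tab, locus, ser)
  expect_equal(as.numeric(phe$ybar), as.numeric(X %*% phe$truth$beta))

  # pure noise: popvar = sigma2 / r exactly
  spec0 <- qtl_sim_spec(locus, ser, variance_config(0, 0, 1, r = 4), "B", seed = 5)
  phe0 <- simulate_phenotypes(spec0, tab)
  expect_equal(pop_var(phe0$ybar), 1 / 4, tolerance = 1e-14)

  # full decomposition: every realized component matches its fraction
  spec2 <- qtl_sim_spec(locus, ser, variance_config(0.3, 0.45, 0.25, r = 5),
                        "DAMB", seed = 11)
  phe2 <- simulate_phenotypes(spec2, tab)
  expect_equal(pop_var(as.numeric(X %*% phe2$truth$beta)), 0.3, tolerance = 1e-13)
  expect_equal(pop_var(phe2$truth$u), 0.45, tolerance = 1e-13)
  expect_equal(pop_var(phe2$truth$eps), 0.25 / 5, tolerance = 1e-13)
  expect_equal(as.numeric(phe2$ybar),
               as.numeric(X %*% phe2$truth$beta) + phe2$truth$u + phe2$truth$eps)
})

test_that("structured strain effects follow the kinship matrix", {
  # duplicated genomes => identical strain effects under the structured null
  set.seed(14)
  states <- matrix(sample.int(8, 12 * 6, replace = TRUE), 12, 6)
  states[2, ] <- states[1, ]
  tab <- one_hot_table(states, loci_per_chr = c(3, 3))
  K <- compute_kinship(tab)
  spec <- qtl_sim_spec(tab$map$locus_id[1], allelic_series(1:8),
                       variance_config(0, 1, 0), "B", seed = 3)
  phe <- simulate_phenotypes(spec, tab, kinship = K)
  expect_equal(phe$truth$u[1], phe$truth$u[2], tolerance = 1e-10)
  expect_equal(pop_var(phe$truth$u), 1, tolerance = 1e-13)
})

test_that("variance configuration and effective size behave as closed forms", {
  expect_equal(effective_qtl_size(variance_config(0.3, 0.4, 0.3, r = 10)),
               0.3 / 0.73, tolerance = 1e-12)
  expect_equal(effective_qtl_size(variance_config(0.2, 0, 0.8, r = 4)), 0.5)
  expect_equal(effective_qtl_size(variance_config(0.35, 0.15, 0.5, r = 1)), 0.35)
  expect_error(variance_config(0.5, 0.6), "sum to exactly 1")

  # monotone in r and in h2_qtl
  sizes_r <- vapply(1:6, function(r)
    effective_qtl_size(variance_config(0.2, 0.3, 0.5, r = r)), numeric(1))
  expect_true(all(diff(sizes_r) > 0))
  sizes_h <- vapply(seq(0.1, 0.6, by = 0.1), function(h)
    effective_qtl_size(variance_config(h, 0.3, 0.7 - h, r = 3)), numeric(1))
  expect_true(all(diff(sizes_h) > 0))
})

test_that("experiment sampling is uniform over loci and reproducible", {
  tab <- mosaic_table(n_strains = 12, n_chr = 2, seed = 13)
  full <- sample_experiment(tab, n_strains(tab), 2, seed = 1)
  expect_equal(full$strains, tab$strains)
  expect_error(sample_experiment(tab, 99, 2), "exceeds the panel")

  e1 <- sample_experiment(tab, 8, 3, seed = 77)
  e2 <- sample_experiment(tab, 8, 3, seed = 77)
  expect_identical(e1$strains, e2$strains)
  expect_identical(e1$locus, e2$locus)
  expect_identical(e1$series$string, e2$series$string)

  set.seed(4)
  draws <- replicate(10000, sample_experiment(tab, 4, 2)$locus)
  counts <- table(factor(draws, levels = tab$map$locus_id))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})
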