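#' Population variance (denominator N)
#'
#' Variance with the population convention `mean((x - mean(x))^2)`, used for
#' all effect rescaling so realized variance fractions match their targets
#' exactly per draw rather than in expectation.
#'
#' @param x Numeric vector.
#' @return Numeric scalar.
#' @export
pop_var <- function(x) mean((x - mean(x))^2)

# rescale x so pop_var(x) == target exactly; target 0 -> zero vector
rescale_pop_var <- function(x, target) {
  if (target == 0) return(rep(0, length(x)))
  v <- pop_var(x)
  if (v <= 0) stop("cannot rescale a constant vector to positive variance")
  x * sqrt(target / v)
}

#' Variance component configuration
#'
#' The three variance fractions of the phenotype model -- QTL effect size
#' `h2_qtl`, polygenic strain effect `h2_strain`, residual noise `sigma2` --
#' which must be nonnegative and sum to exactly 1, plus the number of
#' replicate observations per strain `r`.  Mapping operates on strain means,
#' whose residual variance is `h2_strain + sigma2 / r`.
#'
#' @param h2_qtl,h2_strain,sigma2 Fractions summing to 1.
#' @param r Replicates per strain, integer >= 1.
#' @return List of class `variance_config`.
#' @export
variance_config <- function(h2_qtl, h2_strain = 0, sigma2 = 1 - h2_qtl - h2_strain,
                            r = 1L) {
  stopifnot(h2_qtl >= 0, h2_strain >= 0, r >= 1)
  if (sigma2 < -1e-9 || abs(h2_qtl + h2_strain + sigma2 - 1) > 1e-9) {
    stop("h2_qtl + h2_strain + sigma2 must sum to exactly 1")
  }
  sigma2 <- max(sigma2, 0)
  structure(list(h2_qtl = h2_qtl, h2_strain = h2_strain, sigma2 = sigma2,
                 r = as.integer(r)),
            class = "variance_config")
}

#' Effective QTL effect size on the strain-mean scale
#'
#' Replicates shrink the noise seen by strain means, so an experiment with
#' `r` replicates, strain effect `h2_strain`, and QTL effect `h2_qtl` is
#' equivalent to a single-observation experiment with effect size
#' `h2_qtl / (h2_qtl + h2_strain + sigma2 / r)`.
#'
#' @param variance A [variance_config()].
#' @return Fraction in (0, 1].
#' @export
#' @examples
#' effective_qtl_size(variance_config(0.3, 0.4, 0.3, r = 10))  # ~0.411
effective_qtl_size <- function(variance) {
  denom <- variance$h2_qtl + variance$h2_strain + variance$sigma2 / variance$r
  if (denom <= 0) stop("all variance components are zero")
  variance$h2_qtl / denom
}

#' QTL design matrix from hard-called diplotypes
#'
#' `X = D A M`: the strains x m allele dosage matrix obtained from the
#' hard-called diplotype incidence `D` (argmax state per strain at the
#' locus), the additive model matrix `A`, and the merge matrix `M` of the
#' allelic series.  Simulation truth uses hard calls; mapping uses the soft
#' probabilities.  Every row sums to 2.
#'
#' @param table A [founder_prob_table()].
#' @param locus Locus id or index.
#' @param series An [allelic_series()].
#' @return Numeric strains x m matrix.
#' @export
build_design <- function(table, locus, series) {
  l <- locus_index(table, locus)
  p <- table$probs[, l, , drop = TRUE]
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  state <- max.col(p, ties.method = "first")
  AM <- additive_model_matrix() %*% series$M
  X <- AM[state, , drop = FALSE]
  rownames(X) <- table$strains
  X
}

#' Scale raw allele effects to a target QTL effect size
#'
#' Multiplies a vector of raw (standard normal) allele effects by a constant
#' so that the QTL explains exactly `h2_qtl` under the chosen effect-size
#' definition, all with population (denominator N) variances:
#' \describe{
#'   \item{B}{`pop_var(2 * beta) = h2_qtl` -- the variance the QTL would
#'     explain in a theoretical population balanced in the functional
#'     alleles; allele values are constant across populations.}
#'   \item{MB}{`pop_var(2 * M beta) = h2_qtl` -- balanced founder
#'     contributions.}
#'   \item{DAMB}{`pop_var(X beta) = h2_qtl` -- the realized variance
#'     explained in the sampled strains (essentially the model R^2); allele
#'     values adjust to the population.}
#' }
#'
#' @param raw Numeric m-vector of unscaled effects (m >= 2).
#' @param definition One of `"B"`, `"MB"`, `"DAMB"`.
#' @param h2_qtl Target fraction.
#' @param X Strains x m design from [build_design()] (required for DAMB).
#' @param M Merge matrix (required for MB).
#' @return Scaled m-vector `beta`.  For DAMB at a locus monomorphic in the
#'   sampled strains (zero realized variance) a condition of class
#'   `ccpower_degenerate_locus` is signalled so callers can resample.
#' @export
scale_allele_effects <- function(raw, definition = c("B", "MB", "DAMB"),
                                 h2_qtl, X = NULL, M = NULL) {
  definition <- match.arg(definition)
  if (length(raw) < 2) stop("need at least 2 allele effects")
  if (h2_qtl == 0) return(rep(0, length(raw)))
  v <- switch(definition,
    B = pop_var(2 * raw),
    MB = {
      if (is.null(M)) stop("Definition MB needs the merge matrix M")
      pop_var(2 * as.numeric(M %*% raw))
    },
    DAMB = {
      if (is.null(X)) stop("Definition DAMB needs the design X")
      pop_var(as.numeric(X %*% raw))
    })
  if (v <= 1e-12) {
    if (definition == "DAMB") {
      stop(structure(class = c("ccpower_degenerate_locus", "error", "condition"),
                     list(message = "locus is monomorphic in the sampled strains: realized QTL variance is zero",
                          call = sys.call(-1))))
    }
    stop("raw allele effects carry no variance under definition ", definition)
  }
  raw * sqrt(h2_qtl / v)
}

#' QTL simulation specification
#'
#' Bundles everything needed to simulate one phenotype draw: the causal
#' locus, the allelic series, the variance configuration, the effect-size
#' definition, the strain subset, and a seed.
#'
#' @param locus Locus id or index.
#' @param series An [allelic_series()].
#' @param variance A [variance_config()].
#' @param definition `"B"`, `"MB"` or `"DAMB"`.
#' @param strains Strain subset (default NULL = all strains in the table).
#' @param seed Optional integer seed.
#' @return List of class `qtl_sim_spec`.
#' @export
qtl_sim_spec <- function(locus, series, variance,
                         definition = c("B", "MB", "DAMB"),
                         strains = NULL, seed = NULL) {
  definition <- match.arg(definition)
  stopifnot(inherits(series, "allelic_series"),
            inherits(variance, "variance_config"))
  structure(list(locus = locus, series = series, variance = variance,
                 definition = definition, strains = strains, seed = seed),
            class = "qtl_sim_spec")
}

#' Simulate strain-mean phenotypes
#'
#' Draws one phenotype vector of strain means
#' `ybar = mu + X beta + u + eps_bar` with `mu = 0`: QTL effects from the
#' hard-called design `X = D A M` scaled per the effect-size definition,
#' strain effects `u` rescaled to population variance `h2_strain`
#' (independent draws by default, or `u ~ N(0, K h2_strain)` when a kinship
#' matrix is supplied for the structured null), and mean residuals rescaled
#' to population variance `sigma2 / r`.  The rescaling makes the realized
#' variance decomposition exact per draw, not just in expectation.
#'
#' @param spec A [qtl_sim_spec()].
#' @param table A [founder_prob_table()].
#' @param kinship Optional strains x strains kinship matrix for correlated
#'   strain effects (structured null).
#' @return List of class `phenotype_set`: `ybar` (named strain means) and
#'   `truth` (locus, series, beta, u, definition, variance).
#' @export
simulate_phenotypes <- function(spec, table, kinship = NULL) {
  strains <- if (is.null(spec$strains)) table$strains else spec$strains
  if (!all(strains %in% table$strains)) stop("strain subset not in table")
  n <- length(strains)
  if (n < 2) stop("need at least 2 strains")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  vc <- spec$variance

  sub <- if (identical(strains, table$strains)) table else subset_strains(table, strains)
  X <- build_design(sub, spec$locus, spec$series)
  raw <- stats::rnorm(spec$series$m)
  beta <- scale_allele_effects(raw, spec$definition, vc$h2_qtl,
                               X = X, M = spec$series$M)
  qtl <- as.numeric(X %*% beta)

  u <- if (vc$h2_strain == 0) {
    rep(0, n)
  } else {
    z <- stats::rnorm(n)
    if (!is.null(kinship)) {
      Ksub <- as.matrix(kinship)[strains, strains]
      z <- as.numeric(kinship_sqrt(Ksub) %*% z)
    }
    rescale_pop_var(z, vc$h2_strain)
  }
  eps <- if (vc$sigma2 == 0) rep(0, n) else {
    rescale_pop_var(stats::rnorm(n), vc$sigma2 / vc$r)
  }

  ybar <- qtl + u + eps
  names(ybar) <- strains
  structure(list(ybar = ybar,
                 truth = list(locus = spec$locus, series = spec$series,
                              beta = beta, u = u, eps = eps,
                              definition = spec$definition, variance = vc)),
            class = "phenotype_set")
}

# symmetric PSD square root, tolerating tiny negative eigenvalues
kinship_sqrt <- function(K, tol = 1e-8) {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values))) {
    stop("kinship matrix is not positive semidefinite within tolerance")
  }
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Sample an experiment: strains, causal locus, allelic series
#'
#' Uniformly samples the strain subset (without replacement), the causal
#' locus, and the allelic series, so power estimates average over these
#' sources of variation.
#'
#' @param table A [founder_prob_table()].
#' @param n_strains Number of strains to draw.
#' @param m_alleles Number of functional alleles for the series.
#' @param seed Optional integer seed.
#' @return List with `strains`, `locus` (locus id), `series`.
#' @export
sample_experiment <- function(table, n_strains, m_alleles, seed = NULL) {
  if (n_strains > n_strains(table)) {
    stop("n_strains exceeds the panel size")
  }
  if (!is.null(seed)) set.seed(seed)
  strains <- if (n_strains == n_strains(table)) table$strains else
    sample(table$strains, n_strains)
  locus <- table$map$locus_id[sample.int(n_loci(table), 1L)]
  series <- sample_series(m_alleles)
  list(strains = strains, locus = locus, series = series)
}
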