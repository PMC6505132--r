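#' Precompute the per-locus regression decomposition for a scan
#'
#' Haley-Knott regression of strain means on founder haplotype dosages fits,
#' at every locus, the model `ybar ~ 1 + P A` and compares it to the
#' intercept-only null by F-test.  Because the design at a locus does not
#' depend on the phenotype, its rank-revealing QR decomposition can be
#' computed once and reused for any number of phenotype vectors -- in
#' particular all permutations of one phenotype -- turning a permutation
#' study into a single matrix product.
#'
#' Dosage columns are rank-deficient whenever a founder is absent among the
#' sampled strains (and always by 1, since dosages sum to 2 and so are
#' collinear with the intercept); dependent columns are dropped by the
#' pivoted QR and the numerator degrees of freedom adjusted to
#' `rank - 1`.
#'
#' @param table A [founder_prob_table()].
#' @param strains Strain subset (default all).
#' @return Scan context object (class `scan_context`) holding the stacked
#'   orthonormal bases, per-locus degrees of freedom, and the marker map.
#' @export
scan_context <- function(table, strains = NULL) {
  if (is.null(strains)) strains <- table$strains
  if (!all(strains %in% table$strains)) stop("strain subset not in table")
  n <- length(strains)
  if (n < 10) stop("need at least 10 strains for an eight-allele scan")
  sub <- if (identical(strains, table$strains)) table else
    subset_strains(table, strains)
  dos <- dosage_array(sub)
  L <- n_loci(sub)
  Qs <- vector("list", L)
  df1 <- integer(L); df2 <- integer(L)
  for (l in seq_len(L)) {
    X <- cbind(1, dos[, l, ])
    qz <- qr(X)
    r <- qz$rank
    df1[l] <- r - 1L
    df2[l] <- n - r
    Qs[[l]] <- qr.Q(qz)[, seq_len(r), drop = FALSE]
  }
  ranks <- vapply(Qs, ncol, integer(1))
  structure(list(QB = do.call(cbind, Qs),
                 group = rep.int(seq_len(L), ranks),
                 df1 = df1, df2 = df2, n = n,
                 strains = strains, map = sub$map),
            class = "scan_context")
}

# logP matrix (loci x phenotype columns) for Y (n x q), given a context
scan_context_logp <- function(ctx, Y, cap = 300) {
  Y <- as.matrix(Y)
  if (nrow(Y) != ctx$n) stop("phenotype rows do not match the scan context")
  q <- ncol(Y)
  yty <- colSums(Y^2)
  null_ss <- yty - colSums(Y)^2 / ctx$n        # TSS about the mean
  Cq <- crossprod(ctx$QB, Y)                   # (sum ranks) x q
  Ess <- rowsum(Cq^2, ctx$group, reorder = TRUE)  # explained incl. intercept
  L <- length(ctx$df1)
  logp <- matrix(0, L, q)
  rss <- sweep(-Ess, 2, yty, `+`)              # yty - Ess, per locus/col
  num <- sweep(Ess, 2, yty - null_ss, `-`)     # Ess - n*ybar^2 = model SS
  rel_tol <- 1e-12
  for (j in seq_len(q)) {
    if (null_ss[j] <= rel_tol * max(yty[j], 1)) next  # constant phenotype
    ok <- ctx$df1 >= 1L & ctx$df2 >= 1L
    Fj <- rep(NA_real_, L)
    numj <- pmax(num[, j], 0)
    rssj <- pmax(rss[, j], 0)
    perfect <- ok & rssj <= rel_tol * null_ss[j]
    usable <- ok & !perfect
    Fj[usable] <- (numj[usable] / ctx$df1[usable]) /
      (rssj[usable] / ctx$df2[usable])
    lp <- rep(0, L)
    lp[usable] <- -stats::pf(Fj[usable], ctx$df1[usable], ctx$df2[usable],
                             lower.tail = FALSE, log.p = TRUE) / log(10)
    lp[perfect] <- cap
    logp[, j] <- pmin(lp, cap)
  }
  logp
}

#' Genome scan by haplotype-dosage regression
#'
#' At every locus, regresses the strain means on an intercept plus the eight
#' founder haplotype dosages (`P A`), tests the fit against the
#' intercept-only null with a rank-aware F-test, and reports the negative
#' base-10 log p-value (logP).  A constant phenotype yields logP 0
#' everywhere; p-values below 1e-300 are capped at logP 300.
#'
#' @param ybar Named (or ordered) strain-mean vector.
#' @param table A [founder_prob_table()], or a precomputed [scan_context()].
#' @param strains Strain subset (default all; ignored when `table` is a
#'   context).
#' @return Object of class `cc_scan`: `map`, `logp` (per-locus), and
#'   `peaks`, a per-chromosome data frame of peak locus, position and logP.
#' @export
scan_genome <- function(ybar, table, strains = NULL) {
  ctx <- if (inherits(table, "scan_context")) table else
    scan_context(table, strains)
  y <- align_phenotype(ybar, ctx$strains)
  logp <- as.numeric(scan_context_logp(ctx, matrix(y, ncol = 1)))
  peaks <- do.call(rbind, lapply(split(seq_len(nrow(ctx$map)), ctx$map$chromosome), function(idx) {
    k <- idx[which.max(logp[idx])]
    data.frame(chromosome = ctx$map$chromosome[k],
               locus_id = ctx$map$locus_id[k],
               position_Mb = ctx$map$position_Mb[k],
               logp = logp[k], stringsAsFactors = FALSE)
  }))
  rownames(peaks) <- NULL
  structure(list(map = ctx$map, logp = logp, peaks = peaks),
            class = "cc_scan")
}

align_phenotype <- function(ybar, strains) {
  if (!is.null(names(ybar))) {
    if (!all(strains %in% names(ybar))) {
      stop("phenotype names do not cover the scanned strains")
    }
    return(as.numeric(ybar[strains]))
  }
  if (length(ybar) != length(strains)) {
    stop("phenotype length does not match the strain subset")
  }
  as.numeric(ybar)
}

#' @export
print.cc_scan <- function(x, ...) {
  cat(sprintf("cc_scan: %d loci, max logP %.2f at %s (chr %s)\n",
              length(x$logp), max(x$logp),
              x$map$locus_id[which.max(x$logp)],
              x$map$chromosome[which.max(x$logp)]))
  invisible(x)
}

#' Batch permutation genome scans
#'
#' Runs genome scans for a set of permutations of the strain means and
#' returns each permutation's genome-wide maximum logP.  The per-locus
#' orthogonal decompositions are computed once and applied to all permuted
#' phenotype columns in a single matrix product, so the result is equal
#' (to numerical precision) to scanning each permuted vector independently.
#'
#' @param ybar Strain-mean vector.
#' @param table A [founder_prob_table()] or [scan_context()].
#' @param strains Strain subset (ignored for a context).
#' @param permutations Integer matrix, `n x k`; each column a permutation
#'   (bijection) of `1..n`.
#' @return Numeric k-vector of genome-wide maximum logPs.
#' @export
batch_permutation_scans <- function(ybar, table, strains = NULL, permutations) {
  ctx <- if (inherits(table, "scan_context")) table else
    scan_context(table, strains)
  y <- align_phenotype(ybar, ctx$strains)
  permutations <- as.matrix(permutations)
  if (nrow(permutations) != ctx$n) stop("permutation length does not match strains")
  for (j in seq_len(ncol(permutations))) {
    p <- permutations[, j]
    if (!identical(sort(as.integer(p)), seq_len(ctx$n))) {
      stop("column ", j, " is not a permutation of 1..n")
    }
  }
  Y <- matrix(y[permutations], nrow = ctx$n)
  logp <- scan_context_logp(ctx, Y)
  apply(logp, 2, max)
}

#' Permutation-calibrated genome-wide significance threshold
#'
#' Permutes the strain means `n_perm` times, records each permutation's
#' genome-wide maximum logP, fits a generalized extreme value distribution
#' to the maxima by maximum likelihood, and returns the upper-`alpha`
#' quantile of the fitted GEV as the significance threshold.  If the GEV
#' fit fails, the empirical `1 - alpha` quantile of the maxima is used
#' instead and the method is recorded as `"empirical"`.
#'
#' @param ybar Strain-mean vector.
#' @param table A [founder_prob_table()] or [scan_context()].
#' @param strains Strain subset (ignored for a context).
#' @param n_perm Number of permutations (default 100; >= 20 recommended).
#' @param alpha Genome-wide error rate (default 0.05).
#' @param seed Optional integer seed for the permutation draws.
#' @return Object of class `cc_threshold`: `alpha`, `value`, `gev`
#'   (loc/scale/shape), `n_perm`, `maxima`, `method`.
#' @export
permutation_thresholds <- function(ybar, table, strains = NULL,
                                   n_perm = 100, alpha = 0.05, seed = NULL) {
  stopifnot(n_perm >= 20, alpha > 0, alpha < 1)
  ctx <- if (inherits(table, "scan_context")) table else
    scan_context(table, strains)
  if (!is.null(seed)) set.seed(seed)
  perms <- replicate(n_perm, sample.int(ctx$n))
  maxima <- batch_permutation_scans(ybar, ctx, permutations = perms)
  threshold_from_maxima(maxima, alpha, n_perm)
}

# shared GEV-or-empirical thresholding of a vector of scan maxima
threshold_from_maxima <- function(maxima, alpha, n_perm = length(maxima)) {
  fit <- fit_gev(maxima)
  if (is.na(fit$loc) || fit$convergence != 0L || fit$scale <= 0) {
    value <- as.numeric(stats::quantile(maxima, 1 - alpha, type = 7))
    method <- "empirical"
    gev <- c(loc = NA_real_, scale = NA_real_, shape = NA_real_)
  } else {
    value <- qgev(1 - alpha, fit$loc, fit$scale, fit$shape)
    method <- "gev"
    gev <- c(loc = fit$loc, scale = fit$scale, shape = fit$shape)
  }
  structure(list(alpha = alpha, value = max(value, 0), gev = gev,
                 n_perm = n_perm, maxima = maxima, method = method),
            class = "cc_threshold")
}

#' @export
print.cc_threshold <- function(x, ...) {
  cat(sprintf("cc_threshold: logP >= %.3f at alpha = %.3g (%s, %d permutations)\n",
              x$value, x$alpha, x$method, x$n_perm))
  invisible(x)
}

#' R-squared of the haplotype model at one locus
#'
#' The proportion of strain-mean variance explained by the eight-allele
#' haplotype regression at a locus -- the effect-size estimate recorded at
#' detected peaks when measuring the Beavis effect.
#'
#' @param ctx A [scan_context()].
#' @param ybar Strain-mean vector.
#' @param locus Locus index into the context map.
#' @return Numeric scalar in [0, 1].
#' @export
locus_r2 <- function(ctx, ybar, locus) {
  y <- align_phenotype(ybar, ctx$strains)
  idx <- which(ctx$group == locus)
  Q <- ctx$QB[, idx, drop = FALSE]
  ess <- sum(crossprod(Q, y)^2)       # includes the intercept direction
  mean_ss <- sum(y)^2 / ctx$n
  tss <- sum(y^2) - mean_ss
  if (tss <= 0) return(0)
  min(max((ess - mean_ss) / tss, 0), 1)
}

#' Serialize a scan to a delimited table
#'
#' @param scan A `cc_scan`.
#' @param path Output file (CSV).
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  data.table::fwrite(data.table::data.table(
    locus_id = scan$map$locus_id, chromosome = scan$map$chromosome,
    position_Mb = scan$map$position_Mb, logp = scan$logp), path)
  invisible(path)
}
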