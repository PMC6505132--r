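#' Classify a genome scan against the simulated QTL
#'
#' Applies the detection rules of the power analysis:
#' \itemize{
#'   \item \strong{true positive} -- the maximum logP within +-`window` Mb
#'     of the simulated QTL exceeds the threshold; the location error is the
#'     distance in Mb from the window peak to the true position.
#'   \item \strong{false positive} -- any locus on a chromosome other than
#'     the QTL chromosome exceeds the threshold.  A simulation can be both a
#'     true and a false positive; the flags are counted independently.
#'   \item \strong{disregarded} -- no significant locus inside the window,
#'     but a significant locus elsewhere on the QTL chromosome.  Such
#'     simulations count as neither true nor false positives (this loses
#'     their off-chromosome false positives too, biasing FPR slightly
#'     downward, but avoids ambiguous edge cases).
#' }
#'
#' @param scan A `cc_scan` from [scan_genome()].
#' @param threshold A `cc_threshold` or a numeric logP cutoff.
#' @param true_locus Locus id of the simulated QTL (must be in the scan map).
#' @param window Half-width of the true-positive window in Mb (default 5).
#' @return List of class `detection_outcome`: `label` (one of
#'   `true_positive`, `false_positive_only`, `disregarded`, `no_detection`),
#'   `false_positive` flag, `distance_Mb` (NA unless TP), `peak_locus`,
#'   `peak_logp`.
#' @export
classify_detection <- function(scan, threshold, true_locus, window = 5) {
  thr <- if (inherits(threshold, "cc_threshold")) threshold$value else threshold
  map <- scan$map
  ti <- match(true_locus, map$locus_id)
  if (is.na(ti)) stop("true locus not in the scan map")
  qtl_chr <- map$chromosome[ti]
  qtl_pos <- map$position_Mb[ti]

  on_chr <- map$chromosome == qtl_chr
  in_window <- on_chr & abs(map$position_Mb - qtl_pos) <= window
  sig <- scan$logp > thr

  tp <- any(sig & in_window)
  fp <- any(sig & !on_chr)
  stray_on_chr <- any(sig & on_chr & !in_window)

  distance <- NA_real_; peak_locus <- NA_character_; peak_logp <- NA_real_
  if (tp) {
    widx <- which(in_window)
    k <- widx[which.max(scan$logp[widx])]
    distance <- abs(map$position_Mb[k] - qtl_pos)
    peak_locus <- map$locus_id[k]
    peak_logp <- scan$logp[k]
    label <- "true_positive"
  } else if (stray_on_chr) {
    label <- "disregarded"
    fp <- FALSE   # disregarded simulations drop out of both counts
  } else if (fp) {
    label <- "false_positive_only"
  } else {
    label <- "no_detection"
  }
  structure(list(label = label, false_positive = fp,
                 distance_Mb = distance, peak_locus = peak_locus,
                 peak_logp = peak_logp, threshold = thr),
            class = "detection_outcome")
}

#' Jeffreys interval for a binomial proportion
#'
#' Equal-tailed interval from the Beta(k + 1/2, n - k + 1/2) posterior, with
#' the usual boundary modification: the lower limit is 0 when `k = 0` and
#' the upper limit is 1 when `k = n`, so the interval always contains the
#' point estimate.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
jeffreys_interval <- function(k, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (k == 0) 0 else stats::qbeta(a, k + 0.5, n - k + 0.5)
  hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 0.5, n - k + 0.5)
  c(lower = lo, upper = hi)
}

#' Summarize detection outcomes into power and FPR
#'
#' Power is the proportion of true positives among all simulations; FPR the
#' proportion flagged as false positives (counted independently).  The
#' power interval is the 95% Jeffreys interval.  Location error statistics
#' come from [regularized_location_error()].
#'
#' @param outcomes List of [classify_detection()] results.
#' @param setting Optional named list/data frame row of setting descriptors
#'   echoed into the summary.
#' @param level Confidence level for the Jeffreys interval.
#' @return One-row data frame of class `power_summary`.
#' @export
summarize_power <- function(outcomes, setting = NULL, level = 0.95) {
  n <- length(outcomes)
  stopifnot(n >= 1)
  labels <- vapply(outcomes, `[[`, character(1), "label")
  k_tp <- sum(labels == "true_positive")
  k_fp <- sum(vapply(outcomes, `[[`, logical(1), "false_positive"))
  ci <- jeffreys_interval(k_tp, n, level)
  dists <- vapply(outcomes, `[[`, numeric(1), "distance_Mb")
  loc <- regularized_location_error(dists[!is.na(dists)], n_sims = n)
  out <- data.frame(
    n_sims = n, power = k_tp / n,
    power_lo = ci[["lower"]], power_hi = ci[["upper"]],
    fpr = k_fp / n,
    mean_loc_err_Mb = loc[["mean"]], q95_loc_err_Mb = loc[["q95"]],
    n_disregarded = sum(labels == "disregarded"),
    stringsAsFactors = FALSE)
  if (!is.null(setting)) out <- cbind(as.data.frame(setting), out)
  class(out) <- c("power_summary", class(out))
  out
}

#' Regularized location error of true-positive detections
#'
#' Mean and 95% quantile of the distance (Mb) between detected and
#' simulated QTL, stabilised with prior pseudo-observations: the mean is a
#' weighted average of the observed distances with pseudo-observations at
#' 2.5 Mb, and the 95% quantile is the empirical quantile of the sample
#' augmented with pseudo-observations at 4.75 Mb.  Those priors are the
#' mean and 95% quantile of a peak uniformly distributed in the +-5 Mb
#' window, i.e. the behaviour of an arbitrarily weak but detected QTL.
#' The pseudo-observation count is 1% of `n_sims` (minimum 1); at the
#' reference 1,000 simulations per setting this is 10.
#'
#' @param distances Numeric vector of observed TP distances, each in
#'   `[0, window]`.
#' @param n_sims Number of simulations in the setting (determines the
#'   pseudo-observation count).
#' @param window Maximum possible distance (default 5 Mb).
#' @return Named numeric `c(mean, q95, n_pseudo)`.
#' @export
regularized_location_error <- function(distances, n_sims, window = 5) {
  if (length(distances) && (any(distances < 0) || any(distances > window))) {
    stop("distances must lie in [0, ", window, "]")
  }
  n_pseudo <- max(1L, round(0.01 * n_sims))
  prior_mean <- window / 2
  prior_q95 <- 0.95 * window
  m <- (sum(distances) + n_pseudo * prior_mean) / (length(distances) + n_pseudo)
  q <- as.numeric(stats::quantile(c(distances, rep(prior_q95, n_pseudo)),
                                  0.95, type = 7))
  c(mean = m, q95 = q, n_pseudo = n_pseudo)
}

# simulate + scan + threshold + classify for one drawn experiment;
# returns the outcome plus bookkeeping. ctx_cache holds a full-panel context.
run_one_simulation <- function(table, n_strains, m_alleles, h2_qtl,
                               definition, r, h2_strain, n_perm, alpha,
                               seed_s, ctx_full = NULL, window = 5,
                               max_resample = 100L) {
  set.seed(seed_s)
  vc <- variance_config(h2_qtl, h2_strain, r = r)
  n_degenerate <- 0L
  repeat {
    exper <- sample_experiment(table, n_strains, m_alleles)
    spec <- qtl_sim_spec(exper$locus, exper$series, vc, definition,
                         strains = exper$strains)
    phe <- tryCatch(simulate_phenotypes(spec, table),
                    ccpower_degenerate_locus = function(e) NULL)
    if (!is.null(phe)) break
    n_degenerate <- n_degenerate + 1L
    if (n_degenerate >= max_resample) {
      stop("exceeded ", max_resample, " degenerate-locus resamples")
    }
  }
  ctx <- if (!is.null(ctx_full) && identical(exper$strains, table$strains)) {
    ctx_full
  } else {
    scan_context(table, exper$strains)
  }
  y <- align_phenotype(phe$ybar, ctx$strains)
  perms <- replicate(n_perm, sample.int(ctx$n))
  logp <- scan_context_logp(ctx, cbind(y, matrix(y[perms], nrow = ctx$n)))
  thr <- threshold_from_maxima(apply(logp[, -1, drop = FALSE], 2, max),
                               alpha, n_perm)
  scan <- structure(list(map = ctx$map, logp = logp[, 1]), class = "cc_scan")
  outcome <- classify_detection(scan, thr, exper$locus, window = window)
  list(outcome = outcome, threshold = thr, n_degenerate = n_degenerate,
       locus = exper$locus, series = phe$truth$series$string,
       ctx = ctx, y = y, scan = scan)
}

#' Run a grid of power simulations
#'
#' For each grid setting and simulation: draw strains, causal locus and
#' allelic series; simulate strain means; scan the genome; calibrate a
#' permutation/GEV threshold; classify the detection.  Results are
#' aggregated per setting with [summarize_power()].  The per-simulation
#' seed is `base seed + simulation counter`, so any single simulation can
#' be reproduced independently.
#'
#' @param table A [founder_prob_table()] (typically reduced).
#' @param grid Data frame with columns `n_strains`, `h2_qtl`, `m_alleles`,
#'   `definition`; optional `r` (default 1) and `h2_strain` (default 0).
#' @param n_sims Simulations per setting.
#' @param n_perm Permutations per simulation (default 100).
#' @param alpha Genome-wide error rate (default 0.05).
#' @param seed Base integer seed.
#' @param window True-positive window half-width in Mb (default 5).
#' @return List with `summary` (one row per setting, including degenerate
#'   resample counts) and `outcomes` (one row per simulation).
#' @export
run_power_grid <- function(table, grid, n_sims, n_perm = 100, alpha = 0.05,
                           seed = 1L, window = 5) {
  grid <- as.data.frame(grid)
  stopifnot(nrow(grid) >= 1)
  if (is.null(grid$r)) grid$r <- 1L
  if (is.null(grid$h2_strain)) grid$h2_strain <- 0
  ctx_full <- if (any(grid$n_strains == n_strains(table))) {
    scan_context(table)
  } else NULL

  summaries <- vector("list", nrow(grid))
  outcome_rows <- list()
  counter <- 0L
  for (g in seq_len(nrow(grid))) {
    st <- grid[g, , drop = FALSE]
    outs <- vector("list", n_sims)
    n_degenerate <- 0L
    for (s in seq_len(n_sims)) {
      counter <- counter + 1L
      res <- run_one_simulation(table, st$n_strains, st$m_alleles, st$h2_qtl,
                                st$definition, st$r, st$h2_strain,
                                n_perm, alpha, seed_s = seed + counter,
                                ctx_full = ctx_full, window = window)
      outs[[s]] <- res$outcome
      n_degenerate <- n_degenerate + res$n_degenerate
      outcome_rows[[counter]] <- data.frame(
        setting = g, sim = s, label = res$outcome$label,
        false_positive = res$outcome$false_positive,
        distance_Mb = res$outcome$distance_Mb,
        threshold = res$threshold$value, locus = res$locus,
        series = res$series, stringsAsFactors = FALSE)
    }
    sm <- summarize_power(outs, setting = st)
    sm$n_degenerate_resampled <- n_degenerate
    summaries[[g]] <- sm
  }
  list(summary = do.call(rbind, summaries),
       outcomes = do.call(rbind, outcome_rows))
}

#' Null simulations under population structure
#'
#' Measures the genome-wide false positive rate when strain effects are
#' correlated through a kinship matrix (`u ~ N(0, K h2_strain)`, no QTL)
#' while the mapping and permutation-threshold protocol still assumes
#' exchangeability.  With `K = I` or `h2_strain = 0` the FPR should sit at
#' `alpha`; genuine structure (e.g. duplicated "cousin" strains) inflates
#' it.  A false positive is any significant locus anywhere in the genome.
#'
#' @param table A [founder_prob_table()]; all strains are used.
#' @param K Kinship matrix matching the table's strains.
#' @param h2_strain_grid Numeric vector of strain-effect fractions.
#' @param n_sims Simulations per grid point.
#' @param n_perm Permutations per simulation.
#' @param alpha Genome-wide error rate.
#' @param seed Base seed.
#' @return Data frame with one row per grid point: `h2_strain`, `fpr`,
#'   `n_sims`, `fpr_lo`, `fpr_hi` (Jeffreys).
#' @export
structured_null_experiment <- function(table, K, h2_strain_grid, n_sims,
                                       n_perm = 100, alpha = 0.05, seed = 1L) {
  K <- as.matrix(K)
  if (!all(table$strains %in% rownames(K))) {
    stop("kinship matrix does not cover the table strains")
  }
  Ksub <- K[table$strains, table$strains]
  Lk <- kinship_sqrt(Ksub)   # errors if K is not PSD within tolerance
  ctx <- scan_context(table)
  n <- ctx$n
  rows <- vector("list", length(h2_strain_grid))
  counter <- 0L
  for (g in seq_along(h2_strain_grid)) {
    h2s <- h2_strain_grid[g]
    stopifnot(h2s >= 0, h2s <= 1)
    k_fp <- 0L
    for (s in seq_len(n_sims)) {
      counter <- counter + 1L
      set.seed(seed + counter)
      u <- if (h2s == 0) rep(0, n) else
        rescale_pop_var(as.numeric(Lk %*% stats::rnorm(n)), h2s)
      eps <- if (h2s == 1) rep(0, n) else
        rescale_pop_var(stats::rnorm(n), 1 - h2s)
      y <- u + eps
      perms <- replicate(n_perm, sample.int(n))
      logp <- scan_context_logp(ctx, cbind(y, matrix(y[perms], nrow = n)))
      thr <- threshold_from_maxima(apply(logp[, -1, drop = FALSE], 2, max),
                                   alpha, n_perm)
      if (any(logp[, 1] > thr$value)) k_fp <- k_fp + 1L
    }
    ci <- jeffreys_interval(k_fp, n_sims)
    rows[[g]] <- data.frame(h2_strain = h2s, fpr = k_fp / n_sims,
                            n_sims = n_sims, fpr_lo = ci[["lower"]],
                            fpr_hi = ci[["upper"]])
  }
  do.call(rbind, rows)
}

#' Measure the Beavis effect (winner's curse)
#'
#' Simulates bi-allelic QTL under Definition DAMB with one replicate and no
#' strain effect, maps them, and -- for detections within the +-5 Mb window
#' -- records the ratio of the peak-locus model R^2 to the simulated
#' `h2_qtl`.  Conditioning on detection inflates the ratio above 1, most
#' strongly for small samples and small effects.
#'
#' @param table A [founder_prob_table()].
#' @param n_strains_grid Numbers of strains to test.
#' @param h2_qtl_grid Simulated effect sizes (Definition DAMB).
#' @param n_sims Simulations per setting.
#' @param n_perm Permutations per simulation.
#' @param alpha Genome-wide error rate.
#' @param seed Base seed.
#' @param window Detection window half-width in Mb (default 5).
#' @return Data frame with one row per setting: `n_strains`, `h2_qtl`,
#'   `n_detected`, `mean_ratio` (NA when nothing was detected).
#' @export
beavis_experiment <- function(table, n_strains_grid, h2_qtl_grid, n_sims,
                              n_perm = 100, alpha = 0.05, seed = 1L,
                              window = 5) {
  ctx_full <- if (any(n_strains_grid == n_strains(table))) {
    scan_context(table)
  } else NULL
  rows <- list()
  counter <- 0L
  for (ns in n_strains_grid) {
    for (h2 in h2_qtl_grid) {
      ratios <- numeric(0)
      for (s in seq_len(n_sims)) {
        counter <- counter + 1L
        res <- run_one_simulation(table, ns, m_alleles = 2, h2_qtl = h2,
                                  definition = "DAMB", r = 1L, h2_strain = 0,
                                  n_perm = n_perm, alpha = alpha,
                                  seed_s = seed + counter,
                                  ctx_full = ctx_full, window = window)
        if (res$outcome$label == "true_positive") {
          peak_idx <- match(res$outcome$peak_locus, res$ctx$map$locus_id)
          ratios <- c(ratios, locus_r2(res$ctx, res$y, peak_idx) / h2)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        n_strains = ns, h2_qtl = h2, n_sims = n_sims,
        n_detected = length(ratios),
        mean_ratio = if (length(ratios)) mean(ratios) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
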