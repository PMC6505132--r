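# Fixture builders shared across the suite.  All fixtures are generated in
# code; nothing is read from disk.

# random probability table: Dirichlet-like rows over the 36 states
random_prob_table <- function(n_strains = 12, loci_per_chr = c(5, 5),
                              seed = 1, concentration = 1) {
  set.seed(seed)
  chrs <- as.character(seq_along(loci_per_chr))
  L <- sum(loci_per_chr)
  probs <- array(0, dim = c(n_strains, L, 36))
  for (i in seq_len(n_strains)) {
    g <- matrix(stats::rgamma(L * 36, shape = concentration), L, 36)
    probs[i, , ] <- g / rowSums(g)
  }
  map <- data.frame(
    locus_id = sprintf("L%03d", seq_len(L)),
    chromosome = rep(chrs, loci_per_chr),
    position_Mb = unlist(lapply(loci_per_chr, function(k) seq_len(k) * 2)),
    stringsAsFactors = FALSE)
  founder_prob_table(probs, map, sprintf("S%02d", seq_len(n_strains)))
}

# one-hot table from a strains x loci matrix of state indices (1..36)
one_hot_table <- function(states, loci_per_chr = ncol(states),
                          positions = NULL) {
  n <- nrow(states); L <- ncol(states)
  chrs <- as.character(seq_along(loci_per_chr))
  probs <- array(0, dim = c(n, L, 36))
  for (i in seq_len(n)) probs[cbind(i, seq_len(L), states[i, ])] <- 1
  if (is.null(positions)) {
    positions <- unlist(lapply(loci_per_chr, function(k) seq_len(k) * 2))
  }
  map <- data.frame(
    locus_id = sprintf("L%03d", seq_len(L)),
    chromosome = rep(chrs, loci_per_chr),
    position_Mb = positions,
    stringsAsFactors = FALSE)
  founder_prob_table(probs, map, sprintf("S%02d", seq_len(n)))
}

# CC-like mosaic table, slightly softened so dosages are probabilistic
mosaic_table <- function(n_strains = 12, n_chr = 4, chr_len = 30,
                         softening = 0.05, seed = 1) {
  simulate_ri_panel(synthetic_genome_config(
    n_strains = n_strains,
    chr_lengths = stats::setNames(rep(chr_len, n_chr), as.character(seq_len(n_chr))),
    marker_spacing = 2, block_length = 10,
    softening = softening, seed = seed))
}

# state index of a homozygous founder (1..8) or heterozygous pair
state_of <- function(label) match(label, diplotype_states())

# independent brute-force scan oracle: lm + F-test locus by locus
oracle_scan_logp <- function(ybar, table, strains = table$strains, cap = 300) {
  sub <- if (identical(strains, table$strains)) table else
    subset_strains(table, strains)
  y <- as.numeric(ybar[strains])
  vapply(seq_len(n_loci(sub)), function(l) {
    dos <- haplotype_dosage(sub, l)
    fit <- stats::lm(y ~ dos)
    rss1 <- sum(stats::residuals(fit)^2)
    rss0 <- sum((y - mean(y))^2)
    df1 <- fit$rank - 1L
    df2 <- length(y) - fit$rank
    if (df1 < 1 || df2 < 1 || rss0 <= 1e-12 * max(sum(y^2), 1)) return(0)
    if (rss1 <= 1e-12 * rss0) return(cap)
    Fv <- ((rss0 - rss1) / df1) / (rss1 / df2)
    min(-stats::pf(Fv, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10), cap)
  }, numeric(1))
}
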