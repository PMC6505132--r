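#' Configuration for the synthetic RI-panel generator
#'
#' Parameters describing a CC-like recombinant inbred panel: 8 founders,
#' near-complete homozygosity, founder haplotype mosaics with geometric
#' block lengths along 19 autosomes plus an X treated as an autosome.
#'
#' Defaults emulate a desk-scale Collaborative Cross stand-in: 20
#' chromosomes of 90 Mb at 1 Mb marker spacing (~1,800 loci), expected
#' haplotype block length 15 Mb (a handful of recombination blocks per
#' chromosome), zero residual heterozygosity and hard (one-hot) probability
#' vectors.  Set `softening > 0` to smear mass off the true diplotype state
#' and mimic confident HMM output.
#'
#' @param n_strains Number of strains to simulate.
#' @param chr_lengths Named numeric vector of chromosome lengths in Mb;
#'   default 20 chromosomes (`"1"`..`"19"`, `"X"`) of 90 Mb.
#' @param marker_spacing Marker spacing in Mb (default 1).
#' @param block_length Expected haplotype block length in Mb (default 15);
#'   the per-interval founder switch probability is
#'   `marker_spacing / block_length`.
#' @param het_rate Probability that a haplotype block is residually
#'   heterozygous between two founders (default 0; CC strains are mostly
#'   homozygous).
#' @param softening Fraction of probability mass smeared uniformly off the
#'   true diplotype state onto the other 35 states, in [0, 1); default 0.
#'   The default "soft" setting used in examples, 0.05, leaves 0.95 mass on
#'   the truth.
#' @param seed Integer seed; generation is reproducible given the seed.
#' @return A list of class `synthetic_genome_config`.
#' @export
synthetic_genome_config <- function(n_strains = 50,
                                    chr_lengths = stats::setNames(rep(90, 20), c(as.character(1:19), "X")),
                                    marker_spacing = 1,
                                    block_length = 15,
                                    het_rate = 0,
                                    softening = 0,
                                    seed = 1L) {
  stopifnot(n_strains >= 2, all(chr_lengths > 0), marker_spacing > 0,
            block_length > 0, het_rate >= 0, het_rate <= 1,
            softening >= 0, softening < 1)
  if (sum(floor(chr_lengths / marker_spacing)) < 1) {
    stop("degenerate config: zero-length genome at this marker spacing")
  }
  structure(list(n_strains = as.integer(n_strains), n_founders = 8L,
                 chr_lengths = chr_lengths, marker_spacing = marker_spacing,
                 block_length = block_length, het_rate = het_rate,
                 softening = softening, seed = as.integer(seed)),
            class = "synthetic_genome_config")
}

#' Simulate a CC-like recombinant inbred panel
#'
#' Generates founder haplotype mosaic genomes: for each strain and
#' chromosome, founder labels follow a first-order Markov chain with switch
#' probability `marker_spacing / block_length` (switches move to a uniformly
#' chosen different founder), producing a homozygous mosaic of geometric
#' blocks.  With probability `het_rate` a block is made residually
#' heterozygous between its founder and a second, random founder.  One-hot
#' diplotype states are optionally smeared into proper probability vectors
#' by `softening`.  Every probability row sums to 1.
#'
#' Strain genomes are generated i.i.d., so the panel is exchangeable by
#' construction; the generator makes no attempt to reproduce realized CC
#' founder imbalance or breeding-funnel structure.
#'
#' @param config A [synthetic_genome_config()].
#' @return A [founder_prob_table()].
#' @export
#' @examples
#' tab <- simulate_ri_panel(synthetic_genome_config(
#'   n_strains = 6, chr_lengths = c("1" = 20, "2" = 20), seed = 42))
#' tab
simulate_ri_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_genome_config"))
  set.seed(config$seed)
  states <- diplotype_states()
  chr_names <- names(config$chr_lengths)
  n_markers <- pmax(1L, floor(config$chr_lengths / config$marker_spacing))
  L <- sum(n_markers)
  n <- config$n_strains
  switch_p <- min(1, config$marker_spacing / config$block_length)

  map <- data.frame(
    locus_id = unlist(lapply(seq_along(chr_names), function(c) {
      sprintf("c%s_%04d", chr_names[c], seq_len(n_markers[c]))
    })),
    chromosome = rep(chr_names, n_markers),
    position_Mb = unlist(lapply(n_markers, function(k) {
      (seq_len(k) - 0.5) * config$marker_spacing
    })),
    stringsAsFactors = FALSE
  )

  state_idx <- matrix(0L, n, L)
  offset <- 0L
  for (c in seq_along(chr_names)) {
    k <- n_markers[c]
    for (i in seq_len(n)) {
      founders <- integer(k)
      founders[1] <- sample.int(8L, 1L)
      if (k > 1) {
        switches <- stats::runif(k - 1) < switch_p
        for (j in 2:k) {
          founders[j] <- if (switches[j - 1]) {
            sample(setdiff(1:8, founders[j - 1]), 1L)
          } else founders[j - 1]
        }
      }
      # block boundaries -> optional residual heterozygosity per block
      block_id <- cumsum(c(1L, as.integer(diff(founders) != 0L)))
      st <- founders   # homozygous state index equals founder index
      if (config$het_rate > 0) {
        for (b in unique(block_id)) {
          if (stats::runif(1) < config$het_rate) {
            members <- which(block_id == b)
            f1 <- founders[members[1]]
            f2 <- sample(setdiff(1:8, f1), 1L)
            st[members] <- het_state_index(f1, f2)
          }
        }
      }
      state_idx[i, offset + seq_len(k)] <- st
    }
    offset <- offset + k
  }

  probs <- array(0, dim = c(n, L, 36))
  if (config$softening > 0) {
    probs[] <- config$softening / 35
  }
  on_truth <- 1 - config$softening
  for (i in seq_len(n)) {
    probs[cbind(i, seq_len(L), state_idx[i, ])] <- on_truth
  }
  founder_prob_table(probs, map, sprintf("SYN%03d", seq_len(n)))
}

# index of the heterozygous state for founders f1 < f2 in the 36-state order
het_state_index <- function(f1, f2) {
  a <- min(f1, f2); b <- max(f1, f2)
  # heterozygote block starts at 9; pairs (1,2),(1,3),...,(1,8),(2,3),...
  8L + (a - 1L) * 8L - (a * (a - 1L)) %/% 2L + (b - a)
}

#' Genome-wide founder contribution shares
#'
#' Mean haplotype-probability share of each founder over all strains and
#' loci; a diagnostic for founder balance.  Shares sum to 1.
#'
#' @param table A [founder_prob_table()].
#' @return Named numeric 8-vector.
#' @export
founder_contribution_table <- function(table) {
  dos <- dosage_array(table)
  shares <- apply(dos / 2, 3, mean)
  names(shares) <- founder_labels()
  shares
}
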