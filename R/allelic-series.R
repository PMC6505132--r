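#' Allelic series: partitions of the founders into functional alleles
#'
#' An allelic series groups the 8 founder haplotypes into `m <= 8`
#' functionally distinct alleles at a QTL.  It is represented by an
#' assignment vector (allele label per founder, canonically numbered by
#' first appearance scanning founders A to H) and the corresponding 8 x m
#' zero/one merge matrix `M` (rows sum to 1, no empty column), which maps
#' haplotype dosages to allele dosages in the design `X = D A M`.
#'
#' @param assignment Integer 8-vector of allele labels.
#' @return Object of class `allelic_series` with elements `assignment`,
#'   `m`, `M` (merge matrix), `string` (e.g. `"11122222"`).
#' @export
#' @examples
#' s <- allelic_series(c(1, 1, 1, 2, 2, 2, 2, 2))
#' s$M
#' balance_class(s)
allelic_series <- function(assignment) {
  assignment <- as.integer(assignment)
  if (length(assignment) != 8L) stop("assignment must label all 8 founders")
  assignment <- canonicalize_assignment(assignment)
  m <- max(assignment)
  M <- matrix(0L, nrow = 8, ncol = m,
              dimnames = list(founder_labels(), paste0("allele", seq_len(m))))
  M[cbind(1:8, assignment)] <- 1L
  structure(list(assignment = assignment, m = m, M = M,
                 string = paste(assignment, collapse = "")),
            class = "allelic_series")
}

#' @export
print.allelic_series <- function(x, ...) {
  cat(sprintf("allelic_series: %s (%d alleles, %s)\n",
              x$string, x$m, balance_class(x)))
  invisible(x)
}

# relabel alleles in order of first appearance (canonical form)
canonicalize_assignment <- function(assignment) {
  lab <- integer(max(assignment))
  nxt <- 0L
  out <- integer(8)
  for (i in 1:8) {
    a <- assignment[i]
    if (lab[a] == 0L) { nxt <- nxt + 1L; lab[a] <- nxt }
    out[i] <- lab[a]
  }
  out
}

#' Parse an allelic series from its 8-character string form
#'
#' @param string E.g. `"11122222"` for a 3v5 bi-allelic series.
#' @return An [allelic_series()].
#' @export
parse_series <- function(string) {
  allelic_series(as.integer(strsplit(string, "")[[1]]))
}

#' Enumerate all allelic series with exactly m alleles
#'
#' All set partitions of the 8 founders into exactly `m` nonempty blocks,
#' in canonical labeling with no duplicates.  The count equals the Stirling
#' number of the second kind S(8, m); in particular S(8, 2) = 127 bi-allelic
#' series.
#'
#' @param n_founders Must be 8.
#' @param m Number of functional alleles, 1..8.
#' @return List of [allelic_series()].
#' @export
enumerate_series <- function(n_founders = 8, m) {
  stopifnot(n_founders == 8)
  if (length(m) != 1 || m < 1 || m > 8) stop("m must be in 1..8")
  out <- list()
  # depth-first over restricted growth strings: founder i may take labels
  # 1..(max used so far + 1); canonical by construction
  recurse <- function(assign, max_used) {
    i <- length(assign) + 1L
    if (i > 8L) {
      if (max_used == m) out[[length(out) + 1L]] <<- allelic_series(assign)
      return(invisible())
    }
    # prune: remaining founders must be able to reach m labels
    if (max_used + (8L - i + 1L) < m) return(invisible())
    for (a in seq_len(min(max_used + 1L, m))) {
      recurse(c(assign, a), max(max_used, a))
    }
  }
  recurse(integer(0), 0L)
  out
}

#' Sample an allelic series uniformly
#'
#' Uniform draw over `enumerate_series(8, m)`; the enumeration is cached
#' per `m` within the session.
#'
#' @param m Number of functional alleles, 2..8 (a one-allele series carries
#'   no QTL variance).
#' @param seed Optional integer seed for a reproducible draw.
#' @return An [allelic_series()].
#' @export
sample_series <- function(m, seed = NULL) {
  if (length(m) != 1 || m < 2 || m > 8) stop("m must be in 2..8")
  if (!is.null(seed)) set.seed(seed)
  pool <- series_cache(m)
  pool[[sample.int(length(pool), 1L)]]
}

.series_env <- new.env(parent = emptyenv())
series_cache <- function(m) {
  key <- as.character(m)
  if (is.null(.series_env[[key]])) .series_env[[key]] <- enumerate_series(8, m)
  .series_env[[key]]
}

#' Balance class of an allelic series
#'
#' The sorted block-size signature, e.g. `"4v4"` for a balanced bi-allelic
#' series or `"7v1"` for one where a single founder carries the minor
#' allele.  Sizes are sorted in decreasing order and joined with `"v"`.
#'
#' @param series An [allelic_series()].
#' @return Character scalar.
#' @export
balance_class <- function(series) {
  sizes <- sort(tabulate(series$assignment, nbins = series$m),
                decreasing = TRUE)
  paste(sizes, collapse = "v")
}
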