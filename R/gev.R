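#' Generalized extreme value density, distribution, quantiles
#'
#' Standard three-parameter GEV with location `loc`, scale `scale` > 0 and
#' shape `shape` (`shape = 0` is the Gumbel limit).  Used to smooth the
#' distribution of permutation genome-scan maxima.
#'
#' @param x,q,p Numeric vectors.
#' @param loc,scale,shape GEV parameters.
#' @param log Return the log density?
#' @return Numeric vector.
#' @name gev
NULL

#' @rdname gev
#' @export
dgev <- function(x, loc = 0, scale = 1, shape = 0, log = FALSE) {
  stopifnot(scale > 0)
  z <- (x - loc) / scale
  if (abs(shape) < 1e-10) {
    logd <- -z - exp(-z) - log(scale)
  } else {
    t <- 1 + shape * z
    logd <- ifelse(t > 0,
                   -(1 / shape + 1) * log(pmax(t, .Machine$double.xmin)) -
                     pmax(t, .Machine$double.xmin)^(-1 / shape) - log(scale),
                   -Inf)
  }
  if (log) logd else exp(logd)
}

#' @rdname gev
#' @export
pgev <- function(q, loc = 0, scale = 1, shape = 0) {
  stopifnot(scale > 0)
  z <- (q - loc) / scale
  if (abs(shape) < 1e-10) return(exp(-exp(-z)))
  t <- 1 + shape * z
  out <- ifelse(t > 0, exp(-t^(-1 / shape)),
                ifelse(shape > 0, 0, 1))
  out
}

#' @rdname gev
#' @export
qgev <- function(p, loc = 0, scale = 1, shape = 0) {
  stopifnot(scale > 0, all(p > 0), all(p < 1))
  if (abs(shape) < 1e-10) return(loc - scale * log(-log(p)))
  loc + scale * ((-log(p))^(-shape) - 1) / shape
}

#' Fit a GEV by maximum likelihood
#'
#' Nelder-Mead maximisation of the GEV log likelihood, initialised at the
#' Gumbel moment estimates (`scale = sd * sqrt(6)/pi`,
#' `loc = mean - 0.5772 * scale`, `shape = 0.1`).
#'
#' @param x Numeric sample (e.g. permutation maxima), length >= 20
#'   recommended for stability.
#' @return List with `loc`, `scale`, `shape`, `convergence` (0 = success),
#'   `logLik`.
#' @export
fit_gev <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2 || stats::sd(x) == 0) {
    return(list(loc = NA_real_, scale = NA_real_, shape = NA_real_,
                convergence = 1L, logLik = NA_real_))
  }
  s0 <- stats::sd(x) * sqrt(6) / pi
  m0 <- mean(x) - 0.57721566 * s0
  nll <- function(par) {
    if (par[2] <= 0) return(1e10)
    ll <- dgev(x, par[1], par[2], par[3], log = TRUE)
    if (any(!is.finite(ll))) return(1e10)
    -sum(ll)
  }
  fit <- tryCatch(
    stats::optim(c(m0, s0, 0.1), nll, method = "Nelder-Mead",
                 control = list(maxit = 2000)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) {
    return(list(loc = NA_real_, scale = NA_real_, shape = NA_real_,
                convergence = 1L, logLik = NA_real_))
  }
  list(loc = fit$par[1], scale = fit$par[2], shape = fit$par[3],
       convergence = fit$convergence, logLik = -fit$value)
}
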