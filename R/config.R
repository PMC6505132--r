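#' Validate an experiment configuration
#'
#' Checks field presence, types and ranges, reporting the offending field
#' by name.  A configuration is a plain named list (typically read from a
#' YAML file) with:
#' \itemize{
#'   \item `experiment`: `"power"`, `"null"` or `"beavis"`.
#'   \item `genome`: either `list(cache = "<dir>")` or
#'     `list(synthetic = list(...))` with [synthetic_genome_config()]
#'     fields.
#'   \item `grid`: axes for the chosen experiment -- for `"power"`:
#'     `n_strains`, `h2_qtl`, `m_alleles` (vectors crossed into a grid),
#'     `definition`, and scalars `r`, `h2_strain`; for `"null"`:
#'     `h2_strain` vector; for `"beavis"`: `n_strains` and `h2_qtl`
#'     vectors.
#'   \item `n_sims`, `n_perm`, `alpha`, `seed`.
#' }
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config list, invisibly typed.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  fail <- function(field, why) stop("config$", field, ": ", why, call. = FALSE)
  if (is.null(config$experiment) ||
      !config$experiment %in% c("power", "null", "beavis")) {
    fail("experiment", "must be one of 'power', 'null', 'beavis'")
  }
  if (is.null(config$genome) ||
      (is.null(config$genome$cache) && is.null(config$genome$synthetic))) {
    fail("genome", "needs either a 'cache' path or a 'synthetic' spec")
  }
  if (is.null(config$n_sims) || config$n_sims < 1) fail("n_sims", "must be >= 1")
  config$n_perm <- config$n_perm %||% 100
  if (config$n_perm < 20) fail("n_perm", "must be >= 20")
  config$alpha <- config$alpha %||% 0.05
  if (config$alpha <= 0 || config$alpha >= 1) fail("alpha", "must be in (0,1)")
  config$seed <- config$seed %||% 1L
  g <- config$grid
  if (is.null(g)) fail("grid", "is required")
  if (config$experiment == "power") {
    for (f in c("n_strains", "h2_qtl", "m_alleles")) {
      if (is.null(g[[f]])) fail(paste0("grid$", f), "is required")
    }
    g$definition <- g$definition %||% "B"
    if (!all(g$definition %in% c("B", "MB", "DAMB"))) {
      fail("grid$definition", "must be B, MB or DAMB")
    }
    g$r <- g$r %||% 1
    g$h2_strain <- g$h2_strain %||% 0
    if (any(g$h2_qtl + g$h2_strain > 1)) {
      fail("grid$h2_qtl", "h2_qtl + h2_strain must not exceed 1")
    }
    if (any(g$h2_qtl < 0) || any(g$h2_strain < 0)) {
      fail("grid$h2_qtl", "variance fractions must be nonnegative")
    }
  } else if (config$experiment == "null") {
    if (is.null(g$h2_strain)) fail("grid$h2_strain", "is required")
    if (any(g$h2_strain < 0 | g$h2_strain > 1)) {
      fail("grid$h2_strain", "must be in [0,1]")
    }
  } else {
    for (f in c("n_strains", "h2_qtl")) {
      if (is.null(g[[f]])) fail(paste0("grid$", f), "is required")
    }
  }
  config$grid <- g
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paper-scale default settings
#'
#' The named preset of the full-scale study design: 100 permutations, alpha
#' 0.05, 1,000 simulations per setting, strain numbers 10-70 by 5 plus 72,
#' QTL effect sizes 1% and 5-95% by 5, and 2/3/8 functional alleles.
#' Desk-scale runs subset these axes.
#'
#' @return Named list of defaults.
#' @export
default_settings <- function() {
  list(n_perm = 100, alpha = 0.05, n_sims = 1000,
       n_strains = c(seq(10, 70, by = 5), 72),
       h2_qtl = c(0.01, seq(0.05, 0.95, by = 0.05)),
       m_alleles = c(2, 3, 8),
       definition = c("B", "DAMB"))
}

#' Run an experiment from a configuration
#'
#' Loads or simulates the genome, dispatches to [run_power_grid()],
#' [structured_null_experiment()] or [beavis_experiment()], and writes the
#' results to `out_dir`: `summary.csv`, `outcomes.csv` (power runs), an
#' echo of the configuration (`config.yaml`), and `provenance.json` with
#' the seed, package version, and a checksum of the genome probabilities.
#' Identical config + seed reproduces byte-identical summaries.
#'
#' @param config Named list or YAML path; see [validate_config()].
#' @param out_dir Output directory (created if needed).
#' @return The output directory, invisibly; results are also returned in
#'   the `"results"` attribute.
#' @export
run_from_config <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  table <- if (!is.null(config$genome$cache)) {
    load_genome_cache(config$genome$cache)
  } else {
    syn <- config$genome$synthetic
    args <- syn[intersect(names(syn), names(formals(synthetic_genome_config)))]
    if (!is.null(syn$chr_lengths)) args$chr_lengths <- unlist(syn$chr_lengths)
    simulate_ri_panel(do.call(synthetic_genome_config, args))
  }

  g <- config$grid
  results <- switch(config$experiment,
    power = {
      grid <- expand.grid(n_strains = g$n_strains, h2_qtl = g$h2_qtl,
                          m_alleles = g$m_alleles, definition = g$definition,
                          stringsAsFactors = FALSE)
      grid$r <- g$r; grid$h2_strain <- g$h2_strain
      res <- run_power_grid(table, grid, n_sims = config$n_sims,
                            n_perm = config$n_perm, alpha = config$alpha,
                            seed = config$seed)
      data.table::fwrite(res$summary, file.path(out_dir, "summary.csv"))
      data.table::fwrite(res$outcomes, file.path(out_dir, "outcomes.csv"))
      res
    },
    null = {
      K <- compute_kinship(table)
      res <- structured_null_experiment(table, K, g$h2_strain,
                                        n_sims = config$n_sims,
                                        n_perm = config$n_perm,
                                        alpha = config$alpha,
                                        seed = config$seed)
      data.table::fwrite(res, file.path(out_dir, "summary.csv"))
      res
    },
    beavis = {
      res <- beavis_experiment(table, g$n_strains, g$h2_qtl,
                               n_sims = config$n_sims,
                               n_perm = config$n_perm,
                               alpha = config$alpha, seed = config$seed)
      data.table::fwrite(res, file.path(out_dir, "summary.csv"))
      res
    })

  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(
    list(seed = config$seed,
         package_version = as.character(utils::packageVersion("ccpower")),
         r_version = R.version.string,
         genome = list(n_strains = n_strains(table), n_loci = n_loci(table),
                       checksum = genome_checksum(table))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  structure(invisible(out_dir), results = results)
}

# order-stable checksum of the probability array and map
genome_checksum <- function(table) {
  v <- c(as.numeric(table$probs),
         as.numeric(table$map$position_Mb))
  sprintf("%.10e", sum(v * seq_along(v) %% 97))
}
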