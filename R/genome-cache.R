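#' Write a genome cache directory
#'
#' Serialises a [founder_prob_table()] to a directory of plain-text tables:
#' one CSV per chromosome (named `chr<label>.csv`, rows strain-major over
#' strain x locus, columns `strain`, `locus_id`, then the 36 diplotype state
#' probabilities), a `marker_map.csv` (`locus_id`, `chromosome`,
#' `position_Mb`), and a `cache.json` sidecar recording the strain list and
#' the diplotype state order.  The layout mirrors the per-chromosome cache
#' directories conventionally used for founder-probability data in
#' multiparental panels.
#'
#' @param table A [founder_prob_table()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @seealso [load_genome_cache()]
#' @export
save_genome_cache <- function(table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  states <- diplotype_states()
  for (chr in unique(table$map$chromosome)) {
    loci <- table$map$locus_id[table$map$chromosome == chr]
    rows <- vector("list", length(table$strains))
    for (i in seq_along(table$strains)) {
      block <- table$probs[i, loci, , drop = FALSE]
      dt <- data.table::as.data.table(matrix(block, nrow = length(loci),
                                             dimnames = list(NULL, states)))
      dt <- cbind(data.table::data.table(strain = table$strains[i],
                                         locus_id = loci), dt)
      rows[[i]] <- dt
    }
    data.table::fwrite(data.table::rbindlist(rows),
                       file.path(dir, paste0("chr", chr, ".csv")))
  }
  data.table::fwrite(
    data.table::as.data.table(
      table$map[, c("locus_id", "chromosome", "position_Mb")]),
    file.path(dir, "marker_map.csv"))
  jsonlite::write_json(
    list(strains = table$strains, states = states,
         n_loci = nrow(table$map),
         chromosomes = unique(table$map$chromosome)),
    file.path(dir, "cache.json"), auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}

#' Load a genome cache directory
#'
#' Reads the per-chromosome probability tables written by
#' [save_genome_cache()] back into a validated [founder_prob_table()].
#' Chromosomes are concatenated in marker-map order; every probability row
#' must be nonnegative and sum to 1 within `tol`.
#'
#' @param dir Cache directory containing `marker_map.csv`, `cache.json`, and
#'   one `chr<label>.csv` per chromosome.
#' @param tol Probability sum tolerance.
#' @return A [founder_prob_table()].
#' @export
load_genome_cache <- function(dir, tol = 1e-6) {
  map_path <- file.path(dir, "marker_map.csv")
  meta_path <- file.path(dir, "cache.json")
  if (!file.exists(map_path)) stop("missing marker_map.csv in ", dir)
  if (!file.exists(meta_path)) stop("missing cache.json in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  states <- diplotype_states()
  if (!identical(as.character(meta$states), states)) {
    stop("cache.json state order does not match the package convention ",
         "(homozygotes AA..HH then heterozygotes AB..GH)")
  }
  strains <- as.character(meta$strains)
  map <- as.data.frame(data.table::fread(map_path,
                                         colClasses = list(character = c("locus_id", "chromosome"))))
  if (anyDuplicated(map$locus_id)) stop("duplicated locus_id in marker map")
  probs <- array(NA_real_, dim = c(length(strains), nrow(map), 36),
                 dimnames = list(strains, map$locus_id, states))
  for (chr in unique(map$chromosome)) {
    path <- file.path(dir, paste0("chr", chr, ".csv"))
    if (!file.exists(path)) stop("missing chromosome file: ", path)
    dt <- data.table::fread(path, colClasses = list(character = c("strain", "locus_id")))
    if (!all(states %in% names(dt))) {
      stop("chromosome file ", path, " lacks the 36 state columns")
    }
    loci <- map$locus_id[map$chromosome == chr]
    for (i in seq_along(strains)) {
      block <- dt[dt$strain == strains[i], ]
      if (!identical(block$locus_id, loci)) {
        stop("chromosome file ", path, " rows for strain ", strains[i],
             " do not match the marker map")
      }
      probs[i, loci, ] <- as.matrix(block[, states, with = FALSE])
    }
  }
  founder_prob_table(probs, map, strains, tol = tol)
}
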