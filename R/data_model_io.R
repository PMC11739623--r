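# Typed readers/writers for the four input tables, the Newick tree,
# posterior archives and the run configuration, plus the shared domain
# constructors and validators.

BAT_SPECIES <- c("perspicillata", "sowelli", "castanea")
SEX_LEVELS <- c("female", "male")
AGE_LEVELS <- c("adult", "subadult", "juvenile")
REPRO_LEVELS <- c("non_reproductive", "reproductive")

#' Construct a validated bat-record table
#'
#' One row per captured individual: species, sex, age class, reproductive
#' condition, forearm length (mm), body mass (g), and a 0/1 occurrence
#' vector over plant species (presence of the plant's seeds in the fecal
#' sample).
#'
#' @param df data.frame with columns `bat_id`, `species`, `sex`,
#'   `age_class`, `repro`, `forearm`, `mass`.
#' @param occurrence integer/numeric matrix of 0/1 with one column per
#'   plant species; column names are the plant labels.
#' @return object of class `bat_records`: the data.frame with the
#'   occurrence matrix attached as `attr(x, "occurrence")`.
#' @export
bat_records <- function(df, occurrence) {
  req <- c("bat_id", "species", "sex", "age_class", "repro", "forearm", "mass")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("bat table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$bat_id)) {
    dup <- unique(df$bat_id[duplicated(df$bat_id)])
    stop("duplicate bat_id: ", paste(dup, collapse = ", "))
  }
  .check_levels(df$species, BAT_SPECIES, "species")
  .check_levels(df$sex, SEX_LEVELS, "sex")
  .check_levels(df$age_class, AGE_LEVELS, "age_class")
  .check_levels(df$repro, REPRO_LEVELS, "repro")
  for (v in c("forearm", "mass")) {
    x <- df[[v]]
    bad <- which(!is.na(x) & (!is.finite(x) | x <= 0))
    if (length(bad)) stop(v, " must be finite and positive; offending rows: ",
                          paste(bad, collapse = ", "))
  }
  occurrence <- as.matrix(occurrence)
  # canonicalise: keep only dim/dimnames (inputs may carry diet_matrix
  # attributes)
  occurrence <- matrix(occurrence, nrow(occurrence), ncol(occurrence),
                       dimnames = dimnames(occurrence))
  if (nrow(occurrence) != nrow(df))
    stop("occurrence matrix has ", nrow(occurrence), " rows but table has ", nrow(df))
  bad <- which(!(occurrence %in% c(0, 1)))
  if (length(bad)) {
    rows <- sort(unique(((bad - 1) %% nrow(occurrence)) + 1))
    stop("occurrence values outside {0,1} in rows: ", paste(rows, collapse = ", "))
  }
  if (ncol(occurrence) > 0 && is.null(colnames(occurrence)))
    stop("occurrence matrix must carry plant labels as column names")
  storage.mode(occurrence) <- "integer"
  out <- df[, req]
  attr(out, "occurrence") <- occurrence
  class(out) <- c("bat_records", "data.frame")
  out
}

.check_levels <- function(x, levels, what) {
  bad <- setdiff(unique(as.character(x[!is.na(x)])), levels)
  if (length(bad))
    stop("unknown ", what, " level(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(levels, collapse = "/"), ")")
  invisible(TRUE)
}

#' Construct a diet matrix
#'
#' @param m numeric matrix, samples in rows, plant species in columns.
#' @param mode `"presence_absence"` (entries in \{0,1\}) or
#'   `"fractional_composition"` (entries in \[0,1\], nonzero rows sum to 1).
#' @param species_labels plant labels; defaults to `colnames(m)`.
#' @return classed matrix `diet_matrix` with attributes `mode` and
#'   `species_labels`.
#' @export
#' @param simplex enforce the row-sum-1 constraint for
#'   fractional-composition data. Real compositions satisfy it; latent
#'   censored values generated from the model's own likelihood (used in
#'   parameter-recovery tests) need not.
diet_matrix <- function(m, mode = c("presence_absence", "fractional_composition"),
                        species_labels = colnames(m), simplex = TRUE) {
  mode <- match.arg(mode)
  m <- as.matrix(m)
  if (is.null(species_labels)) stop("diet matrix needs plant species labels")
  if (length(species_labels) != ncol(m)) stop("label/column count mismatch")
  colnames(m) <- species_labels
  if (mode == "presence_absence") {
    if (!all(m %in% c(0, 1))) stop("presence_absence entries must be 0/1")
  } else {
    if (any(m < 0 | m > 1)) stop("fractional_composition entries must lie in [0,1]")
    if (simplex) {
      rs <- rowSums(m)
      if (any(rs > 0 & abs(rs - 1) > 1e-8))
        stop("fractional_composition rows must sum to 1 (or 0 if all-absent)")
    }
  }
  structure(m, mode = mode, species_labels = species_labels,
            class = c("diet_matrix", "matrix", "array"))
}

#' @export
print.diet_matrix <- function(x, ...) {
  cat("diet_matrix:", nrow(x), "samples x", ncol(x), "plant species, mode =",
      attr(x, "mode"), "\n")
  invisible(x)
}

#' Read a bat-record table and its occurrence matrix from delimited text
#'
#' Plant-occurrence columns are identified either by a declared prefix
#' (e.g. `"piper_"`) or by an explicit column list; the remaining schema
#' columns are mapped by name.
#'
#' @param path path to a delimited text file with header.
#' @param plant_prefix prefix identifying occurrence columns.
#' @param plant_cols explicit occurrence column names (overrides prefix).
#' @param sep field separator, default comma.
#' @return list with `records` (a [bat_records] table) and `diet`
#'   (a presence/absence [diet_matrix]).
#' @export
read_bat_table <- function(path, plant_prefix = "piper_", plant_cols = NULL,
                           sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(plant_cols))
    plant_cols <- grep(paste0("^", plant_prefix), names(df), value = TRUE)
  if (!length(plant_cols)) stop("no plant occurrence columns found in ", path)
  occ <- as.matrix(df[, plant_cols, drop = FALSE])
  labels <- sub(paste0("^", plant_prefix), "", plant_cols)
  bad <- which(apply(occ, 1, function(r) any(!(r %in% c(0, 1)))))
  if (length(bad))
    stop("malformed occurrence values (not 0/1) in row(s): ",
         paste(bad, collapse = ", "))
  colnames(occ) <- labels
  recs <- bat_records(df[, setdiff(names(df), plant_cols), drop = FALSE], occ)
  diet <- diet_matrix(occ, "presence_absence")
  list(records = recs, diet = diet)
}

#' Write a bat-record table (inverse of [read_bat_table])
#'
#' @param records a [bat_records] object.
#' @param path output path.
#' @param plant_prefix prefix to prepend to plant labels for the
#'   occurrence columns.
#' @export
write_bat_table <- function(records, path, plant_prefix = "piper_") {
  occ <- attr(records, "occurrence")
  out <- cbind(as.data.frame(records),
               as.data.frame(occ) |> stats::setNames(paste0(plant_prefix, colnames(occ))))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bite-force table
#'
#' Expects columns `bat_id`, `species`, `sex`, `head_length`, `head_width`,
#' `head_height`, `forearm`, `mass`, `max_bite_force`. Only adult,
#' non-pregnant/non-lactating individuals enter the allometric models; if
#' the file carries an `eligible` column, ineligible rows are dropped with
#' a message.
#'
#' @param path CSV path.
#' @return data.frame of class `biteforce_records`.
#' @export
read_biteforce_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("bat_id", "species", "sex", "head_length", "forearm", "mass",
           "max_bite_force")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("bite-force table missing columns: ",
                         paste(miss, collapse = ", "))
  if ("eligible" %in% names(df)) {
    drop <- !as.logical(df$eligible)
    if (any(drop)) message("dropping ", sum(drop), " ineligible bite-force record(s)")
    df <- df[!drop, , drop = FALSE]
  }
  .check_levels(df$species, BAT_SPECIES, "species")
  .check_levels(df$sex, SEX_LEVELS, "sex")
  if (any(df$max_bite_force <= 0)) stop("max_bite_force must be positive")
  if (any(df$head_length <= 0)) stop("head_length must be positive")
  class(df) <- c("biteforce_records", "data.frame")
  df
}

#' Read a plant fruit/seed trait table
#'
#' Expects `plant_species`, `fruit_length`, `fruit_width`, `seed_length`,
#' `seed_width` (mm); shape indices (length/width) are computed if absent.
#'
#' @param path CSV path.
#' @return data.frame of class `plant_traits` with `fruit_shape_index`
#'   and `seed_shape_index` columns.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("plant_species", "fruit_length", "fruit_width", "seed_length",
           "seed_width")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("trait table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$plant_species)) stop("duplicate plant_species in trait table")
  if (is.null(df$fruit_shape_index))
    df$fruit_shape_index <- shape_index(df$fruit_length, df$fruit_width)
  if (is.null(df$seed_shape_index))
    df$seed_shape_index <- shape_index(df$seed_length, df$seed_width)
  if (any(df$fruit_shape_index <= 0) || any(df$seed_shape_index <= 0))
    stop("shape indices must be strictly positive")
  class(df) <- c("plant_traits", "data.frame")
  df
}

#' Read a single-tree Newick file
#'
#' @param path Newick file with branch lengths. Ultrametricity is not
#'   assumed.
#' @param required_tips optional character vector; an error lists any of
#'   these missing from the tree.
#' @return an [ape::read.tree] `phylo` object.
#' @export
read_newick <- function(path, required_tips = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1]]
  }
  if (length(tr$tip.label) == 0) stop("tree has zero tips")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels in tree")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch lengths in tree")
  if (!is.null(required_tips)) {
    miss <- setdiff(required_tips, tr$tip.label)
    if (length(miss))
      stop("tree is missing modeled species: ", paste(miss, collapse = ", "))
  }
  tr
}

#' Analysis configuration
#'
#' Bundles the knobs shared by the pipeline stages. Defaults follow the
#' published run lengths for the joint model (20,000 iterations, 4,000
#' burn-in).
#'
#' @param mode response mode for the joint model.
#' @param n_iterations,n_burnin,thin,n_chains MCMC controls.
#' @param rng_seed integer seed.
#' @param covariates modeled bat covariates (design columns are built
#'   from these).
#' @param rare_threshold plant species whose share of total presence
#'   observations falls below this are dropped (default 0.01).
#' @param hpd_prob HPD mass for interval summaries (default 0.95).
#' @param dimension_reduction reserved; only `"none"` is implemented.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(mode = c("fractional_composition", "presence_absence"),
                            n_iterations = 20000L, n_burnin = 4000L,
                            thin = 10L, n_chains = 2L, rng_seed = 1L,
                            covariates = c("species", "age_class", "sex",
                                           "repro", "mass", "forearm"),
                            rare_threshold = 0.01, hpd_prob = 0.95,
                            dimension_reduction = "none") {
  mode <- match.arg(mode)
  stopifnot(n_burnin < n_iterations, thin >= 1, n_chains >= 1,
            rare_threshold >= 0, rare_threshold < 1,
            hpd_prob > 0, hpd_prob < 1)
  if (!identical(dimension_reduction, "none"))
    stop("only dimension_reduction = 'none' is implemented")
  structure(list(mode = mode, n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 n_chains = as.integer(n_chains), rng_seed = as.integer(rng_seed),
                 covariates = covariates, rare_threshold = rare_threshold,
                 hpd_prob = hpd_prob, dimension_reduction = dimension_reduction),
            class = "analysis_config")
}

#' Read an analysis configuration from a JSON file
#' @param path JSON file whose keys match [analysis_config] arguments.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, raw)
}

#' Write a posterior archive
#'
#' Serialises MCMC draws as a directory of per-parameter delimited tables
#' plus a JSON manifest (seed, dimensions, chain structure), so that a
#' run can be archived and reloaded without binary formats.
#'
#' @param samples a `gjam_posterior` object from [fit_gjam].
#' @param dir output directory (created if needed).
#' @export
write_posterior_archive <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nd <- nrow(samples$B)
  flat <- function(x) matrix(x, nrow = dim(x)[1])
  utils::write.csv(cbind(chain = samples$chain, iteration = samples$iteration,
                         deviance = samples$deviance),
                   file.path(dir, "chain_index.csv"), row.names = FALSE)
  bm <- flat(samples$B)
  colnames(bm) <- as.vector(outer(samples$covariate_labels, samples$species_labels,
                                  paste, sep = ":"))
  utils::write.csv(bm, file.path(dir, "B_draws.csv"), row.names = FALSE)
  em <- flat(samples$E)
  colnames(em) <- as.vector(outer(samples$species_labels, samples$species_labels,
                                  paste, sep = ":"))
  utils::write.csv(em, file.path(dir, "E_draws.csv"), row.names = FALSE)
  manifest <- list(n_draws = nd, K = length(samples$covariate_labels),
                   P = length(samples$species_labels),
                   covariate_labels = samples$covariate_labels,
                   species_labels = samples$species_labels,
                   mode = samples$mode, seed = samples$seed,
                   config = unclass(samples$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a posterior archive written by [write_posterior_archive]
#' @param dir archive directory.
#' @return a `gjam_posterior` object (latent snapshots are not archived).
#' @export
read_posterior_archive <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  idx <- utils::read.csv(file.path(dir, "chain_index.csv"))
  K <- manifest$K; P <- manifest$P; nd <- manifest$n_draws
  bm <- as.matrix(utils::read.csv(file.path(dir, "B_draws.csv"), check.names = FALSE))
  em <- as.matrix(utils::read.csv(file.path(dir, "E_draws.csv"), check.names = FALSE))
  structure(list(B = array(bm, dim = c(nd, K, P)),
                 E = array(em, dim = c(nd, P, P)),
                 deviance = idx$deviance, chain = idx$chain,
                 iteration = idx$iteration,
                 covariate_labels = manifest$covariate_labels,
                 species_labels = manifest$species_labels,
                 mode = manifest$mode, seed = manifest$seed,
                 config = manifest$config),
            class = "gjam_posterior")
}
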