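# Pipeline orchestration: prep -> joint model (both response modes, DIC
# compared) -> consumption indices and sensitivity -> bite-force models
# -> phylogenetic trait battery, from one configuration, with a run
# manifest recording seeds, input hashes and stage timings.

.file_hash <- function(path) {
  # dependency-free content hash (djb2 over the raw bytes), good enough
  # for change detection in the manifest
  raw <- as.double(readBin(path, "raw", file.info(path)$size))
  m <- 2147483647
  w <- (31^(seq_along(raw) %% 12)) %% m
  sprintf("%d-%08x", length(raw), as.integer(sum((raw * w) %% m) %% m))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data reading and validation, rare-species
#' filtering and design encoding, the joint attribute model in both
#' presence/absence and fractional-composition modes (reporting DIC for
#' each and flagging the better fit), consumption-index and sensitivity
#' summaries, the hierarchical bite-force models (one per size
#' covariate), and the four-response phylogenetic trait battery. Any
#' stage failure halts with the stage name and cause.
#'
#' @param bats_csv,biteforce_csv,traits_csv,tree_file input paths.
#' @param config an [analysis_config].
#' @param out_dir output directory for stage CSV/JSON artifacts.
#' @param quiet suppress stage logging.
#' @return a `run_manifest` list: stage timings, input hashes, DIC
#'   comparison, output paths.
#' @export
run_all <- function(bats_csv, biteforce_csv, traits_csv, tree_file,
                    config = analysis_config(), out_dir, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[frugijam] ", ...)
  stages <- list()
  run_stage <- function(name, fn) {
    say("stage: ", name)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }

  prep <- run_stage("prep", function() {
    inp <- read_bat_table(bats_csv)
    Ypa <- filter_rare_species(inp$diet, config$rare_threshold)
    if (length(attr(Ypa, "dropped")))
      say("dropped rare plant species: ",
          paste(attr(Ypa, "dropped"), collapse = ", "))
    X <- encode_design(inp$records, config$covariates)
    Ypa <- diet_matrix(unclass(Ypa)[attr(X, "kept_rows"), , drop = FALSE],
                       "presence_absence")
    list(records = inp$records, X = X, Ypa = Ypa, Yfc = to_fractional(Ypa))
  })

  fits <- run_stage("gjam", function() {
    cfg_pa <- config; cfg_pa$mode <- "presence_absence"
    cfg_fc <- config; cfg_fc$mode <- "fractional_composition"
    fit_pa <- fit_gjam(prep$X, prep$Ypa, cfg_pa)
    fit_fc <- fit_gjam(prep$X, prep$Yfc, cfg_fc)
    list(pa = fit_pa, fc = fit_fc,
         dic = list(pa = dic(fit_pa, prep$X)$dic, fc = dic(fit_fc, prep$X)$dic))
  })
  better <- if (fits$dic$fc <= fits$dic$pa) "fractional_composition" else
    "presence_absence"
  say("DIC: PA = ", round(fits$dic$pa, 1), ", FC = ", round(fits$dic$fc, 1),
      " -> better fit: ", better)
  best_fit <- if (better == "fractional_composition") fits$fc else fits$pa

  idx <- run_stage("indices", function() {
    tab <- consumption_indices(best_fit, prob = config$hpd_prob)
    utils::write.csv(tab, file.path(out_dir, "indices.csv"), row.names = FALSE)
    sens <- sensitivity(best_fit, prob = config$hpd_prob)
    utils::write.csv(sens, file.path(out_dir, "sensitivity.csv"),
                     row.names = FALSE)
    write_posterior_archive(best_fit, file.path(out_dir, "posterior"))
    list(table = tab, sensitivity = sens)
  })

  bite <- run_stage("biteforce", function() {
    bf <- read_biteforce_table(biteforce_csv)
    fits <- lapply(c("none", "ln_mass", "ln_forearm"), function(sz)
      fit_biteforce(bf, sz, n_iterations = config$n_iterations,
                    n_burnin = config$n_burnin, thin = config$thin,
                    n_chains = config$n_chains, seed = config$rng_seed))
    names(fits) <- c("none", "ln_mass", "ln_forearm")
    r2 <- lapply(fits, variance_explained)
    cortest <- pearson_with_t(log(bf$head_length), log(bf$forearm))
    summ <- data.frame(model = names(fits),
                       r2_data = vapply(r2, `[[`, 0, "data_level"),
                       r2_species = vapply(r2, `[[`, 0, "species_level"))
    utils::write.csv(summ, file.path(out_dir, "biteforce_r2.csv"),
                     row.names = FALSE)
    list(fits = fits, r2 = summ, head_forearm = cortest)
  })

  traits <- run_stage("traits", function() {
    tr <- read_trait_table(traits_csv)
    tree <- read_newick(tree_file, required_tips = idx$table$plant)
    C <- phylo_covariance(tree, unique(idx$table$plant))
    bat <- run_trait_battery(idx$table, tr, C, seed = config$rng_seed,
                             n_iterations = config$n_iterations,
                             n_burnin = config$n_burnin, thin = config$thin)
    utils::write.csv(bat$flags, file.path(out_dir, "trait_flags.csv"),
                     row.names = FALSE)
    bat
  })

  manifest <- list(
    seed = config$rng_seed,
    config = unclass(config),
    inputs = list(bats = .file_hash(bats_csv),
                  biteforce = .file_hash(biteforce_csv),
                  traits = .file_hash(traits_csv),
                  tree = .file_hash(tree_file)),
    stage_seconds = stages,
    dic = fits$dic, better_fit = better,
    outputs = list(indices = file.path(out_dir, "indices.csv"),
                   sensitivity = file.path(out_dir, "sensitivity.csv"),
                   posterior = file.path(out_dir, "posterior"),
                   biteforce_r2 = file.path(out_dir, "biteforce_r2.csv"),
                   trait_flags = file.path(out_dir, "trait_flags.csv")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(c(manifest,
              list(indices = idx$table, sensitivity = idx$sensitivity,
                   biteforce = bite, trait_battery = traits)),
            class = "run_manifest")
}
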