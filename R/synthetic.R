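# Synthetic-data generators emulating every input table with known
# ground truth, for parameter-recovery, calibration and end-to-end
# pipeline tests. Defaults reproduce the shape of the field study: 318
# bats split 84/111/123 across the three species, ~18 plant responses
# with a zero-inflated occurrence matrix, 10 bite-force records per
# species, and a pure-birth plant tree with Brownian trait evolution.

# Species-level morphometric world (means on the raw scale, log-normal
# variation): castanea is the smallest, perspicillata the largest,
# consistent with the genus' published ranges.
.BAT_TRAITS <- list(
  perspicillata = list(forearm = 41.5, mass = 18.5, head = 23.5),
  sowelli = list(forearm = 38.5, mass = 15.0, head = 22.0),
  castanea = list(forearm = 36.0, mass = 12.5, head = 20.5))

#' Simulate a cohort of bat records (without diet)
#'
#' Species counts are multinomial with the study's mix by default;
#' forearm and mass are species-specific log-normal with correlation
#' 0.7; sex, age class and reproductive condition are categorical with
#' configurable rates (defaults: half male, mostly adults, 40%
#' reproductive).
#'
#' @param n cohort size.
#' @param species_mix probabilities over
#'   (perspicillata, sowelli, castanea).
#' @param cv_forearm,cv_mass log-scale coefficients of variation.
#' @param trait_cor forearm-mass correlation on the log scale.
#' @param age_probs,male_prob,repro_prob categorical rates.
#' @return a [bat_records] table with an all-zero occurrence matrix of
#'   zero columns (diet attached separately by [simulate_diet]).
#' @export
simulate_bats <- function(n = 318,
                          species_mix = c(84, 111, 123) / 318,
                          cv_forearm = 0.03, cv_mass = 0.10,
                          trait_cor = 0.7,
                          age_probs = c(adult = 0.78, subadult = 0.13,
                                        juvenile = 0.09),
                          male_prob = 0.5, repro_prob = 0.4) {
  if (abs(sum(species_mix) - 1) > 1e-8 || any(species_mix < 0))
    stop("species_mix must be probabilities summing to 1")
  species <- sample(BAT_SPECIES, n, replace = TRUE, prob = species_mix)
  Sig <- matrix(c(cv_forearm^2, trait_cor * cv_forearm * cv_mass,
                  trait_cor * cv_forearm * cv_mass, cv_mass^2), 2)
  z <- if (cv_forearm == 0 && cv_mass == 0) matrix(0, n, 2) else
    MASS::mvrnorm(n, c(0, 0), Sig)
  fa <- ms <- numeric(n)
  for (s in BAT_SPECIES) {
    idx <- species == s
    fa[idx] <- .BAT_TRAITS[[s]]$forearm * exp(z[idx, 1])
    ms[idx] <- .BAT_TRAITS[[s]]$mass * exp(z[idx, 2])
  }
  df <- data.frame(
    bat_id = sprintf("bat_%04d", seq_len(n)),
    species = species,
    sex = sample(SEX_LEVELS, n, TRUE, c(1 - male_prob, male_prob)),
    age_class = sample(names(age_probs), n, TRUE, age_probs),
    repro = sample(REPRO_LEVELS, n, TRUE, c(1 - repro_prob, repro_prob)),
    forearm = round(fa, 2), mass = round(ms, 2))
  occ <- matrix(integer(0), nrow = n, ncol = 0)
  colnames(occ) <- character(0)
  bat_records(df, occ)
}

#' Simulate a diet matrix from the latent joint model
#'
#' Draws latent rows W ~ N(X B_true, E_true) and maps them to
#' observations. Presence/absence: y = 1\[w > 0\]. Fractional
#' composition supports two generative conventions: `"censor"` (the
#' sampler's own likelihood — y = w on (0,1), censored to 0 below and 1
#' above; use this for parameter-recovery tests) and `"renormalize"`
#' (positive latent parts renormalized to the simplex over positive
#' cells — produces true compositions but is not the model the sampler
#' assumes).
#'
#' @param X design matrix (n x K).
#' @param B_true K x P coefficient matrix.
#' @param E_true P x P residual correlation (positive definite).
#' @param mode response mode.
#' @param fc_method fractional-composition convention (see above).
#' @param species_labels plant labels (default piper_01..P).
#' @return a [diet_matrix]; the latent matrix in `attr(out, "W")`.
#' @export
simulate_diet <- function(X, B_true, E_true,
                          mode = c("presence_absence", "fractional_composition"),
                          fc_method = c("censor", "renormalize"),
                          species_labels = NULL) {
  mode <- match.arg(mode); fc_method <- match.arg(fc_method)
  X <- as.matrix(X)
  P <- ncol(B_true)
  if (ncol(X) != nrow(B_true)) stop("design/coefficient shapes disagree")
  ev <- min(eigen(E_true, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("E_true is not positive definite")
  if (is.null(species_labels)) species_labels <- sprintf("piper_%02d", seq_len(P))
  W <- X %*% B_true + matrix(stats::rnorm(nrow(X) * P), nrow(X), P) %*% chol(E_true)
  colnames(W) <- species_labels
  if (mode == "presence_absence") {
    Y <- (W > 0) * 1L
  } else if (fc_method == "censor") {
    Y <- W
    Y[W <= 0] <- 0
    Y[W >= 1] <- 1
  } else {
    Y <- matrix(0, nrow(W), P)
    posrows <- which(apply(W, 1, function(r) any(r > 0)))
    for (i in posrows) {
      pos <- W[i, ] > 0
      Y[i, pos] <- W[i, pos] / sum(W[i, pos])
    }
    colnames(Y) <- species_labels
  }
  out <- diet_matrix(Y, mode, species_labels,
                     simplex = !(mode == "fractional_composition" &&
                                   fc_method == "censor"))
  attr(out, "W") <- W
  attr(out, "fc_method") <- if (mode == "fractional_composition") fc_method else NA
  out
}

#' Simulate a plant tree and Brownian shape traits
#'
#' Pure-birth tree scaled to unit height; fruit and seed shape indices
#' evolve by Brownian motion on the log scale (exponentiated, so indices
#' stay positive). Sister species are therefore more similar than
#' distant ones.
#'
#' @param P number of plant species (>= 2).
#' @param birth_rate pure-birth speciation rate.
#' @param trait_sigma Brownian sd over the unit-height tree.
#' @param root_fruit,root_seed root shape indices (length/width; fruits
#'   of these plants are elongated spikes, seeds nearly round).
#' @param labels tip labels (default piper_01..P).
#' @return list `tree` (phylo, unit height), `traits` (a `plant_traits`
#'   data.frame with dimensions and shape indices).
#' @export
simulate_tree_and_traits <- function(P, birth_rate = 1, trait_sigma = 0.3,
                                     root_fruit = 2.5, root_seed = 1.2,
                                     labels = NULL) {
  if (P < 2) stop("need P >= 2")
  if (is.null(labels)) labels <- sprintf("piper_%02d", seq_len(P))
  tree <- ape::rphylo(P, birth = birth_rate, death = 0)
  tree$tip.label <- labels
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  C <- phylo_covariance(tree)
  bm <- function(root) {
    if (trait_sigma == 0) rep(root, P) else
      root * exp(MASS::mvrnorm(1, rep(0, P), trait_sigma^2 * C[labels, labels]))
  }
  fruit_shape <- bm(root_fruit)
  seed_shape <- bm(root_seed)
  # back out plausible dimensions (mm): fruit width ~ 5, seed width ~ 1
  traits <- data.frame(plant_species = labels,
                       fruit_length = round(5 * fruit_shape, 3),
                       fruit_width = 5,
                       seed_length = round(1 * seed_shape, 3),
                       seed_width = 1,
                       fruit_shape_index = fruit_shape,
                       seed_shape_index = seed_shape)
  class(traits) <- c("plant_traits", "data.frame")
  list(tree = tree, traits = traits)
}

#' Default bite-force generating parameters
#'
#' The stated world for the allometric generator: log-scale head slope
#' 2.5, male effect 0.1, between-species intercept sd 0.1, residual sd
#' 0.05, baseline chosen so maximum bite forces land in the genus'
#' 9-13 N range.
#' @return named list of truth parameters.
#' @export
biteforce_truth_default <- function() {
  # head_cv 0.08 keeps within-species variation dominant, so the pooled
  # n=30 head-forearm Pearson R lands near the 0.76 within-species value
  # instead of being inflated by the collinear species means
  list(mu_alpha = -5.35, sigma_between = 0.1, sigma_within = 0.05,
       beta_sex = 0.1, beta_head = 2.5, head_cv = 0.08,
       head_forearm_cor = 0.76)
}

#' Simulate bite-force records
#'
#' Head length is species-specific log-normal; forearm is generated with
#' the stated log-scale correlation with head length; ln(bite force)
#' follows the hierarchical allometric model.
#'
#' @param n_per_species records per bat species.
#' @param truth parameter list as in [biteforce_truth_default]; a
#'   component `alpha` (named per species) may pin the intercepts,
#'   otherwise they are drawn from N(mu_alpha, sigma_between^2).
#' @return list `records` (a `biteforce_records` data.frame) and
#'   `truth` (with the realised intercepts attached).
#' @export
simulate_biteforce <- function(n_per_species = 10,
                               truth = biteforce_truth_default()) {
  if (is.null(truth$alpha)) {
    truth$alpha <- stats::setNames(
      stats::rnorm(3, truth$mu_alpha, truth$sigma_between), BAT_SPECIES)
  }
  rows <- list()
  for (s in BAT_SPECIES) {
    n <- n_per_species
    r <- truth$head_forearm_cor
    z <- MASS::mvrnorm(n, c(0, 0),
                       matrix(c(1, r, r, 1), 2) * truth$head_cv^2)
    head <- .BAT_TRAITS[[s]]$head * exp(z[, 1])
    fore <- .BAT_TRAITS[[s]]$forearm * exp(z[, 2])
    male <- stats::rbinom(n, 1, 0.5)
    lnbite <- truth$alpha[s] + truth$beta_sex * male +
      truth$beta_head * log(head) + stats::rnorm(n, 0, truth$sigma_within)
    rows[[s]] <- data.frame(
      bat_id = sprintf("bf_%s_%02d", substr(s, 1, 4), seq_len(n)),
      species = s, sex = ifelse(male == 1, "male", "female"),
      head_length = round(head, 2),
      head_width = round(head * 0.62, 2), head_height = round(head * 0.48, 2),
      forearm = round(fore, 2),
      mass = round(.BAT_TRAITS[[s]]$mass * exp(z[, 2] * 2), 2),
      max_bite_force = round(exp(lnbite), 3), eligible = TRUE)
  }
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  class(rec) <- c("biteforce_records", "data.frame")
  list(records = rec, truth = truth)
}

# Named scenarios (stated worlds) for make_fixture; latent effect sizes
# 0.3-0.7 are detectable at n = 318 without being trivial.
.scenarios <- function() {
  list(
    null = list(n = 318, P = 12, effect = 0, trait_effect = 0),
    `strong-species-effect` = list(n = 318, P = 12, effect = 0.6,
                                   effect_type = "species", trait_effect = 0),
    `forearm-effect` = list(n = 318, P = 12, effect = 0.5,
                            effect_type = "forearm", trait_effect = 0),
    `trait-effect` = list(n = 318, P = 12, effect = 0.5,
                          effect_type = "species", trait_effect = 0.8),
    `paper-shaped` = list(n = 318, P = 18, effect = 0.45,
                          effect_type = "species", trait_effect = 0))
}

#' Generating coefficient matrix for a named scenario
#'
#' Species intercept rows sit at -1.1 (zero-inflated occurrence, ~14%
#' baseline presence on the latent probit scale); planted effects
#' perturb either a species row or the forearm row on a minority of
#' plant columns; all other cells are exactly zero (null cells for
#' calibration).
#'
#' @param scenario scenario name.
#' @param K,P design/response dimensions.
#' @param covariate_labels design column labels.
#' @return K x P matrix with attribute `effect_cells` (logical matrix of
#'   planted nonzero non-intercept cells).
#' @export
scenario_coefficients <- function(scenario, K, P, covariate_labels) {
  sc <- .scenarios()[[scenario]]
  if (is.null(sc)) stop("unknown scenario: ", scenario)
  B <- matrix(0, K, P, dimnames = list(covariate_labels, NULL))
  B[intersect(BAT_SPECIES, covariate_labels), ] <- -1.1
  eff <- matrix(FALSE, K, P, dimnames = dimnames(B))
  if (sc$effect > 0) {
    target_cols <- seq_len(max(1, P %/% 4))
    if (identical(sc$effect_type, "species")) {
      B["perspicillata", target_cols] <- B["perspicillata", target_cols] + sc$effect
      B["castanea", target_cols] <- B["castanea", target_cols] - sc$effect
      eff[c("perspicillata", "castanea"), target_cols] <- TRUE
    } else {
      B["forearm", target_cols] <- sc$effect
      eff["forearm", target_cols] <- TRUE
    }
  }
  attr(B, "effect_cells") <- eff
  attr(B, "scenario") <- sc
  B
}

#' Write a complete synthetic dataset bundle to disk
#'
#' Generates all four input tables plus the Newick tree for a named
#' scenario and writes them with a JSON truth manifest, reproducibly for
#' a fixed seed.
#'
#' @param name scenario: one of `"null"`, `"strong-species-effect"`,
#'   `"forearm-effect"`, `"trait-effect"`, `"paper-shaped"`.
#' @param seed integer seed.
#' @param dir output directory.
#' @param mode diet response mode to generate.
#' @return (invisibly) list with paths and the `SyntheticTruth` list.
#' @export
make_fixture <- function(name, seed, dir,
                         mode = c("presence_absence", "fractional_composition")) {
  mode <- match.arg(mode)
  sc <- .scenarios()[[name]]
  if (is.null(sc)) stop("unknown scenario: ", name,
                        " (have: ", paste(names(.scenarios()), collapse = ", "), ")")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  recs <- simulate_bats(sc$n)
  X <- encode_design(recs)
  K <- ncol(X); P <- sc$P
  tt <- simulate_tree_and_traits(P)
  B <- scenario_coefficients(name, K, P, colnames(X))
  if (sc$trait_effect > 0) {
    # couple the forearm coefficient row to fruit shape across plants so
    # the downstream trait regression has a planted slope to recover
    B["forearm", ] <- sc$trait_effect *
      as.vector(scale(tt$traits$fruit_shape_index))
    ec <- attr(B, "effect_cells"); ec["forearm", ] <- TRUE
    attr(B, "effect_cells") <- ec
  }
  E <- 0.3 + 0.7 * diag(P)
  Y <- simulate_diet(X, B, E, mode = mode)
  occ <- if (mode == "presence_absence") unclass(Y) else (unclass(Y) > 0) * 1L
  storage.mode(occ) <- "integer"
  recs2 <- bat_records(as.data.frame(recs), occ)
  bf <- simulate_biteforce(10)
  paths <- list(bats = file.path(dir, "bats.csv"),
                biteforce = file.path(dir, "biteforce.csv"),
                traits = file.path(dir, "plant_traits.csv"),
                tree = file.path(dir, "plants.nwk"),
                truth = file.path(dir, "truth.json"))
  write_bat_table(recs2, paths$bats)
  utils::write.csv(bf$records, paths$biteforce, row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(tt$traits), paths$traits,
                   row.names = FALSE, quote = FALSE)
  ape::write.tree(tt$tree, paths$tree)
  truth <- list(scenario = name, seed = seed, mode = mode,
                n = sc$n, P = P, K = K,
                covariate_labels = colnames(X),
                species_labels = attr(Y, "species_labels"),
                B_true = B, E_offdiag = 0.3,
                effect_cells = attr(B, "effect_cells"),
                biteforce = bf$truth, trait_effect = sc$trait_effect)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(list(paths = paths, truth = truth, diet = Y, design = X))
}
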