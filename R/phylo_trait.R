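# Phylogenetic regression of consumption indices on fruit/seed shape
# traits with a Brownian-motion random effect from the plant tree.
#
# Model, per plant species p:
#   index_p = b0 + b_f * fruit_shape_p + b_s * seed_shape_p + u_p + e_p
#   u ~ N(0, s2_phylo * C),  e ~ N(0, s2_res * I)
# C is the shared-branch-length (Brownian) covariance from the tree,
# scaled to unit height. Priors: flat normals on the slopes (precision
# 1e-6), inverse-gamma(1/2, 1/2) on s2_res, and half-Cauchy on the
# phylogenetic sd (heavy-tailed, scale sqrt(1000)) via parameter
# expansion.

#' Phylogenetic (Brownian) covariance from a tree
#'
#' C\[i,j\] = branch length shared by the root-to-tip paths of tips i and
#' j, scaled so the maximum diagonal (tree height) is 1.
#'
#' @param tree an `ape` phylo object with branch lengths.
#' @param labels tip subset/order to return (all tips by default).
#' @return symmetric PSD matrix with unit maximum diagonal.
#' @export
phylo_covariance <- function(tree, labels = NULL) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  C <- ape::vcv(tree)
  if (!is.null(labels)) {
    miss <- setdiff(labels, rownames(C))
    if (length(miss)) stop("missing tip(s): ", paste(miss, collapse = ", "))
    C <- C[labels, labels, drop = FALSE]
  }
  h <- max(diag(C))
  if (h <= 0) stop("tree has zero height")
  C / h
}

#' Fit the phylogenetic trait regression by Gibbs sampling
#'
#' @param indices named numeric vector: one consumption-index value
#'   (posterior median from the joint model) per plant species.
#' @param traits a `plant_traits` data.frame carrying
#'   `fruit_shape_index` and `seed_shape_index`.
#' @param C phylogenetic covariance from [phylo_covariance]; names must
#'   cover the index names.
#' @param n_iterations,n_burnin,thin,seed MCMC controls. Published
#'   setting: 200,000 iterations, sample every 100, 10,000 burn-in; the
#'   default is a desk-scale 50,000/100/5,000.
#' @param standardize standardize the trait columns (coefficients are
#'   then per-SD effects); flags are unaffected.
#' @param hpd_prob HPD mass for the significance flags.
#' @return object of class `trait_posterior`: data.frame `draws`
#'   (intercept, beta_fruit, beta_seed, s2_phylo, s2_res), `summary`
#'   with HPDs and flags, `ess` per parameter.
#' @export
fit_trait_model <- function(indices, traits, C,
                            n_iterations = 50000L, n_burnin = 5000L,
                            thin = 100L, seed = 1L, standardize = TRUE,
                            hpd_prob = 0.95) {
  traits <- as.data.frame(traits)
  sp <- intersect(names(indices), traits$plant_species)
  if (length(sp) < 5) stop("need >= 5 plant species with traits and an index")
  y <- indices[sp]
  ti <- match(sp, traits$plant_species)
  Xt <- cbind(fruit_shape = traits$fruit_shape_index[ti],
              seed_shape = traits$seed_shape_index[ti])
  if (any(apply(Xt, 2, stats::sd) == 0)) stop("constant trait column")
  if (standardize) Xt <- scale(Xt)
  X <- cbind(intercept = 1, Xt)
  miss <- setdiff(sp, rownames(C))
  if (length(miss)) stop("covariance missing species: ", paste(miss, collapse = ", "))
  C <- C[sp, sp]
  P <- length(y); Kt <- ncol(X)
  Cinv <- solve(C + diag(1e-10, P))
  set.seed(seed)
  beta <- rep(0, Kt); u <- rep(0, P)
  s2r <- stats::var(y); s2p <- s2r; ap <- 1
  hc_scale <- sqrt(1000)
  keep <- (n_iterations - n_burnin) %/% thin
  cols <- c(colnames(X), "s2_phylo", "s2_res")
  draws <- matrix(NA_real_, keep, length(cols), dimnames = list(NULL, cols))
  pos <- 0L
  XtXbase <- crossprod(X)
  for (iter in seq_len(n_iterations)) {
    # beta | u, s2r (flat normal prior, precision 1e-6)
    V <- solve(XtXbase / s2r + diag(1e-6, Kt))
    m <- V %*% crossprod(X, y - u) / s2r
    beta <- as.vector(m + t(chol(V)) %*% stats::rnorm(Kt))
    # u | beta, s2p, s2r
    Q <- Cinv / s2p + diag(P) / s2r
    Vu <- solve(Q)
    mu <- Vu %*% ((y - X %*% beta) / s2r)
    u <- as.vector(mu + t(chol(Vu)) %*% stats::rnorm(P))
    # s2_res | .  prior IG(1/2, 1/2)  (V = 1, nu = 1)
    e <- y - X %*% beta - u
    s2r <- 1 / stats::rgamma(1, 0.5 + P / 2, 0.5 + sum(e^2) / 2)
    # s2_phylo: half-Cauchy via parameter expansion, quadratic form u'C^-1 u
    up <- .update_variance_px(as.numeric(t(u) %*% Cinv %*% u), P, ap, hc_scale)
    s2p <- up[["s2"]]; ap <- up[["a"]]
    if (iter > n_burnin && (iter - n_burnin) %% thin == 0) {
      pos <- pos + 1L
      draws[pos, ] <- c(beta, s2p, s2r)
    }
  }
  draws <- as.data.frame(draws)
  summ <- do.call(rbind, lapply(cols, function(p) {
    h <- hpd(draws[[p]], hpd_prob, min_draws = min(100L, nrow(draws)))
    data.frame(parameter = p, median = stats::median(draws[[p]]),
               hpd_lo = h[1], hpd_hi = h[2],
               significant = (p %in% colnames(Xt)) && (h[1] > 0 || h[2] < 0))
  }))
  rownames(summ) <- NULL
  structure(list(draws = draws, summary = summ, species = sp,
                 ess = vapply(draws, ess, 0), seed = seed),
            class = "trait_posterior")
}

#' @export
print.trait_posterior <- function(x, ...) {
  cat("trait_posterior:", nrow(x$draws), "draws,", length(x$species),
      "plant species\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Run the four-response trait battery
#'
#' Fits one phylogenetic trait regression per focal covariate of the
#' joint model (default: forearm, mass, and the castanea and
#' perspicillata species indices), using the posterior medians from a
#' [consumption_indices] table as the response.
#'
#' @param index_table a `consumption_index_table`.
#' @param traits a `plant_traits` table.
#' @param C phylogenetic covariance.
#' @param covariates the four focal covariates (rows of the coefficient
#'   matrix) to use as responses.
#' @param ... passed to [fit_trait_model].
#' @return named list of `trait_posterior` objects plus a `flags`
#'   data.frame (response x trait significance).
#' @export
run_trait_battery <- function(index_table, traits, C,
                              covariates = c("forearm", "mass",
                                             "castanea", "perspicillata"),
                              ...) {
  miss <- setdiff(covariates, unique(index_table$covariate))
  if (length(miss)) stop("index table lacks covariate(s): ",
                         paste(miss, collapse = ", "))
  fits <- lapply(covariates, function(cv) {
    sub <- index_table[index_table$covariate == cv, ]
    fit_trait_model(stats::setNames(sub$median, sub$plant), traits, C, ...)
  })
  names(fits) <- covariates
  flags <- do.call(rbind, lapply(covariates, function(cv) {
    s <- fits[[cv]]$summary
    data.frame(response = cv,
               fruit_significant = s$significant[s$parameter == "fruit_shape"],
               seed_significant = s$significant[s$parameter == "seed_shape"])
  }))
  list(fits = fits, flags = flags)
}
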