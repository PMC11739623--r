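# Bite-force allometry: least-squares prechecks, the hierarchical
# Bayesian scaling model with species-specific intercepts and
# half-Cauchy variance priors, Gelman-Pardoe variance explained, and the
# head-forearm correlation.
#
# Model (natural log scale):
#   ln(bite_i) = alpha_species(i) + b_sex * male_i + b_head * ln(head_i)
#                [+ b_size * ln(size_i)] + eps_i,  eps ~ N(0, sigma_w^2)
#   alpha_s ~ N(mu_alpha, sigma_b^2)
#   sigma_w, sigma_b ~ half-Cauchy(scale 25), sampled by the
#   inverse-gamma parameter-expansion identity (keeps Gibbs conjugate).

#' Ordinary least-squares precheck for bite-force predictors
#'
#' Fits bite force on sex and head length (optionally with
#' species-specific intercepts) by least squares and reports
#' coefficients with t statistics (coef/se on residual df) and two-sided
#' p values. Run on the natural-log scale by default for consistency
#' with the hierarchical models.
#'
#' @param data a `biteforce_records` data.frame.
#' @param species_intercepts add per-species intercepts.
#' @param log_scale analyse ln(bite force) and ln(head length).
#' @return data.frame `term`, `estimate`, `se`, `t`, `df`, `p`.
#' @export
fit_ols_precheck <- function(data, species_intercepts = FALSE, log_scale = TRUE) {
  df <- as.data.frame(data)
  y <- if (log_scale) log(df$max_bite_force) else df$max_bite_force
  hl <- if (log_scale) log(df$head_length) else df$head_length
  male <- as.numeric(df$sex == "male")
  if (species_intercepts) {
    fit <- stats::lm(y ~ 0 + factor(df$species) + male + hl)
  } else {
    fit <- stats::lm(y ~ male + hl)
  }
  sm <- summary(fit)$coefficients
  if (any(is.na(stats::coef(fit)))) stop("collinear predictors in precheck")
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             t = sm[, 3], df = fit$df.residual, p = sm[, 4],
             row.names = NULL)
}

# Half-Cauchy(scale A) via parameter expansion:
#   sigma^2 | a ~ IG(1/2, 1/a),  a ~ IG(1/2, 1/A^2)
# marginally sigma ~ half-Cauchy(A). Each Gibbs block below updates
# (sigma^2, a) with the data-augmented conjugate conditionals.
.update_variance_px <- function(ss, n, a, A) {
  # clamps keep the chain finite when a variance collapses toward zero
  s2 <- 1 / stats::rgamma(1, (n + 1) / 2, min(1 / a + ss / 2, 1e12))
  s2 <- min(max(s2, 1e-12), 1e12)
  a_new <- 1 / stats::rgamma(1, 1, min(1 / A^2 + 1 / s2, 1e12))
  a_new <- min(max(a_new, 1e-12), 1e12)
  c(s2 = s2, a = a_new)
}

#' Fit the hierarchical bite-force scaling model
#'
#' Gibbs sampler for the log-scale allometric model with
#' species-specific intercepts drawn from a common normal, optional body
#' size covariate (ln mass or ln forearm), and half-Cauchy priors on the
#' between- and within-species standard deviations.
#'
#' @param data a `biteforce_records` data.frame (>= 2 species with >= 2
#'   records each).
#' @param size_covariate `"none"`, `"ln_mass"` or `"ln_forearm"`.
#' @param n_iterations,n_burnin,thin,n_chains MCMC controls. The
#'   published setting is 4 chains of 500,000 with 250,000 burn-in,
#'   thinning 250; the default here is a desk-scale 4 x 20,000.
#' @param seed integer seed (chain c uses seed + c - 1).
#' @param hc_scale half-Cauchy scale for both sd priors (log-Newton
#'   scale).
#' @return object of class `biteforce_posterior`: data.frame `draws`
#'   (one row per stored draw: alpha per species, betas, mu_alpha,
#'   sigma_between, sigma_within, chain), the model frame, and
#'   convergence summaries (`psrf`, `ess`).
#' @export
fit_biteforce <- function(data, size_covariate = c("none", "ln_mass", "ln_forearm"),
                          n_iterations = 20000L, n_burnin = 10000L,
                          thin = 10L, n_chains = 4L, seed = 1L,
                          hc_scale = 25) {
  size_covariate <- match.arg(size_covariate)
  df <- as.data.frame(data)
  sp <- factor(df$species)
  if (nlevels(sp) < 2 || any(table(sp) < 2))
    stop("need >= 2 species with >= 2 records each")
  if (any(df$max_bite_force <= 0) || any(df$head_length <= 0))
    stop("bite force and head length must be positive to log")
  y <- log(df$max_bite_force)
  Xf <- cbind(male = as.numeric(df$sex == "male"),
              ln_head = log(df$head_length))
  if (size_covariate == "ln_mass") Xf <- cbind(Xf, ln_mass = log(df$mass))
  if (size_covariate == "ln_forearm") Xf <- cbind(Xf, ln_forearm = log(df$forearm))
  # center the predictors for sampling: ln(head) is nearly constant, so
  # uncentered intercepts and the head slope are close to collinear and
  # the alternating blocks mix far too slowly. Draws are de-centered
  # before storage, so reported intercepts are on the raw scale.
  centers <- colMeans(Xf)
  Xc <- sweep(Xf, 2, centers)
  n <- length(y); S <- nlevels(sp); Kf <- ncol(Xf)
  si <- as.integer(sp)
  keep <- (n_iterations - n_burnin) %/% thin
  cols <- c(paste0("alpha_", levels(sp)), colnames(Xf), "mu_alpha",
            "sigma_between", "sigma_within")
  draws <- matrix(NA_real_, keep * n_chains, length(cols),
                  dimnames = list(NULL, cols))
  chain_id <- integer(keep * n_chains)
  pos <- 0L
  for (chain in seq_len(n_chains)) {
    set.seed(seed + chain - 1L)
    alpha <- as.numeric(tapply(y, si, mean)); mu_a <- mean(alpha)
    beta <- rep(0, Kf); s2w <- stats::var(y); s2b <- s2w / 2
    aw <- ab <- 1
    XtX <- crossprod(Xc)
    for (iter in seq_len(n_iterations)) {
      # betas | alpha, s2w  (flat prior, ridge 1e-8 for stability)
      r <- y - alpha[si]
      V <- solve(XtX + diag(1e-8, Kf))
      m <- V %*% crossprod(Xc, r)
      beta <- as.vector(m + t(chol(V * s2w)) %*% stats::rnorm(Kf))
      # alpha_s | rest
      r2 <- as.vector(y - Xc %*% beta)
      for (s in seq_len(S)) {
        ns <- sum(si == s)
        prec <- ns / s2w + 1 / s2b
        mean_s <- (sum(r2[si == s]) / s2w + mu_a / s2b) / prec
        alpha[s] <- stats::rnorm(1, mean_s, sqrt(1 / prec))
      }
      # mu_alpha | alpha (flat prior)
      mu_a <- stats::rnorm(1, mean(alpha), sqrt(s2b / S))
      # variance components via parameter expansion
      up <- .update_variance_px(sum((r2 - alpha[si])^2), n, aw, hc_scale)
      s2w <- up[["s2"]]; aw <- up[["a"]]
      up <- .update_variance_px(sum((alpha - mu_a)^2), S, ab, hc_scale)
      s2b <- up[["s2"]]; ab <- up[["a"]]
      if (iter > n_burnin && (iter - n_burnin) %% thin == 0) {
        pos <- pos + 1L
        shift <- sum(beta * centers)   # de-center: raw-scale intercepts
        draws[pos, ] <- c(alpha - shift, beta, mu_a - shift,
                          sqrt(s2b), sqrt(s2w))
        chain_id[pos] <- chain
      }
    }
  }
  draws <- as.data.frame(draws)
  draws$chain <- chain_id
  conv <- .biteforce_convergence(draws, cols, n_chains)
  structure(list(draws = draws, parameters = cols,
                 species = levels(sp), size_covariate = size_covariate,
                 model_frame = data.frame(y = y, Xf, species = sp),
                 psrf = conv$psrf, ess = conv$ess, seed = seed),
            class = "biteforce_posterior")
}

.biteforce_convergence <- function(draws, cols, n_chains) {
  ps <- es <- stats::setNames(rep(NA_real_, length(cols)), cols)
  for (p in cols) {
    byc <- split(draws[[p]], draws$chain)
    if (n_chains >= 2) ps[p] <- psrf(byc)
    es[p] <- sum(vapply(byc, ess, 0))
  }
  list(psrf = ps, ess = es)
}

#' @export
print.biteforce_posterior <- function(x, ...) {
  cat("biteforce_posterior:", nrow(x$draws), "draws,",
      length(x$species), "species, size covariate:", x$size_covariate, "\n")
  qs <- t(apply(x$draws[x$parameters], 2, stats::quantile,
                c(0.025, 0.5, 0.975)))
  print(round(qs, 4))
  invisible(x)
}

#' Gelman-Pardoe variance explained by level
#'
#' For each level of the hierarchy, R^2 = 1 - E[V(errors)] / E[V(data)],
#' the expectations taken over posterior draws and V the finite-sample
#' variance across units at that level. Data level: errors are the
#' observation residuals. Species level: errors are the intercept
#' deviations alpha_s - mu_alpha against the variance of the alpha_s.
#'
#' @param posterior a `biteforce_posterior`.
#' @return list `data_level`, `species_level` (values <= 1; can be
#'   negative for a worse-than-mean model).
#' @export
variance_explained <- function(posterior) {
  mf <- posterior$model_frame
  y <- mf$y
  if (stats::var(y) == 0) stop("response has zero variance")
  Xf <- as.matrix(mf[, setdiff(names(mf), c("y", "species")), drop = FALSE])
  si <- as.integer(mf$species)
  d <- posterior$draws
  acol <- paste0("alpha_", posterior$species)
  bcol <- colnames(Xf)
  ev_res <- ev_y <- ev_a <- ev_adev <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    alpha <- as.numeric(d[i, acol])
    fitted <- alpha[si] + Xf %*% as.numeric(d[i, bcol])
    e <- y - fitted
    ev_res[i] <- stats::var(as.vector(e))
    ev_y[i] <- stats::var(as.vector(fitted + e))
    ev_a[i] <- stats::var(alpha)
    ev_adev[i] <- stats::var(alpha - d$mu_alpha[i])
  }
  list(data_level = 1 - mean(ev_res) / mean(ev_y),
       species_level = if (mean(ev_a) > 0) 1 - mean(ev_adev) / mean(ev_a) else NA_real_)
}

#' Pearson correlation with its t statistic
#'
#' @param x,y numeric vectors, length >= 3, finite.
#' @return list `R`, `t`, `df` (= n - 2), `p` (two-sided).
#' @export
pearson_with_t <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  n <- length(x)
  R <- stats::cor(x, y)
  if (abs(R) >= 1) {
    t <- sign(R) * Inf; p <- 0
  } else {
    t <- R * sqrt(n - 2) / sqrt(1 - R^2)
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  list(R = R, t = t, df = n - 2, p = p)
}

#' Sample from the half-Cauchy prior by the parameter-expansion chain
#'
#' Runs the two-block inverse-gamma Gibbs chain with no data; its
#' stationary distribution is half-Cauchy(scale). Used to verify the
#' prior implementation.
#'
#' @param n number of draws.
#' @param scale half-Cauchy scale.
#' @param thin thinning (the chain mixes fast; small thinning suffices).
#' @return vector of sd draws.
#' @export
rhalfcauchy_px <- function(n, scale = 25, thin = 5L) {
  s2 <- 1; a <- 1
  out <- numeric(n)
  for (i in seq_len(n * thin)) {
    up <- .update_variance_px(0, 0, a, scale)
    s2 <- up[["s2"]]; a <- up[["a"]]
    if (i %% thin == 0) out[i %/% thin] <- sqrt(s2)
  }
  out
}
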