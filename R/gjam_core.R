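# Joint attribute model: Gibbs sampling of latent consumption
# tendencies, coefficients and residual correlation under censoring,
# plus sensitivity, DIC, HPD summaries and posterior predictive checks.
#
# Observation model: each sample i has a latent row w_i ~ N(x_i B, Sigma)
# over P plant species. Presence/absence data censor the latent scale at
# zero (y=0 <-> w <= 0, y=1 <-> w > 0); fractional-composition data are
# observed exactly on (0,1), censored below at 0 and above at 1. The
# chain runs on the unnormalised covariance scale; every stored Sigma
# draw is rescaled to a correlation matrix E. Under presence/absence
# censoring the latent scale is unidentified, so the stored coefficient
# columns are rescaled with it (probit normalisation); fractional
# composition's exact cells anchor the scale, so B is stored as drawn.

#' Build the censoring map for a diet matrix
#'
#' For each cell, records either an exact latent value or the open/closed
#' latent interval consistent with the observation.
#'
#' @param Y a [diet_matrix].
#' @return list of class `censor_map` with matrices `lo`, `hi` (interval
#'   bounds; `lo == hi` marks nothing), logical `exact`, and `value`
#'   (the pinned latent value where `exact`).
#' @export
build_censor_map <- function(Y) {
  stopifnot(inherits(Y, "diet_matrix"))
  m <- unclass(Y); mode <- attr(Y, "mode")
  lo <- matrix(-Inf, nrow(m), ncol(m)); hi <- matrix(Inf, nrow(m), ncol(m))
  exact <- matrix(FALSE, nrow(m), ncol(m)); value <- m
  if (mode == "presence_absence") {
    hi[m == 0] <- 0
    lo[m == 1] <- 0
  } else {
    if (any(m < 0 | m > 1)) stop("fractional values outside [0,1]")
    hi[m == 0] <- 0
    lo[m == 1] <- 1
    mid <- m > 0 & m < 1
    exact[mid] <- TRUE
  }
  structure(list(lo = lo, hi = hi, exact = exact, value = value, mode = mode),
            class = "censor_map")
}

# Truncated standard-conditional normal draw via inverse CDF. Bounds may
# be infinite; numerically guarded against pnorm saturation.
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- plo + stats::runif(n) * (phi - plo)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  stats::qnorm(u, mean, sd)
}

#' One sweep of latent-variable updates
#'
#' Redraws every censored cell from its full-conditional univariate
#' normal — the conditional of row i's multivariate normal N(x_i B,
#' Sigma) given the other P-1 latent values — truncated to the cell's
#' interval. Exact (observed) cells are never touched. Cells are swept in
#' fixed column-major order.
#'
#' @param W current latent matrix (n x P).
#' @param B coefficient matrix (K x P).
#' @param Sigma residual covariance (P x P), positive definite.
#' @param X design matrix (n x K).
#' @param map a `censor_map`.
#' @return updated latent matrix.
#' @export
sample_latent <- function(W, B, Sigma, X, map) {
  P <- ncol(W)
  Mu <- X %*% B
  ev <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("residual covariance not positive definite (min eigenvalue ",
                    signif(ev, 3), ")")
  for (p in seq_len(P)) {
    cens <- !map$exact[, p]
    if (!any(cens)) next
    if (P == 1) {
      cm <- Mu[, 1]; cv <- Sigma[1, 1]
    } else {
      g <- solve(Sigma[-p, -p, drop = FALSE], Sigma[-p, p])
      cv <- Sigma[p, p] - sum(Sigma[p, -p] * g)
      cm <- Mu[, p] + (W[, -p, drop = FALSE] - Mu[, -p, drop = FALSE]) %*% g
    }
    cv <- max(cv, 1e-12)
    idx <- which(cens)
    W[idx, p] <- .rtruncnorm(length(idx), cm[idx], sqrt(cv),
                             map$lo[idx, p], map$hi[idx, p])
  }
  W
}

#' Draw the coefficient matrix from its conjugate full conditional
#'
#' Matrix-normal conditional of B given the latent matrix and residual
#' covariance, under a ridge prior with small precision tau (effectively
#' flat at the default 1e-6).
#'
#' @param W latent matrix (n x P).
#' @param Sigma residual covariance (P x P).
#' @param X design matrix, full column rank.
#' @param prior_precision ridge precision tau.
#' @return a K x P coefficient draw.
#' @export
sample_coefficients <- function(W, Sigma, X, prior_precision = 1e-6) {
  K <- ncol(X); P <- ncol(W)
  XtX <- crossprod(X) + diag(prior_precision, K)
  R <- tryCatch(chol(XtX), error = function(e) stop("design is rank deficient"))
  M <- backsolve(R, forwardsolve(t(R), crossprod(X, W)))
  Z <- matrix(stats::rnorm(K * P), K, P)
  # B = M + chol(XtX)^-1 Z chol(Sigma): matrix-normal MN(M, XtX^-1, Sigma)
  M + backsolve(R, Z) %*% chol(Sigma)
}

#' Draw the residual covariance from its inverse-Wishart full conditional
#'
#' Prior: inverse-Wishart with identity scale and P + 2 degrees of
#' freedom (proper, weakly informative, prior mean = identity).
#'
#' @param residuals n x P matrix W - XB.
#' @param prior_df,prior_scale inverse-Wishart prior (defaults P + 2, I).
#' @return a P x P covariance draw.
#' @export
sample_covariance <- function(residuals, prior_df = NULL, prior_scale = NULL) {
  n <- nrow(residuals); P <- ncol(residuals)
  if (n <= P) stop("n (", n, ") must exceed P (", P,
                   "): add samples or reduce responses (full-rank regime)")
  if (is.null(prior_df)) prior_df <- P + 2
  if (is.null(prior_scale)) prior_scale <- diag(P)
  S <- prior_scale + crossprod(residuals)
  df <- prior_df + n
  # Sigma ~ IW(df, S)  <=>  Sigma^-1 ~ Wishart(df, S^-1)
  Prec <- stats::rWishart(1, df, solve(S))[, , 1]
  Sigma <- solve(Prec)
  (Sigma + t(Sigma)) / 2
}

#' Rescale a covariance draw to correlation, adjusting coefficients
#'
#' The probit/Tobit identifiability normalisation: E = D Sigma D with
#' D = diag(Sigma)^(-1/2), and each coefficient column scaled by the
#' matching D entry.
#'
#' @param Sigma covariance draw.
#' @param B coefficient draw (columns match Sigma).
#' @return list with correlation `E` (unit diagonal exactly) and
#'   `B` rescaled.
#' @export
rescale_to_correlation <- function(Sigma, B) {
  d <- 1 / sqrt(diag(Sigma))
  E <- Sigma * tcrossprod(d)
  diag(E) <- 1
  list(E = E, B = B %*% diag(d, length(d)))
}

.gauss_deviance <- function(W, Mu, Sigma) {
  R <- chol(Sigma)
  res <- (W - Mu) %*% backsolve(R, diag(ncol(W)))
  n <- nrow(W)
  n * (ncol(W) * log(2 * pi) + 2 * sum(log(diag(R)))) + sum(res^2)
}

#' Fit the joint attribute model by Gibbs sampling
#'
#' Full loop: latent sweep, coefficient draw, covariance draw; thinned
#' post-burn-in draws are stored after rescaling to the correlation
#' scale. Per-draw deviance is the latent-Gaussian deviance given the
#' censor map (the observed-data likelihood under censoring has no
#' closed form). Chains are seeded as `seed + chain - 1`; runs are
#' deterministic given (seed, config, inputs).
#'
#' @param X a [encode_design] matrix (or any numeric design matrix).
#' @param Y a [diet_matrix].
#' @param config an [analysis_config]; `mode` must match `Y`.
#' @param prior_precision ridge precision for the coefficient prior.
#' @param store_latent store the posterior mean latent matrix (always on)
#'   and, if `TRUE`, thinned latent snapshots (memory heavy).
#' @return object of class `gjam_posterior`: arrays `B` (draws x K x P,
#'   correlation scale), `E` (draws x P x P), vectors `deviance`,
#'   `chain`, `iteration`, matrix `W_mean`, labels, config, seed.
#' @export
fit_gjam <- function(X, Y, config = analysis_config(mode = attr(Y, "mode")),
                     prior_precision = 1e-6, store_latent = FALSE) {
  stopifnot(inherits(Y, "diet_matrix"))
  if (config$mode != attr(Y, "mode"))
    stop("config mode (", config$mode, ") does not match diet matrix mode (",
         attr(Y, "mode"), ")")
  X <- as.matrix(X); n <- nrow(X); K <- ncol(X); P <- ncol(Y)
  if (nrow(Y) != n) stop("design and diet matrices disagree on n")
  if (n <= P) stop("n must exceed P for the full-rank covariance sampler")
  map <- build_censor_map(Y)
  n_keep <- (config$n_iterations - config$n_burnin) %/% config$thin
  nd <- n_keep * config$n_chains
  Bdr <- array(NA_real_, c(nd, K, P))
  Edr <- array(NA_real_, c(nd, P, P))
  dev <- numeric(nd); ch <- integer(nd); it <- integer(nd)
  Wdr <- if (store_latent) array(NA_real_, c(nd, n, P)) else NULL
  Wsum <- matrix(0, n, P); Bsum_cov <- matrix(0, K, P); Esum_cov <- matrix(0, P, P)
  pos <- 0L
  for (chain in seq_len(config$n_chains)) {
    set.seed(config$rng_seed + chain - 1L)
    # init: exact cells at y; censored cells a half-unit inside the bound
    W <- map$value
    W[!map$exact & is.finite(map$hi)] <- map$hi[!map$exact & is.finite(map$hi)] - 0.5
    low_only <- !map$exact & !is.finite(map$hi)
    W[low_only] <- map$lo[low_only] + 0.5
    B <- matrix(0, K, P); Sigma <- diag(P)
    for (iter in seq_len(config$n_iterations)) {
      W <- sample_latent(W, B, Sigma, X, map)
      B <- sample_coefficients(W, Sigma, X, prior_precision)
      Sigma <- sample_covariance(W - X %*% B)
      if (iter > config$n_burnin &&
          (iter - config$n_burnin) %% config$thin == 0) {
        d <- .gauss_deviance(W, X %*% B, Sigma)
        if (!is.finite(d)) stop("non-finite deviance at iteration ", iter)
        pos <- pos + 1L
        rs <- rescale_to_correlation(Sigma, B)
        # PA censoring removes the latent scale: store the probit-
        # normalised coefficients. FC exact cells anchor the scale, so
        # B stays on the data scale (only Sigma is reported as a
        # correlation).
        Bdr[pos, , ] <- if (map$mode == "presence_absence") rs$B else B
        Edr[pos, , ] <- rs$E
        dev[pos] <- d; ch[pos] <- chain; it[pos] <- iter
        Wsum <- Wsum + W; Bsum_cov <- Bsum_cov + B; Esum_cov <- Esum_cov + Sigma
        if (store_latent) Wdr[pos, , ] <- W
      }
    }
  }
  structure(list(B = Bdr, E = Edr, deviance = dev, chain = ch, iteration = it,
                 W_mean = Wsum / nd, B_mean_cov = Bsum_cov / nd,
                 Sigma_mean = Esum_cov / nd, W_draws = Wdr,
                 covariate_labels = colnames(X),
                 species_labels = attr(Y, "species_labels"),
                 mode = config$mode, seed = config$rng_seed, config = config,
                 n = n),
            class = "gjam_posterior")
}

#' @export
print.gjam_posterior <- function(x, ...) {
  cat("gjam_posterior:", dim(x$B)[1], "draws,",
      length(x$covariate_labels), "covariates x",
      length(x$species_labels), "plant species, mode =", x$mode, "\n")
  invisible(x)
}

#' Covariate sensitivity
#'
#' For each covariate row b_q of the coefficient matrix and each stored
#' draw, the quadratic form f_q = b_q E^-1 b_q' summarises how much that
#' covariate, weighted by the inverse residual correlation, contributes
#' to the fitted responses. Reported as posterior mean with an HPD
#' interval, ranked by mean.
#'
#' @param samples a `gjam_posterior`.
#' @param prob HPD mass.
#' @return data.frame `covariate`, `mean`, `hpd_lo`, `hpd_hi`, sorted
#'   decreasing by mean.
#' @export
sensitivity <- function(samples, prob = 0.95) {
  nd <- dim(samples$B)[1]; K <- dim(samples$B)[2]
  f <- matrix(NA_real_, nd, K)
  for (d in seq_len(nd)) {
    E <- samples$E[d, , ]
    Einv <- tryCatch(solve(E), error = function(e) {
      warning("singular correlation draw; using pseudo-inverse")
      .pseudo_inverse(E)
    })
    Bq <- samples$B[d, , , drop = TRUE]
    if (is.null(dim(Bq))) Bq <- matrix(Bq, nrow = K)
    f[d, ] <- rowSums((Bq %*% Einv) * Bq)
  }
  out <- data.frame(covariate = samples$covariate_labels,
                    mean = colMeans(f),
                    hpd_lo = apply(f, 2, function(v)
                      hpd(v, prob, min_draws = min(100L, length(v)))[1]),
                    hpd_hi = apply(f, 2, function(v)
                      hpd(v, prob, min_draws = min(100L, length(v)))[2]))
  out[order(-out$mean), ]
}

.pseudo_inverse <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval of the sorted draws containing
#' `ceiling(prob * n)` of them.
#'
#' @param draws numeric vector of posterior draws (>= 100 unless
#'   `min_draws` lowered).
#' @param prob probability mass.
#' @param min_draws guard against summarising too-short chains.
#' @return numeric `c(lo, hi)`.
#' @export
hpd <- function(draws, prob = 0.95, min_draws = 100L) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < min_draws) stop("need at least ", min_draws, " draws for an HPD")
  m <- ceiling(prob * n)
  if (m >= n) return(range(draws))
  s <- sort(draws)
  widths <- s[m:n] - s[seq_len(n - m + 1)]
  j <- which.min(widths)
  c(s[j], s[j + m - 1])
}

#' Consumption-index table
#'
#' Per (covariate, plant species): posterior median, HPD interval, and
#' the strong-response flag (HPD excludes zero) with its sign.
#'
#' @param samples a `gjam_posterior`.
#' @param covariates subset of covariate labels (default all).
#' @param prob HPD mass.
#' @return data.frame of class `consumption_index_table` with columns
#'   `covariate`, `plant`, `median`, `hpd_lo`, `hpd_hi`, `strong`,
#'   `sign`.
#' @export
consumption_indices <- function(samples, covariates = NULL, prob = 0.95) {
  if (is.null(covariates)) covariates <- samples$covariate_labels
  ki <- match(covariates, samples$covariate_labels)
  if (anyNA(ki)) stop("unknown covariate(s): ",
                      paste(covariates[is.na(ki)], collapse = ", "))
  rows <- list()
  for (a in seq_along(ki)) {
    for (p in seq_along(samples$species_labels)) {
      d <- samples$B[, ki[a], p]
      h <- hpd(d, prob, min_draws = min(100L, length(d)))
      med <- stats::median(d)
      strong <- h[1] > 0 || h[2] < 0
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = covariates[a], plant = samples$species_labels[p],
        median = med, hpd_lo = h[1], hpd_hi = h[2], strong = strong,
        sign = ifelse(!strong, 0, ifelse(med > 0, 1, -1)))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("consumption_index_table", "data.frame")
  out
}

#' Deviance information criterion
#'
#' DIC = mean deviance + pD with pD = mean deviance - deviance at the
#' posterior-mean parameters. The deviance is the latent-Gaussian
#' deviance given the censor map; the posterior-mean evaluation uses the
#' stored posterior means of B, Sigma and the latent matrix.
#'
#' @param samples a `gjam_posterior` carrying per-draw deviance.
#' @param X the design matrix used in the fit.
#' @return list `dic`, `mean_deviance`, `pD`.
#' @export
dic <- function(samples, X) {
  if (is.null(samples$deviance)) stop("no per-draw deviance stored")
  dbar <- mean(samples$deviance)
  dhat <- .gauss_deviance(samples$W_mean, as.matrix(X) %*% samples$B_mean_cov,
                          samples$Sigma_mean)
  pd <- dbar - dhat
  list(dic = dbar + pd, mean_deviance = dbar, pD = pd)
}

#' Posterior predictive simulation
#'
#' For each (thinned) stored draw, simulates latent W* ~ N(XB, E) and
#' censors to the fitted data mode (presence/absence: indicator of
#' positives; fractional composition: zeros below 0, ones above 1, exact
#' in between).
#'
#' @param samples a `gjam_posterior`.
#' @param X design matrix.
#' @param n_draws number of stored draws to use (default min(200, all)).
#' @return list of simulated response matrices.
#' @export
posterior_predict <- function(samples, X, n_draws = NULL) {
  X <- as.matrix(X)
  nd <- dim(samples$B)[1]
  if (is.null(n_draws)) n_draws <- min(200L, nd)
  use <- round(seq(1, nd, length.out = n_draws))
  P <- length(samples$species_labels)
  lapply(use, function(d) {
    B <- matrix(samples$B[d, , ], ncol = P)
    L <- chol(samples$E[d, , ] + diag(1e-10, P))
    W <- X %*% B + matrix(stats::rnorm(nrow(X) * P), nrow(X), P) %*% L
    if (samples$mode == "presence_absence") {
      (W > 0) * 1L
    } else {
      W[W < 0] <- 0; W[W > 1] <- 1
      W
    }
  })
}

#' Richness and Shannon-diversity posterior predictive summaries
#'
#' Per sample: richness = number of present (nonzero) responses; Shannon
#' diversity H = -sum y log y over the nonzero fractional entries.
#' Returns observed values alongside predictive means and central 95%
#' bands, ready for a 1:1-line check.
#'
#' @param Ysim list of simulated matrices from [posterior_predict].
#' @param Yobs observed [diet_matrix].
#' @return data.frame per sample: observed/predicted richness and
#'   diversity with 2.5/97.5% predictive quantiles.
#' @export
ppc_summaries <- function(Ysim, Yobs) {
  rich <- function(m) rowSums(m > 0)
  shan <- function(m) apply(m, 1, function(y) {
    y <- y[y > 0]
    if (!length(y)) 0 else -sum(y * log(y))
  })
  obs_r <- rich(unclass(Yobs)); obs_h <- shan(unclass(Yobs))
  sim_r <- sapply(Ysim, rich); sim_h <- sapply(Ysim, shan)
  data.frame(
    sample = seq_along(obs_r),
    richness_obs = obs_r,
    richness_pred = rowMeans(sim_r),
    richness_lo = apply(sim_r, 1, stats::quantile, 0.025),
    richness_hi = apply(sim_r, 1, stats::quantile, 0.975),
    diversity_obs = obs_h,
    diversity_pred = rowMeans(sim_h),
    diversity_lo = apply(sim_h, 1, stats::quantile, 0.025),
    diversity_hi = apply(sim_h, 1, stats::quantile, 0.975))
}
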