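test_that("censor map encodes the Tobit partitions", {
  pa <- diet_matrix(rbind(c(0, 1), c(1, 0)), "presence_absence",
                    species_labels = c("a", "b"))
  mp <- build_censor_map(pa)
  expect_equal(mp$hi[1, 1], 0)          # y=0 -> (-Inf, 0]
  expect_equal(mp$lo[1, 1], -Inf)
  expect_equal(mp$lo[1, 2], 0)          # y=1 -> (0, Inf)
  expect_equal(mp$hi[1, 2], Inf)
  expect_false(any(mp$exact))

  fc <- diet_matrix(rbind(c(0, 0.25), c(1, 0.75)), "fractional_composition",
                    species_labels = c("a", "b"), simplex = FALSE)
  mf <- build_censor_map(fc)
  expect_true(mf$exact[1, 2])           # y=0.25 exact
  expect_equal(unname(mf$value[1, 2]), 0.25)
  expect_equal(mf$hi[1, 1], 0)          # y=0 censored below
  expect_equal(mf$lo[2, 1], 1)          # y=1 -> [1, Inf)
  expect_false(mf$exact[2, 1])
})

test_that("latent updates match truncated-normal oracles", {
  # half-normal: P=1, all cells censored to (-Inf, 0], mean 0, sd 1
  n <- 1e5
  Y <- diet_matrix(matrix(0L, n, 1, dimnames = list(NULL, "a")),
                   "presence_absence")
  mp <- build_censor_map(Y)
  X <- matrix(1, n, 1)
  set.seed(1)
  W <- sample_latent(matrix(-0.5, n, 1), matrix(0, 1, 1), diag(1), X, mp)
  expect_true(all(W <= 0))
  # rejection-sampling oracle for the lower-half normal mean
  set.seed(2)
  z <- rnorm(4e5); oracle <- mean(z[z <= 0])
  expect_equal(mean(W), oracle, tolerance = 0.012)
  expect_equal(mean(W), -sqrt(2 / pi), tolerance = 0.01)

  # exact cells are never touched
  fc <- diet_matrix(matrix(c(0.3, 0.6), 50, 2, byrow = TRUE,
                           dimnames = list(NULL, c("a", "b"))),
                    "fractional_composition", simplex = FALSE)
  mf <- build_censor_map(fc)
  W0 <- mf$value
  Wk <- W0
  for (s in 1:100)
    Wk <- sample_latent(Wk, matrix(0, 1, 2), diag(2), matrix(1, 50, 1), mf)
  expect_identical(Wk, W0)

  # P=2, correlation 0.9: conditional-mean slope recovered
  Sigma <- matrix(c(1, 0.9, 0.9, 1), 2)
  n2 <- 5000
  w2 <- rnorm(n2)
  map2 <- list(lo = matrix(-Inf, n2, 2), hi = matrix(Inf, n2, 2),
               exact = cbind(rep(FALSE, n2), rep(TRUE, n2)),
               value = cbind(0, w2), mode = "fractional_composition")
  class(map2) <- "censor_map"
  set.seed(3)
  Wd <- sample_latent(cbind(0, w2), matrix(0, 1, 2), Sigma,
                      matrix(1, n2, 1), map2)
  slope <- coef(lm(Wd[, 1] ~ w2))[2]
  expect_equal(unname(slope), 0.9, tolerance = 0.03)

  # non-PD covariance is an error
  expect_error(sample_latent(cbind(0, w2), matrix(0, 1, 2),
                             matrix(c(1, 1.2, 1.2, 1), 2),
                             matrix(1, n2, 1), map2),
               "positive definite")
})

test_that("coefficient draws follow the conjugate matrix-normal", {
  set.seed(4)
  n <- 400; K <- 3; P <- 2
  X <- cbind(1, matrix(rnorm(n * (K - 1)), n, K - 1))
  W <- matrix(rnorm(n * P), n, P)
  ols <- solve(crossprod(X), crossprod(X, W))
  draws <- replicate(400, sample_coefficients(W, diag(P), X, 0))
  expect_lt(max(abs(apply(draws, c(1, 2), mean) - ols)), 0.01)
  # posterior sd shrinks like 1/sqrt(n): empirical sd ~ sqrt(diag solve(XtX))
  theo <- sqrt(diag(solve(crossprod(X))))
  expect_lt(max(abs(apply(draws, c(1, 2), sd)[, 1] - theo) / theo), 0.15)
})

test_that("covariance draws follow the inverse-Wishart conditional", {
  set.seed(5)
  R <- matrix(rnorm(4000 * 3), 4000, 3)
  E_acc <- matrix(0, 3, 3)
  for (i in 1:60) {
    S <- sample_covariance(R)
    rs <- rescale_to_correlation(S, matrix(0, 1, 3))
    expect_equal(diag(rs$E), rep(1, 3))
    expect_equal(rs$E, t(rs$E))
    E_acc <- E_acc + rs$E
  }
  E_bar <- E_acc / 60
  expect_lt(max(abs(E_bar[upper.tri(E_bar)])), 0.05)

  # known correlation 0.7 recovered
  set.seed(6)
  Z <- MASS::mvrnorm(3000, c(0, 0), matrix(c(1, 0.7, 0.7, 1), 2))
  E2 <- rescale_to_correlation(sample_covariance(Z), matrix(0, 1, 2))$E
  expect_equal(E2[1, 2], 0.7, tolerance = 0.05)
  expect_error(sample_covariance(matrix(rnorm(4), 2, 2)), "exceed")
})

test_that("hpd finds the shortest interval", {
  set.seed(7)
  h <- hpd(rnorm(1e5))
  expect_equal(h[1], -1.96, tolerance = 0.05)
  expect_equal(h[2], 1.96, tolerance = 0.05)
  expect_equal(hpd(rep(3.5, 200)), c(3.5, 3.5))
  he <- hpd(rexp(1e5))
  expect_lt(he[1], 0.02)
  expect_equal(he[2], qexp(0.95), tolerance = 0.08)
  expect_error(hpd(rnorm(50)), "at least")
})

test_that("sensitivity equals the quadratic form b E^-1 b'", {
  sf <- small_fit()$fit
  sens <- sensitivity(sf)
  # brute-force oracle on the stored draws
  nd <- dim(sf$B)[1]
  for (q in c(1, 4)) {
    fq <- sapply(seq_len(nd), function(d)
      sf$B[d, q, ] %*% solve(sf$E[d, , ]) %*% sf$B[d, q, ])
    expect_equal(sens$mean[sens$covariate == sf$covariate_labels[q]],
                 mean(fq), tolerance = 1e-10)
  }
  # zero coefficient row -> 0; unit row with E=I -> 1
  fake <- sf
  fake$B[] <- 0
  fake$B[, 2, 1] <- 1
  for (d in seq_len(nd)) fake$E[d, , ] <- diag(dim(sf$E)[2])
  s2 <- sensitivity(fake)
  expect_equal(s2$mean[s2$covariate == sf$covariate_labels[2]], 1)
  expect_equal(s2$mean[s2$covariate == sf$covariate_labels[1]], 0)
})

test_that("consumption indices flag HPD-excluding-zero cells", {
  sf <- small_fit()$fit
  tab <- consumption_indices(sf)
  expect_s3_class(tab, "consumption_index_table")
  expect_equal(nrow(tab), length(sf$covariate_labels) * length(sf$species_labels))
  expect_true(all(tab$hpd_lo <= tab$median & tab$median <= tab$hpd_hi))
  expect_identical(tab$strong, tab$hpd_lo > 0 | tab$hpd_hi < 0)
  expect_identical(tab$sign, ifelse(!tab$strong, 0, sign(tab$median)))
  # all-positive draws for a cell -> strong positive
  fake <- sf; fake$B[, 1, 1] <- abs(fake$B[, 1, 1]) + 0.1
  t2 <- consumption_indices(fake, covariates = sf$covariate_labels[1])
  expect_true(t2$strong[1] && t2$sign[1] == 1)
})

test_that("dic returns mean deviance plus pD, zero for degenerate draws", {
  sf <- small_fit()
  d <- dic(sf$fit, sf$cohort$X)
  expect_equal(d$dic, d$mean_deviance + d$pD)
  expect_true(is.finite(d$pD))
  # degenerate posterior: every draw identical -> pD == 0
  fake <- sf$fit
  nd <- dim(fake$B)[1]
  for (i in seq_len(nd)) {
    fake$B[i, , ] <- fake$B_mean_cov
    fake$E[i, , ] <- fake$Sigma_mean
  }
  # recompute the deviance each draw would have had at the mean state
  X <- sf$cohort$X
  dev0 <- frugijam:::.gauss_deviance(fake$W_mean, X %*% fake$B_mean_cov,
                                     fake$Sigma_mean)
  fake$deviance <- rep(dev0, nd)
  d2 <- dic(fake, X)
  expect_equal(d2$pD, 0)
})

test_that("fit is deterministic, respects censoring, stores valid draws", {
  co <- synth_cohort(n = 100, P = 3, seed = 9)
  cfg <- analysis_config(mode = "presence_absence", n_iterations = 300,
                         n_burnin = 100, thin = 2, n_chains = 2, rng_seed = 21)
  f1 <- fit_gjam(co$X, co$Y, cfg, store_latent = TRUE)
  f2 <- fit_gjam(co$X, co$Y, cfg, store_latent = TRUE)
  expect_identical(f1$B, f2$B)
  expect_identical(f1$deviance, f2$deviance)
  expect_equal(dim(f1$B)[1], 2 * (300 - 100) %/% 2)

  # every stored E draw: unit diagonal, symmetric, PSD
  for (d in seq_len(dim(f1$E)[1])) {
    E <- f1$E[d, , ]
    expect_equal(diag(E), rep(1, 3))
    expect_equal(E, t(E))
    expect_gt(min(eigen(E, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
  # latent snapshots respect the censor intervals
  mp <- build_censor_map(co$Y)
  for (d in seq_len(dim(f1$W_draws)[1])) {
    W <- f1$W_draws[d, , ]
    expect_true(all(W >= mp$lo & W <= mp$hi))
  }
})

test_that("posterior predictive checks recover self-simulated data", {
  sf <- small_fit()
  sims <- posterior_predict(sf$fit, sf$cohort$X, n_draws = 100)
  expect_true(all(sims[[1]] %in% c(0, 1)))
  pp <- ppc_summaries(sims, sf$cohort$Y)
  # observed richness inside the central 95% band for >= 90% of samples
  inside <- mean(pp$richness_obs >= pp$richness_lo &
                   pp$richness_obs <= pp$richness_hi)
  expect_gte(inside, 0.9)
  # FC summaries: H = log 2 for an even split, 0 for empty rows
  fc <- diet_matrix(rbind(c(0.5, 0.5), c(0, 0)), "fractional_composition",
                    species_labels = c("a", "b"))
  pp2 <- ppc_summaries(list(unclass(fc)), fc)
  expect_equal(pp2$diversity_obs, c(log(2), 0))
  expect_equal(pp2$richness_obs, c(2, 0))
})
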