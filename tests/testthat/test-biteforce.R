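test_that("OLS precheck reports coefficients, t and p", {
  set.seed(1)
  bf <- simulate_biteforce(10)$records
  # noiseless linear relation -> enormous t, p ~ 0
  bf0 <- bf
  bf0$max_bite_force <- exp(-5 + 2.5 * log(bf0$head_length) +
                              0.1 * (bf0$sex == "male"))
  out <- suppressWarnings(fit_ols_precheck(bf0))  # "essentially perfect fit"
  expect_lt(out$p[out$term == "hl"], 1e-12)
  expect_gt(abs(out$t[out$term == "hl"]), 1e5)
  expect_equal(out$df[1], nrow(bf0) - 3)

  # response orthogonal to the male dummy by construction -> coef ~ 0
  bfo <- bf
  bfo$sex <- rep(c("male", "female"), 15)
  y <- rep(c(1, -1, -1, 1), length.out = 30)  # mean zero within each sex
  bfo$head_length <- 22 * exp(rnorm(30, 0, 0.01))
  bfo$max_bite_force <- exp(y * 0.2 + 3)
  out2 <- fit_ols_precheck(bfo)
  expect_gt(out2$p[out2$term == "male"], 0.5)

  # species-intercept variant returns one intercept per species
  out3 <- fit_ols_precheck(bf, species_intercepts = TRUE)
  expect_equal(sum(grepl("species", out3$term)), 3)
})

test_that("OLS precheck CIs achieve nominal coverage on simulated data", {
  set.seed(2)
  hits <- 0; reps <- 200
  for (r in seq_len(reps)) {
    n <- 30
    hl <- rnorm(n, 3.1, 0.05)
    male <- rbinom(n, 1, 0.5)
    y <- -5 + 2.5 * hl + 0.1 * male + rnorm(n, 0, 0.05)
    df <- data.frame(max_bite_force = exp(y), head_length = exp(hl),
                     sex = ifelse(male == 1, "male", "female"),
                     species = "sowelli", bat_id = seq_len(n),
                     forearm = 38, mass = 15)
    class(df) <- c("biteforce_records", "data.frame")
    out <- fit_ols_precheck(df)
    est <- out$estimate[out$term == "hl"]; se <- out$se[out$term == "hl"]
    crit <- qt(0.975, out$df[1])
    if (est - crit * se <= 2.5 && 2.5 <= est + crit * se) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.90); expect_lt(hits / reps, 0.99)
})

test_that("hierarchical model recovers planted parameters", {
  set.seed(3)
  sim <- simulate_biteforce(20)   # n = 60
  fit <- fit_biteforce(sim$records, "none", n_iterations = 6000,
                       n_burnin = 2000, thin = 4, n_chains = 2, seed = 4)
  tr <- sim$truth
  for (par in c("ln_head", "male")) {
    d <- fit$draws[[ifelse(par == "male", "male", "ln_head")]]
    truthv <- if (par == "male") tr$beta_sex else tr$beta_head
    expect_lt(abs(mean(d) - truthv), 2 * sd(d))
  }
  # species intercepts near their realised values
  for (s in names(tr$alpha)) {
    d <- fit$draws[[paste0("alpha_", s)]]
    expect_lt(abs(mean(d) - tr$alpha[s]), 3 * sd(d))
  }
})

test_that("between-species variance shrinks to zero when absent", {
  set.seed(4)
  tr <- biteforce_truth_default()
  tr$alpha <- setNames(rep(tr$mu_alpha, 3),
                       c("perspicillata", "sowelli", "castanea"))
  sim <- simulate_biteforce(20, tr)
  fit <- fit_biteforce(sim$records, "none", n_iterations = 6000,
                       n_burnin = 2000, thin = 4, n_chains = 2, seed = 5)
  expect_lt(median(fit$draws$sigma_between), 0.05)
})

test_that("a shifted species intercept separates in the posterior", {
  set.seed(5)
  tr <- biteforce_truth_default()
  tr$alpha <- setNames(c(tr$mu_alpha, tr$mu_alpha, tr$mu_alpha + 1),
                       c("perspicillata", "sowelli", "castanea"))
  sim <- simulate_biteforce(15, tr)
  fit <- fit_biteforce(sim$records, "none", n_iterations = 6000,
                       n_burnin = 2000, thin = 4, n_chains = 2, seed = 6)
  # the marginal intercept HPDs share the head-slope uncertainty, so the
  # shift is assessed on the pairwise contrast, where it cancels
  h_diff <- hpd(fit$draws$alpha_castanea - fit$draws$alpha_sowelli)
  expect_gt(h_diff[1], 0.5)
  expect_lt(abs(median(fit$draws$alpha_castanea -
                         fit$draws$alpha_sowelli) - 1), 0.3)
})

test_that("Gelman-Pardoe variance explained matches planted ratios", {
  set.seed(6)
  # noiseless: R^2 -> 1
  tr <- biteforce_truth_default(); tr$sigma_within <- 1e-6
  sim <- simulate_biteforce(20, tr)
  fit <- fit_biteforce(sim$records, "none", n_iterations = 4000,
                       n_burnin = 1500, thin = 4, n_chains = 2, seed = 7)
  expect_gt(variance_explained(fit)$data_level, 0.999)

  # pure-noise response: R^2 ~ 0
  sim2 <- simulate_biteforce(67)   # n = 201
  noisy <- sim2$records
  set.seed(8)
  noisy$max_bite_force <- exp(rnorm(nrow(noisy), 2.4, 0.3))
  fit2 <- fit_biteforce(noisy, "none", n_iterations = 4000,
                        n_burnin = 1500, thin = 4, n_chains = 2, seed = 8)
  expect_lt(abs(variance_explained(fit2)$data_level), 0.1)

  # explained:residual variance planted 9:1 -> data-level R^2 ~ 0.9
  set.seed(9)
  n <- 300
  hl <- rnorm(n, 0, 1)             # signal variance 1 * beta^2 = 9
  y <- 3 * hl + rnorm(n, 0, 1)     # residual variance 1
  df <- data.frame(max_bite_force = exp(y / 10), head_length = exp(hl / 10),
                   sex = "female",
                   species = rep(c("perspicillata", "sowelli", "castanea"),
                                 length.out = n),
                   bat_id = seq_len(n), forearm = 38, mass = 15)
  class(df) <- c("biteforce_records", "data.frame")
  fit3 <- fit_biteforce(df, "none", n_iterations = 4000, n_burnin = 1500,
                        thin = 4, n_chains = 2, seed = 10)
  expect_equal(variance_explained(fit3)$data_level, 0.9, tolerance = 0.05)
})

test_that("pearson_with_t matches the closed-form t", {
  x <- 1:20
  expect_equal(pearson_with_t(x, x * 2 + 1)$R, 1)
  # constructed exact sample correlation 0.76 at n = 30
  set.seed(10)
  z1 <- scale(rnorm(30)); z2 <- rnorm(30)
  z2 <- scale(resid(lm(z2 ~ z1)))
  r <- 0.76
  y <- r * z1 + sqrt(1 - r^2) * z2
  pw <- pearson_with_t(as.vector(z1), as.vector(y))
  expect_equal(pw$R, 0.76, tolerance = 1e-12)
  expect_equal(pw$t, 0.76 * sqrt(28) / sqrt(1 - 0.76^2), tolerance = 1e-12)
  expect_equal(pw$df, 28)
  expect_lt(pw$p, 1e-5)
  expect_error(pearson_with_t(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("prior-only half-Cauchy chain matches the target distribution", {
  set.seed(11)
  draws <- rhalfcauchy_px(1e4, scale = 25)
  ks <- suppressWarnings(ks.test(draws, function(q) 2 / pi * atan(q / 25)))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("variance limits reproduce pooled and independent OLS", {
  # sigma_between -> 0 (forced by data pooling) handled above; here the
  # hierarchical intercepts with well-separated species approach the
  # per-species OLS intercepts
  set.seed(12)
  tr <- biteforce_truth_default()
  tr$alpha <- setNames(tr$mu_alpha + c(-0.8, 0, 0.8),
                       c("perspicillata", "sowelli", "castanea"))
  sim <- simulate_biteforce(25, tr)
  fit <- fit_biteforce(sim$records, "none", n_iterations = 6000,
                       n_burnin = 2000, thin = 4, n_chains = 2, seed = 13)
  mf <- fit$model_frame
  ols <- lm(y ~ 0 + species + male + ln_head, data = mf)
  for (s in fit$species) {
    a_hat <- mean(fit$draws[[paste0("alpha_", s)]])
    a_ols <- coef(ols)[[paste0("species", s)]]
    expect_equal(a_hat, a_ols, tolerance = 0.12)
  }
})
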