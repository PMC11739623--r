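# Shared fixture builders; everything is generated in code.

toy_bat_df <- function() {
  data.frame(
    bat_id = c("b1", "b2", "b3"),
    species = c("perspicillata", "sowelli", "castanea"),
    sex = c("male", "female", "female"),
    age_class = c("adult", "adult", "juvenile"),
    repro = c("non_reproductive", "reproductive", "non_reproductive"),
    forearm = c(41.2, 38.9, 36.1),
    mass = c(18.2, 15.1, 12.4))
}

toy_occurrence <- function() {
  m <- matrix(c(1, 0, 0, 1,
                0, 1, 0, 0,
                1, 1, 0, 1), 3, 4, byrow = TRUE)
  colnames(m) <- paste0("sp", 1:4)
  m
}

# Small synthetic cohort with diet, for design/prevalence tests.
synth_cohort <- function(n = 120, P = 5, seed = 42, effect = 0.8) {
  set.seed(seed)
  recs <- simulate_bats(n)
  X <- encode_design(recs)
  B <- matrix(0, ncol(X), P, dimnames = list(colnames(X), NULL))
  B[c("perspicillata", "sowelli", "castanea"), ] <- -0.6
  B["perspicillata", 1] <- B["perspicillata", 1] + effect
  E <- 0.2 + 0.8 * diag(P)
  Y <- simulate_diet(X, B, E, "presence_absence")
  recs <- bat_records(as.data.frame(recs), unclass(Y))
  list(records = recs, X = X, Y = Y, B = B, E = E)
}

# Small fitted gjam posterior, cached per session for summary tests.
small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- synth_cohort(n = 150, P = 6, seed = 7)
      cfg <- analysis_config(mode = "presence_absence", n_iterations = 500,
                             n_burnin = 200, thin = 2, n_chains = 2,
                             rng_seed = 5)
      cache <<- list(fit = fit_gjam(co$X, co$Y, cfg), cohort = co, cfg = cfg)
    }
    cache
  }
})
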