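# MCMC convergence diagnostics: split-chain Gelman-Rubin PSRF and
# autocorrelation-based effective sample size.

#' Potential scale reduction factor (split-chain Gelman-Rubin R-hat)
#'
#' Each chain is split in half (so within-chain non-stationarity inflates
#' the statistic) and the classical between/within variance ratio is
#' computed over the resulting 2m half-chains.
#'
#' @param chains a list of numeric vectors (>= 2 chains, equal lengths
#'   after truncation to the shortest) or a matrix with one chain per
#'   column.
#' @return scalar R-hat; approaches 1 at convergence.
#' @export
psrf <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (length(chains) < 2) stop("PSRF needs at least 2 chains")
  n <- min(lengths(chains))
  if (n < 10) stop("chains too short for PSRF (need >= 10)")
  chains <- lapply(chains, function(x) x[seq_len(n)])
  half <- n %/% 2
  splits <- unlist(lapply(chains, function(x)
    list(x[seq_len(half)], x[(n - half + 1):n])), recursive = FALSE)
  m <- length(splits); len <- half
  means <- vapply(splits, mean, 0)
  vars <- vapply(splits, stats::var, 0)
  B <- len * stats::var(means)
  Wv <- mean(vars)
  var_plus <- (len - 1) / len * Wv + B / len
  sqrt(var_plus / Wv)
}

#' Effective sample size of a single chain
#'
#' Uses the autocorrelation series truncated by Geyer's initial positive
#' sequence rule (stop when the sum of an adjacent lag pair goes
#' non-positive): ESS = n / (1 + 2 * sum rho_t).
#'
#' @param chain numeric vector (length >= 10).
#' @return effective sample size (capped at n).
#' @export
ess <- function(chain) {
  n <- length(chain)
  if (n < 10) stop("chain too short for ESS (need >= 10)")
  ac <- stats::acf(chain, lag.max = min(n - 1, 2000), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  # ac[1] is lag 0 = 1; pair lags (1,2), (3,4), ...
  s <- 0
  t <- 2
  while (t + 1 <= length(ac)) {
    pair <- ac[t] + ac[t + 1]
    if (pair <= 0) break
    s <- s + pair
    t <- t + 2
  }
  min(n, n / (1 + 2 * s))
}
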