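# Independent oracles used across the suite. None of these call the package's
# own estimation paths.

# Brute-force Poisson log-likelihood maximiser: iterative grid refinement
# over a shrinking box. The Poisson log-likelihood with log link is strictly
# concave, so the argmax stays inside the refined box as long as each new
# half-width exceeds the current grid spacing.
grid_mle <- function(y, X, half = 4, grid_n = 11L, n_zoom = 16L) {
  p <- ncol(X)
  centre <- c(log(mean(y)), rep(0, p - 1L))
  half <- rep(half, p)
  for (z in seq_len(n_zoom)) {
    grids <- lapply(seq_len(p), function(j) {
      seq(centre[j] - half[j], centre[j] + half[j], length.out = grid_n)
    })
    G <- as.matrix(expand.grid(grids))
    ETA <- X %*% t(G)
    ll <- colSums(y * ETA - exp(ETA))
    centre <- G[which.max(ll), ]
    spacing <- 2 * half / (grid_n - 1L)
    half <- 1.5 * spacing
  }
  stats::setNames(centre, colnames(X))
}

# Independent re-implementation of the three-step Monte-Carlo composition CI
# as a plain replicate loop (no vectorised sharing with the implementation).
mc_ci_oracle <- function(obs, cf, se, n_draws, seed) {
  p <- obs / sum(obs)
  G <- length(cf)
  set.seed(seed)
  d <- matrix(NA_real_, n_draws, G)
  for (r in seq_len(n_draws)) {
    x <- stats::rnorm(G, cf, se)
    d[r, ] <- 100 * (p - x / sum(x))
  }
  apply(d, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE,
        type = 7)
}

# A small fixed monthly fixture shared by several files: the built-in
# monthly demo register at its default seed, fitted once.
monthly_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- demo_scenario("monthly")
      series <- generate_group_series(sc)
      spec <- model_spec("monthly", exposure = sc$exposure)
      cache <<- list(
        scenario = sc, series = series, spec = spec,
        fits = lapply(stats::setNames(series$groups, series$groups),
                      function(g) its_poisson(series, spec, g))
      )
    }
    cache
  }
})

# Random small count series + design for oracle-equivalence checks.
random_small_problem <- function(seed) {
  set.seed(seed)
  n <- sample(8:20, 1L)
  p <- sample(1:3, 1L)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (p >= 2L) X <- cbind(X, x1 = stats::runif(n, -1, 1))
  if (p >= 3L) X <- cbind(X, x2 = stats::rbinom(n, 1L, 0.4))
  beta <- c(log(stats::runif(1, 5, 60)), stats::runif(p - 1L, -0.8, 0.8))
  y <- stats::rpois(n, exp(X %*% beta))
  if (sum(y) == 0 || qr(X)$rank < p) return(random_small_problem(seed + 1000L))
  list(y = y, X = X)
}
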