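# Independent brute-force oracles used to validate the main implementations.
# These deliberately share no code with the package internals.

# mean silhouette by direct enumeration of all pairwise distances
brute_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# minimum WCSS over every assignment of n points to k labels (k^n search,
# restricted to assignments using all k clusters)
brute_kmeans_wcss <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  assignments <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  best_assignment <- NULL
  for (r in seq_len(nrow(assignments))) {
    a <- assignments[r, ]
    if (length(unique(a)) < k) next
    wcss <- 0
    for (cl in unique(a)) {
      pts <- x[a == cl, , drop = FALSE]
      ctr <- colMeans(pts)
      wcss <- wcss + sum(sweep(pts, 2, ctr)^2)
    }
    if (wcss < best) {
      best <- wcss
      best_assignment <- a
    }
  }
  list(wcss = best, assignment = unname(best_assignment))
}

# exact Gaussian log-likelihood of the random-intercept model from the full
# n x n covariance matrix, with GLS beta at the given variance pair
full_loglik <- function(X, y, group, sigma_u, sigma_e) {
  n <- length(y)
  Z <- outer(group, unique(group), `==`) * 1
  V <- sigma_u^2 * tcrossprod(Z) + diag(sigma_e^2, n)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  ll <- -0.5 * (n * log(2 * pi) + determinant(V, logarithm = TRUE)$modulus +
                  t(r) %*% Vi %*% r)
  list(logLik = as.numeric(ll), beta = drop(beta))
}

# dense grid search plus Nelder-Mead refinement over (log sigma_u, log
# sigma_e), maximizing the exact likelihood above
grid_ml_oracle <- function(X, y, group) {
  sd_y <- stats::sd(y)
  grid_u <- c(1e-4, seq(0.05, 3, length.out = 25)) * sd_y
  grid_e <- seq(0.05, 3, length.out = 25) * sd_y
  best <- list(ll = -Inf)
  for (su in grid_u) for (se in grid_e) {
    ll <- full_loglik(X, y, group, su, se)$logLik
    if (ll > best$ll) best <- list(ll = ll, su = su, se = se)
  }
  refine <- stats::optim(log(c(best$su, best$se)), function(p) {
    -full_loglik(X, y, group, exp(p[1]), exp(p[2]))$logLik
  }, method = "Nelder-Mead",
  control = list(reltol = 1e-14, maxit = 5000))
  # also consider the sigma_u = 0 boundary
  prof_e <- stats::optimize(function(le) {
    -full_loglik(X, y, group, 1e-12, exp(le))$logLik
  }, interval = log(c(sd_y * 1e-3, sd_y * 10)), tol = 1e-12)
  if (-prof_e$objective > -refine$value) {
    sigma_u <- 0
    sigma_e <- exp(prof_e$minimum)
    ll <- -prof_e$objective
  } else {
    sigma_u <- exp(refine$par[1])
    sigma_e <- exp(refine$par[2])
    ll <- -refine$value
  }
  fit <- full_loglik(X, y, group, max(sigma_u, 1e-12), sigma_e)
  list(sigma_u = sigma_u, sigma_e = sigma_e, logLik = ll, beta = fit$beta)
}

# small model-data generator used across LMM tests
make_lmm_data <- function(n_countries = 6, obs = 5, beta = c(12, -6, 0.2),
                          sigma_u = 3, sigma_e = 4, seed = 1,
                          years = 2000:2020, p_developing = 0.6) {
  withr::with_seed(seed, {
    country <- rep(sprintf("C%02d", seq_len(n_countries)), each = obs)
    developing <- rep(stats::rbinom(n_countries, 1, p_developing), each = obs)
    if (length(unique(developing)) == 1L) developing[seq_len(obs)] <- 1 - developing[1]
    year <- sample(years, n_countries * obs, replace = TRUE)
    u <- rep(stats::rnorm(n_countries, 0, sigma_u), each = obs)
    flp <- beta[1] + beta[2] * developing + beta[3] * (year - 2000) + u +
      stats::rnorm(n_countries * obs, 0, sigma_e)
    data.frame(country = country, developing = developing, year = year,
               flp = flp, stringsAsFactors = FALSE)
  })
}

write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
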